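test_that("spike-in normalization matches the hand-evaluated offset", {
  # probe raws {8, 32}, spike-in raws {2, 8}: offset = (1 + 3) / 2 = 2
  probes <- manual_probes(target_ip = c(8, 32), target_sup = c(8, 32),
                          spike_ip = c(2, 8))
  out <- normalize_spikein(probes)
  tgt <- out[out$target_class != "spike_in", ]
  expect_equal(tgt$log2_ip_norm, c(1, 3))
  expect_equal(tgt$log2_sup_norm, c(1, 3))
  # spike-ins themselves are normalized too
  sp <- out[out$target_class == "spike_in", ]
  expect_equal(mean(sp$log2_ip_norm), 0)
})

test_that("normalization is exactly invariant to per-channel rescaling", {
  set.seed(42)
  probes <- manual_probes(target_ip = 2^runif(20, 4, 14),
                          target_sup = 2^runif(20, 4, 14),
                          spike_ip = 2^runif(8, 10, 12),
                          spike_sup = 2^runif(8, 10, 12))
  scaled <- dplyr::mutate(probes, ip_raw = ip_raw * 13.7, sup_raw = sup_raw * 0.31)
  n1 <- normalize_spikein(probes)
  n2 <- normalize_spikein(scaled)
  expect_equal(n2$log2_ip_norm, n1$log2_ip_norm, tolerance = 1e-12)
  expect_equal(n2$log2_sup_norm, n1$log2_sup_norm, tolerance = 1e-12)
})

test_that("unit spike-ins give a zero offset", {
  probes <- manual_probes(target_ip = c(4, 16), target_sup = c(2, 2),
                          spike_ip = c(1, 1, 1))
  out <- normalize_spikein(probes)
  tgt <- out[out$target_class != "spike_in", ]
  expect_equal(tgt$log2_ip_norm, log2(c(4, 16)))
  expect_equal(tgt$log2_sup_norm, log2(c(2, 2)))
})

test_that("a sample without spike-ins is a hard error naming the sample", {
  probes <- manual_probes(c(8), c(8), spike_ip = c(2))
  orphan <- dplyr::mutate(probes[probes$target_class != "spike_in", ],
                          sample_id = "s2")
  expect_error(normalize_spikein(dplyr::bind_rows(probes, orphan)), "s2")
})

test_that("QC retention implements the 3-of-6 P/M rule per channel pair", {
  flags6 <- function(ip, sup = ip) {
    tibble::tibble(
      probe_id = "p1", target_id = "t1", target_class = "circRNA",
      sample_id = paste0("s", 1:6), group = rep(c("tumor", "normal"), each = 3),
      ip_raw = 100, sup_raw = 100, ip_flag = ip, sup_flag = sup
    )
  }
  expect_true(qc_filter(flags6(c("P", "P", "M", "A", "A", "A")))$retained)
  expect_false(qc_filter(flags6(rep("A", 6)))$retained)
  expect_false(qc_filter(flags6(c("P", "M", "A", "A", "A", "A")))$retained)
  # a sample only counts when BOTH channels are P/M
  mixed <- flags6(c("P", "P", "P", "A", "A", "A"),
                  c("A", "P", "P", "P", "P", "P"))
  expect_false(qc_filter(mixed)$retained) # only samples 2,3 qualify
  # probes missing samples abort
  expect_error(qc_filter(flags6(rep("P", 6))[1:4, ], n_samples = 6), "missing samples")
})

test_that("methylation level follows IP / (IP + Sup)", {
  expect_equal(methylation_level(2.5, 2.5), 0.5)
  expect_equal(methylation_level(log2(3), log2(1)), 0.75)
  # monotone to 1 as the Sup channel vanishes
  sup <- seq(0, -30, by = -5)
  vals <- methylation_level(rep(5, length(sup)), sup)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_gt(vals[length(vals)], 0.999)
})

test_that("m6A quantity is the normalized IP intensity, untouched", {
  expect_equal(m6a_quantity(0), 0)
  expect_equal(m6a_quantity(2.5), 2.5)
  # doubling the linear IP raw with fixed spike-ins raises quantity by 1
  p1 <- manual_probes(c(64), c(16), spike_ip = c(4, 16))
  p2 <- dplyr::mutate(p1, ip_raw = ifelse(target_class == "spike_in", ip_raw, ip_raw * 2))
  q1 <- normalize_spikein(p1)
  q2 <- normalize_spikein(p2)
  d <- q2$log2_ip_norm[q2$target_class != "spike_in"] -
    q1$log2_ip_norm[q1$target_class != "spike_in"]
  expect_equal(d, 1)
  # quantity is invariant to Sup-channel perturbation
  p3 <- dplyr::mutate(p1, sup_raw = sup_raw * 100)
  q3 <- normalize_spikein(p3)
  expect_equal(q3$log2_ip_norm, q1$log2_ip_norm)
})

test_that("noiseless quantification recovers the true fraction exactly", {
  set.seed(5)
  f <- runif(200, 0.05, 0.95)
  truth <- make_truth(f_tumor = f)
  probes <- simulate_intensities(truth, noiseless_config(seed = 5))
  quants <- quantify_m6a(probes)
  merged <- dplyr::left_join(quants, truth$targets, by = "target_id")
  expect_equal(merged$modified_percent, merged$f_tumor, tolerance = 1e-12)
})
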