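test_that("annotation generation is deterministic and structurally sound", {
  cfg <- sim_config(n_genes = 50, seed = 7)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  genes <- a1$genes
  circs <- a1$circs
  expect_gt(nrow(circs), 0)

  # every circ's exons are a subset of its host's exons (exhaustive check)
  for (i in seq_len(nrow(circs))) {
    g <- genes[genes$gene_id == circs$host_gene_id[i], ]
    gex <- g$exons[[1]]
    cex <- circs$exons[[i]]
    for (j in seq_len(nrow(cex))) {
      expect_true(any(gex$start == cex$start[j] & gex$end == cex$end[j]))
    }
  }

  # exons ordered, non-overlapping; regions partition the transcript
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
    expect_equal(genes$utr5_len[i] + genes$cds_len[i] + genes$utr3_len[i],
                 genes$tx_length[i])
  }

  # spliced length equals exon-length sum, <= genomic span, equality iff 1 exon
  span <- circs$span_end - circs$span_start
  expect_true(all(circs$spliced_length <= span))
  expect_identical(circs$spliced_length == span, circs$exon_count == 1L)
})

test_that("single-exon circ model has spliced length equal to its span", {
  cc <- circ_model("c1", "chr1", data.frame(start = 100, end = 180))
  expect_equal(cc$spliced_length, 80)
  expect_equal(cc$span_end - cc$span_start, 80)
})

test_that("noiseless symmetric intensities give IP equal to Sup", {
  truth <- make_truth(f_tumor = rep(0.5, 10))
  probes <- simulate_intensities(truth, noiseless_config(seed = 1))
  tgt <- probes[probes$target_class != "spike_in", ]
  expect_equal(tgt$ip_raw, tgt$sup_raw)
})

test_that("fully unmethylated targets emit the configured intensity floor", {
  truth <- make_truth(f_tumor = rep(0, 5))
  probes <- simulate_intensities(truth, noiseless_config(seed = 1, floor = 1))
  tgt <- probes[probes$target_class != "spike_in", ]
  expect_true(all(tgt$ip_raw == 1))
  expect_true(all(tgt$sup_raw > 1))
})

test_that("QC flags follow the configured P/M/A rates", {
  truth <- make_truth(f_tumor = rep(0.4, 2000))
  probes <- simulate_intensities(truth, sim_config(
    seed = 2, flag_probs = c(P = 0.9, M = 0.05, A = 0.05)
  ))
  tgt <- probes[probes$target_class != "spike_in", ]
  rates <- table(tgt$ip_flag) / nrow(tgt)
  expect_equal(unname(rates[["P"]]), 0.9, tolerance = 0.02)
  expect_equal(unname(rates[["A"]]), 0.05, tolerance = 0.2)
})

test_that("simulated peaks overlap their source gene's exons (brute force)", {
  sim <- simulate_study(sim_config(n_genes = 20, seed = 3))
  peaks <- sim$peaks
  expect_gt(nrow(peaks), 0)
  for (i in seq_len(nrow(peaks))) {
    gid <- sub("_site\\d+$", "", peaks$name[i])
    g <- sim$genes[sim$genes$gene_id == gid, ]
    ex <- g$exons[[1]]
    hit <- any(vapply(seq_len(nrow(ex)), function(j) {
      overlaps_1bp(peaks$start[i], peaks$end[i], ex$start[j], ex$end[j])
    }, logical(1)))
    expect_true(hit)
    expect_identical(peaks$strand[i], g$strand)
    expect_equal(peaks$end[i] - peaks$start[i], sim$config$peak_width)
  }
})

test_that("no true sites yields an empty peak set", {
  truth <- list(sites = tibble::tibble(gene_id = character(),
                                       site_index = integer(), tx_pos = numeric()))
  genes <- gene_model("g1", "chr1", data.frame(start = 0, end = 300),
                      utr5_len = 50, cds_len = 200, utr3_len = 50)
  expect_equal(nrow(simulate_peaks(truth, genes)), 0)
})

test_that("the full study generator is seed-deterministic", {
  s1 <- simulate_study(sim_config(n_genes = 10, seed = 11))
  s2 <- simulate_study(sim_config(n_genes = 10, seed = 11))
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
})
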