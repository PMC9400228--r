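test_that("fold change matches direct arithmetic on both metrics", {
  expect_equal(fold_change(c(0.4, 0.4), c(0.4, 0.4), "level"),
               list(ratio = 1, log2_fc = 0))
  fc <- fold_change(c(8, 9), c(7, 8), "quantity") # +1 log2 unit
  expect_equal(fc$ratio, 2)
  expect_equal(fc$log2_fc, 1)
  expect_equal(fold_change(c(0.6, 0.6), c(0.3, 0.3), "level")$ratio, 2)
})

test_that("Welch test handles degenerate and regular inputs", {
  expect_equal(test_differential(c(0.4, 0.4, 0.4), c(0.4, 0.4, 0.4), "level"), 1)
  expect_true(is.na(test_differential(0.5, c(0.4, 0.45), "level")))
  p <- test_differential(c(8.1, 8.3, 7.9), c(7.2, 7.0, 7.4), "quantity")
  expect_true(p > 0 && p < 1)
  # agrees with a direct t.test on the transformed scale
  tum <- c(0.6, 0.62, 0.58)
  nor <- c(0.31, 0.30, 0.33)
  expect_equal(test_differential(tum, nor, "level"),
               t.test(qlogis(tum), qlogis(nor))$p.value)
})

test_that("a 5-sigma shift at n = 3 vs 3 is detected almost always", {
  set.seed(101)
  n_sim <- 400
  hits <- vapply(seq_len(n_sim), function(i) {
    tum <- rnorm(3, mean = 5, sd = 1)
    nor <- rnorm(3, mean = 0, sd = 1)
    test_differential(tum, nor, "quantity") < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("call thresholds are strict and direction-aware", {
  mk_quants <- function(tumor, normal) {
    tibble::tibble(
      target_id = "t1", target_class = "circRNA",
      sample_id = paste0("s", 1:6), group = rep(c("tumor", "normal"), each = 3),
      log2_ip_norm = 0, log2_sup_norm = 0,
      modified_percent = c(tumor, normal), quantity = log2(c(tumor, normal))
    )
  }
  up <- call_differential(mk_quants(c(0.60, 0.61, 0.59), c(0.300, 0.301, 0.299)), "level")
  expect_equal(up$direction, "up")
  expect_true(up$passes)

  # fold change 1.4: below the 1.5 gate regardless of significance
  mid <- call_differential(mk_quants(c(0.420, 0.421, 0.419), c(0.300, 0.301, 0.299)), "level")
  expect_lt(mid$p_value, 0.001)
  expect_equal(mid$direction, "none")

  dn <- call_differential(mk_quants(c(0.300, 0.301, 0.299), c(0.60, 0.61, 0.59)), "level")
  expect_equal(dn$direction, "down")
})

test_that("calls are invariant to sample order within groups", {
  sim <- simulate_study(sim_config(n_genes = 30, seed = 9))
  quants <- quantify_m6a(sim$probes)
  shuffled <- dplyr::arrange(quants, dplyr::desc(sample_id), target_id)
  c1 <- call_differential(quants, "level")
  c2 <- call_differential(shuffled, "level")
  c2 <- c2[match(c1$target_id, c2$target_id), ]
  expect_equal(c1$p_value, c2$p_value)
  expect_equal(c1$direction, c2$direction)
})

test_that("intersection obeys set algebra", {
  lv <- tibble::tibble(target_id = c("a", "b", "c"), direction = c("up", "up", "down"))
  qt <- tibble::tibble(target_id = c("b", "c", "d"), direction = c("up", "up", "down"))
  it <- intersect_calls(lv, qt)
  expect_equal(it$up_both, "b")
  expect_equal(it$down_both, character(0))

  disj <- intersect_calls(
    tibble::tibble(target_id = "a", direction = "up"),
    tibble::tibble(target_id = "b", direction = "up")
  )
  expect_equal(length(disj$up_both), 0)

  # randomized property: |both| <= min of the inputs, equal to brute force
  set.seed(77)
  universe <- sprintf("t%05d", 1:10000)
  for (i in 1:5) {
    lv_up <- sample(universe, 104); lv_dn <- sample(setdiff(universe, lv_up), 145)
    qt_up <- sample(universe, 2586); qt_dn <- sample(setdiff(universe, qt_up), 472)
    it <- intersect_calls(
      tibble::tibble(target_id = c(lv_up, lv_dn),
                     direction = rep(c("up", "down"), c(104, 145))),
      tibble::tibble(target_id = c(qt_up, qt_dn),
                     direction = rep(c("up", "down"), c(2586, 472)))
    )
    brute_up <- lv_up[vapply(lv_up, function(x) x %in% qt_up, logical(1))]
    expect_setequal(it$up_both, brute_up)
    expect_lte(length(it$up_both), min(104, 2586))
    expect_lte(length(it$down_both), min(145, 472))
    expect_equal(length(intersect(it$up_both, it$down_both)), 0)
  }
})

test_that("published up-regulated rows all survive the screen", {
  tbl <- published_call_table("up")
  screened <- screen_calls(tbl)
  expect_true(all(screened$passes))
  expect_true(all(screened$direction == "up"))
  # the top row: p = 6.559e-6, fold change 2.037 -> up
  krt7 <- screened[screened$host_gene == "KRT7", ]
  expect_equal(krt7$p_value, 6.559e-06)
  expect_equal(krt7$direction, "up")
})

test_that("published down-regulated rows screen as down under the linear reading", {
  screened <- screen_calls(published_call_table("down"))
  expect_true(all(screened$p_value < 0.05))
  expect_true(all(screened$direction == "down"))
})
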