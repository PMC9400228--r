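test_that("spliced length reproduces published single-exon spans", {
  up <- published_call_table("up")
  foxm1 <- up[up$host_gene == "FOXM1", ]
  cc <- circ_model("circFOXM1", foxm1$chrom,
                   data.frame(start = foxm1$start, end = foxm1$end))
  expect_equal(spliced_length(cc)$spliced_length, 549)
  expect_equal(foxm1$length_bp, 549)

  dn <- published_call_table("down")
  znf <- dn[dn$host_gene == "ZNF385A", ]
  cc2 <- circ_model("circZNF385A", znf$chrom,
                    data.frame(start = znf$start, end = znf$end))
  expect_equal(spliced_length(cc2)$spliced_length, 80)

  multi <- circ_model("c3", "chr1", data.frame(start = c(0, 200), end = c(100, 300)))
  expect_equal(spliced_length(multi)$spliced_length, 200)

  bad <- circ_model("c4", "chr1", data.frame(start = c(0, 200), end = c(100, 300)))
  bad$exons[[1]] <- tibble::tibble(start = c(0, 50), end = c(100, 150))
  expect_error(spliced_length(bad), "overlapping")
})

test_that("exon-count histogram equals a brute-force tally", {
  one <- circ_model("c1", "chr1", data.frame(start = c(0, 200), end = c(100, 300)))
  h1 <- exon_count_histogram(one)
  expect_equal(h1$exon_count, 2L)
  expect_equal(h1$n, 1L)

  empty <- exon_count_histogram(one[0, ])
  expect_equal(nrow(empty), 0)

  circs <- simulate_annotation(sim_config(n_genes = 60, seed = 5))$circs
  h <- exon_count_histogram(circs)
  brute <- table(circs$exon_count)
  expect_equal(h$n, as.integer(brute[as.character(h$exon_count)]))
  expect_equal(sum(h$n), nrow(circs))
  expect_equal(attr(h, "fraction_1to3"), mean(circs$exon_count <= 3))
})

test_that("length staging uses half-open 100-bp bins", {
  c250 <- circ_model("c1", "chr1", data.frame(start = 0, end = 250))
  h <- length_histogram(c250)
  expect_equal(h$bin_start, 200)
  expect_equal(h$bin_end, 300)
  expect_equal(h$n, 1L)

  c100 <- circ_model("c2", "chr1", data.frame(start = 0, end = 100))
  h2 <- length_histogram(c100)
  expect_equal(h2$bin_start, 100) # boundary goes to the upper bin

  set.seed(8)
  lens <- sample(50:2000, 1000, replace = TRUE)
  circs <- purrr::map(seq_along(lens), function(i) {
    circ_model(paste0("c", i), "chr1", data.frame(start = 0, end = lens[i]))
  }) |> purrr::list_rbind()
  h3 <- length_histogram(circs)
  brute <- table(floor(lens / 100) * 100)
  expect_equal(h3$n, as.integer(brute[as.character(h3$bin_start)]))
  expect_equal(sum(h3$n), 1000)
  # permutation invariance
  h4 <- length_histogram(circs[sample(nrow(circs)), ])
  expect_equal(h3, h4, ignore_attr = TRUE)
})

test_that("metagene profile concentrates and normalizes correctly", {
  g <- gene_model("g1", "chr1", data.frame(start = 1000, end = 2300),
                  utr5_len = 100, cds_len = 1000, utr3_len = 200)
  # all sites at the CDS start (transcript coord 100 -> genomic 1100)
  sites <- tibble::tibble(chrom = "chr1", start = rep(1100, 5), end = rep(1101, 5))
  prof <- metagene_profile(sites, g, bins_per_region = 10)
  expect_equal(sum(prof$density), 1)
  top <- prof[prof$density > 0, ]
  expect_equal(nrow(top), 1)
  expect_equal(as.character(top$region), "cds")
  expect_equal(top$bin, 1L)

  # sites exactly uniform across the CDS: flat CDS bins, empty UTR bins
  pos <- 1100:2099
  sites_u <- tibble::tibble(chrom = "chr1", start = pos, end = pos + 1)
  prof_u <- metagene_profile(sites_u, g, bins_per_region = 10)
  expect_equal(sum(prof_u$density), 1)
  cds <- prof_u[prof_u$region == "cds", ]
  expect_true(all(abs(cds$density - 0.1) < 1e-12))
  expect_true(all(prof_u$density[prof_u$region != "cds"] == 0))

  # zero sites: empty, flagged
  empty <- metagene_profile(sites[0, ], g)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_mapped"), 0L)

  # intronic/unannotated sites are excluded and counted
  off <- tibble::tibble(chrom = "chr1", start = 5000, end = 5001)
  prof_o <- metagene_profile(dplyr::bind_rows(sites, off), g, bins_per_region = 10)
  expect_equal(attr(prof_o, "n_unmapped"), 1L)
  expect_equal(sum(prof_o$density), 1)
})

test_that("circ position on the tripartite axis honours CDS halves and regions", {
  # two equal CDS exons; circ over the first CDS exon -> front half
  g <- gene_model("g1", "chr1",
                  data.frame(start = c(0, 1000, 2000, 3000),
                             end = c(100, 1500, 2500, 3200)),
                  utr5_len = 100, cds_len = 1000, utr3_len = 200)
  circ_front <- circ_model("c1", "chr1", data.frame(start = 1000, end = 1500),
                           host_gene_id = "g1")
  pos <- circ_position_in_host(circ_front, g)
  expect_equal(pos$region, "cds_front")

  circ_back <- circ_model("c2", "chr1", data.frame(start = 2000, end = 2500),
                          host_gene_id = "g1")
  expect_equal(circ_position_in_host(circ_back, g)$region, "cds_back")

  circ_utr3 <- circ_model("c3", "chr1", data.frame(start = 3000, end = 3200),
                          host_gene_id = "g1")
  expect_equal(circ_position_in_host(circ_utr3, g)$region, "utr3")

  # a circ not contained in the host errors with both ids
  stray <- circ_model("c4", "chr1", data.frame(start = 4000, end = 4100),
                      host_gene_id = "g1")
  expect_error(circ_position_in_host(stray, g), "c4.*g1")
})

test_that("region assignment is invariant under strand reversal", {
  sim <- simulate_annotation(sim_config(n_genes = 15, seed = 13))
  genes <- sim$genes
  circs <- sim$circs
  p1 <- circ_position_in_host(circs, genes)

  # mirror all coordinates and flip strands: 5'->3' logic must not change
  m <- 3e8
  flip_ex <- function(ex) {
    tibble::tibble(start = m - ex$end, end = m - ex$start) |> dplyr::arrange(start)
  }
  genes2 <- genes |>
    dplyr::mutate(strand = ifelse(strand == "+", "-", "+"),
                  exons = purrr::map(exons, flip_ex))
  circs2 <- circs |>
    dplyr::mutate(strand = ifelse(strand == "+", "-", "+"),
                  exons = purrr::map(exons, flip_ex),
                  new_start = m - span_end, new_end = m - span_start,
                  span_start = new_start, span_end = new_end) |>
    dplyr::select(-new_start, -new_end)
  p2 <- circ_position_in_host(circs2, genes2)
  expect_equal(p2$region, p1$region)
  expect_equal(p2$tx_mid, p1$tx_mid)
})
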