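#' Simulate gene and circRNA models
#'
#' Generates host-gene transcript models (ordered, non-overlapping exons
#' partitioned into 5'UTR, CDS and 3'UTR) and exon-derived circRNAs, each a
#' contiguous run of its host's exons joined by back-splicing. Exon-count and
#' spliced-length distributions are skewed toward 1-3 exons and 200-500 bp,
#' the regime the array predominantly detects. Coordinates are 0-based
#' half-open throughout.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   * `genes`: tibble, one row per gene (`gene_id`, `chrom`, `strand`,
#'     `utr5_len`, `cds_len`, `utr3_len`, `tx_length`, `n_exons`, and an
#'     `exons` list-column of `start`/`end` tibbles in genomic order);
#'   * `circs`: tibble, one row per circRNA (`circ_id`, `host_gene_id`,
#'     `chrom`, `strand`, `span_start`, `span_end`, `exon_count`,
#'     `spliced_length`, `exons` list-column).
#' @export
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 5, seed = 7))
#' ann$circs
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes

  chroms <- paste0("chr", 1:22)
  genes <- purrr::map(seq_len(n), function(i) {
    n_ex <- sample(3:10, 1)
    widths <- sample(90:320, n_ex, replace = TRUE)
    introns <- sample(200:2000, n_ex - 1, replace = TRUE)
    start0 <- sample(1e6:2e8, 1)
    starts <- start0 + cumsum(c(0, widths[-n_ex] + introns))
    exons <- tibble::tibble(start = starts, end = starts + widths)
    txlen <- sum(widths)
    utr5 <- max(1L, round(runif(1, 0.08, 0.20) * txlen))
    utr3 <- max(1L, round(runif(1, 0.15, 0.35) * txlen))
    tibble::tibble(
      gene_id = sprintf("GENE%04d", i),
      chrom = sample(chroms, 1),
      strand = sample(c("+", "-"), 1),
      utr5_len = utr5,
      cds_len = txlen - utr5 - utr3,
      utr3_len = utr3,
      tx_length = txlen,
      n_exons = n_ex,
      exons = list(exons)
    )
  }) |> purrr::list_rbind()

  circ_rows <- list()
  k <- 0L
  for (i in seq_len(n)) {
    n_circ <- rpois(1, config$n_circ_per_gene)
    if (n_circ == 0) next
    g <- genes[i, ]
    ex <- g$exons[[1]]
    for (j in seq_len(n_circ)) {
      k <- k + 1L
      n_take <- sample(1:5, 1, prob = c(0.45, 0.30, 0.15, 0.07, 0.03))
      n_take <- min(n_take, g$n_exons)
      first <- sample(seq_len(g$n_exons - n_take + 1), 1)
      cex <- ex[first:(first + n_take - 1), , drop = FALSE]
      circ_rows[[k]] <- tibble::tibble(
        circ_id = sprintf("circ_%05d", k),
        host_gene_id = g$gene_id,
        chrom = g$chrom,
        strand = g$strand,
        span_start = min(cex$start),
        span_end = max(cex$end),
        exon_count = n_take,
        spliced_length = sum(cex$end - cex$start),
        exons = list(cex)
      )
    }
  }
  circs <- if (k == 0L) empty_circs() else purrr::list_rbind(circ_rows)
  list(genes = genes, circs = circs)
}

empty_circs <- function() {
  tibble::tibble(
    circ_id = character(), host_gene_id = character(), chrom = character(),
    strand = character(), span_start = numeric(), span_end = numeric(),
    exon_count = integer(), spliced_length = numeric(), exons = list()
  )
}

#' Build a circRNA model from explicit exon intervals
#'
#' Convenience constructor used for single circRNAs, e.g. when entering a
#' published back-splice span by hand. Coordinates are 0-based half-open.
#'
#' @param circ_id Identifier.
#' @param chrom Chromosome name.
#' @param exons Tibble or data frame with `start`, `end` columns.
#' @param host_gene_id,strand,circbase_id Optional annotation fields.
#' @return One-row circRNA tibble matching [simulate_annotation()]'s `circs`.
#' @export
#' @examples
#' circ_model("c1", "chr12", data.frame(start = 2983142, end = 2983691))
circ_model <- function(circ_id, chrom, exons, host_gene_id = NA_character_,
                       strand = "+", circbase_id = NA_character_) {
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  stopifnot(nrow(exons) >= 1, all(exons$end > exons$start))
  exons <- exons[order(exons$start), ]
  tibble::tibble(
    circ_id = circ_id, circbase_id = circbase_id,
    host_gene_id = host_gene_id, chrom = chrom, strand = strand,
    span_start = min(exons$start), span_end = max(exons$end),
    exon_count = nrow(exons),
    spliced_length = sum(exons$end - exons$start),
    exons = list(exons)
  )
}

#' Build a gene model from explicit exon intervals
#'
#' Companion constructor to [circ_model()] for hand-specified transcripts.
#' Region lengths are transcript (spliced) lengths and must sum to the
#' total exon length.
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param exons Tibble or data frame with `start`, `end` (0-based half-open).
#' @param utr5_len,cds_len,utr3_len Spliced lengths of the three regions.
#' @param strand `"+"` or `"-"`.
#' @return One-row gene tibble matching [simulate_annotation()]'s `genes`.
#' @export
#' @examples
#' gene_model("g1", "chr1", data.frame(start = 0, end = 1000),
#'            utr5_len = 100, cds_len = 700, utr3_len = 200)
gene_model <- function(gene_id, chrom, exons, utr5_len, cds_len, utr3_len,
                       strand = "+") {
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  stopifnot(all(exons$end > exons$start))
  exons <- exons[order(exons$start), ]
  txlen <- sum(exons$end - exons$start)
  stopifnot(utr5_len + cds_len + utr3_len == txlen)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    utr5_len = utr5_len, cds_len = cds_len, utr3_len = utr3_len,
    tx_length = txlen, n_exons = nrow(exons), exons = list(exons)
  )
}
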