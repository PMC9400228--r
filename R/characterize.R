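#' Spliced length of circRNAs
#'
#' Sum of exon-block lengths — the length of the mature circular transcript,
#' not the genomic back-splice span. Equals the span only for single-exon
#' circRNAs.
#'
#' @param circs circRNA tibble with an `exons` list-column (or `span_start`/
#'   `span_end` for single-exon records without blocks).
#' @return The input with the `spliced_length` column (re)computed.
#' @export
#' @examples
#' circ_model("c1", "chr12", data.frame(start = 2983142, end = 2983691)) |>
#'   spliced_length()
spliced_length <- function(circs) {
  lens <- purrr::map_dbl(seq_len(nrow(circs)), function(i) {
    ex <- circs$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in circRNA '", circs$circ_id[i], "'")
    }
    sum(ex$end - ex$start)
  })
  dplyr::mutate(circs, spliced_length = lens)
}

#' Exon-count histogram of circRNAs
#'
#' Tallies circRNAs by number of exons; the companion statistic is the
#' fraction with 1-3 exons, the regime where m6A-circRNAs concentrate.
#'
#' @param circs circRNA tibble with `exon_count`.
#' @return Tibble `exon_count`, `n`, with attribute `fraction_1to3`.
#' @export
exon_count_histogram <- function(circs) {
  if (nrow(circs) == 0) {
    out <- tibble::tibble(exon_count = integer(), n = integer())
    attr(out, "fraction_1to3") <- NA_real_
    return(out)
  }
  out <- circs |>
    dplyr::count(.data$exon_count, name = "n") |>
    dplyr::arrange(.data$exon_count)
  attr(out, "fraction_1to3") <- mean(circs$exon_count >= 1 & circs$exon_count <= 3)
  out
}

#' Spliced-length histogram staged in fixed-width bins
#'
#' Stages circRNA spliced lengths into half-open bins `[0, s)`, `[s, 2s)`,
#' ... of width `stage` bp (default 100); reports alongside the fraction in
#' the 200-500 bp range where m6A-circRNAs predominate.
#'
#' @param circs circRNA tibble with `spliced_length`.
#' @param stage Bin width in bp.
#' @return Tibble `bin_start`, `bin_end`, `n`, with attribute
#'   `fraction_200to500`.
#' @export
length_histogram <- function(circs, stage = 100) {
  stopifnot(stage > 0)
  if (nrow(circs) == 0) {
    out <- tibble::tibble(bin_start = numeric(), bin_end = numeric(), n = integer())
    attr(out, "fraction_200to500") <- NA_real_
    return(out)
  }
  bin <- floor(circs$spliced_length / stage)
  out <- tibble::tibble(bin = bin) |>
    dplyr::count(.data$bin, name = "n") |>
    dplyr::transmute(bin_start = .data$bin * stage,
                     bin_end = (.data$bin + 1) * stage, n = .data$n) |>
    dplyr::arrange(.data$bin_start)
  attr(out, "fraction_200to500") <-
    mean(circs$spliced_length >= 200 & circs$spliced_length < 500)
  out
}

# Map site midpoints onto host transcripts. Returns one row per site with
# gene assignment, transcript coordinate, and tripartite axis position;
# sites whose midpoint is not exonic in any gene get NA.
map_sites_to_tx <- function(sites, genes) {
  stopifnot(nrow(genes) > 0)
  mid <- floor((sites$start + sites$end) / 2)
  exon_tbl <- genes |>
    dplyr::select("gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = mid + 1, width = 1)
  )
  exon_gr <- GenomicRanges::GRanges(
    exon_tbl$chrom, IRanges::IRanges(start = exon_tbl$start + 1, end = exon_tbl$end)
  )
  hits <- GenomicRanges::findOverlaps(site_gr, exon_gr)
  assign <- tibble::tibble(
    site = S4Vectors::queryHits(hits),
    gene_id = exon_tbl$gene_id[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::distinct(.data$site, .keep_all = TRUE) # first gene wins, deterministically

  out <- tibble::tibble(site = seq_len(nrow(sites)), mid = mid) |>
    dplyr::left_join(assign, by = "site") |>
    dplyr::left_join(genes, by = "gene_id")
  txpos <- purrr::pmap_dbl(
    list(out$mid, out$exons, out$strand, out$gene_id),
    function(m, ex, st, gid) {
      if (is.na(gid)) return(NA_real_)
      genomic_to_tx(m, ex, st)
    }
  )
  reg <- purrr::pmap_df(
    list(txpos, out$utr5_len, out$cds_len, out$utr3_len),
    function(tp, u5, cds, u3) {
      if (is.na(tp)) return(tibble::tibble(region = NA_character_, rel_pos = NA_real_, axis_pos = NA_real_))
      region_of_tx(tp, u5, cds, u3)
    }
  )
  dplyr::bind_cols(
    tibble::tibble(site_index = out$site, gene_id = out$gene_id, tx_pos = txpos),
    reg
  )
}

#' Metagene profile over the tripartite transcript axis
#'
#' Maps each site's midpoint to transcript coordinates on its host gene
#' (strand-aware), assigns it to 5'UTR, CDS or 3'UTR, normalizes the
#' position within its region, and accumulates a pooled site density over
#' `bins_per_region` bins per region. Densities sum to 1 whenever at least
#' one site maps; sites not overlapping any annotated exon are counted and
#' excluded.
#'
#' @param sites Interval tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param genes Gene models tibble.
#' @param bins_per_region Number of bins in each of the three regions.
#' @return Tibble `region`, `bin` (1-based within region), `axis_start`
#'   (pooled axis, region length 1), `density`; attributes `n_mapped` and
#'   `n_unmapped`. Zero mapped sites give an empty tibble.
#' @export
metagene_profile <- function(sites, genes, bins_per_region = 50) {
  stopifnot(bins_per_region >= 1)
  grid <- tidyr::crossing(
    region = c("utr5", "cds", "utr3"),
    bin = seq_len(bins_per_region)
  )
  if (nrow(sites) == 0) {
    out <- dplyr::mutate(grid, axis_start = NA_real_, density = NA_real_)[0, ]
    attr(out, "n_mapped") <- 0L
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  mapped <- map_sites_to_tx(sites, genes)
  ok <- !is.na(mapped$region)
  n_mapped <- sum(ok)
  if (n_mapped == 0) {
    out <- dplyr::mutate(grid, axis_start = NA_real_, density = NA_real_)[0, ]
    attr(out, "n_mapped") <- 0L
    attr(out, "n_unmapped") <- nrow(sites)
    return(out)
  }
  m <- mapped[ok, ]
  m$bin <- pmin(floor(m$rel_pos * bins_per_region) + 1L, bins_per_region)
  counts <- m |>
    dplyr::count(.data$region, .data$bin, name = "n")
  out <- grid |>
    dplyr::left_join(counts, by = c("region", "bin")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      region = factor(.data$region, levels = c("utr5", "cds", "utr3")),
      axis_start = (as.integer(.data$region) - 1) + (.data$bin - 1) / bins_per_region,
      density = .data$n / n_mapped
    ) |>
    dplyr::arrange(.data$axis_start) |>
    dplyr::select("region", "bin", "axis_start", "density")
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_unmapped") <- as.integer(nrow(sites) - n_mapped)
  out
}

#' Position of circRNAs within their host transcript
#'
#' Maps each circRNA's spliced midpoint (in host transcript coordinates)
#' onto the tripartite 5'UTR/CDS/3'UTR axis and labels the CDS half it falls
#' in: `cds_front` for normalized CDS position < 0.5, `cds_back` otherwise.
#'
#' @param circs circRNA tibble; every circRNA's exons must be contained in
#'   its host gene's exons.
#' @param genes Gene models tibble.
#' @return Tibble `circ_id`, `host_gene_id`, `tx_mid`, `region` (one of
#'   `utr5`, `cds_front`, `cds_back`, `utr3`), `axis_pos`.
#' @export
circ_position_in_host <- function(circs, genes) {
  purrr::map(seq_len(nrow(circs)), function(i) {
    cc <- circs[i, ]
    g <- gene_row(genes, cc$host_gene_id)
    gex <- g$exons[[1]]
    cex <- cc$exons[[1]]
    contained <- purrr::map_lgl(seq_len(nrow(cex)), function(j) {
      any(gex$start <= cex$start[j] & gex$end >= cex$end[j])
    })
    if (!all(contained)) {
      stop("circRNA '", cc$circ_id, "' has exons outside host gene '", g$gene_id, "'")
    }
    # transcript interval covered by the circ: map first/last circ bases
    tx_ends <- genomic_to_tx(c(min(cex$start), max(cex$end) - 1), gex, g$strand)
    tx_mid <- floor(mean(range(tx_ends)))
    reg <- region_of_tx(tx_mid, g$utr5_len, g$cds_len, g$utr3_len)
    region <- reg$region
    if (region == "cds") region <- if (reg$rel_pos < 0.5) "cds_front" else "cds_back"
    tibble::tibble(circ_id = cc$circ_id, host_gene_id = g$gene_id,
                   tx_mid = tx_mid, region = region, axis_pos = reg$axis_pos)
  }) |> purrr::list_rbind()
}

#' Per-chromosome circRNA counts
#'
#' @param circs circRNA tibble.
#' @return Tibble `chrom`, `n`.
#' @export
chromosome_counts <- function(circs) {
  dplyr::count(circs, .data$chrom, name = "n")
}
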