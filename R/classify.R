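#' Host-gene m6A status from peak intervals
#'
#' A gene counts as m6A-methylated when at least one peak interval overlaps
#' at least one of its exons by >= 1 bp (exonic overlap only; intronic peaks
#' do not count). For each overlapping peak whose midpoint is exonic, the
#' tripartite region of the midpoint (`utr5`/`cds`/`utr3`) is reported.
#'
#' @param genes Gene models tibble.
#' @param peaks Peak interval tibble (`chrom`, `start`, `end`, optional
#'   `strand`; 0-based half-open). Unstranded peaks (`.` or absent) match
#'   either strand.
#' @return Tibble `gene_id`, `host_methylated`, `peak_regions` (list-column
#'   of region labels, possibly empty).
#' @export
host_m6a_status <- function(genes, peaks) {
  empty <- tibble::tibble(
    gene_id = genes$gene_id,
    host_methylated = FALSE,
    peak_regions = purrr::map(genes$gene_id, ~character())
  )
  if (nrow(peaks) == 0) return(empty)

  exon_tbl <- genes |>
    dplyr::select("gene_id", "chrom", "strand", "exons") |>
    tidyr::unnest("exons")
  exon_gr <- GenomicRanges::GRanges(
    exon_tbl$chrom,
    IRanges::IRanges(start = exon_tbl$start + 1, end = exon_tbl$end),
    strand = exon_tbl$strand
  )
  pk_strand <- if ("strand" %in% names(peaks)) peaks$strand else rep("*", nrow(peaks))
  pk_strand[is.na(pk_strand) | pk_strand == "."] <- "*"
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(start = peaks$start + 1, end = peaks$end),
    strand = pk_strand
  )
  hits <- GenomicRanges::findOverlaps(peak_gr, exon_gr, minoverlap = 1)
  if (length(hits) == 0) return(empty)

  hit_tbl <- tibble::tibble(
    peak = S4Vectors::queryHits(hits),
    gene_id = exon_tbl$gene_id[S4Vectors::subjectHits(hits)]
  ) |> dplyr::distinct()

  # region of each overlapping peak's midpoint on that gene's transcript
  regions <- hit_tbl |>
    dplyr::mutate(
      region = purrr::map2_chr(.data$peak, .data$gene_id, function(p, gid) {
        g <- gene_row(genes, gid)
        mid <- floor((peaks$start[p] + peaks$end[p]) / 2)
        tp <- genomic_to_tx(mid, g$exons[[1]], g$strand)
        if (is.na(tp)) return(NA_character_)
        region_of_tx(tp, g$utr5_len, g$cds_len, g$utr3_len)$region
      })
    ) |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(peak_regions = list(.data$region), .groups = "drop")

  tibble::tibble(gene_id = genes$gene_id) |>
    dplyr::mutate(host_methylated = .data$gene_id %in% hit_tbl$gene_id) |>
    dplyr::left_join(regions, by = "gene_id") |>
    dplyr::mutate(peak_regions = purrr::map(.data$peak_regions, ~ if (is.null(.x)) character() else .x))
}

#' Four-way circRNA subgroup label
#'
#' The joint m6A taxonomy: neither transcript methylated (`neither`), host
#' mRNA only (`host_only`), circRNA only (`circ_only`), or both (`both`).
#'
#' @param circ_methylated,host_methylated Logical vectors (recycled to a
#'   common length).
#' @return Factor with levels `neither`, `host_only`, `circ_only`, `both`.
#' @export
#' @examples
#' classify_circ(c(FALSE, TRUE), c(FALSE, TRUE))
classify_circ <- function(circ_methylated, host_methylated) {
  stopifnot(!anyNA(circ_methylated), !anyNA(host_methylated))
  lab <- dplyr::case_when(
    !circ_methylated & !host_methylated ~ "neither",
    !circ_methylated & host_methylated ~ "host_only",
    circ_methylated & !host_methylated ~ "circ_only",
    TRUE ~ "both"
  )
  factor(lab, levels = c("neither", "host_only", "circ_only", "both"))
}

#' Classify every circRNA by joint circ/host m6A status
#'
#' Binarizes each circRNA's own microarray m6A state and combines it with
#' its host gene's MeRIP-seq peak status via [classify_circ()]. Two
#' binarization modes are exposed: `"threshold"` (default) calls a circRNA
#' methylated when its mean tumor-group modified percent exceeds
#' `level_threshold`; `"calls"` uses membership in the dual-criterion
#' up/down universe of an [intersect_calls()] result.
#'
#' @param circs circRNA tibble.
#' @param genes Gene models tibble.
#' @param peaks Peak interval tibble.
#' @param quants [quantify_m6a()] output (needed for `mode = "threshold"`).
#' @param intersection [intersect_calls()] result (for `mode = "calls"`).
#' @param mode `"threshold"` or `"calls"`.
#' @param level_threshold Modified-percent cutoff for threshold mode.
#' @return Tibble `circ_id`, `host_gene_id`, `circ_methylated`,
#'   `host_methylated`, `label`, `host_peak_regions`.
#' @export
classify_subgroups <- function(circs, genes, peaks, quants = NULL,
                               intersection = NULL,
                               mode = c("threshold", "calls"),
                               level_threshold = 0.2) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    stopifnot(!is.null(quants))
    tumor_level <- quants |>
      dplyr::filter(.data$group == "tumor", .data$target_id %in% circs$circ_id) |>
      dplyr::group_by(.data$target_id) |>
      dplyr::summarise(mean_level = mean(.data$modified_percent), .groups = "drop")
    circ_meth <- setNames(tumor_level$mean_level > level_threshold, tumor_level$target_id)
  } else {
    stopifnot(!is.null(intersection))
    universe <- union(intersection$up_both, intersection$down_both)
    circ_meth <- setNames(circs$circ_id %in% universe, circs$circ_id)
  }
  if (!all(circs$circ_id %in% names(circ_meth))) {
    miss <- setdiff(circs$circ_id, names(circ_meth))
    stop("no quantification for circRNA(s): ", paste(head(miss, 10), collapse = ", "))
  }
  host <- host_m6a_status(genes, peaks)
  out <- circs |>
    dplyr::select("circ_id", "host_gene_id") |>
    dplyr::left_join(host, by = c(host_gene_id = "gene_id")) |>
    dplyr::mutate(
      circ_methylated = unname(circ_meth[.data$circ_id]),
      label = classify_circ(.data$circ_methylated, .data$host_methylated)
    ) |>
    dplyr::rename(host_peak_regions = "peak_regions") |>
    dplyr::select("circ_id", "host_gene_id", "circ_methylated",
                  "host_methylated", "label", "host_peak_regions")
  out
}

#' Tally of subgroup labels
#'
#' @param labels Tibble with a `label` column (or a factor of labels).
#' @return Tibble `label`, `n` with all four levels present (zeros kept).
#' @export
subgroup_summary <- function(labels) {
  lv <- c("neither", "host_only", "circ_only", "both")
  x <- if (is.data.frame(labels)) labels$label else labels
  x <- factor(x, levels = lv)
  tibble::tibble(label = factor(lv, levels = lv),
                 n = as.integer(table(x)[lv]))
}
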