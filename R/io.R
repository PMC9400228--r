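#' Read a probe-intensity table
#'
#' TSV with columns `probe_id`, `target_id`, `target_class`, `sample_id`,
#' `group`, `ip_raw`, `sup_raw`, `ip_flag`, `sup_flag`. Intensities below
#' the floor (including negatives) are clipped up to it with a single
#' warning reporting how many values were floored.
#'
#' @param path File path.
#' @param floor Intensity floor epsilon.
#' @return Validated probe-record tibble.
#' @export
read_probe_table <- function(path, floor = 1) {
  cols <- c("probe_id", "target_id", "target_class", "sample_id", "group",
            "ip_raw", "sup_raw", "ip_flag", "sup_flag")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(cols %in% names(x))) {
    stop("probe table missing column(s): ", paste(setdiff(cols, names(x)), collapse = ", "))
  }
  x <- x[cols]
  bad_num <- which(!is.finite(x$ip_raw) | !is.finite(x$sup_raw))
  if (length(bad_num) > 0) {
    stop("malformed intensity at data row(s): ", paste(head(bad_num, 10), collapse = ", "))
  }
  bad_class <- unique(x$target_class[!x$target_class %in% c("circRNA", "mRNA", "spike_in")])
  if (length(bad_class) > 0) stop("unknown target_class: ", paste(bad_class, collapse = ", "))
  bad_flag <- !x$ip_flag %in% c("P", "M", "A") | !x$sup_flag %in% c("P", "M", "A")
  if (any(bad_flag)) {
    stop("invalid QC flag at data row(s): ", paste(head(which(bad_flag), 10), collapse = ", "))
  }
  dup <- duplicated(x[c("probe_id", "sample_id")])
  if (any(dup)) {
    stop("duplicate (probe_id, sample_id) row(s): ",
         paste(head(paste(x$probe_id[dup], x$sample_id[dup]), 10), collapse = ", "))
  }
  n_floored <- sum(x$ip_raw < floor) + sum(x$sup_raw < floor)
  if (n_floored > 0) {
    warning(n_floored, " intensit", if (n_floored == 1) "y" else "ies",
            " below floor ", floor, "; clipped")
    x$ip_raw <- pmax(x$ip_raw, floor)
    x$sup_raw <- pmax(x$sup_raw, floor)
  }
  tibble::as_tibble(x)
}

#' Write a probe-intensity table
#' @param probes Probe-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(path)
}

# Genomic sub-intervals of a gene's 5'UTR/CDS/3'UTR, obtained by cutting
# each exon at the region boundaries in transcript coordinates.
gene_region_intervals <- function(gene) {
  ex <- exons_tx_order(gene$exons[[1]], gene$strand)
  widths <- ex$end - ex$start
  offsets <- cumsum(c(0, widths[-length(widths)]))
  bounds <- c(utr5 = 0, cds = gene$utr5_len,
              utr3 = gene$utr5_len + gene$cds_len,
              end = gene$tx_length)
  pieces <- list()
  for (i in seq_len(nrow(ex))) {
    for (r in c("utr5", "cds", "utr3")) {
      lo <- max(offsets[i], bounds[[r]])
      hi <- min(offsets[i] + widths[i], bounds[[which(names(bounds) == r) + 1]])
      if (hi <= lo) next
      a <- lo - offsets[i]
      b <- hi - offsets[i]
      gi <- if (identical(gene$strand, "-")) {
        c(start = ex$end[i] - b, end = ex$end[i] - a)
      } else {
        c(start = ex$start[i] + a, end = ex$start[i] + b)
      }
      pieces[[length(pieces) + 1]] <-
        tibble::tibble(start = gi[["start"]], end = gi[["end"]], region = r)
    }
  }
  purrr::list_rbind(pieces) |> dplyr::arrange(.data$start)
}

#' Write gene models as GTF
#'
#' Emits `exon`, `CDS`, `five_prime_utr` and `three_prime_utr` features
#' (1-based inclusive coordinates, converted from the internal 0-based
#' half-open models).
#'
#' @param genes Gene models tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gtf <- function(genes, path) {
  feature_name <- c(utr5 = "five_prime_utr", cds = "CDS", utr3 = "three_prime_utr")
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id, g$gene_id)
    ex <- g$exons[[1]]
    exon_rows <- tibble::tibble(
      chrom = g$chrom, source = "circm6a", feature = "exon",
      start = ex$start + 1, end = ex$end, score = ".",
      strand = g$strand, frame = ".", attrs = attrs
    )
    reg <- gene_region_intervals(g)
    reg_rows <- tibble::tibble(
      chrom = g$chrom, source = "circm6a",
      feature = feature_name[reg$region],
      start = reg$start + 1, end = reg$end, score = ".",
      strand = g$strand, frame = ".", attrs = attrs
    )
    dplyr::bind_rows(exon_rows, reg_rows)
  }) |> purrr::list_rbind()
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE,
                   quote = "none", escape = "none")
  invisible(path)
}

#' Write circRNA models as BED12
#'
#' The back-splice span is the BED interval; exon blocks go in the block
#' fields. The name field is `circ_id|host_gene_id` so the host linkage
#' survives the round trip.
#'
#' @param circs circRNA tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(circs, path) {
  rows <- purrr::map(seq_len(nrow(circs)), function(i) {
    cc <- circs[i, ]
    ex <- cc$exons[[1]]
    ex <- ex[order(ex$start), ]
    tibble::tibble(
      chrom = cc$chrom, start = cc$span_start, end = cc$span_end,
      name = paste0(cc$circ_id, "|", cc$host_gene_id), score = 0,
      strand = cc$strand, thick_start = cc$span_start, thick_end = cc$span_end,
      rgb = "0,0,0", block_count = nrow(ex),
      block_sizes = paste0(paste(ex$end - ex$start, collapse = ","), ","),
      block_starts = paste0(paste(ex$start - cc$span_start, collapse = ","), ",")
    )
  }) |> purrr::list_rbind()
  readr::write_tsv(rows, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write peak intervals as BED6
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `name`, `score`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(peaks, path) {
  readr::write_tsv(peaks[c("chrom", "start", "end", "name", "score", "strand")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read peak intervals from BED
#' @param path BED6 path (0-based half-open, as BED is defined).
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_peak_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read gene and circRNA models
#'
#' GTF (1-based inclusive) and circRNA BED (0-based half-open) are converted
#' to the internal 0-based half-open models at this boundary. BED12 blocks
#' become circ exons; a single-block or BED6 record becomes a one-exon circ.
#'
#' @param gtf_path GTF with `exon`, `CDS`, `five_prime_utr`,
#'   `three_prime_utr` features carrying `gene_id` attributes.
#' @param circ_bed_path circRNA BED6/BED12; name field `circ_id` or
#'   `circ_id|host_gene_id`.
#' @return List with `genes` and `circs` tibbles. circRNAs naming a host
#'   gene absent from the GTF abort with the offending ids.
#' @export
read_annotation <- function(gtf_path, circ_bed_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  tbl <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    gene_id = gr$gene_id
  )
  genes <- tbl |>
    dplyr::filter(.data$feature == "exon") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      chrom = .data$chrom[1], strand = .data$strand[1],
      exons = list(tibble::tibble(start = start, end = end)),
      n_exons = dplyr::n(),
      tx_length = sum(.data$end - .data$start),
      .groups = "drop"
    )
  region_len <- tbl |>
    dplyr::filter(.data$feature %in% c("five_prime_utr", "CDS", "three_prime_utr")) |>
    dplyr::group_by(.data$gene_id, .data$feature) |>
    dplyr::summarise(len = sum(.data$end - .data$start), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "len", values_fill = 0)
  for (nm in c("five_prime_utr", "CDS", "three_prime_utr")) {
    if (!nm %in% names(region_len)) region_len[[nm]] <- 0
  }
  genes <- genes |>
    dplyr::left_join(region_len, by = "gene_id") |>
    dplyr::mutate(
      utr5_len = dplyr::coalesce(.data$five_prime_utr, 0),
      cds_len = dplyr::coalesce(.data$CDS, 0),
      utr3_len = dplyr::coalesce(.data$three_prime_utr, 0)
    ) |>
    dplyr::select("gene_id", "chrom", "strand", "utr5_len", "cds_len",
                  "utr3_len", "tx_length", "n_exons", "exons")

  bed <- rtracklayer::import(circ_bed_path, format = "bed")
  circs <- purrr::map(seq_along(bed), function(i) {
    g <- bed[i]
    nm <- if (!is.null(g$name)) g$name else sprintf("circ_%05d", i)
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    circ_id <- parts[1]
    host <- if (length(parts) > 1) parts[2] else NA_character_
    blocks <- if (!is.null(g$blocks) && length(g$blocks[[1]]) > 0) {
      b <- g$blocks[[1]] # 1-based within the span
      tibble::tibble(
        start = GenomicRanges::start(g) - 1 + BiocGenerics::start(b) - 1,
        end = GenomicRanges::start(g) - 1 + BiocGenerics::end(b)
      )
    } else {
      tibble::tibble(start = GenomicRanges::start(g) - 1, end = GenomicRanges::end(g))
    }
    circ_model(circ_id, as.character(GenomicRanges::seqnames(g)), blocks,
               host_gene_id = host, strand = as.character(GenomicRanges::strand(g)))
  }) |> purrr::list_rbind()
  if (nrow(circs) > 0) {
    circs$strand[circs$strand == "*"] <- "+"
    known <- circs$host_gene_id %in% genes$gene_id | is.na(circs$host_gene_id)
    if (!all(known)) {
      stop("circRNA(s) referencing absent host gene(s): ",
           paste(circs$circ_id[!known], collapse = ", "))
    }
  }
  list(genes = genes, circs = circs)
}

#' Write a simulated study to disk
#'
#' Probe TSV, gene GTF, circRNA BED12, peak BED6 and ground-truth TSVs, the
#' interchange formats of the whole pipeline.
#'
#' @param sim Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    probes = file.path(outdir, "probes.tsv"),
    genes = file.path(outdir, "genes.gtf"),
    circs = file.path(outdir, "circs.bed"),
    peaks = file.path(outdir, "peaks.bed"),
    truth_targets = file.path(outdir, "truth_targets.tsv"),
    truth_subgroups = file.path(outdir, "truth_subgroups.tsv")
  )
  write_probe_table(sim$probes, paths[["probes"]])
  write_gene_gtf(sim$genes, paths[["genes"]])
  write_circ_bed(sim$circs, paths[["circs"]])
  write_peak_bed(sim$peaks, paths[["peaks"]])
  readr::write_tsv(sim$truth$targets, paths[["truth_targets"]], progress = FALSE)
  readr::write_tsv(sim$truth$subgroups, paths[["truth_subgroups"]], progress = FALSE)
  invisible(paths)
}

#' Published top-10 differential m6A-circRNA tables
#'
#' The two printed ranked tables of up- and down-regulated m6A-circRNAs
#' shipped as plain-text fixtures: ArrayStar/circBase ids, p-value, the
#' printed fold-change column (linear ratio), host gene, chromosome, printed
#' spliced length (bp, `NA` where not printed) and the genomic back-splice
#' span (0-based half-open `start`/`end`, so `end - start` is the genomic
#' span length).
#'
#' @param which `"up"` or `"down"`.
#' @return Tibble of 10 rows.
#' @export
#' @examples
#' published_call_table("up")
published_call_table <- function(which = c("up", "down")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("table_", which, ".tsv"),
                      package = "circm6a", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Apply the differential screen to a ranked call table
#'
#' Re-applies the dual thresholds (linear fold change and p-value, strict
#' inequalities) to a table of per-target statistics, e.g. a published
#' ranked list, labelling each row `up`, `down` or `none`. Fold changes
#' below 1 are treated as down-regulation ratios (`fc < 1/fc_threshold`).
#'
#' @param calls Tibble with `p_value` and `fold_change` (linear ratio).
#' @param fc_threshold,p_threshold Screen thresholds.
#' @return The input with `direction` and `passes` columns added.
#' @export
screen_calls <- function(calls, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(all(c("p_value", "fold_change") %in% names(calls)))
  calls |>
    dplyr::mutate(
      direction = dplyr::case_when(
        .data$fold_change > fc_threshold & .data$p_value < p_threshold ~ "up",
        .data$fold_change < 1 / fc_threshold & .data$p_value < p_threshold ~ "down",
        TRUE ~ "none"
      ),
      passes = .data$direction != "none"
    )
}
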