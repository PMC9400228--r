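#' Pipeline configuration
#'
#' Paths to the four interchange inputs plus every analysis threshold, in
#' one validated object consumed by [run_pipeline()].
#'
#' @param probe_path Probe-intensity TSV.
#' @param gtf_path Gene-model GTF.
#' @param circ_bed_path circRNA BED6/BED12.
#' @param peak_bed_path m6A peak BED.
#' @param outdir Output directory.
#' @param fc_threshold,p_threshold Differential screen thresholds.
#' @param qc_min_ok QC retention rule: minimum samples with P/M flags.
#' @param bins_per_region Metagene bins per tripartite region.
#' @param stage_bp Length-histogram stage width (bp).
#' @param level_threshold Modified-percent cutoff binarizing a circRNA as
#'   m6A-methylated for subgroup classification.
#' @param floor Intensity floor epsilon.
#' @param seed Integer seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(probe_path, gtf_path, circ_bed_path, peak_bed_path,
                            outdir, fc_threshold = 1.5, p_threshold = 0.05,
                            qc_min_ok = 3, bins_per_region = 50, stage_bp = 100,
                            level_threshold = 0.2, floor = 1, seed = 1L) {
  cfg <- list(
    probe_path = probe_path, gtf_path = gtf_path,
    circ_bed_path = circ_bed_path, peak_bed_path = peak_bed_path,
    outdir = outdir, fc_threshold = fc_threshold, p_threshold = p_threshold,
    qc_min_ok = qc_min_ok, bins_per_region = bins_per_region,
    stage_bp = stage_bp, level_threshold = level_threshold,
    floor = floor, seed = as.integer(seed)
  )
  stopifnot(cfg$fc_threshold > 0, cfg$p_threshold >= 0, cfg$qc_min_ok >= 0,
            cfg$bins_per_region >= 1, cfg$stage_bp > 0, cfg$floor > 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reads the probe table and annotations, then executes quantification, the
#' differential screens on both metrics, their intersection, the genomic
#' characterization of the intersected differential circRNAs, and the
#' subgroup classification. Every stage's tables are written under
#' `config$outdir` together with a structured run log from which the
#' filtering narrative (QC retention, threshold passes, intersection sizes)
#' can be reconstructed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results (`quants`,
#'   `level_calls`, `quantity_calls`, `intersection`, `exon_hist`,
#'   `length_hist`, `metagene`, `circ_positions`, `subgroups`,
#'   `subgroup_counts`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  note("config", "seed=", config$seed,
       " fc_threshold=", config$fc_threshold, " p_threshold=", config$p_threshold,
       " qc_min_ok=", config$qc_min_ok, " level_threshold=", config$level_threshold)

  probes <- run_stage("read", read_probe_table(config$probe_path, floor = config$floor))
  ann <- run_stage("read", read_annotation(config$gtf_path, config$circ_bed_path))
  peaks <- run_stage("read", read_peak_bed(config$peak_bed_path))
  note("read", "probes=", nrow(probes), " genes=", nrow(ann$genes),
       " circs=", nrow(ann$circs), " peaks=", nrow(peaks))

  qc <- run_stage("quantify", qc_filter(probes, min_ok = config$qc_min_ok))
  note("quantify", "probes_in=", nrow(qc), " retained=", sum(qc$retained),
       " dropped_qc=", sum(!qc$retained))
  quants <- run_stage("quantify",
                      quantify_m6a(probes, min_ok = config$qc_min_ok, floor = config$floor))
  note("quantify", "targets_quantified=", dplyr::n_distinct(quants$target_id))

  level_calls <- run_stage("differential",
    call_differential(quants, "level", config$fc_threshold, config$p_threshold))
  quantity_calls <- run_stage("differential",
    call_differential(quants, "quantity", config$fc_threshold, config$p_threshold))
  for (calls in list(level_calls, quantity_calls)) {
    g <- glance(calls)
    note("differential", "metric=", g$metric, " tested=", g$n_tested,
         " up=", g$n_up, " down=", g$n_down,
         " untestable=", g$n_targets - g$n_tested)
  }
  inter <- run_stage("differential", intersect_calls(level_calls, quantity_calls))
  note("intersect", "up_both=", length(inter$up_both),
       " down_both=", length(inter$down_both))

  diff_ids <- union(inter$up_both, inter$down_both)
  diff_circs <- ann$circs[ann$circs$circ_id %in% diff_ids, ]
  note("characterize", "differential_circs=", nrow(diff_circs))
  exon_hist <- run_stage("characterize", exon_count_histogram(diff_circs))
  length_hist <- run_stage("characterize", length_histogram(diff_circs, stage = config$stage_bp))
  metagene <- run_stage("characterize",
    metagene_profile(peaks, ann$genes, bins_per_region = config$bins_per_region))
  note("characterize", "peaks_mapped=", attr(metagene, "n_mapped"),
       " peaks_unmapped=", attr(metagene, "n_unmapped"))
  circ_pos <- run_stage("characterize", {
    linked <- diff_circs[!is.na(diff_circs$host_gene_id), ]
    if (nrow(linked) > 0) circ_position_in_host(linked, ann$genes) else
      tibble::tibble(circ_id = character(), host_gene_id = character(),
                     tx_mid = numeric(), region = character(), axis_pos = numeric())
  })

  subgroups <- run_stage("classify",
    classify_subgroups(ann$circs[!is.na(ann$circs$host_gene_id), ], ann$genes,
                       peaks, quants = quants,
                       level_threshold = config$level_threshold))
  counts <- subgroup_summary(subgroups)
  note("classify", paste(counts$label, counts$n, sep = "=", collapse = " "))

  paths <- c(
    quants = file.path(config$outdir, "quants.tsv"),
    level_calls = file.path(config$outdir, "calls_level.tsv"),
    quantity_calls = file.path(config$outdir, "calls_quantity.tsv"),
    venn = file.path(config$outdir, "venn.json"),
    exon_hist = file.path(config$outdir, "exon_histogram.tsv"),
    length_hist = file.path(config$outdir, "length_histogram.tsv"),
    metagene = file.path(config$outdir, "metagene_profile.tsv"),
    circ_positions = file.path(config$outdir, "circ_positions.tsv"),
    chrom_counts = file.path(config$outdir, "chromosome_counts.tsv"),
    subgroups = file.path(config$outdir, "subgroups.tsv"),
    subgroup_summary = file.path(config$outdir, "subgroup_summary.json"),
    log = file.path(config$outdir, "run_log.txt")
  )
  readr::write_tsv(quants, paths[["quants"]], progress = FALSE)
  readr::write_tsv(tidy(level_calls), paths[["level_calls"]], progress = FALSE)
  readr::write_tsv(tidy(quantity_calls), paths[["quantity_calls"]], progress = FALSE)
  jsonlite::write_json(lapply(unclass(inter), as.character), paths[["venn"]], pretty = TRUE)
  readr::write_tsv(exon_hist, paths[["exon_hist"]], progress = FALSE)
  readr::write_tsv(length_hist, paths[["length_hist"]], progress = FALSE)
  readr::write_tsv(metagene, paths[["metagene"]], progress = FALSE)
  readr::write_tsv(circ_pos, paths[["circ_positions"]], progress = FALSE)
  readr::write_tsv(chromosome_counts(diff_circs), paths[["chrom_counts"]], progress = FALSE)
  subgroups_flat <- dplyr::mutate(
    subgroups,
    host_peak_regions = purrr::map_chr(.data$host_peak_regions, paste, collapse = ",")
  )
  readr::write_tsv(subgroups_flat, paths[["subgroups"]], progress = FALSE)
  jsonlite::write_json(setNames(as.list(counts$n), as.character(counts$label)),
                       paths[["subgroup_summary"]], auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, paths[["log"]])

  invisible(list(
    quants = quants, level_calls = level_calls, quantity_calls = quantity_calls,
    intersection = inter, exon_hist = exon_hist, length_hist = length_hist,
    metagene = metagene, circ_positions = circ_pos, subgroups = subgroups,
    subgroup_counts = counts, paths = paths, log = log_lines
  ))
}
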