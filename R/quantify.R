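#' Spike-in anchored normalization
#'
#' Normalizes raw two-channel intensities against the exogenous spike-in
#' panel: per sample and channel,
#' `log2(norm) = log2(raw) - mean(log2(spike-in raw))`.
#' Because the offset is a per-channel constant, any global rescaling of a
#' channel cancels exactly; spike-ins themselves are normalized too.
#'
#' @param probes Probe-record tibble (see [simulate_intensities()] for the
#'   column contract); `target_class == "spike_in"` rows are the anchors.
#' @param floor Intensity floor applied before `log2`.
#' @return The input with `log2_ip_norm` and `log2_sup_norm` columns added.
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 5, seed = 1))
#' normalize_spikein(sim$probes)
normalize_spikein <- function(probes, floor = 1) {
  stopifnot(all(c("target_class", "sample_id", "ip_raw", "sup_raw") %in% names(probes)))
  spikes <- dplyr::filter(probes, .data$target_class == "spike_in")
  missing <- setdiff(unique(probes$sample_id), unique(spikes$sample_id))
  if (length(missing) > 0) {
    stop("no spike-in probes for sample(s): ", paste(missing, collapse = ", "),
         " (both channels require >= 1 spike-in per sample)")
  }
  offsets <- spikes |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      offset_ip = mean(log2(pmax(.data$ip_raw, floor))),
      offset_sup = mean(log2(pmax(.data$sup_raw, floor))),
      .groups = "drop"
    )
  probes |>
    dplyr::left_join(offsets, by = "sample_id") |>
    dplyr::mutate(
      log2_ip_norm = log2(pmax(.data$ip_raw, floor)) - .data$offset_ip,
      log2_sup_norm = log2(pmax(.data$sup_raw, floor)) - .data$offset_sup
    ) |>
    dplyr::select(-"offset_ip", -"offset_sup")
}

#' QC-flag retention filter
#'
#' Keeps a probe when at least `min_ok` of its samples carry a Present (P) or
#' Marginal (M) detection flag; a sample counts only if BOTH channels are
#' P or M in that sample, since both are needed to form the IP/(IP+Sup)
#' ratio. The default reproduces the 3-of-6 rule of a 3 vs 3 design.
#'
#' @param probes Probe-record tibble with `ip_flag`, `sup_flag`.
#' @param min_ok Minimum number of qualifying samples.
#' @param n_samples Expected number of samples per probe; probes with missing
#'   samples abort with their ids.
#' @return Per-probe report tibble: `probe_id`, `n_ok`, `retained`. Spike-in
#'   rows are exempt from the rule (always retained).
#' @export
qc_filter <- function(probes, min_ok = 3, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(probes$sample_id)
  report <- probes |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      target_class = .data$target_class[1],
      n_samples_seen = dplyr::n_distinct(.data$sample_id),
      n_ok = sum(.data$ip_flag %in% c("P", "M") & .data$sup_flag %in% c("P", "M")),
      .groups = "drop"
    )
  short <- report$probe_id[report$n_samples_seen < n_samples]
  if (length(short) > 0) {
    stop("probe(s) missing samples: ", paste(head(short, 10), collapse = ", "),
         if (length(short) > 10) " ..." else "")
  }
  report |>
    dplyr::mutate(retained = .data$n_ok >= min_ok | .data$target_class == "spike_in") |>
    dplyr::select("probe_id", "n_ok", "retained")
}

#' m6A methylation level (modified percent)
#'
#' Fraction of a transcript's copies carrying m6A, computed from normalized
#' intensities on the linear scale:
#' `modified% = IP / (IP + Sup) = 2^log2_ip / (2^log2_ip + 2^log2_sup)`.
#' Strictly inside (0, 1) for finite inputs, and exactly 0.5 when the
#' normalized channels are equal.
#'
#' @param log2_ip_norm,log2_sup_norm Normalized log2 intensities.
#' @return Numeric vector of fractions.
#' @export
#' @examples
#' methylation_level(log2(3), log2(1)) # 0.75
methylation_level <- function(log2_ip_norm, log2_sup_norm) {
  stopifnot(all(is.finite(log2_ip_norm)), all(is.finite(log2_sup_norm)))
  # computed via the logistic of the log-ratio for numerical stability
  1 / (1 + 2^(log2_sup_norm - log2_ip_norm))
}

#' m6A quantity
#'
#' The absolute amount of methylated transcript: the normalized IP (Cy5)
#' log2 intensity, unchanged. Invariant to anything in the Sup channel.
#'
#' @param log2_ip_norm Normalized IP log2 intensity.
#' @return `log2_ip_norm`.
#' @export
m6a_quantity <- function(log2_ip_norm) {
  stopifnot(all(is.finite(log2_ip_norm)))
  log2_ip_norm
}

#' Per-target m6A quantification
#'
#' Full quantification stage: QC retention, spike-in normalization, probe to
#' target aggregation (mean of normalized log2 intensities when several
#' probes map to one target), then both per-sample measures.
#'
#' @param probes Probe-record tibble.
#' @param min_ok,n_samples QC rule parameters, see [qc_filter()].
#' @param floor Intensity floor.
#' @return Tibble with one row per retained target x sample: `target_id`,
#'   `target_class`, `sample_id`, `group`, `log2_ip_norm`, `log2_sup_norm`,
#'   `modified_percent`, `quantity`. Spike-in targets are dropped from the
#'   output (they are controls, not biology).
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 10, seed = 1))
#' quants <- quantify_m6a(sim$probes)
quantify_m6a <- function(probes, min_ok = 3, n_samples = NULL, floor = 1) {
  keep <- qc_filter(probes, min_ok = min_ok, n_samples = n_samples)
  retained <- keep$probe_id[keep$retained]
  normed <- probes |>
    dplyr::filter(.data$probe_id %in% retained) |>
    normalize_spikein(floor = floor)
  normed |>
    dplyr::filter(.data$target_class != "spike_in") |>
    dplyr::group_by(.data$target_id, .data$target_class, .data$sample_id, .data$group) |>
    dplyr::summarise(
      log2_ip_norm = mean(.data$log2_ip_norm),
      log2_sup_norm = mean(.data$log2_sup_norm),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      modified_percent = methylation_level(.data$log2_ip_norm, .data$log2_sup_norm),
      quantity = m6a_quantity(.data$log2_ip_norm)
    )
}
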