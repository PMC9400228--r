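#' Simulate two-channel probe intensities
#'
#' Measurement model for the IP (Cy5) / Sup (Cy3) array: for each target and
#' sample,
#' `IP_raw = abundance * f * ip_efficiency * noise` and
#' `Sup_raw = abundance * (1 - f) * noise`, with independent log-normal noise
#' per channel (`log2`-sd `noise_log2_sd`). Raw intensities are clipped below
#' at the configured floor. Spike-in probes carry fixed known intensities,
#' identical in both channels and across samples by default (they anchor the
#' normalization); P/M/A detection flags are drawn independently per probe,
#' sample and channel, except spike-ins which are always `P`.
#'
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @return Tibble of probe records: `probe_id`, `target_id`, `target_class`,
#'   `sample_id`, `group`, `ip_raw`, `sup_raw`, `ip_flag`, `sup_flag`.
#' @export
simulate_intensities <- function(truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  targets <- truth$targets
  ns <- config$n_samples_per_group
  samples <- tibble::tibble(
    sample_id = c(paste0("tumor_", seq_len(ns)), paste0("normal_", seq_len(ns))),
    group = rep(c("tumor", "normal"), each = ns)
  )

  grid <- tidyr::crossing(targets, samples) |>
    dplyr::mutate(
      abundance = ifelse(.data$group == "tumor", .data$abundance_tumor, .data$abundance_normal),
      f = ifelse(.data$group == "tumor", .data$f_tumor, .data$f_normal)
    )
  n <- nrow(grid)
  noise_ip <- 2^rnorm(n, 0, config$noise_log2_sd)
  noise_sup <- 2^rnorm(n, 0, config$noise_log2_sd)
  probes <- grid |>
    dplyr::transmute(
      probe_id = paste0("p_", .data$target_id),
      target_id = .data$target_id,
      target_class = .data$target_class,
      sample_id = .data$sample_id,
      group = .data$group,
      ip_raw = pmax(.data$abundance * .data$f * config$ip_efficiency * noise_ip, config$floor),
      sup_raw = pmax(.data$abundance * (1 - .data$f) * noise_sup, config$floor),
      ip_flag = draw_flags(n, config$flag_probs),
      sup_flag = draw_flags(n, config$flag_probs)
    )

  spike <- spikein_panel(config)
  sp_grid <- tidyr::crossing(spike, samples)
  m <- nrow(sp_grid)
  sp_noise_ip <- 2^rnorm(m, 0, config$spikein_noise_log2_sd)
  sp_noise_sup <- 2^rnorm(m, 0, config$spikein_noise_log2_sd)
  spikes <- sp_grid |>
    dplyr::transmute(
      probe_id = paste0("p_", .data$spike_id),
      target_id = .data$spike_id,
      target_class = "spike_in",
      sample_id = .data$sample_id,
      group = .data$group,
      ip_raw = pmax(.data$intensity * sp_noise_ip, config$floor),
      sup_raw = pmax(.data$intensity * sp_noise_sup, config$floor),
      ip_flag = "P",
      sup_flag = "P"
    )

  dplyr::bind_rows(probes, spikes) |>
    dplyr::arrange(.data$probe_id, .data$sample_id)
}

# Fixed exogenous control panel: intensities log2-spaced over 2 log2 units.
spikein_panel <- function(config) {
  n <- config$n_spikeins
  tibble::tibble(
    spike_id = sprintf("spike_%02d", seq_len(n)),
    intensity = 2^seq(10, 12, length.out = n)
  )
}

draw_flags <- function(n, flag_probs) {
  sample(names(flag_probs), n, replace = TRUE, prob = flag_probs)
}
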