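#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate the
#' study design the package targets: 3 tumor vs 3 normal samples hybridized to
#' a two-channel IP (Cy5) / Sup (Cy3) array with a fixed spike-in panel.
#'
#' @param n_genes Number of host genes to simulate.
#' @param n_circ_per_gene Mean number of circRNAs per gene (Poisson).
#' @param n_samples_per_group Samples per group (tumor and normal alike).
#' @param n_spikeins Size of the exogenous spike-in panel.
#' @param abundance_log2_mean,abundance_log2_sd Log2-normal parameters of
#'   per-target total abundance (linear intensity units).
#' @param noise_log2_sd Per-channel multiplicative measurement noise,
#'   log-normal with this sd on the log2 scale.
#' @param ip_efficiency Fraction of methylated RNA captured by the IP in
#'   (0, 1]; 1 means lossless capture.
#' @param effect_targets_frac Fraction of targets given a true tumor-vs-normal
#'   difference.
#' @param effect_log2fc Planted effect size, log2 fold change.
#' @param frac_methylated Probability a target is truly m6A-methylated.
#' @param host_methylated_prob Probability a host gene carries >= 1 true
#'   mRNA m6A site (independent of its circRNAs' methylation).
#' @param flag_probs Named probabilities of the P/M/A detection flags drawn
#'   independently per probe x sample x channel.
#' @param spikein_noise_log2_sd Optional log2-sd of spike-in noise; 0 keeps
#'   the panel identical across samples (the normalization anchor).
#' @param peak_width Width in bp of MeRIP-seq-like peak intervals.
#' @param floor Intensity floor epsilon; raw intensities are clipped below at
#'   this value so log2 is defined.
#' @param seed Integer seed; identical seed and config give identical output.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
sim_config <- function(n_genes = 200,
                       n_circ_per_gene = 1,
                       n_samples_per_group = 3,
                       n_spikeins = 8,
                       abundance_log2_mean = 10,
                       abundance_log2_sd = 1.5,
                       noise_log2_sd = 0.25,
                       ip_efficiency = 1,
                       effect_targets_frac = 0.15,
                       effect_log2fc = 1.5,
                       frac_methylated = 0.5,
                       host_methylated_prob = 0.5,
                       flag_probs = c(P = 0.9, M = 0.05, A = 0.05),
                       spikein_noise_log2_sd = 0,
                       peak_width = 100,
                       floor = 1,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_circ_per_gene = n_circ_per_gene,
    n_samples_per_group = as.integer(n_samples_per_group),
    n_spikeins = as.integer(n_spikeins),
    abundance_log2_mean = abundance_log2_mean,
    abundance_log2_sd = abundance_log2_sd,
    noise_log2_sd = noise_log2_sd,
    ip_efficiency = ip_efficiency,
    effect_targets_frac = effect_targets_frac,
    effect_log2fc = effect_log2fc,
    frac_methylated = frac_methylated,
    host_methylated_prob = host_methylated_prob,
    flag_probs = flag_probs,
    spikein_noise_log2_sd = spikein_noise_log2_sd,
    peak_width = peak_width,
    floor = floor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 1L, cfg$n_samples_per_group >= 1L, cfg$n_spikeins >= 1L,
    cfg$n_circ_per_gene >= 0,
    cfg$abundance_log2_sd >= 0, cfg$noise_log2_sd >= 0,
    cfg$spikein_noise_log2_sd >= 0,
    cfg$ip_efficiency > 0, cfg$ip_efficiency <= 1,
    cfg$effect_targets_frac >= 0, cfg$effect_targets_frac <= 1,
    cfg$frac_methylated >= 0, cfg$frac_methylated <= 1,
    cfg$host_methylated_prob >= 0, cfg$host_methylated_prob <= 1,
    length(cfg$flag_probs) == 3L,
    all(sort(names(cfg$flag_probs)) == c("A", "M", "P")),
    abs(sum(cfg$flag_probs) - 1) < 1e-8,
    cfg$peak_width >= 1, cfg$floor > 0
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ",
      x$n_samples_per_group, " vs ", x$n_samples_per_group, " samples, ",
      x$n_spikeins, " spike-ins, noise_log2_sd = ", x$noise_log2_sd,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
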