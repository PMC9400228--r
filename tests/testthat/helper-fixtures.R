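# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal truth object with hand-chosen per-target states, bypassing the
# stochastic truth generator so tests control f and abundance exactly.
make_truth <- function(f_tumor, f_normal = f_tumor, abundance = 2^10,
                       target_class = "circRNA") {
  n <- length(f_tumor)
  list(targets = tibble::tibble(
    target_id = sprintf("t%04d", seq_len(n)),
    target_class = target_class,
    gene_id = NA_character_,
    methylated = f_tumor > 0.2,
    f_tumor = f_tumor,
    f_normal = f_normal,
    abundance_tumor = rep_len(abundance, n),
    abundance_normal = rep_len(abundance, n),
    effect_metric = "none",
    effect_direction = "none"
  ))
}

# Deterministic config: no noise, lossless IP, all flags Present.
noiseless_config <- function(...) {
  sim_config(noise_log2_sd = 0, ip_efficiency = 1,
             flag_probs = c(P = 1, M = 0, A = 0), ...)
}

# A hand-built probe table: one target plus spike-ins, one sample.
manual_probes <- function(target_ip, target_sup, spike_ip, spike_sup = spike_ip,
                          sample_id = "s1", group = "tumor") {
  n <- length(target_ip)
  dplyr::bind_rows(
    tibble::tibble(
      probe_id = paste0("p", seq_len(n)), target_id = paste0("t", seq_len(n)),
      target_class = "circRNA", sample_id = sample_id, group = group,
      ip_raw = target_ip, sup_raw = target_sup, ip_flag = "P", sup_flag = "P"
    ),
    tibble::tibble(
      probe_id = paste0("sp", seq_along(spike_ip)),
      target_id = paste0("spike_", seq_along(spike_ip)),
      target_class = "spike_in", sample_id = sample_id, group = group,
      ip_raw = spike_ip, sup_raw = spike_sup, ip_flag = "P", sup_flag = "P"
    )
  )
}

# Brute-force interval overlap (the O(n^2) oracle for findOverlaps paths).
overlaps_1bp <- function(a_start, a_end, b_start, b_end) {
  max(a_start, b_start) < min(a_end, b_end)
}
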