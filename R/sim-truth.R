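#' Simulate ground-truth methylation states and abundances
#'
#' Draws, for every array target (each circRNA and each host mRNA), a true
#' total abundance and a true m6A-modified fraction `f` per group, plants
#' tumor-vs-normal effects on a configurable fraction of targets, and places
#' true mRNA m6A sites on host transcripts. circRNA and host methylation
#' states are drawn independently, matching the observation that whether a
#' circRNA is methylated is unrelated to its host gene's status.
#'
#' Planted effects come in two kinds, mirroring the two array metrics:
#' `level` effects change the modified fraction between groups at a fixed
#' linear ratio of `2^effect_log2fc`, `quantity` effects change abundance by
#' the same ratio with `f` untouched.
#'
#' @param annotation Output of [simulate_annotation()].
#' @param config A [sim_config()].
#' @return A list with `targets` (per-target truth), `sites` (true mRNA m6A
#'   site transcript coordinates), and `subgroups` (per-circRNA truth labels
#'   as assigned by [classify_circ()] logic on the true states).
#' @export
simulate_truth <- function(annotation, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  circs <- annotation$circs

  host_methylated <- setNames(
    rbinom(nrow(genes), 1, config$host_methylated_prob) == 1, genes$gene_id
  )

  targets <- dplyr::bind_rows(
    tibble::tibble(
      target_id = circs$circ_id, target_class = "circRNA",
      gene_id = circs$host_gene_id,
      methylated = rbinom(nrow(circs), 1, config$frac_methylated) == 1
    ),
    tibble::tibble(
      target_id = genes$gene_id, target_class = "mRNA",
      gene_id = genes$gene_id,
      methylated = unname(host_methylated)
    )
  )
  nt <- nrow(targets)

  f_base <- ifelse(targets$methylated, runif(nt, 0.30, 0.80), runif(nt, 0.01, 0.10))
  ab_base <- 2^rnorm(nt, config$abundance_log2_mean, config$abundance_log2_sd)

  has_effect <- runif(nt) < config$effect_targets_frac
  effect_metric <- ifelse(has_effect, sample(c("level", "quantity"), nt, replace = TRUE), "none")
  effect_dir <- ifelse(has_effect, sample(c("up", "down"), nt, replace = TRUE), "none")
  ratio <- 2^config$effect_log2fc

  f_tumor <- f_base
  f_normal <- f_base
  ab_tumor <- ab_base
  ab_normal <- ab_base

  lev <- effect_metric == "level"
  if (any(lev)) {
    # keep both fractions well inside (0,1) at an exact planted ratio
    low <- runif(sum(lev), 0.05, 0.30)
    up <- effect_dir[lev] == "up"
    f_tumor[lev] <- ifelse(up, low * ratio, low)
    f_normal[lev] <- ifelse(up, low, low * ratio)
  }
  qty <- effect_metric == "quantity"
  if (any(qty)) {
    up <- effect_dir[qty] == "up"
    ab_tumor[qty] <- ab_base[qty] * ifelse(up, ratio, 1 / ratio)
  }

  targets <- targets |>
    dplyr::mutate(
      f_tumor = f_tumor, f_normal = f_normal,
      abundance_tumor = ab_tumor, abundance_normal = ab_normal,
      effect_metric = effect_metric, effect_direction = effect_dir
    )

  # true mRNA m6A sites: biased toward the stop codon / 3'UTR region
  sites <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!host_methylated[[g$gene_id]]) return(NULL)
    n_sites <- sample(1:3, 1)
    near_stop <- runif(n_sites) < 0.6
    lo <- ifelse(near_stop, g$utr5_len + 0.8 * g$cds_len, 0)
    hi <- ifelse(near_stop, g$tx_length, g$tx_length)
    pos <- floor(runif(n_sites, lo, hi))
    tibble::tibble(gene_id = g$gene_id, site_index = seq_len(n_sites),
                   tx_pos = pmin(pos, g$tx_length - 1))
  }) |> purrr::list_rbind()
  if (is.null(sites) || nrow(sites) == 0) {
    sites <- tibble::tibble(gene_id = character(), site_index = integer(), tx_pos = numeric())
  }

  circ_truth <- targets |>
    dplyr::filter(.data$target_class == "circRNA") |>
    dplyr::transmute(
      circ_id = .data$target_id,
      host_gene_id = .data$gene_id,
      circ_methylated = .data$f_tumor > 0.2,
      host_methylated = unname(host_methylated[.data$gene_id])
    ) |>
    dplyr::mutate(label = classify_circ(.data$circ_methylated, .data$host_methylated))

  list(targets = targets, sites = sites, subgroups = circ_truth)
}
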