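#' Group fold change for one target
#'
#' Linear fold change (tumor over normal) on the metric's natural scale:
#' for `level`, the ratio of mean modified fractions; for `quantity`,
#' `2^(mean tumor log2 - mean normal log2)`.
#'
#' @param tumor_values,normal_values Per-sample values; fractions for
#'   `metric = "level"`, log2 intensities for `metric = "quantity"`.
#' @param metric `"level"` or `"quantity"`.
#' @return Named list with `ratio` (linear) and `log2_fc`.
#' @export
#' @examples
#' fold_change(c(0.6, 0.6), c(0.3, 0.3), "level") # ratio 2
fold_change <- function(tumor_values, normal_values, metric = c("level", "quantity")) {
  metric <- match.arg(metric)
  stopifnot(length(tumor_values) >= 1, length(normal_values) >= 1,
            all(is.finite(tumor_values)), all(is.finite(normal_values)))
  if (metric == "level") {
    mn <- mean(normal_values)
    if (mn <= 0) stop("normal-group mean at or below zero: ratio undefined")
    ratio <- mean(tumor_values) / mn
  } else {
    ratio <- 2^(mean(tumor_values) - mean(normal_values))
  }
  list(ratio = ratio, log2_fc = log2(ratio))
}

#' Welch two-sample test for one target
#'
#' Two-sided Welch t-test on the analysis scale: modified fractions are
#' logit-transformed (they are bounded in (0,1)); quantities are already
#' log2. Degenerate inputs where both groups are constant return `p = 1`
#' when equal and `p = 0` when different; fewer than two values per group is
#' untestable and returns `NA`.
#'
#' @param tumor_values,normal_values Per-sample values on the metric's
#'   natural scale.
#' @param metric `"level"` or `"quantity"`.
#' @return p-value in `[0, 1]`, or `NA_real_` if untestable.
#' @export
test_differential <- function(tumor_values, normal_values, metric = c("level", "quantity")) {
  metric <- match.arg(metric)
  if (length(tumor_values) < 2 || length(normal_values) < 2) return(NA_real_)
  if (metric == "level") {
    stopifnot(all(tumor_values > 0 & tumor_values < 1),
              all(normal_values > 0 & normal_values < 1))
    tumor_values <- qlogis(tumor_values)
    normal_values <- qlogis(normal_values)
  }
  if (stats::sd(tumor_values) == 0 && stats::sd(normal_values) == 0) {
    return(if (isTRUE(all.equal(mean(tumor_values), mean(normal_values)))) 1 else 0)
  }
  t.test(tumor_values, normal_values, var.equal = FALSE)$p.value
}

#' Call differential m6A targets on one metric
#'
#' Applies the dual-threshold screen per target: a target passes as `up`
#' when the linear fold change exceeds `fc_threshold` and the Welch p-value
#' is below `p_threshold`, and as `down` when the fold change is below
#' `1/fc_threshold` at the same significance. Inequalities are strict. No
#' multiple-testing correction enters the calls; a Benjamini-Hochberg
#' adjusted column is reported for information.
#'
#' @param quants Output of [quantify_m6a()] (or any tibble with `target_id`,
#'   `group` and the metric's value column).
#' @param metric `"level"` (uses `modified_percent`) or `"quantity"`.
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param p_threshold Significance threshold (default 0.05).
#' @return An object of class `m6a_calls`: a tibble of per-target calls
#'   (`target_id`, group means, `fold_change`, `log2_fc`, `p_value`,
#'   `p_adj`, `direction`, `passes`) with the metric and thresholds stored
#'   as attributes. Untestable targets (insufficient replicates) are kept
#'   with `p_value = NA` and `passes = FALSE`.
#' @export
#' @examples
#' sim <- simulate_study(sim_config(n_genes = 30, seed = 1))
#' calls <- quantify_m6a(sim$probes) |> call_differential("level")
#' glance(calls)
call_differential <- function(quants, metric = c("level", "quantity"),
                              fc_threshold = 1.5, p_threshold = 0.05) {
  metric <- match.arg(metric)
  value_col <- if (metric == "level") "modified_percent" else "quantity"
  stopifnot(value_col %in% names(quants), all(c("tumor", "normal") %in% quants$group))

  per_target <- quants |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      target_class = .data$target_class[1],
      tumor = list(.data[[value_col]][.data$group == "tumor"]),
      normal = list(.data[[value_col]][.data$group == "normal"]),
      .groups = "drop"
    )

  calls <- per_target |>
    dplyr::mutate(
      group_mean_tumor = purrr::map_dbl(.data$tumor, mean),
      group_mean_normal = purrr::map_dbl(.data$normal, mean),
      fc = purrr::map2(.data$tumor, .data$normal, fold_change, metric = metric),
      fold_change = purrr::map_dbl(.data$fc, "ratio"),
      log2_fc = purrr::map_dbl(.data$fc, "log2_fc"),
      p_value = purrr::map2_dbl(.data$tumor, .data$normal, test_differential, metric = metric)
    ) |>
    dplyr::select(-"tumor", -"normal", -"fc") |>
    dplyr::mutate(
      p_adj = p.adjust(.data$p_value, method = "BH"),
      direction = dplyr::case_when(
        is.na(.data$p_value) ~ "none",
        .data$fold_change > fc_threshold & .data$p_value < p_threshold ~ "up",
        .data$fold_change < 1 / fc_threshold & .data$p_value < p_threshold ~ "down",
        TRUE ~ "none"
      ),
      passes = .data$direction != "none"
    )

  structure(calls,
            class = c("m6a_calls", class(calls)),
            metric = metric,
            fc_threshold = fc_threshold,
            p_threshold = p_threshold)
}

#' @method tidy m6a_calls
#' @export
tidy.m6a_calls <- function(x, ...) {
  tibble::as_tibble(unclass_calls(x))
}

#' @method glance m6a_calls
#' @export
glance.m6a_calls <- function(x, ...) {
  tibble::tibble(
    metric = attr(x, "metric"),
    n_targets = nrow(x),
    n_tested = sum(!is.na(x$p_value)),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    fc_threshold = attr(x, "fc_threshold"),
    p_threshold = attr(x, "p_threshold")
  )
}

unclass_calls <- function(x) {
  class(x) <- setdiff(class(x), "m6a_calls")
  x
}

#' Intersect the two differential call sets
#'
#' The dual-criterion screen: a target is differentially m6A-methylated when
#' it passes in the same direction on BOTH metrics, so `up_both` is the
#' intersection of the level-up and quantity-up sets (likewise `down_both`),
#' as drawn in a Venn diagram.
#'
#' @param level_calls,quantity_calls `m6a_calls` objects (or tibbles with
#'   `target_id`, `direction`) over the same target universe.
#' @return An object of class `m6a_intersection`: list of id sets
#'   `up_level`, `down_level`, `up_quantity`, `down_quantity`, `up_both`,
#'   `down_both`.
#' @export
intersect_calls <- function(level_calls, quantity_calls) {
  sets <- list(
    up_level = level_calls$target_id[level_calls$direction == "up"],
    down_level = level_calls$target_id[level_calls$direction == "down"],
    up_quantity = quantity_calls$target_id[quantity_calls$direction == "up"],
    down_quantity = quantity_calls$target_id[quantity_calls$direction == "down"]
  )
  sets$up_both <- intersect(sets$up_level, sets$up_quantity)
  sets$down_both <- intersect(sets$down_level, sets$down_quantity)
  structure(sets, class = "m6a_intersection")
}

#' @export
print.m6a_intersection <- function(x, ...) {
  cat("<m6a_intersection>\n")
  for (nm in names(x)) cat("  ", nm, ": ", length(x[[nm]]), " targets\n", sep = "")
  invisible(x)
}

#' @method tidy m6a_intersection
#' @export
tidy.m6a_intersection <- function(x, ...) {
  ids <- unique(unlist(x, use.names = FALSE))
  tibble::tibble(
    target_id = ids,
    in_up_level = ids %in% x$up_level,
    in_up_quantity = ids %in% x$up_quantity,
    in_down_level = ids %in% x$down_level,
    in_down_quantity = ids %in% x$down_quantity,
    in_up_both = ids %in% x$up_both,
    in_down_both = ids %in% x$down_both
  )
}

#' @method glance m6a_intersection
#' @export
glance.m6a_intersection <- function(x, ...) {
  tibble::as_tibble(lapply(x, length))
}
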