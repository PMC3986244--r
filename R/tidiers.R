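## broom-style tidiers for the package's result objects.

#' Tidy an association scan
#'
#' @param x A `lipid_assoc` tibble from [association_scan()].
#' @param ... Unused.
#' @return A plain tibble, one row per feature.
#' @export
tidy.lipid_assoc <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @describeIn tidy.lipid_assoc One-row scan summary: feature counts,
#'   significant features (adjusted p < 0.05), skipped features.
#' @export
glance.lipid_assoc <- function(x, ...) {
  tibble(contrast = x$contrast[1], level = x$level[1],
         n_features = nrow(x),
         n_significant = sum(x$p_adj < 0.05, na.rm = TRUE),
         n_skipped = sum(x$status != "ok"),
         analysis_scale = attr(x, "analysis_scale") %||% NA_character_)
}

#' Tidy cross-validation trials into per-metric summaries
#'
#' @param x A `cv_trials` tibble from [run_repeated_cv()].
#' @param ... Unused.
#' @return [aggregate_trials()] output: metric, mean, 95% CI, n used.
#' @export
tidy.cv_trials <- function(x, ...) aggregate_trials(x)

#' @describeIn tidy.cv_trials One-row design/performance summary.
#' @export
glance.cv_trials <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(n_trials = nrow(x), k_folds = cfg$k_folds, repeats = cfg$repeats,
         feature_count = attr(x, "feature_count"),
         mean_auc = mean(x$auc, na.rm = TRUE),
         mean_accuracy = mean(x$accuracy, na.rm = TRUE))
}

#' Tidy a cross-validation report
#'
#' @param x A `lipid_cv_report` from [cv_report()].
#' @param ... Unused.
#' @return The per-metric summary tibble (mean, 95% CI).
#' @export
tidy.lipid_cv_report <- function(x, ...) x$summary

#' @describeIn tidy.lipid_cv_report One-row report summary (chosen model
#'   size, headline performance).
#' @export
glance.lipid_cv_report <- function(x, ...) {
  auc <- x$summary[x$summary$metric == "auc", ]
  acc <- x$summary[x$summary$metric == "accuracy", ]
  tibble(n_star = x$n_star, n_trials = nrow(x$trials),
         mean_auc = auc$mean, auc_ci95_low = auc$ci95_low,
         auc_ci95_high = auc$ci95_high, mean_accuracy = acc$mean)
}

#' Tidy a model-size selection
#'
#' @param x A `cv_size_selection` from [select_model_size()].
#' @param ... Unused.
#' @return The AUC-versus-size curve tibble.
#' @export
tidy.cv_size_selection <- function(x, ...) x$curve

#' @describeIn tidy.cv_size_selection One-row summary with the chosen size.
#' @export
glance.cv_size_selection <- function(x, ...) {
  tibble(n_star = x$n_star,
         max_mean_auc = max(x$curve$mean_auc),
         n_candidates = nrow(x$curve))
}

#' Tidy risk-equation cohort scores
#'
#' @param x A `risk_scores` object from [score_cohort()].
#' @param ... Unused.
#' @return The per-sample risks tibble.
#' @export
tidy.risk_scores <- function(x, ...) x$risks

#' @describeIn tidy.risk_scores One-row summary with the C-statistic.
#' @export
glance.risk_scores <- function(x, ...) {
  tibble(equation = x$equation$name, form = x$equation$form,
         c_statistic = x$auc, n_used = x$n_used, n_excluded = x$n_excluded)
}
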