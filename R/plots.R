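## ggplot2 graphics for the result objects.

#' Volcano-style plot of an association scan
#'
#' Log10 odds ratio per IQR against -log10 adjusted p-value; features past
#' the FDR threshold are highlighted.
#'
#' @param object A `lipid_assoc` from [association_scan()].
#' @param alpha FDR significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lipid_assoc <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(tidy(object), .data$status == "ok")
  df <- mutate(df, significant = .data$p_adj < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$or_per_iqr),
                                   y = -log10(.data$p_adj),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "log10 OR per IQR", y = "-log10 adjusted p",
                  colour = sprintf("FDR < %g", alpha),
                  title = object$contrast[1],
                  subtitle = sprintf("%s level", object$level[1])) +
    ggplot2::theme_minimal()
}

#' Mean AUC versus model size
#'
#' @param object A `cv_size_selection` from [select_model_size()].
#' @param ... Unused.
#' @return A ggplot with the 95% CI ribbon and the chosen size marked.
#' @export
autoplot.cv_size_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n_features,
                                             y = .data$mean_auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low,
                                      ymax = .data$ci95_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_star, linetype = "dashed") +
    ggplot2::labs(x = "features in model", y = "mean cross-validated AUC",
                  title = sprintf("model size selection (n* = %d)",
                                  object$n_star)) +
    ggplot2::theme_minimal()
}

#' Per-trial AUC distribution
#'
#' @param object A `cv_trials` tibble from [run_repeated_cv()].
#' @param ... Unused.
#' @return A ggplot histogram of per-trial AUC with the mean marked.
#' @export
autoplot.cv_trials <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(object$auc, na.rm = TRUE),
                        colour = "red") +
    ggplot2::labs(x = "per-trial AUC", y = "trials") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot.cv_size_selection AUC-versus-size curve of a full
#'   report.
#' @export
autoplot.lipid_cv_report <- function(object, ...) {
  autoplot(structure(list(n_star = object$n_star, curve = object$curve),
                     class = "cv_size_selection"))
}

#' Feature-inclusion stability barplot
#'
#' @param inclusion An inclusion tibble from [inclusion_table()] (or a
#'   `lipid_cv_report`).
#' @param top_n Number of top-ranked features to show.
#' @return A ggplot.
#' @export
plot_inclusion <- function(inclusion, top_n = 20) {
  if (inherits(inclusion, "lipid_cv_report")) inclusion <- inclusion$inclusion
  df <- head(arrange(inclusion, .data$rank), top_n)
  df <- mutate(df, feature_id = factor(.data$feature_id,
                                       levels = rev(.data$feature_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_id,
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "inclusion frequency (% of trials)") +
    ggplot2::theme_minimal()
}

#' Risk-score distributions by outcome
#'
#' @param object A `risk_scores` object from [score_cohort()].
#' @param ... Unused.
#' @return A ggplot (boxplot + jittered points).
#' @export
autoplot.risk_scores <- function(object, ...) {
  df <- object$risks
  outcome_col <- setdiff(names(df), c("sample_id", "linear_predictor", "risk"))[1]
  df$outcome <- factor(df[[outcome_col]], levels = c(0, 1),
                       labels = c("no event", "event"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$risk)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "10-year predicted risk",
                  title = sprintf("%s (C-statistic %.3f)",
                                  object$equation$name, object$auc)) +
    ggplot2::theme_minimal()
}
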