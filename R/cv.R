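## Repeated class-stratified k-fold cross-validation with in-fold univariate
## ROC-AUC feature selection and a soft-margin linear SVM, plus the
## aggregation into performance summaries, an AUC-versus-model-size curve and
## feature-inclusion stability frequencies.

#' Configure the cross-validation harness
#'
#' Defaults reproduce the study design: 3-fold class-stratified
#' cross-validation repeated 400 times (1200 trials), linear soft-margin SVM
#' with unit penalty, confusion metrics at the margin midpoint.
#'
#' @param k_folds Number of folds (>= 2).
#' @param repeats Number of repeated random stratified partitions (>= 1).
#' @param max_features Largest candidate model size for
#'   [select_model_size()].
#' @param classifier_c Soft-margin penalty `C > 0` of the linear SVM.
#' @param decision_threshold Decision-value threshold for the confusion
#'   metrics (0 = margin midpoint).
#' @param seed Integer seed; the full metric stream is reproducible from it.
#' @return A `cv_config` list.
#' @export
#' @examples
#' cv_config(repeats = 10, seed = 1)
cv_config <- function(k_folds = 3L, repeats = 400L, max_features = 30L,
                      classifier_c = 1, decision_threshold = 0, seed = 1L) {
  if (k_folds < 2) abort("`k_folds` must be >= 2")
  if (repeats < 1) abort("`repeats` must be >= 1")
  if (max_features < 1) abort("`max_features` must be >= 1")
  if (classifier_c <= 0) abort("`classifier_c` must be > 0")
  structure(list(k_folds = as.integer(k_folds),
                 repeats = as.integer(repeats),
                 max_features = as.integer(max_features),
                 classifier_c = classifier_c,
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Class-stratified fold assignment
#'
#' Partitions samples into `k` folds preserving the class proportions: within
#' each class, fold sizes differ by at most one. Assignment consumes the
#' current RNG stream.
#'
#' @param labels Binary (or small categorical) class labels, one per sample.
#' @param k Number of folds; every class must have at least `k` members.
#' @return Integer fold id in `1..k` per sample.
#' @export
#' @examples
#' withr::with_seed(1, stratified_folds(rep(c(0, 1), c(45, 23)), 3))
stratified_folds <- function(labels, k) {
  idx_by_class <- split(seq_along(labels), labels)
  small <- names(idx_by_class)[lengths(idx_by_class) < k]
  if (length(small) > 0) {
    abort(sprintf("class(es) smaller than k = %d: %s", k,
                  paste(small, collapse = ", ")))
  }
  folds <- integer(length(labels))
  for (idx in idx_by_class) {
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Rank-based ROC AUC
#'
#' AUC as the probability that a random positive scores above a random
#' negative, ties counting one half — computed from midranks, hence exactly
#' the Mann-Whitney U statistic divided by n1*n0.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)) # 0.75
auc_rank <- function(scores, labels) {
  pos <- labels %in% c(1, TRUE) | labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate AUC feature ranking
#'
#' Orders features by decreasing two-sided discrimination |AUC - 0.5| of the
#' feature values against the training labels (anti-discriminating features
#' are as informative as discriminating ones for a classifier that can
#' negate a weight); ties break lexicographically on the feature id, so the
#' ranking is a deterministic function of the training data alone. Constant
#' features have AUC 0.5 and sort last.
#'
#' @param x Training feature matrix (or tibble), columns named.
#' @param labels Training labels (1/TRUE = positive).
#' @param quiet Suppress the constant-feature warning (used inside CV loops).
#' @return Tibble ordered by rank: `rank`, `feature_id`, `auc`, `score`.
#' @export
rank_features <- function(x, labels, quiet = FALSE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  aucs <- apply(x, 2, auc_rank, labels = labels)
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const) && !quiet) {
    warn(sprintf("constant feature(s) ranked last: %s",
                 paste(colnames(x)[const], collapse = ", ")))
  }
  out <- tibble(feature_id = colnames(x), auc = unname(aucs),
                score = abs(unname(aucs) - 0.5))
  out <- arrange(out, desc(.data$score), .data$feature_id)
  mutate(out, rank = row_number(), .before = 1)
}

#' Train a soft-margin linear support vector classifier
#'
#' Linear-kernel SVM minimising the soft-margin hinge objective
#' 0.5 ||w||^2 + C * sum(hinge), solved by libsvm via [e1071::svm()].
#' Features are expected pre-centred/scaled with training-fold statistics;
#' the scale parameters may be stored on the classifier so that
#' [predict.linear_svm()] can transform new data identically.
#'
#' @param x Training feature matrix (columns named).
#' @param y Labels in `{-1, +1}` (or 0/1; 1 = positive). Both classes needed.
#' @param c Penalty `C > 0`.
#' @param center,scale Optional per-feature training-fold centre/scale to
#'   store with the model (applied by `predict`).
#' @return A `linear_svm` object: `weights`, `bias`, `feature_ids`,
#'   `center`, `scale`. Decision value = `x %*% weights + bias`, positive
#'   class predicted when above the threshold.
#' @export
#' @examples
#' m <- train_linear_svm(cbind(x = c(-1, 1)), c(-1, 1), c = 10)
#' round(unname(m$weights), 3)
train_linear_svm <- function(x, y, c = 1, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y_pm <- ifelse(y > 0, 1, -1)
  if (length(unique(y_pm)) < 2) abort("both classes must be present")
  f <- factor(y_pm, levels = c(1, -1))
  fit <- e1071::svm(x = x, y = f, kernel = "linear", cost = c,
                    scale = FALSE, type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  ## libsvm orients decision values towards whichever class appeared first
  ## in the training data; normalise so positive decisions mean class +1
  if (fit$labels[1] != 1L) {
    w <- -w
    b <- -b
  }
  structure(list(weights = setNames(as.numeric(w), colnames(x)),
                 bias = as.numeric(b),
                 feature_ids = colnames(x),
                 center = center, scale = scale,
                 cost = c),
            class = "linear_svm")
}

#' @describeIn train_linear_svm Decision values for new samples (applying
#'   any stored centre/scale).
#' @param object A `linear_svm`.
#' @param newdata Matrix or tibble containing the model's features.
#' @param ... Unused.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_ids, drop = FALSE])
  if (!is.null(object$center)) x <- sweep(x, 2, object$center, `-`)
  if (!is.null(object$scale)) x <- sweep(x, 2, object$scale, `/`)
  drop(x %*% object$weights) + object$bias
}

## hinge objective, used by invariants/tests via lipidcvd:::svm_objective
svm_objective <- function(model, x, y) {
  y_pm <- ifelse(y > 0, 1, -1)
  d <- drop(as.matrix(x) %*% model$weights) + model$bias
  0.5 * sum(model$weights^2) + model$cost * sum(pmax(0, 1 - y_pm * d))
}

#' Confusion-matrix performance metrics at a threshold
#'
#' Accuracy, sensitivity, specificity, PPV and NPV (all in percent) of the
#' positive-if-above-threshold rule. Ratios with a zero denominator are
#' reported as `NA` (missing), never as zero.
#'
#' @param decision_values Continuous classifier scores.
#' @param labels Binary labels (1/TRUE = positive); both classes required.
#' @param threshold Decision threshold (default 0, the margin midpoint).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percent).
#' @export
#' @examples
#' confusion_metrics(c(1, 2, -1, -2, -3, 1), c(1, 1, 1, 0, 0, 0))
confusion_metrics <- function(decision_values, labels, threshold = 0) {
  pos <- labels %in% c(1, TRUE) | labels > 0
  if (all(pos) || !any(pos)) abort("both classes must be present")
  pred <- decision_values > threshold
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble(accuracy = ratio(tp + tn, tp + tn + fp + fn),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn))
}

#' Run the repeated stratified cross-validation harness
#'
#' For each repeat, samples are randomly partitioned into `k_folds`
#' class-stratified folds; each fold serves as the test set exactly once, so
#' `k_folds * repeats` trials are performed (1200 at the 3-fold / 400-repeat
#' defaults). Within each trial, strictly on the training two-thirds:
#' features are centred and scaled to unit SD, ranked by univariate
#' |AUC - 0.5|, the top `feature_count` are kept, and a linear soft-margin
#' SVM is fitted. The held-out third is transformed with the training-fold
#' statistics and scored; AUC uses the continuous decision values and the
#' other metrics the configured threshold. The held-out fold never
#' influences feature selection, scaling or training.
#'
#' @param x Sample-by-feature matrix or tibble (columns named; an optional
#'   `sample_id` column is dropped).
#' @param labels Binary outcome per sample (1 = positive class).
#' @param feature_count Number of features per model (>= 1).
#' @param config A [cv_config()].
#' @return A `cv_trials` tibble: one row per trial with `trial_index`,
#'   `repeat_index`, `fold_index`, the six performance measures
#'   (`accuracy`, `auc`, `sensitivity`, `specificity`, `ppv`, `npv`) and the
#'   list-column `selected_features`; attribute `selection_counts` holds the
#'   per-feature inclusion counts.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(seed = 2))
#' fm <- cv_features(coh, "conventional")
#' run_repeated_cv(fm$x, fm$y, 4, cv_config(repeats = 2, seed = 9))
run_repeated_cv <- function(x, labels, feature_count, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  if (feature_count < 1) abort("`feature_count` must be >= 1")
  if (is_tibble(x) || is.data.frame(x)) {
    x <- x[setdiff(names(x), "sample_id")]
    x <- as.matrix(x)
  }
  if (feature_count > ncol(x)) {
    abort(sprintf("`feature_count` (%d) exceeds available features (%d)",
                  feature_count, ncol(x)))
  }
  counts <- setNames(integer(ncol(x)), colnames(x))
  trials <- vector("list", config$k_folds * config$repeats)
  t_i <- 0L
  withr::with_seed(config$seed, {
    for (r in seq_len(config$repeats)) {
      folds <- stratified_folds(labels, config$k_folds)
      for (f in seq_len(config$k_folds)) {
        t_i <- t_i + 1L
        tr <- folds != f
        res <- cv_trial(x[tr, , drop = FALSE], labels[tr],
                        x[!tr, , drop = FALSE], labels[!tr],
                        feature_count, config)
        counts[res$selected] <- counts[res$selected] + 1L
        trials[[t_i]] <- bind_cols(
          tibble(trial_index = t_i, repeat_index = r, fold_index = f),
          res$metrics,
          tibble(selected_features = list(res$selected)))
      }
    }
  })
  out <- bind_rows(trials)
  class(out) <- c("cv_trials", class(out))
  attr(out, "selection_counts") <- counts
  attr(out, "config") <- config
  attr(out, "feature_count") <- as.integer(feature_count)
  out
}

## One train/test trial. Everything derived from the training portion only.
cv_trial <- function(xtr, ytr, xte, yte, feature_count, config) {
  ctr <- colMeans(xtr)
  scl <- apply(xtr, 2, sd)
  scl[scl == 0] <- 1
  xtr_s <- sweep(sweep(xtr, 2, ctr, `-`), 2, scl, `/`)
  ranking <- rank_features(xtr_s, ytr, quiet = TRUE)
  sel <- ranking$feature_id[seq_len(feature_count)]
  model <- train_linear_svm(xtr_s[, sel, drop = FALSE], ytr,
                            c = config$classifier_c,
                            center = ctr[sel], scale = scl[sel])
  dec <- predict(model, xte)
  metrics <- confusion_metrics(dec, yte, config$decision_threshold)
  metrics <- mutate(metrics, auc = auc_rank(dec, yte), .after = "accuracy")
  list(metrics = metrics, selected = sel, model = model)
}

CV_METRICS <- c("accuracy", "auc", "sensitivity", "specificity", "ppv", "npv")

#' Aggregate per-trial metrics into means with 95% confidence intervals
#'
#' Mean and normal-approximation 95% CI (mean +/- 1.96 SD/sqrt(n)) per
#' performance measure over trials; missing values (e.g. undefined PPV in a
#' trial without positive predictions) are excluded pairwise with the count
#' used reported.
#'
#' @param trials A `cv_trials` tibble from [run_repeated_cv()] (>= 2 rows).
#' @return Tibble: `metric`, `mean`, `ci95_low`, `ci95_high`, `n_used`.
#' @export
aggregate_trials <- function(trials) {
  if (nrow(trials) < 2) abort("need at least 2 trials to aggregate")
  z <- qnorm(0.975)
  rows <- purrr::map(intersect(CV_METRICS, names(trials)), function(m) {
    v <- trials[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble(metric = m, mean = NA_real_, ci95_low = NA_real_,
                    ci95_high = NA_real_, n_used = 0L))
    }
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    tibble(metric = m, mean = mean(v),
           ci95_low = mean(v) - z * se, ci95_high = mean(v) + z * se,
           n_used = length(v))
  })
  bind_rows(rows)
}

#' Choose the model size maximising the mean cross-validated AUC
#'
#' Runs the harness at each candidate feature count and returns the smallest
#' count attaining the maximal mean AUC (parsimony tie-break), together with
#' the full AUC-versus-size curve. All candidate sizes are evaluated with the
#' same seed, so they share the same fold sequences (paired comparison).
#'
#' @param x,labels As in [run_repeated_cv()].
#' @param config A [cv_config()]; candidates are `1..max_features`.
#' @param sizes Optional explicit candidate sizes.
#' @param repeats Repeats per candidate (default `config$repeats`; a reduced
#'   count makes the size search cheaper than the final run).
#' @return A `cv_size_selection` list: `n_star`, `curve` (tibble
#'   `n_features`, `mean_auc`, `ci95_low`, `ci95_high`).
#' @export
select_model_size <- function(x, labels, config = cv_config(),
                              sizes = NULL, repeats = NULL) {
  sizes <- sizes %||% seq_len(config$max_features)
  repeats <- repeats %||% config$repeats
  cfg <- config
  cfg$repeats <- as.integer(repeats)
  rows <- purrr::map(sizes, function(k) {
    tr <- run_repeated_cv(x, labels, k, cfg)
    agg <- aggregate_trials(tr)
    auc <- agg[agg$metric == "auc", ]
    tibble(n_features = k, mean_auc = auc$mean,
           ci95_low = auc$ci95_low, ci95_high = auc$ci95_high)
  })
  curve <- bind_rows(rows)
  n_star <- curve$n_features[which.max(curve$mean_auc)] # which.max = first max
  ## guard: which.max returns the first maximum in vector order; with sizes
  ## ascending that is the smallest size attaining the maximum
  structure(list(n_star = as.integer(n_star), curve = curve),
            class = "cv_size_selection")
}

#' Feature-inclusion stability table
#'
#' Converts per-feature selection counts into the percentage of trials in
#' which each feature entered the model, ranked by decreasing frequency
#' (ties broken by feature id).
#'
#' @param selection_counts Named integer vector of selection counts (the
#'   `selection_counts` attribute of a `cv_trials` object, or any named
#'   counts).
#' @param n_trials Total number of trials; all counts must be `<=` it.
#' @return Tibble: `rank`, `feature_id`, `count`, `frequency` (percent).
#' @export
#' @examples
#' inclusion_table(c(TG_01 = 1140, DG_02 = 30), 1200)
inclusion_table <- function(selection_counts, n_trials) {
  if (any(selection_counts > n_trials)) {
    abort("selection counts cannot exceed the number of trials")
  }
  if (any(selection_counts < 0)) abort("selection counts must be >= 0")
  out <- tibble(feature_id = names(selection_counts),
                count = as.integer(selection_counts),
                frequency = 100 * as.numeric(selection_counts) / n_trials)
  out <- arrange(out, desc(.data$frequency), .data$feature_id)
  mutate(out, rank = row_number(), .before = 1)
}

#' Assemble the cross-validation feature table for a cohort
#'
#' Builds the sample-by-feature table and binary outcome for the
#' case-vs-control prediction task from a cohort, for one of the three
#' study feature sets: lipid species alone, conventional lipids alone
#' (HDL-C, LDL-C, total cholesterol, triglycerides), or both combined.
#' Concentration features enter on the log10 scale.
#'
#' @param cohort A `lipid_cohort` (or compatible list).
#' @param set `"species"`, `"conventional"` or `"combined"`.
#' @param case_group,control_group Groups defining the task (defaults:
#'   HIV cases vs HIV controls).
#' @return List: `x` (feature matrix), `y` (binary outcome, 1 = case),
#'   `sample_id`.
#' @export
cv_features <- function(cohort, set = c("species", "conventional", "combined"),
                        case_group = "HIV_CASE", control_group = "HIV_CONTROL") {
  set <- match.arg(set)
  parts <- as_cohort_parts(cohort)
  keep <- parts$samples$group %in% c(case_group, control_group)
  samples <- parts$samples[keep, , drop = FALSE]
  lip <- parts$lipids[match(samples$sample_id, parts$lipids$sample_id), ,
                      drop = FALSE]
  conv_cols <- c("hdl", "ldl", "tc", "tg")
  species <- log10(as.matrix(lip[setdiff(names(lip), "sample_id")]))
  conv <- log10(as.matrix(as.data.frame(samples[conv_cols])))
  x <- switch(set,
              species = species,
              conventional = conv,
              combined = cbind(species, conv))
  list(x = x, y = as.integer(samples$group == case_group),
       sample_id = samples$sample_id)
}

#' Full cross-validation report (model-size search + final harness)
#'
#' Convenience composition: searches the model size on a (typically reduced)
#' number of repeats, reruns the harness at the chosen size with the full
#' repeat count, and aggregates performance, the AUC-versus-size curve and
#' the feature-inclusion stability table into one report object.
#'
#' @param x,labels As in [run_repeated_cv()].
#' @param config A [cv_config()].
#' @param sizes Candidate model sizes (default `1..max_features`).
#' @param size_repeats Repeats used during the size search (default 20).
#' @return A `lipid_cv_report` list: `summary`, `n_star`, `curve`,
#'   `inclusion`, `trials`, `config`.
#' @export
cv_report <- function(x, labels, config = cv_config(), sizes = NULL,
                      size_repeats = 20) {
  sel <- select_model_size(x, labels, config, sizes = sizes,
                           repeats = min(size_repeats, config$repeats))
  trials <- run_repeated_cv(x, labels, sel$n_star, config)
  structure(list(
    summary = aggregate_trials(trials),
    n_star = sel$n_star,
    curve = sel$curve,
    inclusion = inclusion_table(attr(trials, "selection_counts"), nrow(trials)),
    trials = trials,
    config = config
  ), class = "lipid_cv_report")
}

#' @export
print.lipid_cv_report <- function(x, ...) {
  cat(sprintf("<lipid_cv_report> %d trials (%d-fold x %d repeats), n* = %d features\n",
              nrow(x$trials), x$config$k_folds, x$config$repeats, x$n_star))
  print(x$summary)
  invisible(x)
}
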