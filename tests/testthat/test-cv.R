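# Cross-validation harness: stratified partitions, AUC ranking, the linear
# SVM, confusion metrics, trial bookkeeping, aggregation, model-size
# selection and inclusion frequencies.

test_that("stratified folds keep class proportions and partition the samples", {
  labels <- rep(c(1, 0), c(23, 45))
  withr::with_seed(1, {
    for (i in 1:10) {
      f <- stratified_folds(labels, 3)
      expect_setequal(unique(f), 1:3)
      # partition: every sample in exactly one fold (by construction a vector)
      case_counts <- table(f[labels == 1])
      ctrl_counts <- table(f[labels == 0])
      expect_true(all(case_counts %in% c(7, 8)))
      expect_equal(sum(case_counts), 23)
      expect_true(all(ctrl_counts == 15))
    }
  })
  withr::with_seed(2, {
    f <- stratified_folds(rep(c(0, 1), each = 6), 3)
    expect_true(all(table(f, rep(c(0, 1), each = 6)) == 2))
  })
  expect_error(withr::with_seed(1, stratified_folds(rep(c(0, 1), c(2, 30)), 3)),
               "smaller than k")
})

test_that("auc_rank matches pair enumeration and tie conventions", {
  expect_equal(auc_rank(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(3, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(auc_rank(1:4, rep(1, 4)), "both classes")
  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(6:20, 1)
      s <- sample(1:8, n, replace = TRUE)
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) next
      expect_equal(auc_rank(s, l), auc_pairs(s, l), tolerance = 1e-12)
    }
  })
})

test_that("rank_features orders by two-sided discrimination with deterministic ties", {
  y <- rep(c(1, 0), each = 10)
  x <- cbind(perfect = y + 0,                       # identical to label
             anti = withr::with_seed(5, -y + rnorm(20, 0, 0.45)), # auc ~ 0.1
             weak = withr::with_seed(6, y * 0.3 + rnorm(20)),
             const = rep(1, 20))
  expect_warning(r <- rank_features(x, y), "constant")
  expect_equal(r$feature_id[1], "perfect")
  expect_equal(r$feature_id[nrow(r)], "const")
  # anti-discriminating beats weak under |auc - 0.5|
  expect_lt(which(r$feature_id == "anti"), which(r$feature_id == "weak"))
  # permuting sample order leaves the ranking unchanged
  perm <- withr::with_seed(8, sample(20))
  r2 <- rank_features(x[perm, c(1:3)], y[perm], quiet = TRUE)
  expect_equal(r2$feature_id, r$feature_id[r$feature_id != "const"])
})

test_that("train_linear_svm recovers max-margin geometry and symmetries", {
  m <- train_linear_svm(cbind(x = c(-1, 1)), c(-1, 1), c = 100)
  expect_equal(unname(m$weights), 1, tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)

  withr::with_seed(9, {
    X <- cbind(a = rnorm(30), b = rnorm(30))
    y <- ifelse(X[, "a"] + 0.5 * rnorm(30) > 0, 1, -1)
  })
  if (length(unique(y)) < 2) y[1] <- -y[1]
  m1 <- train_linear_svm(X, y, c = 1)
  # duplicating every point with the penalty halved leaves the solution alone
  m2 <- train_linear_svm(rbind(X, X), c(y, y), c = 0.5)
  expect_equal(m1$weights, m2$weights, tolerance = 2e-3)
  expect_equal(m1$bias, m2$bias, tolerance = 2e-3)
  # flipping all labels negates the decision function
  m3 <- train_linear_svm(X, -y, c = 1)
  expect_equal(m3$weights, -m1$weights, tolerance = 1e-6)
  expect_equal(m3$bias, -m1$bias, tolerance = 1e-6)
  # hinge objective at the solution is no worse than the trivial w = 0, b = 0
  obj <- lipidcvd:::svm_objective(m1, X, y)
  obj0 <- 1 * length(y) # w = 0, b = 0 => hinge loss of 1 per sample
  expect_lte(obj, obj0)

  # degenerate identical rows with mixed labels: converges, no crash
  Xd <- matrix(1, nrow = 6, ncol = 2, dimnames = list(NULL, c("a", "b")))
  md <- train_linear_svm(Xd, rep(c(1, -1), 3), c = 1)
  expect_true(all(is.finite(md$weights)))
})

test_that("confusion_metrics computes the standard ratios and flags undefined ones", {
  # TP=2, FN=1, TN=3, FP=0
  m <- confusion_metrics(c(1, 2, -1, -2, -3, -1), c(1, 1, 1, 0, 0, 0))
  expect_equal(m$sensitivity, 200 / 3, tolerance = 1e-9)
  expect_equal(m$specificity, 100)
  expect_equal(m$ppv, 100)
  expect_equal(m$npv, 75)
  expect_equal(m$accuracy, 500 / 6, tolerance = 1e-9)

  perfect <- confusion_metrics(c(1, 1, -1, -1), c(1, 1, 0, 0))
  expect_true(all(unlist(perfect) == 100))

  none_pos <- confusion_metrics(c(-1, -2, -3, -4), c(1, 0, 1, 0))
  expect_true(is.na(none_pos$ppv))
  expect_false(is.na(none_pos$npv))
})

test_that("the harness emits k*repeats reproducible trials with training-only selection", {
  coh <- generate_cohort(tiny_config(seed = 2))
  fm <- cv_features(coh, "species")
  cfg <- cv_config(repeats = 4, seed = 77)
  tr <- run_repeated_cv(fm$x, fm$y, 2, cfg)
  expect_equal(nrow(tr), 12)
  expect_equal(max(tr$repeat_index), 4)
  expect_equal(sort(unique(tr$fold_index)), 1:3)
  expect_true(all(lengths(tr$selected_features) == 2))
  counts <- attr(tr, "selection_counts")
  expect_equal(sum(counts), 12 * 2)
  # determinism
  tr2 <- run_repeated_cv(fm$x, fm$y, 2, cfg)
  metrics <- c("accuracy", "auc", "sensitivity", "specificity", "ppv", "npv")
  expect_equal(as.data.frame(tr[metrics]), as.data.frame(tr2[metrics]))
  expect_identical(tr$selected_features, tr2$selected_features)
  expect_error(run_repeated_cv(fm$x, fm$y, 0, cfg), ">= 1")
  expect_error(run_repeated_cv(fm$x, fm$y, 99, cfg), "exceeds")
})

test_that("held-out labels influence nothing but the recorded metrics", {
  coh <- generate_cohort(tiny_config(seed = 6))
  fm <- cv_features(coh, "species")
  cfg <- cv_config(repeats = 5, seed = 12)
  k <- cfg$k_folds
  withr::with_seed(cfg$seed, {
    for (r in seq_len(cfg$repeats)) {
      folds <- stratified_folds(fm$y, k)
      for (f in seq_len(k)) {
        tr_idx <- folds != f
        yte <- fm$y[!tr_idx]
        res1 <- lipidcvd:::cv_trial(fm$x[tr_idx, ], fm$y[tr_idx],
                                    fm$x[!tr_idx, ], yte, 2, cfg)
        res2 <- lipidcvd:::cv_trial(fm$x[tr_idx, ], fm$y[tr_idx],
                                    fm$x[!tr_idx, ], rev(yte), 2, cfg)
        expect_identical(res1$selected, res2$selected)
        expect_identical(res1$model$weights, res2$model$weights)
        expect_identical(res1$model$bias, res2$model$bias)
      }
    }
  })
})

test_that("aggregate_trials returns normal-approximation CIs with pairwise exclusion", {
  tr <- tibble::tibble(accuracy = c(70, 80, 90), auc = c(0.7, 0.8, 0.9),
                       sensitivity = c(NA, 50, 70), specificity = c(90, 90, 90),
                       ppv = c(NA, NA, NA), npv = c(60, 70, 80))
  agg <- aggregate_trials(tr)
  auc <- agg[agg$metric == "auc", ]
  expect_equal(auc$mean, 0.8)
  expect_equal(auc$ci95_high - auc$mean, 1.96 * 0.1 / sqrt(3), tolerance = 1e-3)
  expect_equal(agg$n_used[agg$metric == "sensitivity"], 2L)
  expect_true(is.na(agg$mean[agg$metric == "ppv"]))
  spec <- agg[agg$metric == "specificity", ]
  expect_equal(spec$ci95_low, spec$ci95_high)  # constant metric, zero width
  expect_true(all(agg$ci95_low <= agg$mean & agg$mean <= agg$ci95_high,
                  na.rm = TRUE))
  expect_error(aggregate_trials(tr[1, ]), "at least 2")
})

test_that("select_model_size takes the smallest size attaining the maximal AUC", {
  # an informative feature duplicated: sizes 1 and 2 give identical rankings
  # of the decision values, so their mean AUCs tie exactly and parsimony
  # must pick 1
  withr::with_seed(14, {
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    sig <- y * 1.5 + rnorm(n)
    x <- cbind(a_sig = sig, b_dup = sig)
  })
  sel <- select_model_size(x, y, cv_config(repeats = 5, max_features = 2,
                                           seed = 3))
  expect_equal(nrow(sel$curve), 2)
  expect_equal(sel$curve$mean_auc[1], sel$curve$mean_auc[2], tolerance = 1e-12)
  expect_equal(sel$n_star, 1L)

  sel1 <- select_model_size(x, y, cv_config(repeats = 3, seed = 4), sizes = 1)
  expect_equal(sel1$n_star, 1L)
  expect_s3_class(tidy(sel1), "tbl_df")
})

test_that("inclusion_table ranks features by stability", {
  tab <- inclusion_table(c(TG_1 = 1140, DG_1 = 0, CE_1 = 600), 1200)
  expect_equal(tab$frequency, c(95, 50, 0))
  expect_equal(tab$feature_id, c("TG_1", "CE_1", "DG_1"))
  expect_equal(tab$rank, 1:3)
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 100))
  expect_error(inclusion_table(c(a = 10), 5), "exceed")
  # ties broken by feature id
  t2 <- inclusion_table(c(b = 5, a = 5), 10)
  expect_equal(t2$feature_id, c("a", "b"))
})

test_that("cv_report composes size search, final run and tidiers", {
  coh <- generate_cohort(tiny_config(seed = 10))
  fm <- cv_features(coh, "conventional")
  rep_obj <- cv_report(fm$x, fm$y, cv_config(repeats = 4, max_features = 3,
                                             seed = 2), size_repeats = 2)
  expect_s3_class(rep_obj, "lipid_cv_report")
  expect_equal(nrow(rep_obj$trials), 12)
  expect_true(rep_obj$n_star >= 1 && rep_obj$n_star <= 3)
  expect_equal(nrow(tidy(rep_obj)), 6)
  g <- glance(rep_obj)
  expect_equal(g$n_trials, 12)
  expect_true(g$mean_auc >= 0 && g$mean_auc <= 1)
  p <- autoplot(rep_obj)
  expect_s3_class(p, "ggplot")
  p2 <- plot_inclusion(rep_obj)
  expect_s3_class(p2, "ggplot")
})
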