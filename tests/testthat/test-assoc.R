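# Association statistics: logistic fits against closed forms, OR-per-IQR
# scaling, BH adjustment against a brute-force oracle, class aggregation,
# rank tests against enumeration, and the association scan contract.

test_that("fit_logistic matches the closed-form 2x2 log odds ratio", {
  # counts: a = (x=1, y=1), b = (x=1, y=0), c = (x=0, y=1), d = (x=0, y=0)
  a <- 10; b <- 20; c <- 30; d <- 40
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  fit <- fit_logistic(cbind(intercept = 1, x = x), y)
  expect_equal(unname(fit$beta["x"]), log(a * d / (b * c)), tolerance = 1e-6)
  expect_equal(unname(fit$beta["x"]), -0.4055, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("intercept-only fit returns the logit of the prevalence", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(cbind(intercept = rep(1, 100)), y)
  expect_equal(unname(fit$beta), log(0.3 / 0.7), tolerance = 1e-6)
})

test_that("fit_logistic flags separation and rejects degenerate inputs", {
  x <- c(-2, -1, 1, 2)
  fit <- fit_logistic(cbind(intercept = 1, x = x), c(0, 0, 1, 1))
  expect_false(fit$converged)
  expect_true(fit$separated)

  expect_error(fit_logistic(cbind(intercept = 1, x = x), c(1, 1, 1, 1)),
               "single class")
  X <- cbind(intercept = 1, x = x, x2 = 2 * x)
  expect_error(fit_logistic(X, c(0, 1, 0, 1)), "collinear.*x2")
})

test_that("or_per_iqr applies the Wald construction on the IQR scale", {
  null <- or_per_iqr(0, 0.2, 1.5)
  expect_equal(null$or_per_iqr, 1)
  expect_equal(null$ci95_low * null$ci95_high, 1, tolerance = 1e-9)

  res <- or_per_iqr(0.5, 0.1, 2)
  z <- qnorm(0.975)
  expect_equal(res$or_per_iqr, exp(1), tolerance = 1e-12)
  expect_equal(res$ci95_low, exp((0.5 - z * 0.1) * 2), tolerance = 1e-12)
  expect_equal(res$ci95_high, exp((0.5 + z * 0.1) * 2), tolerance = 1e-12)
  # hand arithmetic at z = 1.96
  expect_equal(res$ci95_low, 1.8367, tolerance = 1e-3)
  expect_equal(res$ci95_high, 4.0228, tolerance = 1e-3)

  expect_equal(or_per_iqr(0.7, 0.1, 1)$or_per_iqr, exp(0.7))
  expect_warning(out <- or_per_iqr(0.5, 0.1, 0), "constant")
  expect_true(is.na(out$or_per_iqr))
  # monotone in beta for fixed positive IQR
  ors <- vapply(c(-1, 0, 0.5, 2),
                function(b) or_per_iqr(b, 0.1, 1.5)$or_per_iqr, numeric(1))
  expect_true(all(diff(ors) > 0))
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the brute-force min-over-suffix oracle and keeps its invariants", {
  withr::with_seed(101, {
    for (i in 1:25) {
      m <- sample(1:8, 1)
      p <- round(runif(m), 3)
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      expect_true(all(adj <= 1))
      # order preservation, and the sorted adjusted values are already
      # monotone (a second min-over-suffix monotonisation changes nothing)
      srt <- adj[order(p)]
      expect_true(all(diff(srt) >= -1e-12))
      expect_equal(rev(cummin(rev(srt))), srt, tolerance = 1e-12)
    }
  })
})

test_that("class_totals sums member species and conserves totals", {
  lip <- tibble::tibble(sample_id = c("s1", "s2"),
                        A_1 = c(1, 10), A_2 = c(2, 20), A_3 = c(3, 30),
                        B_1 = c(4, 40))
  cm <- tibble::tibble(species_id = c("A_1", "A_2", "A_3", "B_1"),
                       class_name = c("A", "A", "A", "B"))
  ct <- class_totals(lip, cm)
  expect_equal(ct$A, c(6, 60))
  expect_equal(ct$B, c(4, 40))          # single-species class = identity
  expect_equal(ct$A + ct$B, rowSums(lip[-1]))  # conservation
  expect_error(class_totals(dplyr::mutate(lip, C_1 = 1), cm), "C_1")
})

test_that("mann_whitney_u matches exact enumeration and handles ties", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / choose(6, 3), tolerance = 1e-12)

  x <- c(1, 2, 2, 3)
  same <- mann_whitney_u(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_gt(same$p, 0.95)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U/(nx*ny) equals the rank AUC on random inputs", {
  withr::with_seed(7, {
    for (i in 1:20) {
      nx <- sample(3:10, 1); ny <- sample(3:10, 1)
      x <- sample(1:6, nx, replace = TRUE) + runif(nx, 0, 0.01)
      y <- sample(1:6, ny, replace = TRUE) + runif(ny, 0, 0.01)
      u <- mann_whitney_u(x, y)$U
      auc <- auc_rank(c(x, y), rep(c(1, 0), c(nx, ny)))
      expect_equal(u / (nx * ny), auc, tolerance = 1e-12)
    }
  })
})

test_that("exact and normal-approximation Mann-Whitney p-values agree for n=6+6", {
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- rnorm(6); y <- rnorm(6, 0.5)
      p_exact <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
      p_norm <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      expect_lt(abs(p_exact - p_norm), 0.02)
      # the package takes the exact path here
      expect_equal(mann_whitney_u(x, y)$p, p_exact, tolerance = 1e-12)
    }
  })
})

test_that("fisher_exact equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(3, 1, 1, 3), fisher_oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  expect_equal(fisher_exact(3, 1, 1, 3), 0.4857, tolerance = 1e-4)
  withr::with_seed(3, {
    for (i in 1:30) {
      tab <- sample(0:12, 4, replace = TRUE)
      if (sum(tab) == 0) next
      expect_equal(do.call(fisher_exact, as.list(tab)),
                   do.call(fisher_oracle, as.list(tab)),
                   tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact(-1, 2, 3, 4), "nonnegative")
})

test_that("association_scan emits one record per feature with a separate class family", {
  coh <- generate_cohort(generator_config(seed = 19))
  ct <- contrast_spec("HIV_CONTROL", "HEALTHY")
  cls <- association_scan(coh, ct, level = "class")
  expect_equal(nrow(cls), 24)
  expect_s3_class(cls, "lipid_assoc")
  sp <- association_scan(coh, ct, level = "species")
  expect_equal(nrow(sp), 316)
  expect_true(all(sp$n_used == 90))
  ok <- !is.na(sp$p_adj)
  expect_true(all(sp$p_adj[ok] >= sp$p_raw[ok]))
  expect_true(all(sp$ci95_low[ok] <= sp$or_per_iqr[ok] &
                  sp$or_per_iqr[ok] <= sp$ci95_high[ok]))
  g <- glance(sp)
  expect_equal(g$n_features, 316)
  expect_error(association_scan(coh, contrast_spec("HIV_CASE", "HIV_CONTROL",
                                                   adjust = "no_such_cov")),
               "no_such_cov")
})

test_that("a strongly injected species attains the smallest adjusted p-value", {
  hits <- vapply(1:10, function(s) {
    cfg <- generator_config(
      group_sizes = c(HIV_CASE = 400, HIV_CONTROL = 400, HEALTHY = 0),
      species_per_class = c(AA = 5, BB = 5), seed = 400 + s,
      effects = effect_spec("AA_02", "CASE_vs_CONTROL", 3.0))
    scan <- association_scan(generate_cohort(cfg),
                             contrast_spec("HIV_CASE", "HIV_CONTROL"))
    scan$feature_id[which.min(scan$p_adj)] == "AA_02"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort_table summarises and compares the configured variables", {
  coh <- generate_cohort(generator_config(seed = 23, confounded = TRUE))
  tab <- cohort_table(coh$samples)
  vars <- setdiff(names(coh$samples), c("sample_id", "group", "cvd_event"))
  expect_equal(nrow(tab), length(vars))
  expect_true(all(c("HIV_CASE", "HIV_CONTROL", "HEALTHY") %in% names(tab)))

  # identical binary variable => p = 1
  s <- coh$samples
  s$always <- 1
  t2 <- cohort_table(s, variables = "always",
                     group_pairs = list(c("HIV_CASE", "HIV_CONTROL")))
  expect_equal(t2$p_HIV_CASE_vs_HIV_CONTROL, 1)
  expect_equal(t2$type, "binary")

  # large constant shift at n = 45 vs 45 => p < 0.001
  s$shifted <- rnorm(nrow(s)) + ifelse(s$group == "HEALTHY", 100, 0)
  t3 <- cohort_table(s, variables = "shifted",
                     group_pairs = list(c("HIV_CONTROL", "HEALTHY")))
  expect_lt(t3$p_HIV_CONTROL_vs_HEALTHY, 0.001)
  expect_error(cohort_table(s, variables = "nope"), "unknown variable")
})
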