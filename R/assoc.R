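## Case-control association scans: per-feature logistic regression with odds
## ratios scaled to an interquartile-range increase, Benjamini-Hochberg FDR
## across each feature family, and the cohort characteristics comparisons
## (Mann-Whitney U / Fisher's exact).

#' Define a two-group contrast for an association scan
#'
#' @param case_group,control_group Distinct group labels; the outcome is 1
#'   for `case_group`.
#' @param adjust Character vector of covariate column names to adjust for
#'   (entered as additional linear terms in every per-feature fit). The
#'   study-design contrasts are HIV control vs healthy adjusted for family
#'   history of CHD, smoking and hsCRP, and HIV case vs HIV control adjusted
#'   for current statin treatment.
#' @return A `contrast_spec` list.
#' @export
#' @examples
#' contrast_spec("HIV_CONTROL", "HEALTHY",
#'               adjust = c("family_history_chd", "smoker", "hscrp"))
#' contrast_spec("HIV_CASE", "HIV_CONTROL", adjust = "statin")
contrast_spec <- function(case_group, control_group, adjust = character()) {
  if (identical(case_group, control_group)) {
    abort("`case_group` and `control_group` must be distinct")
  }
  structure(list(case_group = case_group, control_group = control_group,
                 adjust = adjust,
                 label = paste0(case_group, "_vs_", control_group)),
            class = "contrast_spec")
}

#' Maximum-likelihood binary logistic regression
#'
#' Thin validated wrapper around binomial iteratively reweighted least
#' squares ([stats::glm.fit()]). The covariance matrix is the inverse
#' observed information at the optimum. Complete separation is detected as a
#' vanishing deviance and reported via `converged = FALSE` rather than as a
#' spuriously precise fit.
#'
#' @param design Numeric design matrix including the intercept column; must
#'   be of full column rank.
#' @param y Binary 0/1 outcome with both classes present.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return List with `beta` (named coefficients), `vcov`, `converged`,
#'   `separated`, `n`.
#' @export
#' @examples
#' X <- cbind(intercept = 1, x = c(0, 0, 1, 1, 0, 1))
#' fit_logistic(X, c(0, 1, 0, 1, 0, 1))$beta
fit_logistic <- function(design, y, max_iter = 100, tol = 1e-10) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (!all(y %in% c(0, 1))) abort("`y` must be binary 0/1")
  if (length(unique(y)) < 2) abort("`y` contains a single class; cannot fit")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    dropped <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    abort(sprintf("design matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  boundary <- FALSE
  fit <- withCallingHandlers(
    glm.fit(design, y, family = binomial(),
            control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        boundary <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  info <- crossprod(design * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(design), ncol(design))
  })
  dimnames(vc) <- list(colnames(design), colnames(design))
  separated <- fit$deviance < 1e-6 ||
    (boundary && max(abs(fit$coefficients)) > 20)
  list(beta = setNames(fit$coefficients, colnames(design)),
       vcov = vc,
       converged = isTRUE(fit$converged) && !separated,
       separated = separated,
       n = length(y))
}

#' Odds ratio (with 95% CI) per interquartile-range increase
#'
#' Rescales a per-unit logistic coefficient to the odds ratio for an increase
#' of one IQR of the predictor on the analysis scale:
#' OR = exp(beta * IQR), Wald CI = exp((beta +/- 1.96 se) * IQR).
#'
#' @param beta,se Coefficient and standard error on the per-unit scale.
#' @param iqr IQR of the predictor on the same scale (> 0); a zero IQR
#'   (constant feature) yields `NA` with a warning, never a silent drop.
#' @return Tibble row: `or_per_iqr`, `ci95_low`, `ci95_high`.
#' @export
#' @examples
#' or_per_iqr(0.5, 0.1, 2) # OR = e
or_per_iqr <- function(beta, se, iqr) {
  if (se < 0) abort("`se` must be >= 0")
  if (!is.finite(iqr) || iqr <= 0) {
    warn("constant feature (IQR = 0): OR per IQR undefined, returning NA")
    return(tibble(or_per_iqr = NA_real_, ci95_low = NA_real_,
                  ci95_high = NA_real_))
  }
  z <- qnorm(0.975)
  tibble(or_per_iqr = exp(beta * iqr),
         ci95_low = exp((beta - z * se) * iqr),
         ci95_high = exp((beta + z * se) * iqr))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' False-discovery-rate adjusted p-values in the input order:
#' q(i) = min over j >= i of (p(j) * m / j) on the ascending sort, capped at 1.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  assert_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Aggregate a species matrix to lipid-class totals
#'
#' Class-level features are the per-sample sum (or mean) of the raw
#' concentrations of the member species. Aggregation is meaningful on the
#' concentration scale, so supply raw values; log-transform afterwards if the
#' analysis scale requires it.
#'
#' @param lipids Tibble: `sample_id` plus one column per species.
#' @param class_map Tibble with `species_id`, `class_name` covering every
#'   species column.
#' @param agg `"sum"` (default) or `"mean"`.
#' @return Tibble: `sample_id` plus one column per class.
#' @export
class_totals <- function(lipids, class_map, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  sp <- setdiff(names(lipids), "sample_id")
  unmapped <- setdiff(sp, class_map$species_id)
  if (length(unmapped) > 0) {
    abort(sprintf("species without a class mapping: %s",
                  paste(head(unmapped, 10), collapse = ", ")))
  }
  cls <- class_map$class_name[match(sp, class_map$species_id)]
  vals <- as.matrix(lipids[sp])
  agg_fun <- if (agg == "sum") rowSums else rowMeans
  members <- split(seq_along(cls), cls)[unique(cls)]
  out <- vapply(members, function(j) agg_fun(vals[, j, drop = FALSE]),
                numeric(nrow(vals)))
  if (nrow(vals) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(members)))
  bind_cols(lipids["sample_id"], as_tibble(out))
}

## Coerce a cohort-like object to raw-scale lipids + samples + class_map.
as_cohort_parts <- function(cohort) {
  stopifnot(all(c("lipids", "samples", "class_map") %in% names(cohort)))
  lipids <- cohort$lipids
  scale_in <- tryCatch(cohort$config$export_scale, error = function(e) NULL)
  if (identical(scale_in, "log10")) {
    sp <- setdiff(names(lipids), "sample_id")
    lipids[sp] <- 10^lipids[sp]
  }
  list(lipids = lipids, samples = cohort$samples, class_map = cohort$class_map)
}

#' Per-feature logistic association scan
#'
#' Fits one logistic regression per feature (lipid species or class) for a
#' two-group contrast: outcome ~ intercept + feature + adjustment covariates.
#' Features enter on the analysis scale (log10 concentration by default); the
#' odds ratio is reported per interquartile-range increase, with the IQR
#' computed on the analysis scale over the samples entering the fit.
#' Benjamini-Hochberg correction is applied across all converged features of
#' the same level within the contrast; species and class families are
#' corrected separately.
#'
#' @param cohort A `lipid_cohort`, or any list with `lipids` (raw
#'   concentrations), `samples` and `class_map` in the package schema.
#' @param contrast A [contrast_spec()].
#' @param level `"species"` or `"class"`.
#' @param analysis_scale `"log10"` (default) or `"raw"`; the scale on which
#'   the predictor (and its IQR) enters the model.
#' @param class_agg Class aggregation rule for `level = "class"`.
#' @return A `lipid_assoc` tibble: one row per feature with `beta`, `se`,
#'   `or_per_iqr`, `ci95_low`, `ci95_high`, `p_raw`, `p_adj`, `iqr_used`,
#'   `n_used`, `converged`, `status` (`"ok"`, `"constant"`, `"unconverged"`).
#'   Non-`ok` rows are retained (enumerated, not dropped) but excluded from
#'   the BH family.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(seed = 3))
#' scan <- association_scan(coh, contrast_spec("HIV_CONTROL", "HEALTHY"),
#'                          level = "class")
#' dplyr::filter(scan, p_adj < 0.05)
association_scan <- function(cohort, contrast,
                             level = c("species", "class"),
                             analysis_scale = c("log10", "raw"),
                             class_agg = c("sum", "mean")) {
  level <- match.arg(level)
  analysis_scale <- match.arg(analysis_scale)
  class_agg <- match.arg(class_agg)
  stopifnot(inherits(contrast, "contrast_spec"))
  parts <- as_cohort_parts(cohort)
  samples <- parts$samples

  feats <- if (level == "species") parts$lipids
           else class_totals(parts$lipids, parts$class_map, agg = class_agg)
  feature_ids <- setdiff(names(feats), "sample_id")
  if (length(feature_ids) == 0) abort("empty feature set")
  missing_cov <- setdiff(contrast$adjust, names(samples))
  if (length(missing_cov) > 0) {
    abort(sprintf("adjustment covariate(s) missing from samples: %s",
                  paste(missing_cov, collapse = ", ")))
  }

  keep <- samples$group %in% c(contrast$case_group, contrast$control_group)
  if (sum(samples$group[keep] == contrast$case_group) < 2 ||
      sum(samples$group[keep] == contrast$control_group) < 2) {
    abort("both contrast groups need at least 2 samples")
  }
  samples <- samples[keep, , drop = FALSE]
  feats <- feats[match(samples$sample_id, feats$sample_id), , drop = FALSE]
  y <- as.integer(samples$group == contrast$case_group)
  covs <- if (length(contrast$adjust) > 0) {
    as.matrix(as.data.frame(samples[contrast$adjust]))
  } else NULL

  rows <- purrr::map(feature_ids, function(fid) {
    x <- feats[[fid]]
    if (analysis_scale == "log10") {
      if (any(x <= 0)) {
        abort(sprintf("feature '%s' has nonpositive values; log10 scale impossible", fid))
      }
      x <- log10(x)
    }
    iqr <- iqr7(x)
    base <- tibble(feature_id = fid, level = level,
                   contrast = contrast$label,
                   beta = NA_real_, se = NA_real_,
                   or_per_iqr = NA_real_, ci95_low = NA_real_,
                   ci95_high = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                   iqr_used = iqr, n_used = length(y),
                   converged = FALSE, status = "constant")
    if (iqr <= 0) return(base)
    X <- cbind(intercept = 1, feature = x, covs)
    fit <- tryCatch(fit_logistic(X, y), error = function(e) NULL)
    if (is.null(fit)) return(mutate(base, status = "unconverged"))
    b <- fit$beta[["feature"]]
    s <- sqrt(fit$vcov["feature", "feature"])
    if (!fit$converged || !is.finite(s)) {
      return(mutate(base, beta = b, converged = FALSE,
                    status = "unconverged"))
    }
    orci <- or_per_iqr(b, s, iqr)
    mutate(base, beta = b, se = s,
           or_per_iqr = orci$or_per_iqr, ci95_low = orci$ci95_low,
           ci95_high = orci$ci95_high,
           p_raw = 2 * pnorm(-abs(b / s)),
           converged = TRUE, status = "ok")
  })
  out <- bind_rows(rows)
  ok <- out$status == "ok"
  out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
  n_skip <- sum(!ok)
  if (n_skip > 0) {
    warn(sprintf("%d feature(s) skipped from the BH family (%s)", n_skip,
                 paste(out$feature_id[!ok], collapse = ", ")))
  }
  class(out) <- c("lipid_assoc", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "analysis_scale") <- analysis_scale
  attr(out, "iqr_basis") <- "samples entering the fit"
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from midranks (ties share ranks). The p-value uses exact
#' enumeration for small tie-free samples (m + n <= 12) and otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction, via [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List with `U` (for `x`) and two-sided `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
mann_whitney_u <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("`x` and `y` must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (m + n <= 12) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  list(U = U, p = min(p, 1))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value summing the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table.
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = groups,
#'   columns = outcome: table `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(3, 1, 1, 3)
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be nonnegative integers")
  }
  if (sum(counts) == 0) abort("at least one margin must be positive")
  fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Cohort characteristics comparison table
#'
#' Summarises each requested variable per group — median (Q1-Q3) for
#' continuous variables, percentage (x/n) for binary — and compares the
#' requested group pairs with Mann-Whitney U (continuous) or Fisher's exact
#' (binary) tests.
#'
#' @param samples Sample metadata tibble with a `group` column.
#' @param variables Variables to summarise; defaults to every column except
#'   `sample_id`, `group` and `cvd_event`. A variable is treated as binary
#'   when all its values are 0/1.
#' @param group_pairs List of length-2 character vectors of group labels.
#' @return Tibble: one row per variable with `variable`, `type`, one summary
#'   column per group, and one `p_<A>_vs_<B>` column per pair.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(seed = 5, confounded = TRUE))
#' cohort_table(coh$samples,
#'              group_pairs = list(c("HIV_CASE", "HIV_CONTROL")))
cohort_table <- function(samples, variables = NULL,
                         group_pairs = list(c("HIV_CASE", "HIV_CONTROL"),
                                            c("HIV_CONTROL", "HEALTHY"),
                                            c("HIV_CASE", "HEALTHY"))) {
  if (is.null(variables)) {
    variables <- setdiff(names(samples), c("sample_id", "group", "cvd_event"))
  }
  missing_vars <- setdiff(variables, names(samples))
  if (length(missing_vars) > 0) {
    abort(sprintf("unknown variable(s): %s", paste(missing_vars, collapse = ", ")))
  }
  groups <- unique(unlist(group_pairs))
  missing_groups <- setdiff(groups, unique(samples$group))
  if (length(missing_groups) > 0) {
    abort(sprintf("group(s) absent from samples: %s",
                  paste(missing_groups, collapse = ", ")))
  }
  rows <- purrr::map(variables, function(v) {
    vals <- samples[[v]]
    binary <- all(vals %in% c(0, 1))
    by_group <- purrr::map_chr(groups, function(g) {
      gv <- vals[samples$group == g]
      if (binary) {
        sprintf("%.1f (%d/%d)", 100 * mean(gv), sum(gv), length(gv))
      } else {
        q <- quantile(gv, c(0.25, 0.5, 0.75), type = 7)
        sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
      }
    })
    pvals <- purrr::map_dbl(group_pairs, function(pair) {
      v1 <- vals[samples$group == pair[1]]
      v2 <- vals[samples$group == pair[2]]
      if (binary) {
        fisher_exact(sum(v1), sum(v1 == 0), sum(v2), sum(v2 == 0))
      } else {
        mann_whitney_u(v1, v2)$p
      }
    })
    out <- tibble(variable = v, type = if (binary) "binary" else "continuous")
    out[groups] <- as.list(by_group)
    out[paste0("p_", purrr::map_chr(group_pairs, paste, collapse = "_vs_"))] <-
      as.list(pvals)
    out
  })
  bind_rows(rows)
}
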