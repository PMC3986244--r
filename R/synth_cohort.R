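## Synthetic case-control lipidomic cohort generator.
##
## Emulates a three-group retrospective case-control design: HIV-positive
## cases with a future coronary event, HIV-positive controls, and healthy
## HIV-negative controls, with a sample-by-species lipid concentration matrix
## and per-sample clinical covariates. Effects are injected as
## group-conditional mean shifts of log-concentration, parameterised by the
## odds ratio per interquartile range they are intended to realise.

GROUPS <- c("HIV_CASE", "HIV_CONTROL", "HEALTHY")
CONTRASTS <- c("HIV_vs_HEALTHY", "CASE_vs_CONTROL")

#' Default lipid species catalogue
#'
#' A plausible targeted-lipidomics panel: 316 species allocated over 24 lipid
#' classes (glycerolipids dominating, free cholesterol a single species). The
#' class vocabulary follows standard lipidomics abbreviations: Cer ceramide,
#' HexCer monohexosylceramide, SM sphingomyelin, PC phosphatidylcholine,
#' PE phosphatidylethanolamine, PI phosphatidylinositol, CE cholesteryl ester,
#' DG diacylglycerol, TG triacylglycerol, the O-/P- prefixed forms their
#' alkyl/alkenyl ethers, and LP* the lyso forms.
#'
#' @return Named integer vector: species count per lipid class (sums to 316).
#' @export
#' @examples
#' sum(default_species_per_class())
default_species_per_class <- function() {
  c(dhCer = 8, Cer = 8, HexCer = 8, Hex2Cer = 6, Hex3Cer = 6, GM3 = 8,
    SM = 22, PC = 42, PC_O = 16, PC_P = 18, LPC = 14, LPC_O = 6,
    PE = 20, PE_O = 10, PE_P = 12, LPE = 8, PI = 14, LPI = 6,
    PS = 8, PG = 6, CE = 22, COH = 1, DG = 15, TG = 32)
}

#' Default covariate models for the three study groups
#'
#' Distributional models for the clinical covariates of the cohort: binary
#' covariates are Bernoulli, blood pressure / BMI / age are normal, and the
#' right-skewed biochemistry (hsCRP, triglycerides, HDL/LDL/total cholesterol,
#' CD4 count) is log-normal. Group-specific parameters reproduce the
#' characteristics table of a treated-HIV coronary-risk cohort (about 91%
#' male, median age ~51 y, smoking and statin use enriched in the HIV groups,
#' low HDL and high triglycerides under antiretroviral therapy).
#'
#' With `confounded = FALSE` (the default) all three groups share the
#' HIV-control parameters, so covariates are independent of group membership
#' and association scans adjusted for them have a clean ground truth. With
#' `confounded = TRUE` the full group-specific distributions are used.
#'
#' @param confounded Logical; draw covariates from group-specific
#'   distributions (`TRUE`) or identical distributions for all groups
#'   (`FALSE`, default).
#' @return Named list of covariate model specifications.
#' @export
default_covariate_models <- function(confounded = FALSE) {
  g <- function(case, ctrl, healthy) {
    if (confounded) c(HIV_CASE = case, HIV_CONTROL = ctrl, HEALTHY = healthy)
    else c(HIV_CASE = ctrl, HIV_CONTROL = ctrl, HEALTHY = ctrl)
  }
  list(
    male        = list(dist = "bernoulli", p = g(0.913, 0.911, 0.933)),
    age         = list(dist = "normal", center = g(51.1, 51.2, 54.0),
                       sd = g(15.2, 13.6, 6.9)),
    sbp         = list(dist = "normal", center = g(128, 120, 121),
                       sd = g(14.8, 14.8, 15.0)),
    bmi         = list(dist = "normal", center = g(23.6, 24.3, 23.6),
                       sd = g(4.5, 4.4, 3.3)),
    smoker      = list(dist = "bernoulli", p = g(0.522, 0.422, 0.067)),
    diabetes    = list(dist = "bernoulli", p = g(0.174, 0.067, 0)),
    family_history_chd = list(dist = "bernoulli", p = g(0.522, 0.200, 0)),
    statin      = list(dist = "bernoulli", p = g(0.348, 0.067, 0)),
    art         = list(dist = "bernoulli", p = g(1, 0.889, 0)),
    detectable_vl = list(dist = "bernoulli", p = g(0.391, 0.422, 0)),
    cd4         = list(dist = "lognormal", center = g(452, 320, 900),
                       log_sd = g(0.604, 0.761, 0.30)),
    hscrp       = list(dist = "lognormal", center = g(2.78, 2.26, 0.64),
                       log_sd = g(0.904, 0.965, 1.048)),
    hdl         = list(dist = "lognormal", center = g(0.74, 0.95, 1.50),
                       log_sd = g(0.363, 0.275, 0.323)),
    ldl         = list(dist = "lognormal", center = g(3.60, 3.30, 2.97),
                       log_sd = g(0.280, 0.321, 0.242)),
    tg          = list(dist = "lognormal", center = g(3.67, 1.77, 1.00),
                       log_sd = g(0.446, 0.467, 0.684)),
    tc          = list(dist = "lognormal", center = g(5.89, 5.20, 5.00),
                       log_sd = g(0.206, 0.230, 0.167))
  )
}

#' Specify an injected group effect for a lipid feature
#'
#' Declares the effect size to inject into a synthetic cohort as the odds
#' ratio per interquartile range (OR/IQR) that a single-feature logistic
#' regression on the corresponding contrast should recover.
#'
#' @param feature_id A species id (e.g. `"TG_01"`) or class name (e.g.
#'   `"DG"`); class effects shift every member species.
#' @param contrast `"HIV_vs_HEALTHY"` (shifts both HIV groups; recovered from
#'   the HIV-control vs healthy fit) or `"CASE_vs_CONTROL"` (shifts HIV cases).
#' @param target_or_per_iqr Positive target odds ratio per IQR.
#' @return An `effect_spec` list.
#' @export
#' @examples
#' effect_spec("DG", "CASE_vs_CONTROL", 3.72)
effect_spec <- function(feature_id, contrast, target_or_per_iqr) {
  contrast <- match.arg(contrast, CONTRASTS)
  if (!is.numeric(target_or_per_iqr) || target_or_per_iqr <= 0) {
    abort("`target_or_per_iqr` must be a positive number")
  }
  structure(list(feature_id = feature_id, contrast = contrast,
                 target_or_per_iqr = target_or_per_iqr),
            class = "effect_spec")
}

#' Configure the synthetic cohort generator
#'
#' The defaults emulate the design of a 113-sample treated-HIV
#' coronary-risk lipidomics study: 23 HIV cases, 45 HIV controls, 45 healthy
#' controls; 316 lipid species in 24 classes; log-normal concentrations with a
#' single shared factor per lipid class inducing within-class correlation.
#'
#' @param group_sizes Named counts per group (`HIV_CASE`, `HIV_CONTROL`,
#'   `HEALTHY`).
#' @param species_per_class Named integer vector, species count per class.
#' @param log_mu Location of species log-concentration (natural-log pmol/mL,
#'   arbitrary units). Scalar or one value per species.
#' @param log_sigma Scale (SD) of species log-concentration; scalar or one
#'   value per species. Must be positive.
#' @param species_mu_sd SD of per-species baseline offsets around `log_mu`
#'   (species abundances in a lipidomics panel span orders of magnitude).
#' @param within_class_loading Shared-factor loading \eqn{\lambda \in [0,1)};
#'   within-class log-concentration correlation is \eqn{\lambda^2}.
#' @param covariate_models As [default_covariate_models()].
#' @param effects List of [effect_spec()] objects.
#' @param export_scale Scale of the exported concentration matrix: `"raw"`
#'   (concentrations, default) or `"log10"`.
#' @param confounded Convenience switch forwarded to
#'   [default_covariate_models()] when `covariate_models` is not supplied.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration (seed included).
#' @return A `generator_config` list.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' sum(cfg$group_sizes)
generator_config <- function(group_sizes = c(HIV_CASE = 23, HIV_CONTROL = 45,
                                             HEALTHY = 45),
                             species_per_class = default_species_per_class(),
                             log_mu = 4, log_sigma = 0.5, species_mu_sd = 1,
                             within_class_loading = 0.6,
                             covariate_models = NULL,
                             effects = list(),
                             export_scale = c("raw", "log10"),
                             confounded = FALSE,
                             seed = 1L) {
  export_scale <- match.arg(export_scale)
  if (is.null(covariate_models)) {
    covariate_models <- default_covariate_models(confounded = confounded)
  }
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% GROUPS)) {
    abort(sprintf("`group_sizes` must be named with a subset of: %s",
                  paste(GROUPS, collapse = ", ")))
  }
  if (any(group_sizes < 0)) abort("all group counts must be >= 0")
  if (is.null(names(species_per_class)) || any(species_per_class < 1)) {
    abort("`species_per_class` must be a named vector of positive counts")
  }
  if (any(log_sigma <= 0)) abort("`log_sigma` must be > 0")
  if (within_class_loading < 0 || within_class_loading >= 1) {
    abort("`within_class_loading` must lie in [0, 1)")
  }
  if (length(effects) > 0 && inherits(effects, "effect_spec")) {
    effects <- list(effects)
  }
  n_species <- sum(species_per_class)
  cfg <- structure(list(
    group_sizes = group_sizes[names(group_sizes)],
    n_classes = length(species_per_class),
    species_per_class = species_per_class,
    n_species = n_species,
    log_mu = log_mu, log_sigma = log_sigma, species_mu_sd = species_mu_sd,
    within_class_loading = within_class_loading,
    covariate_models = covariate_models,
    effects = effects,
    export_scale = export_scale,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_effects(cfg)
  cfg
}

species_catalogue <- function(species_per_class) {
  classes <- names(species_per_class)
  tibble(
    species_id = unlist(purrr::map2(classes, species_per_class,
                                    function(cl, k) sprintf("%s_%02d", cl, seq_len(k)))),
    class_name = rep(classes, times = species_per_class)
  )
}

validate_effects <- function(cfg) {
  cat <- species_catalogue(cfg$species_per_class)
  known <- c(cat$species_id, names(cfg$species_per_class))
  for (ef in cfg$effects) {
    if (!inherits(ef, "effect_spec")) abort("`effects` must be effect_spec objects")
    if (!ef$feature_id %in% known) {
      abort(sprintf("effect refers to unknown feature '%s'", ef$feature_id))
    }
  }
  invisible(cfg)
}

#' Log-scale mean shift implied by a target odds ratio per IQR
#'
#' Converts an effect expressed as an odds ratio per interquartile range into
#' a group-conditional Gaussian mean shift on the log-concentration scale.
#' For two equal-variance Gaussian populations whose means differ by
#' \eqn{\delta}, the posterior log-odds of membership is linear in the value
#' with slope \eqn{\delta/\sigma^2}; setting that slope to
#' \eqn{\log(\theta)/\mathrm{IQR}} gives
#' \deqn{\delta = \sigma^2 \log(\theta) / \mathrm{IQR}.}
#'
#' Note the IQR supplied here is the one the slope is referred to. When a
#' shift is injected, the pooled two-group sample IQR exceeds the
#' within-group IQR, so [generate_cohort()] calibrates the shift against the
#' pooled mixture IQR (see [calibrate_shift()]) rather than using the null
#' IQR directly.
#'
#' @param theta Target odds ratio per IQR (> 0).
#' @param sigma Log-scale SD of the feature (> 0).
#' @param iqr IQR of the feature on the analysis scale (> 0).
#' @return The log-scale mean shift `delta`.
#' @export
#' @examples
#' shift_from_target_or(1, 0.5, 0.7)            # null effect -> 0
#' shift_from_target_or(exp(1), 1, 1.349)       # ~0.7413
shift_from_target_or <- function(theta, sigma, iqr) {
  if (!all(theta > 0, sigma > 0, iqr > 0)) {
    abort("`theta`, `sigma` and `iqr` must all be positive")
  }
  beta <- log(theta) / iqr
  beta * sigma^2
}

## IQR of a two-component normal mixture N(0, sigma^2) / N(delta, sigma^2)
## with weights w (length 2, summing to 1).
mixture_iqr <- function(delta, sigma, w = c(0.5, 0.5)) {
  w <- w / sum(w)
  cdf <- function(q) w[1] * pnorm(q, 0, sigma) + w[2] * pnorm(q, delta, sigma)
  qf <- function(p) {
    lo <- min(0, delta) - 10 * sigma
    hi <- max(0, delta) + 10 * sigma
    uniroot(function(q) cdf(q) - p, c(lo, hi), tol = 1e-10)$root
  }
  qf(0.75) - qf(0.25)
}

#' Calibrate a log-scale shift to realise a target OR per pooled IQR
#'
#' Fixed-point iteration of [shift_from_target_or()] against the interquartile
#' range of the pooled two-group mixture: the returned shift `delta` satisfies
#' \eqn{(\delta/\sigma^2)\,\mathrm{IQR}_{pool}(\delta) = \log\theta}, so a
#' single-feature logistic regression on a large sample from the two shifted
#' populations recovers an odds ratio per (pooled sample) IQR of \eqn{\theta}.
#'
#' @param theta Target odds ratio per IQR (> 0).
#' @param sigma Log-scale SD of the feature (> 0).
#' @param weights Length-2 relative sizes of (reference, shifted) groups.
#' @return The calibrated shift `delta`.
#' @export
#' @examples
#' calibrate_shift(3.72, 0.5)
calibrate_shift <- function(theta, sigma, weights = c(0.5, 0.5)) {
  if (theta == 1) return(0)
  delta <- shift_from_target_or(theta, sigma, GAUSS_IQR * sigma)
  for (i in 1:20) {
    iqr <- mixture_iqr(delta, sigma, weights)
    new <- shift_from_target_or(theta, sigma, iqr)
    if (abs(new - delta) < 1e-10) break
    delta <- new
  }
  delta
}

#' Odds ratio per IQR that realises a target single-feature AUC
#'
#' Under the calibrated Gaussian-shift injection, the population AUC of the
#' shifted feature is \eqn{\Phi(d/\sqrt 2)} with standardised shift
#' \eqn{d = \delta/\sigma}. This helper inverts the relationship so tests can
#' inject a feature of known discriminative power.
#'
#' @param auc Target AUC in (0, 1).
#' @param weights Length-2 relative sizes of (reference, shifted) groups.
#' @return The target OR per IQR to pass to [effect_spec()].
#' @export
#' @examples
#' target_or_for_auc(0.9)
target_or_for_auc <- function(auc, weights = c(0.5, 0.5)) {
  stopifnot(auc > 0, auc < 1)
  d <- sqrt(2) * qnorm(auc)
  exp(d * mixture_iqr(d, 1, weights))
}

#' Draw clinical covariates for one study group
#'
#' Draws `n` covariate rows from the configured group-specific distributions.
#' Uses the current R random-number stream: results are deterministic given
#' the stream state (wrap in [withr::with_seed()] or let [generate_cohort()]
#' manage seeding).
#'
#' @param config A [generator_config()].
#' @param group One of `"HIV_CASE"`, `"HIV_CONTROL"`, `"HEALTHY"`.
#' @param n Number of rows (>= 0).
#' @return A tibble with `n` rows: `group` plus one column per covariate.
#' @export
generate_covariates <- function(config, group, n) {
  if (!group %in% names(config$group_sizes)) {
    abort(sprintf("unknown group '%s'", group))
  }
  stopifnot(n >= 0)
  cols <- purrr::map(config$covariate_models, function(m) {
    switch(m$dist,
      bernoulli = rbinom(n, 1, m$p[[group]]),
      normal    = rnorm(n, m$center[[group]], m$sd[[group]]),
      lognormal = rlnorm(n, log(m$center[[group]]), m$log_sd[[group]]),
      abort(sprintf("unknown covariate distribution '%s'", m$dist))
    )
  })
  out <- as_tibble(cols)
  out <- bind_cols(tibble(group = rep(group, n)), out)
  out
}

## Approximate SD of log(sum of correlated log-normals) with member
## locations mu, scales s and equicorrelation rho = lambda^2 of the logs
## (Fenton-Wilkinson moment matching).
log_total_sd <- function(mu, s, lambda) {
  m1 <- exp(mu + s^2 / 2)
  E <- sum(m1)
  rho <- matrix(lambda^2, length(mu), length(mu))
  diag(rho) <- 1
  V <- sum(outer(m1, m1) * (exp(rho * outer(s, s)) - 1))
  sqrt(log(1 + V / E^2))
}

effect_delta <- function(ef, sigma, group_sizes) {
  w <- switch(ef$contrast,
    HIV_vs_HEALTHY = c(group_sizes[["HEALTHY"]], group_sizes[["HIV_CONTROL"]]),
    CASE_vs_CONTROL = c(group_sizes[["HIV_CONTROL"]], group_sizes[["HIV_CASE"]]))
  calibrate_shift(ef$target_or_per_iqr, sigma, w)
}

shifted_groups <- function(contrast) {
  switch(contrast,
    HIV_vs_HEALTHY = c("HIV_CASE", "HIV_CONTROL"),
    CASE_vs_CONTROL = "HIV_CASE")
}

#' Generate a synthetic case-control lipidomic cohort
#'
#' Draws a sample-by-species concentration matrix and an aligned sample
#' metadata table. Log-concentrations are Gaussian with one shared factor per
#' lipid class (within-class correlation = loading squared, zero across
#' classes); configured effects are injected as calibrated group-conditional
#' mean shifts so that single-feature logistic regressions recover the target
#' odds ratios per IQR (see [calibrate_shift()]).
#'
#' @param config A [generator_config()].
#' @return A `lipid_cohort` list with elements `lipids` (tibble: `sample_id`
#'   plus one concentration column per species, on `config$export_scale`),
#'   `samples` (tibble: `sample_id`, `group`, `cvd_event`, covariates),
#'   `class_map` (tibble: `species_id`, `class_name`) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(seed = 7))
#' dim(coh$lipids)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_effects(config)
  cat <- species_catalogue(config$species_per_class)
  n_sp <- nrow(cat)
  sizes <- config$group_sizes
  n <- sum(sizes)
  sigma <- rep_len(config$log_sigma, n_sp)
  mu0 <- rep_len(config$log_mu, n_sp)

  withr::with_seed(config$seed, {
    mu <- mu0 + rnorm(n_sp, 0, config$species_mu_sd)
    groups <- rep(names(sizes), times = sizes)

    ## shared per-class factor + independent residual, on the log scale
    lam <- config$within_class_loading
    logx <- matrix(0, n, n_sp)
    cls_idx <- split(seq_len(n_sp), cat$class_name)
    for (members in cls_idx) {
      f <- rnorm(n)
      eps <- matrix(rnorm(n * length(members)), n, length(members))
      z <- lam * f + sqrt(1 - lam^2) * eps
      logx[, members] <- sweep(sweep(z, 2, sigma[members], `*`), 2,
                               mu[members], `+`)
    }

    ## inject calibrated effects
    for (ef in config$effects) {
      rows <- groups %in% shifted_groups(ef$contrast)
      if (ef$feature_id %in% cat$species_id) {
        j <- which(cat$species_id == ef$feature_id)
        delta <- effect_delta(ef, sigma[j], sizes)
        logx[rows, j] <- logx[rows, j] + delta
      } else {
        ## class effect: one uniform log-shift of every member species moves
        ## the log class total by exactly that shift, so calibrate against
        ## the SD of the log class total (Fenton-Wilkinson approximation)
        members <- which(cat$class_name == ef$feature_id)
        sigma_c <- log_total_sd(mu[members], sigma[members], lam)
        delta <- effect_delta(ef, sigma_c, sizes)
        logx[rows, members] <- logx[rows, members] + delta
      }
    }

    covs <- purrr::map(names(sizes), function(g) {
      generate_covariates(config, g, sizes[[g]])
    })
    samples <- bind_rows(covs)
  })

  sample_ids <- sprintf("S%03d", seq_len(n))
  samples <- bind_cols(tibble(sample_id = sample_ids), samples)
  samples <- mutate(samples,
                    cvd_event = as.integer(.data$group == "HIV_CASE"),
                    .after = "group")

  vals <- switch(config$export_scale,
                 raw = exp(logx),
                 log10 = logx / log(10))
  colnames(vals) <- cat$species_id
  lipids <- bind_cols(tibble(sample_id = sample_ids), as_tibble(vals))

  structure(list(lipids = lipids, samples = samples,
                 class_map = cat, config = config),
            class = "lipid_cohort")
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("<lipid_cohort> %d samples x %d species (%d classes), scale=%s\n",
              nrow(x$lipids), nrow(x$class_map),
              length(unique(x$class_map$class_name)),
              x$config$export_scale))
  tab <- table(x$samples$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  effects injected: %d; seed: %d\n",
              length(x$config$effects), x$config$seed))
  invisible(x)
}
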