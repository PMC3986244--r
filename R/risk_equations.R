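## Declarative evaluator for 10-year coronary heart disease risk equations
## (Framingham-, Reynolds- and D:A:D-style comparators). Coefficient values
## are data: equations are defined in editable YAML configuration (templates
## shipped under inst/extdata/equations/ carry placeholder coefficients),
## never hard-coded.

RISK_TRANSFORMS <- c("identity", "natural_log", "binary")

#' Define a 10-year risk equation
#'
#' A risk equation is a linear predictor over per-sample covariates plus a
#' baseline, in one of two standard forms:
#' \describe{
#'   \item{`cox_survival`}{risk = 1 - S0 ^ exp(L - L_ref), with baseline
#'     10-year survival `S0` at the reference predictor `L_ref`
#'     (Framingham/Reynolds structure).}
#'   \item{`log_rate`}{risk = 1 - exp(-exp(L) * t) over horizon `t` years
#'     (D:A:D structure; cumulative antiretroviral exposure enters as
#'     years-of-exposure identity terms).}
#' }
#' Each term is `coefficient * g(value)` with `g` one of `identity`
#' (`value - center`), `natural_log` (`log(value) - log(center)`, default
#' center 1) or `binary` (`value`, 0/1).
#'
#' @param name Equation name.
#' @param form `"cox_survival"` or `"log_rate"`.
#' @param terms Tibble/data frame with columns `variable`, `transform`,
#'   `coefficient`.
#' @param baseline_survival `S0` in (0, 1] (cox form).
#' @param horizon Horizon `t > 0` in years (rate form; default 10).
#' @param centering Named list of per-variable reference values.
#' @return A `risk_equation` object.
#' @export
#' @examples
#' eq <- risk_equation("demo", "cox_survival",
#'   terms = tibble::tibble(variable = c("age", "hdl", "smoker"),
#'                          transform = c("identity", "natural_log", "binary"),
#'                          coefficient = c(0.05, -0.9, 0.6)),
#'   baseline_survival = 0.95, centering = list(age = 50, hdl = 1.3))
#' ten_year_risk(eq, 0)
risk_equation <- function(name, form = c("cox_survival", "log_rate"),
                          terms, baseline_survival = NULL, horizon = NULL,
                          centering = list()) {
  form <- match.arg(form)
  terms <- as_tibble(terms)
  stopifnot(all(c("variable", "transform", "coefficient") %in% names(terms)))
  bad <- setdiff(terms$transform, RISK_TRANSFORMS)
  if (length(bad) > 0) {
    abort(sprintf("unknown transform(s): %s", paste(bad, collapse = ", ")))
  }
  if (form == "cox_survival") {
    if (is.null(baseline_survival) || baseline_survival <= 0 ||
        baseline_survival > 1) {
      abort("cox_survival form needs `baseline_survival` in (0, 1]")
    }
  } else {
    horizon <- horizon %||% 10
    if (horizon <= 0) abort("`horizon` must be > 0 years")
  }
  structure(list(name = name, form = form, terms = terms,
                 baseline_survival = baseline_survival, horizon = horizon,
                 centering = centering),
            class = "risk_equation")
}

#' @export
print.risk_equation <- function(x, ...) {
  cat(sprintf("<risk_equation> %s (%s), %d terms\n",
              x$name, x$form, nrow(x$terms)))
  print(x$terms)
  invisible(x)
}

#' Linear predictor of a risk equation
#'
#' Evaluates L = sum of coefficient * transform(value) over the equation's
#' terms for each row of `data`.
#'
#' @param eq A [risk_equation()].
#' @param data Data frame/tibble containing every equation variable.
#' @return Numeric vector, one L per row.
#' @export
linear_predictor <- function(eq, data) {
  stopifnot(inherits(eq, "risk_equation"))
  missing_vars <- setdiff(eq$terms$variable, names(data))
  if (length(missing_vars) > 0) {
    abort(sprintf("missing variable(s): %s", paste(missing_vars, collapse = ", ")))
  }
  L <- numeric(nrow(data))
  for (i in seq_len(nrow(eq$terms))) {
    v <- eq$terms$variable[i]
    x <- data[[v]]
    if (any(!is.finite(x))) abort(sprintf("non-finite value in '%s'", v))
    ref <- eq$centering[[v]]
    contrib <- switch(eq$terms$transform[i],
      identity = x - (ref %||% 0),
      natural_log = {
        if (any(x <= 0)) abort(sprintf("log transform of nonpositive '%s'", v))
        log(x) - log(ref %||% 1)
      },
      binary = {
        assert_flag01(x, v)
        x
      })
    L <- L + eq$terms$coefficient[i] * contrib
  }
  L
}

#' 10-year risk from a linear predictor
#'
#' @param eq A [risk_equation()].
#' @param L Linear predictor value(s).
#' @param L_ref Cohort reference predictor (cox form; default 0, i.e. the
#'   centering built into the terms).
#' @return Risk in `[0, 1]`, monotone increasing in `L`.
#' @export
#' @examples
#' eq <- risk_equation("demo", "cox_survival",
#'   tibble::tibble(variable = "age", transform = "identity",
#'                  coefficient = 0.05),
#'   baseline_survival = 0.95)
#' ten_year_risk(eq, log(2)) # 1 - 0.95^2
ten_year_risk <- function(eq, L, L_ref = 0) {
  stopifnot(inherits(eq, "risk_equation"))
  r <- switch(eq$form,
    cox_survival = 1 - eq$baseline_survival^exp(L - L_ref),
    log_rate = 1 - exp(-exp(L) * eq$horizon))
  pmin(pmax(r, 0), 1)
}

#' Score a cohort with a risk equation
#'
#' Computes the per-sample 10-year risk and the (non-cross-validated)
#' discrimination of the risks against a binary outcome, the C-statistic,
#' via [auc_rank()]. Samples with missing/non-finite required covariates are
#' excluded and reported.
#'
#' @param eq A [risk_equation()].
#' @param samples Sample metadata tibble (must include `sample_id`, the
#'   outcome column and the equation variables).
#' @param outcome Name of the binary outcome column (default `"cvd_event"`).
#' @param L_ref Reference linear predictor for the cox form.
#' @return A `risk_scores` list: `risks` (tibble `sample_id`, `linear_predictor`,
#'   `risk`, outcome), `auc`, `n_used`, `n_excluded`, `excluded_ids`, `equation`.
#' @export
score_cohort <- function(eq, samples, outcome = "cvd_event", L_ref = 0) {
  stopifnot(inherits(eq, "risk_equation"))
  if (!outcome %in% names(samples)) {
    abort(sprintf("outcome column '%s' not found", outcome))
  }
  y <- samples[[outcome]]
  assert_flag01(y, outcome)
  missing_vars <- setdiff(eq$terms$variable, names(samples))
  if (length(missing_vars) > 0) {
    abort(sprintf("missing variable(s): %s", paste(missing_vars, collapse = ", ")))
  }
  need <- unique(eq$terms$variable)
  ok <- rowSums(!is.finite(as.matrix(as.data.frame(samples[need])))) == 0
  excluded <- samples$sample_id[!ok]
  use <- samples[ok, , drop = FALSE]
  L <- linear_predictor(eq, use)
  risks <- tibble(sample_id = use$sample_id, linear_predictor = L,
                  risk = ten_year_risk(eq, L, L_ref))
  risks[[outcome]] <- use[[outcome]]
  structure(list(risks = risks,
                 auc = auc_rank(risks$risk, use[[outcome]]),
                 n_used = nrow(use),
                 n_excluded = length(excluded),
                 excluded_ids = excluded,
                 equation = eq),
            class = "risk_scores")
}

#' @export
print.risk_scores <- function(x, ...) {
  cat(sprintf("<risk_scores> %s: n = %d (excluded %d), C-statistic = %.3f\n",
              x$equation$name, x$n_used, x$n_excluded, x$auc))
  invisible(x)
}

#' Read / write risk-equation YAML configuration
#'
#' The YAML mirrors the [risk_equation()] fields (`name`, `form`, `terms` as
#' a list of variable/transform/coefficient entries, `baseline_survival` or
#' `horizon`, `centering`, optional free-text `citation`/`notes`). A
#' serialised equation re-read from disk produces bit-identical risks.
#'
#' @param path YAML file path.
#' @return `read_risk_equation()`: a `risk_equation`;
#'   `write_risk_equation()`: `path`, invisibly.
#' @export
read_risk_equation <- function(path) {
  cfg <- yaml::read_yaml(path)
  terms <- bind_rows(purrr::map(cfg$terms, as_tibble))
  risk_equation(name = cfg$name, form = cfg$form, terms = terms,
                baseline_survival = cfg$baseline_survival,
                horizon = cfg$horizon,
                centering = cfg$centering %||% list())
}

#' @rdname read_risk_equation
#' @param eq A [risk_equation()].
#' @export
write_risk_equation <- function(eq, path) {
  stopifnot(inherits(eq, "risk_equation"))
  out <- list(name = eq$name, form = eq$form,
              terms = purrr::transpose(as.list(eq$terms)))
  if (!is.null(eq$baseline_survival)) out$baseline_survival <- eq$baseline_survival
  if (!is.null(eq$horizon)) out$horizon <- eq$horizon
  if (length(eq$centering) > 0) out$centering <- eq$centering
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
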