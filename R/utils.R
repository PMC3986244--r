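## Internal helpers: seeding, validation, small numerics.

#' Derive a reproducible sub-stream seed from a global seed
#'
#' Pipeline stages draw from independent, individually re-runnable random
#' streams. Each stage seed is a deterministic function of the global seed and
#' a stage label, kept within the 32-bit signed integer range R requires.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"crossval"`).
#' @return An integer seed.
#' @export
#' @examples
#' substream_seed(42, "simulate")
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  # simple polynomial rolling hash of the label, folded into [0, 2^31 - 2]
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483646 + 1)
}

assert_flag01 <- function(x, name) {
  if (!all(x %in% c(0L, 1L))) {
    bad <- which(!(x %in% c(0L, 1L)))
    abort(sprintf("column '%s' must be binary 0/1; offending row(s): %s",
                  name, paste(head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

assert_prob <- function(p, name = "p") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(p)
}

## IQR by the inclusive linear-interpolation rule (quantile type 7, the R
## default). The OR-per-IQR scaling depends on this choice, so it is pinned
## here rather than left to callers.
iqr7 <- function(x) {
  q <- quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

## Gaussian IQR / SD ratio: qnorm(.75) - qnorm(.25)
GAUSS_IQR <- qnorm(0.75) - qnorm(0.25)

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)
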