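# Independent brute-force oracles used to cross-check the package's
# statistical primitives, plus small fixture builders.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Benjamini-Hochberg by direct evaluation of the min-over-suffix definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m),
                function(i) min(1, min(ps[i:m] * m / (i:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sided Fisher exact p by enumeration over the hypergeometric support
# (tables with probability <= observed, with the customary relative slack).
fisher_oracle <- function(a, b, c, d) {
  m <- a + c   # column-1 margin
  n <- b + d   # column-2 margin
  k <- a + b   # row-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC by direct enumeration of all positive/negative pairs.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Small cohort for fast tests: 2 classes, a handful of species.
tiny_config <- function(seed = 1, ...) {
  generator_config(
    group_sizes = c(HIV_CASE = 10, HIV_CONTROL = 15, HEALTHY = 15),
    species_per_class = c(AA = 3, BB = 2),
    seed = seed, ...)
}

demo_equation_path <- function() {
  system.file("extdata", "equations", "demo_synthetic.yaml",
              package = "lipidcvd")
}
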