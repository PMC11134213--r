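# Small in-code fixtures shared across test files.

# A concentration matrix with explicit values and optional missing cells.
make_cm <- function(values, compartment = "placenta", samples = NULL,
                    metabolites = NULL) {
  values <- as.matrix(values)
  rownames(values) <- samples %||% sprintf("S%02d", seq_len(nrow(values)))
  colnames(values) <- metabolites %||% sprintf("met%02d", seq_len(ncol(values)))
  concentration_matrix(values, compartment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random standardized blocks for PLS tests.
random_blocks <- function(n, p, q, seed = 1) {
  withr::with_seed(seed, {
    list(X = center_scale(matrix(rnorm(n * p), n, p)),
         Y = center_scale(matrix(rnorm(n * q), n, q)))
  })
}

# Blocks sharing one latent factor of given strength (log-scale model).
shared_factor_blocks <- function(n, p, q, strength = 2, noise = 1, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    X <- outer(f, runif(p, 0.6, 1) * sample(c(-1, 1), p, TRUE) * strength) +
      matrix(rnorm(n * p, 0, noise), n, p)
    Y <- outer(f, runif(q, 0.6, 1) * sample(c(-1, 1), q, TRUE) * strength) +
      matrix(rnorm(n * q, 0, noise), n, q)
    list(X = center_scale(X), Y = center_scale(Y), factor = f)
  })
}

# Direct step-up BH oracle, independent of bh_adjust().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Tiny registry builder for pair_dyads tests.
make_registry <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}
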