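#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, restoring the prior
#' RNG state afterwards so callers never perturb the session stream.
#' All stochastic operations in the package route through this helper,
#' which is what makes cohort generation and permutation tests fully
#' reproducible from their `seed` arguments.
#'
#' @param seed integer scalar, or NULL to use the current stream as-is.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a stream so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Derive independent child seeds from a master seed so that each random
## pipeline stage can be re-run in isolation with its logged seed.
derive_seeds <- function(master, n, labels = NULL) {
  s <- with_seed(master, sample.int(.Machine$integer.max, n))
  if (!is.null(labels)) names(s) <- labels
  s
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) && x <= 1
  if (!ok) {
    stop(sprintf("`%s` must be a single value in %s", name,
                 if (open_left) "(0, 1]" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

## Full-precision numeric formatting for text round-trips: %.17g guarantees
## read.table() recovers the identical double.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}
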