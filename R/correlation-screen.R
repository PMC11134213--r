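## Spearman correlation screens with Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} m * p_(j) / j` capped at 1,
#' returned in the input order. `NA` entries stay `NA` and do not count
#' toward the family size.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return vector of q-values aligned with the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH", n = sum(ok))
  q
}

## Two-sided p for a midrank Spearman rho via the t approximation
## (t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df).
spearman_p <- function(rho, n) {
  if (is.na(rho) || n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Pairwise Spearman screen within or between metabolomes
#'
#' Computes midrank Spearman correlations for every metabolite pair, with
#' two-sided p-values from the t approximation and BH q-values across the
#' whole screen (the screen is the FDR family). Between-block mode pairs
#' every column of `X` with every column of `Y`; self mode (`Y = NULL`)
#' screens the upper triangle of one block. Pairs are evaluated on
#' pairwise-complete observations; pairs with fewer than `min_n` complete
#' observations or a constant column are flagged and excluded from the
#' FDR family.
#'
#' @param X a [concentration_matrix()] (or plain numeric matrix).
#' @param Y a second, row-aligned [concentration_matrix()], or NULL for a
#'   within-block screen.
#' @param min_n minimum pairwise-complete observations (default 5).
#' @return data.frame of class `pairwise_screen` with columns `feature_x`,
#'   `compartment_x`, `feature_y`, `compartment_y`, `estimate`, `p_value`,
#'   `q_value`, `n_used`, `flagged`.
#' @export
spearman_screen <- function(X, Y = NULL, min_n = 5L) {
  xinfo <- as_block(X)
  self <- is.null(Y)
  yinfo <- if (self) xinfo else as_block(Y)
  Xv <- xinfo$values; Yv <- yinfo$values
  if (nrow(Xv) != nrow(Yv)) stop("blocks must be row-aligned", call. = FALSE)

  pairs <- if (self) {
    idx <- which(upper.tri(diag(ncol(Xv))), arr.ind = TRUE)
    data.frame(i = idx[, 1L], j = idx[, 2L])
  } else {
    expand.grid(i = seq_len(ncol(Xv)), j = seq_len(ncol(Yv)))
  }

  est <- p <- rep(NA_real_, nrow(pairs))
  nu <- integer(nrow(pairs))
  flag <- logical(nrow(pairs))

  complete <- !anyNA(Xv) && !anyNA(Yv)
  if (complete) {
    ## fast path: one midrank transform, one correlation matrix
    R <- suppressWarnings(stats::cor(Xv, Yv, method = "spearman"))
    n <- nrow(Xv)
    sdx <- apply(Xv, 2L, stats::sd); sdy <- apply(Yv, 2L, stats::sd)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      nu[k] <- n
      if (sdx[i] == 0 || sdy[j] == 0) { flag[k] <- TRUE; next }
      est[k] <- R[i, j]
      p[k] <- spearman_p(est[k], n)
    }
  } else {
    for (k in seq_len(nrow(pairs))) {
      x <- Xv[, pairs$i[k]]; y <- Yv[, pairs$j[k]]
      ok <- !is.na(x) & !is.na(y)
      nu[k] <- sum(ok)
      if (nu[k] < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        flag[k] <- TRUE
        next
      }
      est[k] <- stats::cor(x[ok], y[ok], method = "spearman")
      p[k] <- spearman_p(est[k], nu[k])
    }
  }

  out <- data.frame(
    feature_x = xinfo$ids[pairs$i],
    compartment_x = xinfo$compartment,
    feature_y = yinfo$ids[pairs$j],
    compartment_y = yinfo$compartment,
    estimate = est,
    p_value = p,
    q_value = bh_adjust(ifelse(flag, NA, p)),
    n_used = nu,
    flagged = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pairwise_screen", "data.frame")
  attr(out, "screen") <- if (self) "within" else "bipartite"
  out
}

## Accept either a concentration_matrix or a bare numeric matrix.
as_block <- function(X) {
  if (inherits(X, "concentration_matrix")) {
    list(values = X$values, ids = X$metabolite_ids, compartment = X$compartment)
  } else if (is.matrix(X) && is.numeric(X)) {
    ids <- colnames(X) %||% sprintf("V%d", seq_len(ncol(X)))
    list(values = X, ids = ids, compartment = NA_character_)
  } else {
    stop("expected a concentration_matrix or numeric matrix", call. = FALSE)
  }
}

#' Write a pairwise screen as TSV
#'
#' @param screen a `pairwise_screen` data.frame.
#' @param path output path.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(as.data.frame(screen), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count discoveries at an FDR threshold
#'
#' @param screen a `pairwise_screen` data.frame.
#' @param q FDR threshold (default 0.10, the reporting rule used
#'   throughout the package).
#' @export
n_significant <- function(screen, q = 0.10) {
  sum(!is.na(screen$q_value) & screen$q_value < q)
}
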