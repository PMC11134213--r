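## Rank-based (Wilcoxon-score) linear regression: Jaeckel dispersion
## minimization with a Newton-type scoring iteration, and the adjusted
## pairwise metabolite screen built on it.

## Wilcoxon scores a(i) = sqrt(12) * (i/(n+1) - 1/2) applied to residual
## ranks (midranks under ties; the fast path places scores by sort order,
## which coincides with midranks when the residuals are all distinct).
wilcoxon_scores <- function(e, a_sorted = NULL) {
  n <- length(e)
  if (is.null(a_sorted)) a_sorted <- sqrt(12) * (seq_len(n) / (n + 1) - 0.5)
  if (anyDuplicated(e)) {
    return(sqrt(12) * (rank(e, ties.method = "average") / (n + 1) - 0.5))
  }
  s <- numeric(n)
  s[order(e)] <- a_sorted
  s
}

## Jaeckel's dispersion D(beta) = sum a(R(e_i)) e_i, a convex piecewise
## linear function of the slopes (intercept-free). Equals the sorted-score
## inner product with the residual order statistics.
jaeckel_dispersion <- function(e, a_sorted = NULL) {
  n <- length(e)
  if (is.null(a_sorted)) a_sorted <- sqrt(12) * (seq_len(n) / (n + 1) - 0.5)
  sum(a_sorted * sort.int(e, method = "quick"))
}

## Koul-Sievers-McKean estimate of tau = (sqrt(12) * int f^2)^(-1), the
## scale parameter of the rank estimator's asymptotic covariance.
## int f^2 equals the density of a residual difference at zero, estimated
## from pairwise |e_i - e_j| with bandwidth the delta-quantile / sqrt(n)
## (delta widens from 0.8 to 0.95 when n/p <= 5). Three finite-sample
## corrections keep the resulting Wald tests near nominal size: the p
## smallest differences are discarded (near-zero differences created by
## fitting p parameters otherwise inflate the density), a
## sqrt(n/(n-p-1)) degrees-of-freedom factor, and a Huber-style
## inflation 1 + ((p+1)/n)(1-h)/h with h = min(1, mean window weight +
## (p+1)/n). Pairs are subsampled above n = 1200 to bound the O(n^2)
## cost.
estimate_tau <- function(e, p, delta = NULL, max_n = 1200L) {
  n_full <- length(e)
  if (length(e) > max_n) e <- e[round(seq(1L, length(e), length.out = max_n))]
  n <- length(e)
  if (is.null(delta)) delta <- if (n / max(p, 1) > 5) 0.8 else 0.95
  d <- sort(abs(outer(e, e, "-")[upper.tri(diag(n))]))
  n_pairs <- length(d)
  if (p + 1L < n_pairs) d <- d[(p + 1L):n_pairs]
  td <- stats::quantile(d, delta, names = FALSE) / sqrt(n)
  if (td <= 0) td <- max(d[d > 0], .Machine$double.eps) / sqrt(n)
  w_mean <- mean(d <= td)
  f0 <- sum(d <= td) / (n_pairs * 2 * td)
  tau <- sqrt(n / max(n - p - 1, 1)) / (sqrt(12) * f0)
  h <- min(1, w_mean + (p + 1) / n)
  tau * (1 + ((p + 1) / n) * (1 - h) / h)
}

#' Rank-based linear regression with Wilcoxon scores
#'
#' Estimates slopes by minimizing Jaeckel's dispersion
#' `D(beta) = sum a(R(e_i)) e_i` with Wilcoxon scores
#' `a(i) = sqrt(12) (i/(n+1) - 1/2)`, giving a regression estimator that is
#' highly efficient under Gaussian errors (ARE ~ 0.955 vs least squares)
#' and robust to gross response outliers. The intercept is the median of
#' the final residuals; slope standard errors come from the
#' Koul-Sievers-McKean scale estimate `tau` via
#' `Var(beta) = tau^2 (Xc' Xc)^{-1}` on the column-centered design, with
#' t-based two-sided p-values on `n - p - 1` degrees of freedom.
#'
#' Minimization starts from the least-squares solution (consistent) and
#' takes damped Newton-type steps `tau (Xc'Xc)^{-1} X' a(R(e))` with
#' step-halving on the dispersion; convergence is declared when the
#' relative coefficient change drops below `tol`.
#'
#' @param y numeric response vector.
#' @param design numeric matrix of predictors (no intercept column).
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter maximum scoring iterations.
#' @return a `rank_fit` list: `coefficients` (intercept first), `se`,
#'   `tau_hat`, `t_values`, `p_values`, `converged`, `n_used`, `dispersion`.
#' @export
wilcoxon_rank_fit <- function(y, design, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 2) stop("need n > p + 2 observations", call. = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) stop("design is rank deficient", call. = FALSE)

  Xc <- sweep(X, 2L, colMeans(X))
  XtXinv <- chol2inv(chol(crossprod(Xc)))
  beta <- qr.coef(qrX, y)[-1L]

  a_sorted <- sqrt(12) * (seq_len(n) / (n + 1) - 0.5)
  e <- as.numeric(y - X %*% beta)
  ord <- order(e)
  tau <- estimate_tau(e, p)
  D <- sum(a_sorted * e[ord])
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ## negative gradient of D; one order() serves both D and the scores
    scores <- if (anyDuplicated(e)) wilcoxon_scores(e, a_sorted) else {
      s <- numeric(n); s[ord] <- a_sorted; s
    }
    g <- crossprod(Xc, scores)
    step <- tau * (XtXinv %*% g)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      e_cand <- as.numeric(y - X %*% cand)
      ord_cand <- order(e_cand)
      D_cand <- sum(a_sorted * e_cand[ord_cand])
      if (D_cand <= D + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (D_cand > D + 1e-12) { converged <- TRUE; break } # at a kink minimum
    moved <- max(abs(lambda * step)) / max(1, max(abs(beta)))
    beta <- cand; e <- e_cand; D <- D_cand; ord <- ord_cand
    if (moved < tol) { converged <- TRUE; break }
  }

  tau <- estimate_tau(e, p)
  se <- tau * sqrt(diag(XtXinv))
  tval <- as.numeric(beta) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p - 1)
  intercept <- stats::median(e)
  coef <- c("(Intercept)" = intercept,
            stats::setNames(as.numeric(beta), colnames(X)))
  structure(
    list(coefficients = coef,
         se = stats::setNames(se, colnames(X)),
         tau_hat = tau,
         t_values = stats::setNames(tval, colnames(X)),
         p_values = stats::setNames(pval, colnames(X)),
         converged = converged,
         n_used = n,
         dispersion = D),
    class = "rank_fit"
  )
}

#' @export
print.rank_fit <- function(x, ...) {
  cat(sprintf("<rank_fit> n = %d, tau = %.4g, converged: %s\n",
              x$n_used, x$tau_hat, x$converged))
  tab <- cbind(Estimate = x$coefficients,
               SE = c(NA, x$se), p = c(NA, x$p_values))
  print(round(tab, 4))
  invisible(x)
}

#' Covariate-adjusted pairwise metabolite screen
#'
#' For every metabolite pair (x from block `X`, y from block `Y`) fits
#' `y ~ x + covariates` by [wilcoxon_rank_fit()] and reports the slope on
#' x with its SE and two-sided p-value; BH q-values are computed across
#' the whole screen (one FDR family per screen). Rows are restricted to
#' complete cases for the covariate set, then pairwise-complete in (x, y).
#'
#' @param X,Y row-aligned [concentration_matrix()] objects (or numeric
#'   matrices); x columns are predictors, y columns responses.
#' @param covariates a [covariate_table()] (or data.frame) row-aligned to
#'   the blocks, or NULL for an unadjusted screen.
#' @param covariate_set names of adjustment covariates (default none).
#' @param transform `"natural"` (raw concentrations) or `"log"` (natural
#'   log; zeros/missing excluded pairwise).
#' @param model_label label recorded on the output (e.g. "model1").
#' @param min_n minimum usable rows per pair beyond the parameter count.
#' @return a `pairwise_screen` data.frame (see [spearman_screen()]) with
#'   columns `se` and `model` added.
#' @export
adjusted_pairwise_screen <- function(X, Y, covariates = NULL,
                                     covariate_set = character(),
                                     transform = c("natural", "log"),
                                     model_label = "model1",
                                     min_n = 10L) {
  transform <- match.arg(transform)
  xinfo <- as_block(X); yinfo <- as_block(Y)
  Xv <- xinfo$values; Yv <- yinfo$values
  if (nrow(Xv) != nrow(Yv)) stop("blocks must be row-aligned", call. = FALSE)
  if (transform == "log") {
    Xv <- suppressWarnings(log(Xv)); Xv[!is.finite(Xv)] <- NA
    Yv <- suppressWarnings(log(Yv)); Yv[!is.finite(Yv)] <- NA
  }

  C <- NULL
  if (length(covariate_set)) {
    if (is.null(covariates)) stop("covariate_set given without covariates",
                                  call. = FALSE)
    unknown <- setdiff(covariate_set, names(covariates))
    if (length(unknown)) stop("unknown covariate(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    C <- as.matrix(as.data.frame(covariates)[, covariate_set, drop = FALSE])
    if (nrow(C) != nrow(Xv)) stop("covariates not row-aligned", call. = FALSE)
    keep <- stats::complete.cases(C)
    Xv <- Xv[keep, , drop = FALSE]; Yv <- Yv[keep, , drop = FALSE]
    C <- C[keep, , drop = FALSE]
  }

  pairs <- expand.grid(i = seq_len(ncol(Xv)), j = seq_len(ncol(Yv)))
  est <- se <- p <- rep(NA_real_, nrow(pairs))
  nu <- integer(nrow(pairs)); flag <- logical(nrow(pairs))
  npar <- 1L + if (is.null(C)) 0L else ncol(C)

  for (k in seq_len(nrow(pairs))) {
    x <- Xv[, pairs$i[k]]; y <- Yv[, pairs$j[k]]
    ok <- !is.na(x) & !is.na(y)
    nu[k] <- sum(ok)
    if (nu[k] < max(min_n, npar + 3L) ||
        stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      flag[k] <- TRUE
      next
    }
    design <- cbind(x = x[ok], if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- tryCatch(wilcoxon_rank_fit(y[ok], design),
                    error = function(e) NULL)
    if (is.null(fit)) { flag[k] <- TRUE; next }
    est[k] <- fit$coefficients[["x"]]
    se[k] <- fit$se[["x"]]
    p[k] <- fit$p_values[["x"]]
  }

  out <- data.frame(
    feature_x = xinfo$ids[pairs$i],
    compartment_x = xinfo$compartment,
    feature_y = yinfo$ids[pairs$j],
    compartment_y = yinfo$compartment,
    estimate = est,
    se = se,
    p_value = p,
    q_value = bh_adjust(ifelse(flag, NA, p)),
    n_used = nu,
    flagged = flag,
    model = model_label,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pairwise_screen", "data.frame")
  attr(out, "screen") <- "adjusted"
  out
}
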