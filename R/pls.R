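## Canonical-mode (sparse) partial least squares between two metabolome
## blocks, with covariate residualization, Q2 leave-one-out component
## selection, a permutation test on the covariance of the first latent
## variate pair, and relevance networks.

#' Partial out covariates from every column of a matrix
#'
#' Replaces each column of `M` by its ordinary least-squares residual on
#' the covariate design (an intercept is always included), so that the
#' downstream PLS operates on variation orthogonal to the covariates.
#'
#' @param M numeric matrix (rows = samples), complete.
#' @param covariates numeric matrix or data.frame of covariates (no
#'   intercept column needed), or NULL to center only.
#' @return matrix of residuals with the dimnames of `M`.
#' @export
residualize <- function(M, covariates = NULL) {
  M <- as.matrix(M)
  if (anyNA(M)) stop("`M` must be complete; subset to complete rows first",
                     call. = FALSE)
  D <- if (is.null(covariates)) matrix(1, nrow(M), 1L) else {
    cbind(1, as.matrix(as.data.frame(covariates)))
  }
  if (anyNA(D)) stop("covariates must be complete", call. = FALSE)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("covariate design is rank deficient", call. = FALSE)
  res <- qr.resid(qrD, M)
  dimnames(res) <- dimnames(M)
  res
}

#' Center and scale columns to mean zero, unit variance
#'
#' @param M numeric matrix with no constant column.
#' @return standardized matrix with attributes `"center"` and `"scale"`.
#' @export
center_scale <- function(M) {
  M <- as.matrix(M)
  ctr <- colMeans(M)
  scl <- apply(M, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("constant column(s): ",
         paste(utils::head(colnames(M)[scl == 0] %||% which(scl == 0), 3L),
               collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(M, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

## Keep the k largest-magnitude entries of v and shrink them toward zero
## by the (k+1)-th magnitude (soft thresholding); k >= length(v) is a
## no-op.
soft_threshold_keep <- function(v, k) {
  p <- length(v)
  if (k >= p) return(v)
  lambda <- sort(abs(v), decreasing = TRUE)[k + 1L]
  sign(v) * pmax(abs(v) - lambda, 0)
}

## One sparse power-iteration component on the cross-product matrix
## M = X'Y. The NIPALS updates a = soft(X'u), b = soft(Y't) only touch X
## and Y through M, so the inner loop runs on the p x q cross-product:
## dense mode is exactly the power method for the leading singular pair.
first_component_M <- function(M, keep_x, keep_y, tol = 1e-10,
                              max_iter = 5000L) {
  p <- nrow(M); q <- ncol(M)
  b <- numeric(q)
  b[which.max(colSums(M^2))] <- 1
  a <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a_new <- soft_threshold_keep(as.numeric(M %*% b), keep_x)
    na <- sqrt(sum(a_new^2))
    if (na == 0) stop("all-zero x-loading after thresholding", call. = FALSE)
    a_new <- a_new / na
    b_new <- soft_threshold_keep(as.numeric(crossprod(M, a_new)), keep_y)
    nb <- sqrt(sum(b_new^2))
    if (nb == 0) stop("all-zero y-loading after thresholding", call. = FALSE)
    b_new <- b_new / nb
    delta <- max(max(abs(a_new - a)), max(abs(b_new - b)))
    a <- a_new; b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  ## sign convention: largest-magnitude x-loading entry positive
  if (a[which.max(abs(a))] < 0) { a <- -a; b <- -b }
  list(a = a, b = b, converged = converged, iterations = it)
}

#' Canonical-mode (sparse) partial least squares
#'
#' Fits `H` latent components between two row-aligned blocks by NIPALS
#' with optional soft-thresholded sparse loadings. Per component, the
#' alternating updates `a = soft(X'u)`, `t = Xa`, `b = soft(Y't)`,
#' `u = Yb` are iterated to convergence; `soft` keeps the budgeted number
#' of largest-magnitude entries and shrinks them by the next magnitude.
#' Canonical deflation regresses each block on its own scores
#' (`X <- X - t t'X / t't`, `Y <- Y - u u'Y / u'u`), modeling the
#' bidirectional association between the blocks rather than predicting
#' one from the other. With full keep budgets the first loading pair is
#' the leading singular-vector pair of `X'Y`.
#'
#' Inputs are used as given: residualize and standardize first (see
#' [residualize()], [center_scale()]).
#'
#' @param X,Y numeric matrices with equal row counts (samples).
#' @param H number of components (>= 1).
#' @param keep_x,keep_y per-component sparsity budgets (scalars are
#'   recycled); default dense (full block width).
#' @param tol NIPALS convergence tolerance on the loading change.
#' @return a `pls_fit`: unit-norm `loadings_x` (p x H), `loadings_y`
#'   (q x H), scores `scores_x`/`scores_y` (n x H), per-component
#'   `covariance` cov(t_h, u_h), `variance_explained` per block, the
#'   budgets, and `converged` per component.
#' @export
fit_canonical_pls <- function(X, Y, H = 1L, keep_x = NULL, keep_y = NULL,
                              tol = 1e-10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks must have equal row counts", call. = FALSE)
  if (H < 1) stop("H must be >= 1", call. = FALSE)
  p <- ncol(X); q <- ncol(Y)
  keep_x <- rep_len(if (is.null(keep_x)) p else keep_x, H)
  keep_y <- rep_len(if (is.null(keep_y)) q else keep_y, H)
  if (any(keep_x < 1 | keep_x > p) || any(keep_y < 1 | keep_y > q)) {
    stop("keep budgets must lie in [1, block width]", call. = FALSE)
  }

  X0 <- X; Y0 <- Y
  ssx_tot <- sum(X0^2); ssy_tot <- sum(Y0^2)
  A <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  B <- matrix(0, q, H, dimnames = list(colnames(Y), NULL))
  Tm <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  Um <- matrix(0, n, H, dimnames = list(rownames(Y), NULL))
  covs <- ve_x <- ve_y <- numeric(H)
  conv <- logical(H)

  for (h in seq_len(H)) {
    M <- crossprod(X, Y)
    comp <- first_component_M(M, keep_x[h], keep_y[h], tol = tol)
    a <- comp$a; b <- comp$b
    t_h <- as.numeric(X %*% a); u_h <- as.numeric(Y %*% b)
    A[, h] <- a; B[, h] <- b
    Tm[, h] <- t_h; Um[, h] <- u_h
    covs[h] <- sum((t_h - mean(t_h)) * (u_h - mean(u_h))) / (n - 1)
    conv[h] <- comp$converged
    xhat <- tcrossprod(t_h, crossprod(X, t_h)) / sum(t_h^2)
    yhat <- tcrossprod(u_h, crossprod(Y, u_h)) / sum(u_h^2)
    ve_x[h] <- sum(xhat^2) / ssx_tot
    ve_y[h] <- sum(yhat^2) / ssy_tot
    X <- X - xhat  # canonical deflation on own scores
    Y <- Y - yhat
  }

  structure(
    list(n_components = H,
         loadings_x = A, loadings_y = B,
         scores_x = Tm, scores_y = Um,
         covariance = covs,
         variance_explained = list(x = ve_x, y = ve_y,
                                   pair = (ve_x + ve_y) / 2),
         keep_x = keep_x, keep_y = keep_y,
         converged = conv, n = n),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d component(s), n = %d\n", x$n_components, x$n))
  for (h in seq_len(x$n_components)) {
    cat(sprintf("  comp %d: cov(t,u) = %.4f, VE x/y = %.1f%%/%.1f%%, keep = %d/%d\n",
                h, x$covariance[h],
                100 * x$variance_explained$x[h],
                100 * x$variance_explained$y[h],
                x$keep_x[h], x$keep_y[h]))
  }
  invisible(x)
}

#' Per-component variance explained
#'
#' Recomputes, from a fit and the (preprocessed) blocks it was fitted on,
#' the proportion of each block's total sum of squares captured by the
#' rank-one reconstruction from that component's scores; the `pair` value
#' averages the two blocks.
#'
#' @param fit a `pls_fit`.
#' @param X,Y the matrices passed to [fit_canonical_pls()].
#' @return list with per-component vectors `x`, `y`, `pair`.
#' @export
variance_explained <- function(fit, X, Y) {
  stopifnot(inherits(fit, "pls_fit"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != fit$n || nrow(Y) != fit$n ||
      ncol(X) != nrow(fit$loadings_x) || ncol(Y) != nrow(fit$loadings_y)) {
    stop("fit and data dimensions do not match", call. = FALSE)
  }
  ssx <- sum(X^2); ssy <- sum(Y^2)
  Xh <- X; Yh <- Y
  ve_x <- ve_y <- numeric(fit$n_components)
  for (h in seq_len(fit$n_components)) {
    t_h <- fit$scores_x[, h]; u_h <- fit$scores_y[, h]
    xhat <- tcrossprod(t_h, crossprod(Xh, t_h)) / sum(t_h^2)
    yhat <- tcrossprod(u_h, crossprod(Yh, u_h)) / sum(u_h^2)
    ve_x[h] <- sum(xhat^2) / ssx
    ve_y[h] <- sum(yhat^2) / ssy
    Xh <- Xh - xhat; Yh <- Yh - yhat
  }
  list(x = ve_x, y = ve_y, pair = (ve_x + ve_y) / 2)
}

#' Q2 component selection by leave-one-out cross-validation
#'
#' For each component `h`, computes the leave-one-out predicted residual
#' sum of squares (PRESS) for predicting the current Y block from the X
#' scores, and `Q2_h = 1 - PRESS_h / RSS_{h-1}` where `RSS_{h-1}` is the
#' residual sum of squares of Y before the component. Components are
#' retained while `Q2_h >= threshold` (0.0975, the conventional rule);
#' the retained count is the longest passing prefix.
#'
#' @param X,Y preprocessed blocks (n >= 10 rows).
#' @param max_H maximum components to evaluate.
#' @param keep_x,keep_y sparsity budgets, as in [fit_canonical_pls()].
#' @param threshold retention threshold on Q2.
#' @return list: `retained` (integer >= 0) and `q2_table` (data.frame
#'   with component, PRESS, RSS_prev, Q2).
#' @export
select_components_q2 <- function(X, Y, max_H = 3L, keep_x = NULL,
                                 keep_y = NULL, threshold = 0.0975) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10) stop("need n >= 10 for leave-one-out selection", call. = FALSE)
  p <- ncol(X); q <- ncol(Y)
  keep_x <- rep_len(if (is.null(keep_x)) p else keep_x, max_H)
  keep_y <- rep_len(if (is.null(keep_y)) q else keep_y, max_H)

  Xh <- X; Yh <- Y
  press <- rss_prev <- q2 <- numeric(max_H)
  for (h in seq_len(max_H)) {
    rss_prev[h] <- sum(Yh^2)
    M <- crossprod(Xh, Yh)
    pr <- 0
    for (i in seq_len(n)) {
      Mi <- M - tcrossprod(Xh[i, ], Yh[i, ])  # cross-product without row i
      comp <- first_component_M(Mi, keep_x[h], keep_y[h], tol = 1e-9)
      t_tr <- Xh[-i, , drop = FALSE] %*% comp$a
      cvec <- crossprod(Yh[-i, , drop = FALSE], t_tr) / sum(t_tr^2)
      pred <- as.numeric(Xh[i, ] %*% comp$a) * as.numeric(cvec)
      pr <- pr + sum((Yh[i, ] - pred)^2)
    }
    press[h] <- pr
    q2[h] <- 1 - pr / rss_prev[h]
    ## deflate with the full-data component before evaluating the next
    comp <- first_component_M(M, keep_x[h], keep_y[h], tol = 1e-10)
    t_h <- as.numeric(Xh %*% comp$a); u_h <- as.numeric(Yh %*% comp$b)
    Xh <- Xh - tcrossprod(t_h, crossprod(Xh, t_h)) / sum(t_h^2)
    Yh <- Yh - tcrossprod(u_h, crossprod(Yh, u_h)) / sum(u_h^2)
  }
  pass <- q2 >= threshold
  retained <- if (all(pass)) max_H else which(!pass)[1L] - 1L
  list(retained = as.integer(retained),
       q2_table = data.frame(component = seq_len(max_H), PRESS = press,
                             RSS_prev = rss_prev, Q2 = q2),
       threshold = threshold)
}

#' Permutation test on the covariance of the first latent variate pair
#'
#' Observed statistic: the sample covariance `cov(t1, u1)` of the first
#' component's scores. Null distribution: rows of `Y` are permuted
#' uniformly at random `B` times (after residualization, so covariate
#' structure is preserved) and the first component refit with the same
#' sparsity budgets. One-sided add-one p-value
#' `(count_ge + 1) / (B + 1)`.
#'
#' @param X,Y preprocessed (residualized, scaled) blocks.
#' @param B number of permutations (default 9999).
#' @param keep_x,keep_y first-component sparsity budgets (default dense).
#' @param seed integer seed making the permutation stream reproducible.
#' @return a `permutation_result`: `observed_statistic`, `B`, `count_ge`,
#'   `p_value`, `seed`.
#' @export
permutation_test_covariance <- function(X, Y, B = 9999L, keep_x = NULL,
                                        keep_y = NULL, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks must be row-aligned", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  p <- ncol(X); q <- ncol(Y)
  kx <- if (is.null(keep_x)) p else keep_x[1L]
  ky <- if (is.null(keep_y)) q else keep_y[1L]

  stat_of <- function(Yperm) {
    M <- crossprod(X, Yperm)
    comp <- first_component_M(M, kx, ky, tol = 1e-9)
    t1 <- as.numeric(X %*% comp$a); u1 <- as.numeric(Yperm %*% comp$b)
    sum((t1 - mean(t1)) * (u1 - mean(u1))) / (n - 1)
  }
  observed <- stat_of(Y)
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(i) stat_of(Y[sample.int(n), , drop = FALSE]),
           numeric(1))
  })
  count_ge <- sum(perm >= observed)
  structure(
    list(observed_statistic = observed, B = as.integer(B),
         count_ge = as.integer(count_ge),
         p_value = (count_ge + 1) / (B + 1),
         seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> cov(t1,u1) = %.4f, B = %d, p = %.4g\n",
              x$observed_statistic, x$B, x$p_value))
  invisible(x)
}

#' Relevance network between two blocks
#'
#' Bipartite similarity between metabolite i of block X and metabolite j
#' of block Y through the shared latent variates:
#' `s_ij = sum_h cor(x_i, z_h) * cor(y_j, z_h)` with
#' `z_h = (t_h + u_h) / 2`. Edges connect only nodes from different
#' blocks and are kept where `|s_ij| >= threshold`, carrying the sign of
#' the association.
#'
#' @param fit a `pls_fit` with at least one component.
#' @param X,Y the (preprocessed) blocks the fit was computed on.
#' @param threshold edge threshold in `[0, 1]` (default 0.5).
#' @param components components to use (default: all in the fit).
#' @return a `relevance_network`: `nodes` (id, block), `edges` (node_x,
#'   node_y, similarity, sign), `similarity` matrix, `threshold`.
#' @export
relevance_network <- function(fit, X, Y, threshold = 0.5,
                              components = seq_len(fit$n_components)) {
  stopifnot(inherits(fit, "pls_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  Z <- (fit$scores_x[, components, drop = FALSE] +
          fit$scores_y[, components, drop = FALSE]) / 2
  Cx <- stats::cor(X, Z)
  Cy <- stats::cor(Y, Z)
  S <- Cx %*% t(Cy)
  ids_x <- colnames(X) %||% sprintf("x%d", seq_len(ncol(X)))
  ids_y <- colnames(Y) %||% sprintf("y%d", seq_len(ncol(Y)))
  dimnames(S) <- list(ids_x, ids_y)
  hit <- which(abs(S) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_x = ids_x[hit[, 1L]],
    node_y = ids_y[hit[, 2L]],
    similarity = S[hit],
    sign = ifelse(S[hit] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-abs(edges$similarity)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = data.frame(id = c(ids_x, ids_y),
                            block = rep(c("x", "y"),
                                        c(length(ids_x), length(ids_y))),
                            stringsAsFactors = FALSE),
         edges = edges, similarity = S, threshold = threshold),
    class = "relevance_network"
  )
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("<relevance_network> %d nodes, %d edge(s) at |s| >= %.2f\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Convert a relevance network to an igraph object
#'
#' Nodes keep their block tag; edges carry the similarity and sign.
#'
#' @param network a `relevance_network`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "relevance_network"))
  used <- unique(c(network$edges$node_x, network$edges$node_y))
  nodes <- network$nodes[network$nodes$id %in% used, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = network$edges[, c("node_x", "node_y", "similarity", "sign")],
    directed = FALSE, vertices = nodes)
}

#' Write a relevance network to GraphML and TSV
#'
#' @param network a `relevance_network`.
#' @param graphml_path optional GraphML output path.
#' @param edges_path optional TSV edge-list output path.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(edges_path)) {
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(network)
}

#' Tune a shared sparsity budget by first-component Q2
#'
#' Evaluates candidate keep budgets (applied to both blocks, capped at
#' each block's width) on the first component's leave-one-out Q2 and
#' returns the maximizer. Grid default: 5, 10, 15, ... up to the block
#' widths.
#'
#' @param X,Y preprocessed blocks.
#' @param grid candidate budgets; default `seq(5, max(p, q), by = 5)`.
#' @return list: `keep_x`, `keep_y`, `q2`, `grid` (with per-budget Q2).
#' @export
tune_sparsity <- function(X, Y, grid = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); q <- ncol(Y)
  if (is.null(grid)) grid <- unique(pmin(c(seq(5L, max(p, q), by = 5L),
                                           max(p, q)), max(p, q)))
  grid <- sort(unique(pmax(1L, grid)))
  q2s <- vapply(grid, function(k) {
    select_components_q2(X, Y, max_H = 1L,
                         keep_x = min(k, p), keep_y = min(k, q))$q2_table$Q2[1L]
  }, numeric(1))
  best <- grid[which.max(q2s)]
  list(keep_x = min(best, p), keep_y = min(best, q),
       q2 = max(q2s),
       grid = data.frame(keep = grid, Q2 = q2s))
}
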