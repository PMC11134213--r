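test_that("residualize produces exact least-squares orthogonality", {
  withr::with_seed(14, {
    n <- 50
    C <- cbind(rbinom(n, 1, 0.5), rnorm(n))
    M <- matrix(rnorm(n * 6), n, 6)
    R <- residualize(M, C)
    D <- cbind(1, C)
    expect_lt(max(abs(crossprod(D, R))), 1e-9)

    # a column equal to a covariate residualizes to zero
    M2 <- cbind(C[, 2], rnorm(n))
    R2 <- residualize(M2, C)
    expect_lt(max(abs(R2[, 1])), 1e-10)

    # a centered column orthogonal to the covariates is unchanged
    v <- residualize(cbind(rnorm(n)), C)[, 1]  # already orthogonal by construction
    expect_equal(residualize(cbind(v), C)[, 1], v, tolerance = 1e-10)

    expect_error(residualize(M, cbind(C, C[, 1])), "rank deficient")
  })
})

test_that("center_scale standardizes and rejects constant columns", {
  withr::with_seed(3, {
    M <- matrix(rnorm(80, 5, 3), 20, 4)
    S <- center_scale(M)
    expect_lt(max(abs(colMeans(S))), 1e-12)
    expect_equal(unname(apply(S, 2, sd)), rep(1, 4), tolerance = 1e-12)
    # idempotent on standardized input
    expect_equal(unname(center_scale(S)), unname(S), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_error(center_scale(cbind(M, 7)), "constant")
  })
})

test_that("dense first loading pair equals the leading singular vectors of X'Y", {
  for (seed in 1:10) {
    b <- random_blocks(30, 10, 8, seed = seed)
    fit <- fit_canonical_pls(b$X, b$Y, H = 1)
    s <- svd(crossprod(b$X, b$Y))
    a <- s$u[, 1]; v <- s$v[, 1]
    if (a[which.max(abs(a))] < 0) { a <- -a; v <- -v }
    expect_lt(max(abs(fit$loadings_x[, 1] - a)), 1e-8)
    expect_lt(max(abs(fit$loadings_y[, 1] - v)), 1e-8)
  }
})

test_that("dense first component maximizes cov(Xa, Yb) over toy blocks", {
  # exhaustive grid over unit vectors in 2 dimensions
  withr::with_seed(6, {
    X <- center_scale(matrix(rnorm(60), 30, 2))
    Y <- center_scale(matrix(rnorm(60), 30, 2))
    fit <- fit_canonical_pls(X, Y, H = 1)
    ang <- seq(0, 2 * pi, length.out = 721)
    best <- max(vapply(ang, function(ta) {
      a <- c(cos(ta), sin(ta))
      max(vapply(ang, function(tb) {
        b <- c(cos(tb), sin(tb))
        cov(X %*% a, Y %*% b)
      }, numeric(1)))
    }, numeric(1)))
    expect_equal(fit$covariance[1], best, tolerance = 1e-4)
  })
})

test_that("symmetry, sparsity budgets and score orthogonality behave", {
  b <- random_blocks(25, 6, 6, seed = 2)
  # Y = X: identical loadings, perfectly correlated variates
  fit <- fit_canonical_pls(b$X, b$X, H = 1)
  expect_equal(fit$loadings_x[, 1], fit$loadings_y[, 1], tolerance = 1e-8)
  expect_equal(cor(fit$scores_x[, 1], fit$scores_y[, 1]), 1, tolerance = 1e-10)

  # keep_x = 1 gives exactly one nonzero x-loading
  f1 <- fit_canonical_pls(b$X, b$Y, H = 1, keep_x = 1)
  expect_equal(sum(f1$loadings_x[, 1] != 0), 1)

  # full budgets reproduce the dense fit exactly
  fd <- fit_canonical_pls(b$X, b$Y, H = 2)
  fs <- fit_canonical_pls(b$X, b$Y, H = 2, keep_x = 6, keep_y = 6)
  expect_identical(fs$loadings_x, fd$loadings_x)
  expect_identical(fs$loadings_y, fd$loadings_y)

  # canonical deflation: within-block score orthogonality
  G <- crossprod(fd$scores_x)
  expect_lt(abs(G[1, 2]) / sqrt(G[1, 1] * G[2, 2]), 1e-8)
  Gu <- crossprod(fd$scores_y)
  expect_lt(abs(Gu[1, 2]) / sqrt(Gu[1, 1] * Gu[2, 2]), 1e-8)

  # unit-norm loadings
  expect_equal(colSums(fd$loadings_x^2), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fit_canonical_pls(b$X, b$Y, H = 1, keep_x = 99), "keep budgets")
})

test_that("variance explained is exact in the rank-one limit and bounded", {
  withr::with_seed(50, {
    f <- rnorm(40)
    X <- outer(f, runif(5, 0.5, 1))   # exactly rank one
    Y <- outer(f, runif(4, 0.5, 1))
    fit <- fit_canonical_pls(X, Y, H = 1)
    expect_equal(fit$variance_explained$pair[1], 1, tolerance = 1e-10)
  })
  b <- random_blocks(30, 6, 5, seed = 9)
  fit <- fit_canonical_pls(b$X, b$Y, H = 3)
  ve <- variance_explained(fit, b$X, b$Y)
  expect_equal(ve$x, fit$variance_explained$x, tolerance = 1e-10)
  expect_lt(ve$pair[1], 1)
  expect_lte(sum(ve$x), 1 + 1e-10)
  expect_lte(sum(ve$y), 1 + 1e-10)
})

test_that("Q2 selection keeps planted components and rejects noise", {
  # strong single shared factor: at least one component retained
  sb <- shared_factor_blocks(60, 10, 8, strength = 3, noise = 0.7, seed = 123)
  sel <- select_components_q2(sb$X, sb$Y, max_H = 2)
  expect_gte(sel$retained, 1)
  expect_true(all(sel$q2_table$Q2 <= 1))
  expect_true(all(sel$q2_table$PRESS >= 0))

  # pure noise: no component retained in most replicates
  kept <- vapply(1:20, function(s) {
    b <- random_blocks(40, 8, 6, seed = 600 + s)
    select_components_q2(b$X, b$Y, max_H = 1)$retained
  }, integer(1))
  expect_gte(mean(kept == 0), 0.9)

  expect_error(select_components_q2(matrix(1:8, 4), matrix(1:8, 4)), "n >= 10")
})

test_that("permutation p-value formula, floor and determinism hold", {
  sb <- shared_factor_blocks(40, 6, 5, strength = 3, noise = 0.5, seed = 77)
  res <- permutation_test_covariance(sb$X, sb$Y, B = 199, seed = 42)
  res2 <- permutation_test_covariance(sb$X, sb$Y, B = 199, seed = 42)
  expect_identical(res$p_value, res2$p_value)
  expect_gte(res$p_value, 1 / 200)
  expect_lte(res$count_ge, 199L)
  # strong planted factor: observed beats all permutations
  expect_equal(res$p_value, 1 / 200)
  expect_error(permutation_test_covariance(sb$X, sb$Y, B = 0), "B must be")
})

test_that("permutation null distribution is super-uniform up to discreteness", {
  pvals <- vapply(1:60, function(s) {
    b <- random_blocks(30, 5, 4, seed = 9000 + s)
    permutation_test_covariance(b$X, b$Y, B = 39, seed = s)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 60))
  }
})

test_that("relevance networks connect planted cross-block partners", {
  withr::with_seed(88, {
    n <- 80; f <- rnorm(n)
    shared <- 2 * f + rnorm(n, 0, 0.4)          # same variable in both blocks
    X <- center_scale(cbind(shared_x = shared,
                            matrix(rnorm(n * 4), n, 4)))
    Y <- center_scale(cbind(shared_y = shared + rnorm(n, 0, 0.2),
                            matrix(rnorm(n * 3), n, 3)))
    colnames(X) <- c("shared_x", paste0("xn", 1:4))
    colnames(Y) <- c("shared_y", paste0("yn", 1:3))
    fit <- fit_canonical_pls(X, Y, H = 1)
    net <- relevance_network(fit, X, Y, threshold = 0.5)
    hit <- net$edges[net$edges$node_x == "shared_x" &
                       net$edges$node_y == "shared_y", ]
    expect_equal(nrow(hit), 1)
    expect_identical(hit$sign, "positive")
    # similarities bounded, edges bipartite by construction
    expect_lte(max(abs(net$similarity)), 1 + 1e-10)
    expect_true(all(net$edges$node_x %in% colnames(X)))
    expect_true(all(net$edges$node_y %in% colnames(Y)))
    # threshold 1 on noisy data: empty graph; invalid threshold errors
    expect_equal(nrow(relevance_network(fit, X, Y, threshold = 1)$edges), 0)
    expect_error(relevance_network(fit, X, Y, threshold = 1.5), "threshold")

    # exports
    g <- as_igraph(net)
    expect_true(igraph::is_igraph(g))
    tsv <- withr::local_tempfile(fileext = ".tsv")
    gml <- withr::local_tempfile(fileext = ".graphml")
    write_network(net, graphml_path = gml, edges_path = tsv)
    expect_true(file.exists(gml))
    back <- read.delim(tsv)
    expect_equal(nrow(back), nrow(net$edges))
  })
})

test_that("sparse fits agree with mixOmics on support and direction", {
  skip_if_not_installed("mixOmics")
  b <- shared_factor_blocks(50, 12, 10, strength = 2, noise = 1, seed = 5)
  keep <- c(5L, 4L)
  fit <- fit_canonical_pls(b$X, b$Y, H = 1, keep_x = keep[1], keep_y = keep[2])
  mo <- mixOmics::spls(b$X, b$Y, ncomp = 1, mode = "canonical",
                       keepX = keep[1], keepY = keep[2], scale = FALSE)
  a_mo <- mo$loadings$X[, 1]
  expect_identical(which(fit$loadings_x[, 1] != 0) |> unname(),
                   which(a_mo != 0) |> unname())
  expect_gt(abs(cor(fit$loadings_x[, 1], a_mo)), 0.999)
})
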