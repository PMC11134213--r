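test_that("two-class fits reduce to binary logistic regression", {
  withr::with_seed(19, {
    n <- 300
    x <- rnorm(n); w <- rbinom(n, 1, 0.4)
    pr <- plogis(-0.5 + 0.8 * x - 0.4 * w)
    cls <- ifelse(runif(n) < pr, "ASD", "TD")
    fit <- fit_multinomial(cls, data.frame(x = x, w = w), reference = "TD")
    oracle <- glm(I(cls == "ASD") ~ x + w, family = binomial)
    expect_lt(max(abs(fit$coefficients["ASD", ] - coef(oracle))), 1e-6)
    # Wald SEs match too
    expect_equal(unname(fit$se["ASD", ]),
                 unname(summary(oracle)$coefficients[, "Std. Error"]),
                 tolerance = 1e-5)
  })
})

test_that("three-class fits agree with nnet and recover planted RRs", {
  skip_if_not_installed("nnet")
  withr::with_seed(23, {
    n <- 2000
    z <- rnorm(n)
    eta <- cbind(ASD = -0.64 + 0 * z, nonTD = -1.48 + log(2) * z)
    pm <- exp(cbind(TD = 0, eta)); pm <- pm / rowSums(pm)
    u <- runif(n)
    cum <- t(apply(pm, 1, cumsum))
    cls <- colnames(pm)[max.col(u <= cum, ties.method = "first")]
    fit <- fit_multinomial(cls, data.frame(z = z), reference = "TD")

    ref <- nnet::multinom(factor(cls, levels = c("TD", "ASD", "nonTD")) ~ z,
                          trace = FALSE, reltol = 1e-12, maxit = 500)
    expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-4)

    # planted nonTD RR = 2, ASD RR = 1
    expect_lt(abs(fit$rr["nonTD", "z"] - 2) / 2, 0.1)
    expect_true(fit$rr_lower["ASD", "z"] < 1 && fit$rr_upper["ASD", "z"] > 1)
  })
})

test_that("reference recoding shifts coefficients but not probabilities", {
  withr::with_seed(31, {
    n <- 400
    z <- rnorm(n)
    cls <- sample(c("TD", "ASD", "nonTD"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
    f1 <- fit_multinomial(cls, data.frame(z = z), reference = "TD")
    f2 <- fit_multinomial(cls, data.frame(z = z), reference = "ASD")
    p1 <- predict(f1)[, c("TD", "ASD", "nonTD")]
    p2 <- predict(f2)[, c("TD", "ASD", "nonTD")]
    expect_equal(p1, p2, tolerance = 1e-7)
    # coefficient identity: beta_nonTD|ASD = beta_nonTD|TD - beta_ASD|TD
    expect_equal(unname(f2$coefficients["nonTD", ]),
                 unname(f1$coefficients["nonTD", ] - f1$coefficients["ASD", ]),
                 tolerance = 1e-6)
  })
})

test_that("Wald CIs cover a null RR at close to nominal rate", {
  covered <- withr::with_seed(57, {
    vapply(1:120, function(i) {
      n <- 400
      z <- rnorm(n)
      cls <- sample(c("TD", "ASD", "nonTD"), n, replace = TRUE,
                    prob = c(0.57, 0.30, 0.13))  # z has no effect
      fit <- fit_multinomial(cls, data.frame(z = z), reference = "TD")
      fit$rr_lower["nonTD", "z"] < 1 && fit$rr_upper["nonTD", "z"] > 1
    }, logical(1))
  })
  # binomial 99% band around 0.95 with 120 replicates
  expect_gte(mean(covered), 0.89)
})

test_that("separation and degenerate classes are reported, not hidden", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  cls <- rep(c("TD", "ASD"), each = 20)  # perfectly separated
  fit <- fit_multinomial(cls, data.frame(x = x))
  expect_true(fit$separation)
  expect_error(fit_multinomial(rep("TD", 30), data.frame(x = rnorm(30))),
               "at least two")
})

test_that("probability curves sum to one and collapse to plug-in at zero covariance", {
  withr::with_seed(61, {
    n <- 250
    z <- rnorm(n)
    cls <- sample(c("TD", "ASD", "nonTD"), n, replace = TRUE,
                  prob = c(0.5, 0.35, 0.15))
    fit <- fit_multinomial(cls, data.frame(z = z), reference = "TD")
    grid <- seq(-2, 2, length.out = 5)
    curve <- simulate_probability_curves(fit, "z", grid, n_draws = 400,
                                         seed = 8)
    sums <- tapply(curve$mean, curve$grid, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(curve$lower <= curve$mean + 1e-12))
    expect_true(all(curve$upper >= curve$mean - 1e-12))
    # determinism in the draws
    curve2 <- simulate_probability_curves(fit, "z", grid, n_draws = 400,
                                          seed = 8)
    expect_identical(curve$mean, curve2$mean)

    # zero covariance: all draws identical, equal to plug-in predictions
    fit0 <- fit
    fit0$vcov[] <- 0
    c0 <- simulate_probability_curves(fit0, "z", grid, n_draws = 50, seed = 1)
    expect_equal(c0$lower, c0$mean, tolerance = 1e-12)
    expect_equal(c0$upper, c0$mean, tolerance = 1e-12)
    X0 <- fit$design; X0[, "z"] <- grid[1]
    plug <- colMeans(predict(fit, X0[, -1, drop = FALSE]))
    expect_equal(unname(c0$mean[c0$grid == grid[1]]), unname(plug),
                 tolerance = 1e-10)
  })
})

test_that("draw means converge toward plug-in predictions as draws grow", {
  withr::with_seed(71, {
    n <- 200
    z <- rnorm(n)
    cls <- sample(c("TD", "ASD", "nonTD"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
    fit <- fit_multinomial(cls, data.frame(z = z), reference = "TD")
    X0 <- fit$design; X0[, "z"] <- 0
    plug <- colMeans(predict(fit, X0[, -1, drop = FALSE]))
    small <- simulate_probability_curves(fit, "z", 0, n_draws = 100, seed = 3)
    big <- simulate_probability_curves(fit, "z", 0, n_draws = 20000, seed = 3)
    err_small <- max(abs(small$mean - unname(plug)))
    err_big <- max(abs(big$mean - unname(plug)))
    expect_lt(err_big, 0.01)
    expect_lt(err_big, err_small + 0.002)
  })
})

test_that("metabolite outcome screen recovers a planted cord-serum effect", {
  cfg <- synthetic_cohort_config(
    n_dyads = 2000, p_per_block = c(placenta = 4L, cord_serum = 4L),
    n_shared_factors = c("placenta:cord_serum" = 1L),
    loading_sparsity = 0, factor_strength = 1, noise_sd = 0.3,
    outcome_coefficients = list(ASD = c(score = 0), nonTD = c(score = log(2))),
    covariate_effects = "none", seed = 303)
  gen <- generate_cohort(cfg)
  # pick the cord metabolite loading most strongly on the shared factor:
  # its z-scored log concentration is a noisy proxy of the score, so the
  # planted positive nonTD effect and null ASD effect should both show
  L <- gen$truth$loadings$cord_serum[["placenta:cord_serum"]][, 1]
  met <- gen$cohort$matrices$cord_serum$metabolite_ids[which.max(abs(L))]
  tab <- metabolite_outcome_screen(
    gen$cohort, c(cord_serum = met),
    covariate_sets = list(unadjusted = character(),
                          adjusted = c("birth_year", "fetal_sex")))
  non_td <- tab[tab$contrast == "nonTD_vs_TD" & tab$model == "unadjusted", ]
  asd <- tab[tab$contrast == "ASD_vs_TD" & tab$model == "unadjusted", ]
  sgn <- sign(L[which.max(abs(L))])
  if (sgn > 0) {
    expect_gt(non_td$RR, 1); expect_gt(non_td$lower, 1)
  } else {
    expect_lt(non_td$RR, 1); expect_lt(non_td$upper, 1)
  }
  expect_true(asd$lower < 1 && asd$upper > 1)

  # identical covariate sets give identical rows
  tab2 <- metabolite_outcome_screen(
    gen$cohort, c(cord_serum = met),
    covariate_sets = list(unadjusted = character(), adjusted = character()))
  expect_equal(tab2$RR[tab2$model == "unadjusted"],
               tab2$RR[tab2$model == "adjusted"], tolerance = 1e-10)

  # constant metabolite column errors
  bad <- gen$cohort
  bad$matrices$cord_serum$values[, met] <- 5
  expect_error(metabolite_outcome_screen(bad, c(cord_serum = met)),
               "constant")
})
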