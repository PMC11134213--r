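## Multinomial logistic models of the three-level neurodevelopmental
## outcome (TD reference, ASD, nonTD), with exponentiated coefficients
## reported as relative risks (strictly, relative risk ratios from the
## multinomial logit; we keep the field's customary "RR" label), Wald
## confidence intervals, and simulated predicted-probability curves.

#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood multinomial logit with a chosen reference class.
#' Full Newton iterations on the stacked coefficient vector with
#' step-halving (the log-likelihood is non-decreasing across iterations);
#' the coefficient covariance is the inverse observed information.
#' Slope `RR = exp(coef)` with 95% Wald intervals and two-sided normal
#' p-values. Quasi-complete separation is flagged (any fitted probability
#' within 1e-8 of 1) and reported rather than silently regularized.
#'
#' @param outcome factor (or character) of class labels.
#' @param predictors numeric matrix or data.frame of predictors (no
#'   intercept column).
#' @param reference reference class (default `"TD"` when present,
#'   otherwise the first level).
#' @param max_iter,tol Newton iteration controls.
#' @return a `multinomial_model`: `coefficients` ((K-1) x p+1 matrix, one
#'   row per non-reference class), `vcov`, `se`, `rr` (with `rr_lower`,
#'   `rr_upper`), `p_values`, `log_lik`, `converged`, `separation`,
#'   `n_used`, `classes`, `reference`, plus the design for downstream
#'   prediction.
#' @export
fit_multinomial <- function(outcome, predictors, reference = NULL,
                            max_iter = 200L, tol = 1e-10) {
  predictors <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- sprintf("x%d", seq_len(ncol(predictors)))
  }
  keep <- stats::complete.cases(predictors) & !is.na(outcome)
  predictors <- predictors[keep, , drop = FALSE]
  outcome <- droplevels(factor(outcome[keep]))
  classes <- levels(outcome)
  K <- length(classes)
  if (K < 2) stop("need at least two observed outcome classes", call. = FALSE)
  if (any(table(outcome) == 0L)) stop("empty outcome class", call. = FALSE)
  if (is.null(reference)) reference <- if ("TD" %in% classes) "TD" else classes[1L]
  if (!reference %in% classes) stop("reference class not observed", call. = FALSE)
  classes <- c(reference, setdiff(classes, reference))
  outcome <- factor(outcome, levels = classes)

  X <- cbind("(Intercept)" = 1, predictors)
  n <- nrow(X); pp <- ncol(X)
  if (qr(X)$rank < pp) stop("predictor design is rank deficient", call. = FALSE)
  Yind <- stats::model.matrix(~ outcome - 1)
  colnames(Yind) <- classes

  nb <- (K - 1L) * pp
  beta <- numeric(nb)  # stacked by class: (class2 coefs, class3 coefs, ...)
  probs_of <- function(beta) {
    Bm <- matrix(beta, nrow = K - 1L, byrow = TRUE)
    eta <- X %*% t(Bm)                      # n x (K-1)
    em <- exp(cbind(0, eta))
    em / rowSums(em)
  }
  loglik_of <- function(beta) {
    P <- probs_of(beta)
    sum(Yind * log(pmax(P, 1e-300)))
  }

  ll <- loglik_of(beta)
  converged <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    P <- probs_of(beta)
    ## score: per non-reference class j, X'(y_j - p_j), stacked class-major
    score <- as.numeric(vapply(2:K, function(j)
      as.numeric(crossprod(X, Yind[, j] - P[, j])), numeric(pp)))
    ## observed information: blocks X' diag(p_j (d_jk - p_k)) X
    info <- matrix(0, nb, nb)
    for (j in 2:K) for (k in 2:K) {
      w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(X, X * w)
      ri <- (j - 2L) * pp + seq_len(pp)
      ci <- (k - 2L) * pp + seq_len(pp)
      info[ri, ci] <- blk
    }
    delta <- tryCatch(solve(info, score), error = function(e)
      MASS::ginv(info) %*% score)
    lambda <- 1
    repeat {
      cand <- beta + lambda * as.numeric(delta)
      ll_cand <- loglik_of(cand)
      if (ll_cand >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand; ll_new <- ll_cand
    if (max(abs(lambda * delta)) < tol || abs(ll_new - ll) < 1e-12) {
      ll <- ll_new; converged <- TRUE; break
    }
    ll <- ll_new
  }

  P <- probs_of(beta)
  separation <- max(P) > 1 - 1e-8
  vc <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  Bm <- matrix(beta, nrow = K - 1L, byrow = TRUE,
               dimnames = list(classes[-1L], colnames(X)))
  SE <- matrix(sqrt(pmax(diag(vc), 0)), nrow = K - 1L, byrow = TRUE,
               dimnames = dimnames(Bm))
  z <- Bm / SE
  pv <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(0.975)
  structure(
    list(coefficients = Bm, vcov = vc, se = SE,
         rr = exp(Bm), rr_lower = exp(Bm - crit * SE),
         rr_upper = exp(Bm + crit * SE),
         p_values = pv,
         log_lik = ll, converged = converged, separation = separation,
         n_used = n, classes = classes, reference = reference,
         design = X, iterations = it),
    class = "multinomial_model"
  )
}

#' @export
print.multinomial_model <- function(x, ...) {
  cat(sprintf("<multinomial_model> classes: %s (ref %s), n = %d, logLik = %.2f%s\n",
              paste(x$classes, collapse = "/"), x$reference, x$n_used,
              x$log_lik,
              if (x$separation) " [separation flagged]" else ""))
  for (cl in rownames(x$coefficients)) {
    cat(sprintf("  %s vs %s:\n", cl, x$reference))
    tab <- cbind(coef = x$coefficients[cl, ], RR = x$rr[cl, ],
                 lo = x$rr_lower[cl, ], hi = x$rr_upper[cl, ],
                 p = x$p_values[cl, ])
    print(round(tab, 4))
  }
  invisible(x)
}

#' Predicted class probabilities
#'
#' @param object a `multinomial_model`.
#' @param newdata numeric matrix of predictors (no intercept column);
#'   default: the fitting data.
#' @param ... unused.
#' @return n x K matrix of probabilities, columns in class order
#'   (reference first).
#' @export
predict.multinomial_model <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$design else
    cbind(1, as.matrix(as.data.frame(newdata)))
  eta <- X %*% t(object$coefficients)
  em <- exp(cbind(0, eta))
  P <- em / rowSums(em)
  colnames(P) <- object$classes
  P
}

#' Simulated predicted-probability curves with 95% bands
#'
#' Draws coefficient vectors from a multivariate normal centered at the
#' estimates with the fitted covariance; for each draw and each grid
#' value of the focal predictor computes observed-value-averaged
#' predicted probabilities (the remaining covariates keep their observed
#' values across the analysis sample, and predictions are averaged over
#' rows). Reports the per-class mean and 2.5/97.5 percentile bands.
#'
#' @param model a converged `multinomial_model`.
#' @param predictor name of the focal predictor column.
#' @param grid numeric grid of predictor values.
#' @param n_draws number of coefficient draws (default 1000).
#' @param seed RNG seed for the draws.
#' @return a `probability_curve` data.frame: `grid`, `class`, `mean`,
#'   `lower`, `upper`; attributes `n_draws`, `seed`, `averaging`.
#' @export
simulate_probability_curves <- function(model, predictor, grid,
                                        n_draws = 1000L, seed = NULL) {
  stopifnot(inherits(model, "multinomial_model"))
  if (!model$converged) stop("model did not converge", call. = FALSE)
  pp <- ncol(model$coefficients)
  if (!predictor %in% colnames(model$coefficients)) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  K <- length(model$classes)
  mu <- as.numeric(t(model$coefficients))
  draws <- with_seed(seed, MASS::mvrnorm(n_draws, mu = mu, Sigma = model$vcov))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1L)

  X <- model$design
  jcol <- match(predictor, colnames(X))
  res <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    Xg <- X
    Xg[, jcol] <- grid[gi]
    pm <- matrix(NA_real_, nrow(draws), K)
    for (d in seq_len(nrow(draws))) {
      Bm <- matrix(draws[d, ], nrow = K - 1L, byrow = TRUE)
      em <- exp(cbind(0, Xg %*% t(Bm)))
      pm[d, ] <- colMeans(em / rowSums(em))
    }
    res[[gi]] <- data.frame(
      grid = grid[gi],
      class = model$classes,
      mean = colMeans(pm),
      lower = apply(pm, 2L, stats::quantile, probs = 0.025, names = FALSE),
      upper = apply(pm, 2L, stats::quantile, probs = 0.975, names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("probability_curve", "data.frame")
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  attr(out, "averaging") <- "observed values over the analysis sample"
  out
}

#' Outcome screen for a single metabolite across compartments
#'
#' Fits unadjusted and covariate-adjusted multinomial models of the
#' outcome on one metabolite per compartment, reporting ASD-vs-TD and
#' nonTD-vs-TD RRs with 95% CIs and p-values. By default the metabolite
#' enters as the z-score of its natural-log concentration (zeros and
#' non-detects drop out); the raw scale is retained as an option.
#'
#' @param cohort a [dyad_cohort()] with covariates and outcome.
#' @param metabolite named character vector: compartment -> metabolite id.
#' @param covariate_sets list with elements `unadjusted` and `adjusted`,
#'   each a character vector of covariate names.
#' @param transform `"log_z"` (default) or `"natural"`.
#' @return data.frame: tissue, model, contrast, RR, lower, upper, p, n.
#' @export
metabolite_outcome_screen <- function(cohort, metabolite,
                                      covariate_sets = list(
                                        unadjusted = character(),
                                        adjusted = character()),
                                      transform = c("log_z", "natural")) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  transform <- match.arg(transform)
  if (is.null(cohort$outcome)) stop("cohort has no outcome", call. = FALSE)
  rows <- list()
  for (comp in names(metabolite)) {
    m <- cohort$matrices[[comp]]
    if (is.null(m)) stop("compartment not in cohort: ", comp, call. = FALSE)
    met <- metabolite[[comp]]
    if (!met %in% m$metabolite_ids) {
      stop(sprintf("metabolite '%s' not in %s", met, comp), call. = FALSE)
    }
    x <- m$values[, met]
    if (transform == "log_z") {
      x <- suppressWarnings(log(x)); x[!is.finite(x)] <- NA
    }
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      stop("constant metabolite column: ", met, call. = FALSE)
    }
    if (transform == "log_z") x <- as.numeric(scale(x))
    for (lab in names(covariate_sets)) {
      cs <- covariate_sets[[lab]]
      pred <- data.frame(metabolite = x)
      if (length(cs)) {
        pred <- cbind(pred, as.data.frame(cohort$covariates)[, cs, drop = FALSE])
      }
      fit <- fit_multinomial(cohort$outcome, pred, reference = "TD")
      for (cl in rownames(fit$coefficients)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tissue = comp, model = lab,
          contrast = paste0(cl, "_vs_TD"),
          RR = fit$rr[cl, "metabolite"],
          lower = fit$rr_lower[cl, "metabolite"],
          upper = fit$rr_upper[cl, "metabolite"],
          p = fit$p_values[cl, "metabolite"],
          n = fit$n_used,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
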