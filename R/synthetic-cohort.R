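## Synthetic cohort generator: log-normal metabolite panels with
## block-shared latent factors, covariate confounding, and a three-class
## outcome driven by the latent scores. Ground truth is recorded so that
## recovery tests can compare estimates against the planted structure.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a tri-compartment pregnancy cohort: 107 dyads with
#' metabolite panels of 48 (maternal serum), 54 (placenta) and 44 (cord
#' serum) analytes, one latent factor shared between placenta and cord
#' serum and none for the maternal pairs, mild covariate confounding, and
#' outcome base rates of 57/30/13% (TD/ASD/nonTD) with a nonTD log
#' relative risk of log(2) per unit of the shared factor and a null ASD
#' effect.
#'
#' The concentration model on the natural-log scale is
#' `log C = intercept + loadings %*% factors + covariate effects + noise`,
#' so concentrations are log-normal: positive and right-skewed, as NMR
#' metabolite panels are. Rank-based stages downstream are invariant to
#' this marginal choice.
#'
#' @param n_dyads number of mother-infant dyads (>= 10).
#' @param p_per_block named integer vector: metabolites per compartment.
#' @param n_shared_factors named integer vector of latent factors per block
#'   pair; names are `"blockA:blockB"`.
#' @param loading_sparsity fraction of zero loadings per factor, in `[0, 1)`.
#' @param factor_strength scale of nonzero loadings (log-concentration
#'   units per factor SD).
#' @param noise_sd residual SD on the log scale.
#' @param covariate_effects `"default"` for mild planted confounding
#'   (metabolic condition 0.3 and gestational age 0.1 log-units on a random
#'   20% of each block), `"none"`, or a named list of covariate-by-metabolite
#'   effect matrices per block.
#' @param outcome_props baseline class probabilities (TD, ASD, nonTD) at
#'   zero linear predictor.
#' @param outcome_coefficients list with elements `ASD` and `nonTD`, each a
#'   named vector of log-RR coefficients; name `score` refers to the first
#'   shared placenta:cord factor, other names to covariate columns.
#' @param missing_rate MCAR probability that a concentration cell is
#'   recorded as not detected.
#' @param n_missing_covariates number of dyads given a missing
#'   `metabolic_condition` covariate (exercises complete-case logic).
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_dyads = 107L,
    p_per_block = c(maternal_serum = 48L, placenta = 54L, cord_serum = 44L),
    n_shared_factors = c("placenta:cord_serum" = 1L,
                         "maternal_serum:placenta" = 0L,
                         "maternal_serum:cord_serum" = 0L),
    loading_sparsity = 0.5,
    factor_strength = 1,
    noise_sd = 0.5,
    covariate_effects = "default",
    outcome_props = c(TD = 0.57, ASD = 0.30, nonTD = 0.13),
    outcome_coefficients = list(
      ASD = c(score = 0, metabolic_condition = 0.2),
      nonTD = c(score = log(2), metabolic_condition = 0.2)),
    missing_rate = 0,
    n_missing_covariates = 0L,
    seed = 1L) {
  if (!is.numeric(n_dyads) || n_dyads < 10) stop("n_dyads must be >= 10", call. = FALSE)
  if (any(p_per_block < 2)) stop("each block needs >= 2 metabolites", call. = FALSE)
  if (is.null(names(p_per_block)) ||
      !all(names(p_per_block) %in% COMPARTMENTS)) {
    stop("p_per_block must be named by compartment", call. = FALSE)
  }
  if (loading_sparsity < 0 || loading_sparsity >= 1) {
    stop("loading_sparsity must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  stopifnot(abs(sum(outcome_props) - 1) < 1e-8, all(outcome_props > 0))
  structure(
    list(n_dyads = as.integer(n_dyads), p_per_block = p_per_block,
         n_shared_factors = n_shared_factors,
         loading_sparsity = loading_sparsity,
         factor_strength = factor_strength, noise_sd = noise_sd,
         covariate_effects = covariate_effects,
         outcome_props = outcome_props,
         outcome_coefficients = outcome_coefficients,
         missing_rate = missing_rate,
         n_missing_covariates = as.integer(n_missing_covariates),
         seed = as.integer(seed)),
    class = "synthetic_cohort_config"
  )
}

## Covariate simulation: binaries Bernoulli(0.5); birth year uniform over
## six calendar years; gestational age at collection normal with SD 10
## days; fasting time gamma with median around 80 minutes.
simulate_covariates <- function(n) {
  bern <- function() stats::rbinom(n, 1L, 0.5)
  data.frame(
    dyad_id = sprintf("D%03d", seq_len(n)),
    birth_year = sample(2009:2014, n, replace = TRUE),
    gestational_age_at_collection = round(stats::rnorm(n, 238, 10)),
    fasting_time = round(stats::rgamma(n, shape = 2, scale = 48)),
    maternal_education = bern(),
    race_ethnicity = bern(),
    home_ownership = bern(),
    prenatal_vitamin_month1 = bern(),
    fetal_sex = bern(),
    delivery_mode = bern(),
    metabolic_condition = bern(),
    stringsAsFactors = FALSE
  )
}

## Design used for planted covariate->metabolite effects (log scale).
confounder_design <- function(cov) {
  cbind(metabolic_condition = cov$metabolic_condition,
        ga10 = (cov$gestational_age_at_collection - 238) / 10)
}

default_covariate_effects <- function(blocks, p_per_block) {
  out <- list()
  for (b in blocks) {
    p <- p_per_block[[b]]
    eff <- matrix(0, 2L, p, dimnames = list(c("metabolic_condition", "ga10"), NULL))
    hit1 <- sample.int(p, max(1L, round(0.2 * p)))
    hit2 <- sample.int(p, max(1L, round(0.2 * p)))
    eff["metabolic_condition", hit1] <- 0.3
    eff["ga10", hit2] <- 0.1
    out[[b]] <- eff
  }
  out
}

#' Generate a synthetic dyad cohort with recorded ground truth
#'
#' Draws covariates, latent factor scores (independent standard normal),
#' sparse loadings, log-normal concentration matrices and a three-class
#' outcome from a multinomial logit on the shared placenta:cord factor
#' score and covariates. Bit-identical output for identical configs.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with elements `cohort` (a [dyad_cohort()]) and `truth`
#'   (factor scores, loadings, planted effects and outcome coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_dyads
  blocks <- names(config$p_per_block)
  cov <- simulate_covariates(n)
  Z <- confounder_design(cov)

  eff <- config$covariate_effects
  if (identical(eff, "default")) {
    eff <- default_covariate_effects(blocks, config$p_per_block)
  } else if (identical(eff, "none")) {
    eff <- lapply(stats::setNames(blocks, blocks), function(b)
      matrix(0, ncol(Z), config$p_per_block[[b]],
             dimnames = list(colnames(Z), NULL)))
  }

  ## latent factors per block pair
  factors <- list()
  contrib <- stats::setNames(
    lapply(blocks, function(b) matrix(0, n, config$p_per_block[[b]])), blocks)
  loading_list <- stats::setNames(vector("list", length(blocks)), blocks)
  for (b in blocks) loading_list[[b]] <- list()

  for (pair in names(config$n_shared_factors)) {
    k <- config$n_shared_factors[[pair]]
    if (k < 1) next
    members <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (!all(members %in% blocks)) next
    f <- matrix(stats::rnorm(n * k), n, k)
    factors[[pair]] <- f
    for (b in members) {
      p <- config$p_per_block[[b]]
      L <- matrix(0, p, k)
      for (j in seq_len(k)) {
        nz <- stats::runif(p) >= config$loading_sparsity
        if (!any(nz)) nz[sample.int(p, 1L)] <- TRUE
        L[nz, j] <- config$factor_strength *
          sample(c(-1, 1), sum(nz), replace = TRUE) *
          stats::runif(sum(nz), 0.8, 1.2)
      }
      loading_list[[b]][[pair]] <- L
      contrib[[b]] <- contrib[[b]] + f %*% t(L)
    }
  }

  mats <- list()
  intercepts <- list()
  for (b in blocks) {
    p <- config$p_per_block[[b]]
    mu <- stats::rnorm(p, log(100), 1)
    intercepts[[b]] <- mu
    logc <- matrix(mu, n, p, byrow = TRUE) + contrib[[b]] +
      Z %*% eff[[b]] + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    vals <- exp(logc)
    prefix <- c(maternal_serum = "ms", placenta = "pl", cord_serum = "cs")[[b]]
    dimnames(vals) <- list(cov$dyad_id,
                           sprintf("%s_met%02d", prefix, seq_len(p)))
    mask <- matrix(FALSE, n, p, dimnames = dimnames(vals))
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p,
                     dimnames = dimnames(vals))
      vals[mask] <- NA_real_
    }
    mats[[b]] <- concentration_matrix(vals, b, mask)
  }

  ## outcome: multinomial logit, TD reference, on the first shared
  ## placenta:cord factor score (zero vector when no factor is planted)
  score <- if (!is.null(factors[["placenta:cord_serum"]])) {
    factors[["placenta:cord_serum"]][, 1L]
  } else rep(0, n)
  base <- log(config$outcome_props[c("ASD", "nonTD")] / config$outcome_props[["TD"]])
  eta <- matrix(0, n, 2L, dimnames = list(NULL, c("ASD", "nonTD")))
  for (cl in c("ASD", "nonTD")) {
    co <- config$outcome_coefficients[[cl]]
    e <- rep(base[[cl]], n)
    for (nm in names(co)) {
      x <- if (nm == "score") score else cov[[nm]]
      e <- e + co[[nm]] * x
    }
    eta[, cl] <- e
  }
  expeta <- cbind(TD = 1, exp(eta))
  probs <- expeta / rowSums(expeta)
  u <- stats::runif(n)
  cum <- t(apply(probs, 1L, cumsum))
  cls <- colnames(probs)[max.col(u <= cum, ties.method = "first")]
  outcome <- factor(cls, levels = OUTCOME_LEVELS)

  if (config$n_missing_covariates > 0) {
    miss <- sample.int(n, min(n, config$n_missing_covariates))
    cov$metabolic_condition[miss] <- NA_integer_
  }

  cohort <- dyad_cohort(cov$dyad_id, sprintf("M%03d", seq_len(n)), mats,
                        covariates = covariate_table(cov), outcome = outcome)
  truth <- list(factors = factors, loadings = loading_list,
                intercepts = intercepts, covariate_effects = eff,
                outcome_coefficients = config$outcome_coefficients,
                outcome_probs = probs, factor_score = score,
                config = config)
  list(cohort = cohort, truth = truth)
}

#' Generate a cohort with no shared latent structure
#'
#' Identical to [generate_cohort()] but with every between-block factor
#' removed: the compartment matrices are mutually independent given the
#' covariates. Used as the null model for FDR and permutation type-I
#' error checks.
#'
#' @param config a [synthetic_cohort_config()].
#' @return a [dyad_cohort()].
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  config$n_shared_factors[] <- 0L
  generate_cohort(config)$cohort
}

#' Write a cohort's tables and ground truth to a directory
#'
#' Emits one concentration CSV per compartment (the same format
#' [read_concentration_table()] reads), a covariate CSV, an outcome CSV
#' and, when supplied, a ground-truth JSON.
#'
#' @param cohort a [dyad_cohort()].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth list from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$matrices)) {
    write_concentration_table(cohort$matrices[[nm]],
                              file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(cohort$covariates)) {
    utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$outcome)) {
    utils::write.csv(data.frame(dyad_id = cohort$dyad_id,
                                outcome = as.character(cohort$outcome)),
                     file.path(dir, "outcome.csv"), row.names = FALSE)
  }
  if (!is.null(truth)) {
    tr <- truth
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}
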