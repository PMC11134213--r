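## Configuration-driven orchestration: filter -> pairing -> Spearman and
## adjusted screens -> (gated) residualized PLS -> Q2 -> permutation ->
## relevance network -> outcome models, with per-stage child seeds and
## TSV/JSON artifacts.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_cohort_config()] to generate the cohort,
#'   or NULL when `input_dir` points at CSV tables on disk.
#' @param input_dir directory holding `<compartment>.csv`,
#'   `covariates.csv`, `outcome.csv` (as written by [write_cohort()]).
#' @param pairs list of length-2 character vectors of compartments to
#'   analyze (default: placenta-cord, maternal-placenta, maternal-cord).
#' @param model1,model2 covariate name vectors for the minimal and fully
#'   adjusted models.
#' @param fdr_level FDR significance level (default 0.10).
#' @param min_detection detection-rate filter threshold (default 0.8).
#' @param exclusion_list metabolite ids dropped as contaminants.
#' @param max_components maximum PLS components evaluated by Q2.
#' @param n_permutations permutations for the covariance test (default 9999).
#' @param sparsity `"auto"` (sparse when n < p + q, the small-cohort
#'   rule), `"dense"`, or `"sparse"`.
#' @param sparsity_grid candidate keep budgets for tuning (default
#'   5, 10, 15, ... up to the block width).
#' @param network_threshold relevance-network edge threshold (default 0.5).
#' @param run_adjusted_screen whether to run the rank-regression screens.
#' @param outcome_metabolite optional named vector compartment ->
#'   metabolite id for the single-metabolite outcome screen.
#' @param seed master seed; each random stage consumes an independently
#'   derived child seed.
#' @param output_dir artifact directory, or NULL to skip writing files.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            pairs = list(c("placenta", "cord_serum"),
                                         c("maternal_serum", "placenta"),
                                         c("maternal_serum", "cord_serum")),
                            model1 = c("birth_year",
                                       "gestational_age_at_collection"),
                            model2 = c("birth_year",
                                       "gestational_age_at_collection",
                                       "fetal_sex", "maternal_education",
                                       "race_ethnicity", "home_ownership",
                                       "prenatal_vitamin_month1",
                                       "metabolic_condition"),
                            fdr_level = 0.10,
                            min_detection = 0.8,
                            exclusion_list = character(),
                            max_components = 2L,
                            n_permutations = 9999L,
                            sparsity = c("auto", "dense", "sparse"),
                            sparsity_grid = NULL,
                            network_threshold = 0.5,
                            run_adjusted_screen = TRUE,
                            outcome_metabolite = NULL,
                            seed = 1L,
                            output_dir = NULL) {
  if (is.null(synthetic) && is.null(input_dir)) {
    stop("provide either `synthetic` or `input_dir`", call. = FALSE)
  }
  if (fdr_level <= 0 || fdr_level >= 1) stop("fdr_level must be in (0,1)",
                                             call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (length(pairs) < 1) stop("at least one compartment pair required",
                              call. = FALSE)
  structure(
    list(synthetic = synthetic, input_dir = input_dir, pairs = pairs,
         model1 = model1, model2 = model2, fdr_level = fdr_level,
         min_detection = min_detection, exclusion_list = exclusion_list,
         max_components = as.integer(max_components),
         n_permutations = as.integer(n_permutations),
         sparsity = match.arg(sparsity),
         sparsity_grid = sparsity_grid,
         network_threshold = network_threshold,
         run_adjusted_screen = isTRUE(run_adjusted_screen),
         outcome_metabolite = outcome_metabolite,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` mapping is passed to [synthetic_cohort_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_cohort_config, y$synthetic)
  }
  if (!is.null(y$pairs)) y$pairs <- lapply(y$pairs, unlist)
  if (!is.null(y$outcome_metabolite)) {
    y$outcome_metabolite <- unlist(y$outcome_metabolite)
  }
  do.call(pipeline_config, y)
}

load_cohort_dir <- function(dir) {
  mats <- list()
  for (comp in COMPARTMENTS) {
    f <- file.path(dir, paste0(comp, ".csv"))
    if (file.exists(f)) mats[[comp]] <- read_concentration_table(f, comp)
  }
  if (!length(mats)) stop("no compartment tables in ", dir, call. = FALSE)
  cov <- NULL
  f <- file.path(dir, "covariates.csv")
  if (file.exists(f)) cov <- covariate_table(utils::read.csv(f))
  outcome <- NULL
  f <- file.path(dir, "outcome.csv")
  if (file.exists(f)) {
    o <- utils::read.csv(f)
    outcome <- stats::setNames(o$outcome, o$dyad_id)
  }
  dyads <- rownames(mats[[1L]]$values)
  list(matrices = mats, covariates = cov,
       outcome = if (is.null(outcome)) NULL else unname(outcome[dyads]),
       dyad_id = dyads)
}

#' Run the full integration pipeline
#'
#' Executes, per compartment pair: detection filtering, complete-case
#' restriction to the fully adjusted covariate set, bipartite Spearman
#' screen, covariate-adjusted rank-regression screens (models 1 and 2),
#' and -- only when at least one screen has a discovery at `q <
#' fdr_level` -- covariate residualization, (sparse) canonical PLS with
#' Q2 component selection, the permutation test on the first latent
#' covariance, the relevance network, and multinomial outcome models on
#' the first latent variate scores. Writes TSV tables, a JSON run
#' summary and a plain-text log (seeds, versions) when `output_dir` is
#' set. Identical config and seed give a bit-identical summary.
#'
#' @param config a [pipeline_config()].
#' @return the run summary list, invisibly when writing artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  stage_names <- c("cohort", "permutation")
  seeds <- derive_seeds(config$seed, length(stage_names), stage_names)
  log_lines <- c(sprintf("dyadomics %s",
                         as.character(utils::packageVersion("dyadomics"))),
                 sprintf("master seed: %d", config$seed),
                 sprintf("stage seeds: %s",
                         paste(sprintf("%s=%d", names(seeds), seeds),
                               collapse = " ")))

  ## ---- cohort ----
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- as.integer(seeds[["cohort"]] %% .Machine$integer.max)
    gen <- generate_cohort(syn)
    matrices <- gen$cohort$matrices
    covariates <- gen$cohort$covariates
    outcome <- gen$cohort$outcome
    dyads <- gen$cohort$dyad_id
    mothers <- gen$cohort$mother_id
  } else {
    loaded <- load_cohort_dir(config$input_dir)
    matrices <- loaded$matrices
    covariates <- loaded$covariates
    outcome <- loaded$outcome
    dyads <- loaded$dyad_id
    mothers <- dyads
  }

  ## detection filter per compartment
  filter_report <- list()
  for (nm in names(matrices)) {
    f <- filter_detection(matrices[[nm]], config$min_detection,
                          config$exclusion_list)
    filter_report[[nm]] <- attr(f, "filter_report")
    matrices[[nm]] <- f
  }

  summary <- list(
    seed = config$seed,
    stage_seeds = as.list(seeds),
    fdr_level = config$fdr_level,
    n_dyads_input = length(dyads),
    filtered = lapply(filter_report, function(r) r$metabolite),
    pairs = list()
  )

  for (pair in config$pairs) {
    key <- paste(pair, collapse = "-")
    bx <- matrices[[pair[1L]]]; by <- matrices[[pair[2L]]]
    if (is.null(bx) || is.null(by)) {
      summary$pairs[[key]] <- list(status = "missing_compartment")
      next
    }
    cohort <- dyad_cohort(dyads, mothers, matrices[pair],
                          covariates = covariates, outcome = outcome)
    if (!is.null(cohort$covariates)) {
      cohort <- complete_case(cohort, intersect(config$model2,
                                                names(cohort$covariates)))
    }
    bx <- cohort$matrices[[pair[1L]]]; by <- cohort$matrices[[pair[2L]]]
    res <- list(n_dyads = n_dyads(cohort))

    ## screens
    sp <- spearman_screen(bx, by)
    res$spearman_significant <- n_significant(sp, config$fdr_level)
    if (!is.null(out_dir)) {
      write_screen_tsv(sp, file.path(out_dir, paste0("spearman_", key, ".tsv")))
    }
    adj_sig <- 0L
    if (config$run_adjusted_screen) {
      adj <- adjusted_pairwise_screen(
        bx, by, cohort$covariates,
        covariate_set = intersect(config$model2, names(cohort$covariates)),
        model_label = "model2")
      adj_sig <- n_significant(adj, config$fdr_level)
      res$adjusted_significant <- adj_sig
      if (!is.null(out_dir)) {
        write_screen_tsv(adj, file.path(out_dir, paste0("adjusted_", key, ".tsv")))
      }
    }

    ## gate: PLS only when a screen found something
    if (res$spearman_significant + adj_sig == 0L) {
      res$pls <- "skipped_no_significant_screen"
      summary$pairs[[key]] <- res
      next
    }

    ## log-transform (zeros treated as missing), keep complete rows,
    ## residualize on model 2, standardize
    Xc <- suppressWarnings(log(bx$values)); Xc[!is.finite(Xc)] <- NA
    Yc <- suppressWarnings(log(by$values)); Yc[!is.finite(Yc)] <- NA
    ok <- stats::complete.cases(Xc) & stats::complete.cases(Yc)
    Xc <- Xc[ok, , drop = FALSE]; Yc <- Yc[ok, , drop = FALSE]
    covd <- if (is.null(cohort$covariates)) NULL else
      as.data.frame(cohort$covariates)[ok,
        intersect(config$model2, names(cohort$covariates)), drop = FALSE]
    Xr <- center_scale(residualize(Xc, covd))
    Yr <- center_scale(residualize(Yc, covd))
    n <- nrow(Xr); p <- ncol(Xr); q <- ncol(Yr)

    use_sparse <- switch(config$sparsity,
                         auto = n < p + q, sparse = TRUE, dense = FALSE)
    keep_x <- keep_y <- NULL
    if (use_sparse) {
      tuned <- tune_sparsity(Xr, Yr, grid = config$sparsity_grid)
      keep_x <- tuned$keep_x; keep_y <- tuned$keep_y
      res$sparsity <- list(keep_x = keep_x, keep_y = keep_y, q2 = tuned$q2)
    }

    sel <- select_components_q2(Xr, Yr, max_H = config$max_components,
                                keep_x = keep_x, keep_y = keep_y)
    res$q2 <- sel$q2_table$Q2
    res$retained_components <- sel$retained
    H <- max(1L, sel$retained)
    fit <- fit_canonical_pls(Xr, Yr, H = H, keep_x = keep_x, keep_y = keep_y)
    res$covariance <- fit$covariance
    res$variance_explained_pair <- fit$variance_explained$pair

    perm_seed <- as.integer((seeds[["permutation"]] + sum(utf8ToInt(key))) %%
                              .Machine$integer.max)
    perm <- permutation_test_covariance(Xr, Yr, B = config$n_permutations,
                                        keep_x = keep_x, keep_y = keep_y,
                                        seed = perm_seed)
    res$permutation <- list(observed = perm$observed_statistic,
                            B = perm$B, p_value = perm$p_value,
                            seed = perm_seed)

    if (perm$p_value < 0.05) {
      net <- relevance_network(fit, Xr, Yr,
                               threshold = config$network_threshold,
                               components = seq_len(H))
      res$network_edges <- nrow(net$edges)
      if (!is.null(out_dir)) {
        write_network(net,
                      graphml_path = file.path(out_dir,
                                               paste0("network_", key, ".graphml")),
                      edges_path = file.path(out_dir,
                                             paste0("network_", key, ".tsv")))
      }

      ## outcome models on the first latent variate scores
      if (!is.null(cohort$outcome) &&
          sum(table(cohort$outcome[ok]) > 0) >= 2) {
        for (side in c("x", "y")) {
          score <- if (side == "x") fit$scores_x[, 1L] else fit$scores_y[, 1L]
          block <- if (side == "x") pair[1L] else pair[2L]
          mm <- tryCatch(
            fit_multinomial(cohort$outcome[ok],
                            data.frame(score = as.numeric(scale(score))),
                            reference = "TD"),
            error = function(e) NULL)
          if (!is.null(mm)) {
            res$outcome[[block]] <- list(
              rr = as.list(mm$rr[, "score"]),
              rr_lower = as.list(mm$rr_lower[, "score"]),
              rr_upper = as.list(mm$rr_upper[, "score"]),
              p = as.list(mm$p_values[, "score"]),
              converged = mm$converged, separation = mm$separation)
          }
        }
      }
    }
    summary$pairs[[key]] <- res
  }

  ## single-metabolite outcome screen
  if (!is.null(config$outcome_metabolite) && !is.null(outcome)) {
    cohort_all <- dyad_cohort(dyads, mothers, matrices,
                              covariates = covariates, outcome = outcome)
    tab <- metabolite_outcome_screen(
      cohort_all, config$outcome_metabolite,
      covariate_sets = list(unadjusted = character(),
                            adjusted = intersect(config$model2,
                                                 names(covariates))))
    summary$metabolite_outcome <- tab
    if (!is.null(out_dir)) {
      utils::write.table(tab, file.path(out_dir, "metabolite_outcome.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    writeLines(c(log_lines, sprintf("finished: %s", format(Sys.time()))),
               file.path(out_dir, "run.log"))
    return(invisible(summary))
  }
  summary
}
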