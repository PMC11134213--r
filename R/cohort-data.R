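## Data model for compartment concentration tables and mother-infant dyads.

COMPARTMENTS <- c("maternal_serum", "placenta", "cord_serum")

#' Units used for each compartment
#'
#' Serum metabolite concentrations are quantified in nmol/L; placental
#' concentrations in nmol/g of tissue. No cross-unit conversion is ever
#' attempted: every downstream method is either rank-based (scale-free) or
#' applied to column-standardized data.
#'
#' @param compartment one of `"maternal_serum"`, `"placenta"`, `"cord_serum"`.
#' @return unit string.
#' @export
compartment_unit <- function(compartment) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (compartment == "placenta") "nmol/g" else "nmol/L"
}

#' Construct a concentration matrix for one compartment
#'
#' The core container for a samples x metabolites table of absolute
#' concentrations from quantitative NMR. Missing entries (metabolite not
#' detected in that sample) are carried both as `NA` in `values` and as
#' `TRUE` in `missing_mask`; retained metabolites are never imputed.
#'
#' @param values numeric matrix, rows = samples, columns = metabolites, with
#'   `dimnames` giving sample and metabolite ids. Non-missing entries must be
#'   non-negative concentrations.
#' @param compartment one of `"maternal_serum"`, `"placenta"`, `"cord_serum"`.
#' @param missing_mask logical matrix of the same dimension; defaults to
#'   `is.na(values)`.
#' @return an object of class `concentration_matrix`.
#' @export
concentration_matrix <- function(values, compartment,
                                 missing_mask = is.na(values)) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids (rownames) and metabolite ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate metabolite ids", call. = FALSE)
  }
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values))) {
    stop("`missing_mask` must be a logical matrix with the dimensions of `values`",
         call. = FALSE)
  }
  dimnames(missing_mask) <- dimnames(values)
  values[missing_mask] <- NA_real_
  if (any(values[!missing_mask & !is.na(values)] < 0)) {
    stop("negative concentrations are not allowed", call. = FALSE)
  }
  structure(
    list(compartment = compartment,
         sample_ids = rownames(values),
         metabolite_ids = colnames(values),
         values = values,
         missing_mask = missing_mask),
    class = "concentration_matrix"
  )
}

#' @export
dim.concentration_matrix <- function(x) dim(x$values)

#' @export
print.concentration_matrix <- function(x, ...) {
  cat(sprintf("<concentration_matrix> %s (%s): %d samples x %d metabolites, %.1f%% missing\n",
              x$compartment, compartment_unit(x$compartment),
              nrow(x$values), ncol(x$values),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' Read a delimited concentration table
#'
#' Expects a CSV (default) or TSV with the sample id in the first column and
#' one metabolite per remaining column. Blank cells (and any string in
#' `na_strings`) mark non-detected metabolites.
#'
#' @param path file path; `.tsv`/`.txt` extensions are read tab-separated.
#' @param compartment compartment label for the resulting matrix.
#' @param sep field separator; inferred from the extension when NULL.
#' @param na_strings strings treated as missing, in addition to blanks.
#' @return a [concentration_matrix()].
#' @export
read_concentration_table <- function(path, compartment, sep = NULL,
                                     na_strings = c("", "NA")) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("table must have a sample-id column plus metabolites",
                           call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path, call. = FALSE)
  met <- colnames(raw)[-1L]
  if (anyDuplicated(met)) stop("duplicate metabolite ids in ", path, call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(met),
                 dimnames = list(ids, met))
  for (j in seq_along(met)) {
    cell <- trimws(raw[[j + 1L]])
    miss <- cell %in% na_strings
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop(sprintf("non-numeric cell(s) in column '%s': %s", met[j],
                   paste(utils::head(cell[bad], 3L), collapse = ", ")),
           call. = FALSE)
    }
    if (any(num[!miss] < 0)) {
      stop(sprintf("negative concentration(s) in column '%s'", met[j]),
           call. = FALSE)
    }
    vals[!miss, j] <- num[!miss]
  }
  concentration_matrix(vals, compartment)
}

#' Write a concentration matrix to delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip reproduces the matrix bit-exactly; missing cells are blank.
#'
#' @param m a [concentration_matrix()].
#' @param path output path; `.tsv`/`.txt` write tab-separated.
#' @param sep field separator; inferred from the extension when NULL.
#' @export
write_concentration_table <- function(m, path, sep = NULL) {
  stopifnot(inherits(m, "concentration_matrix"))
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  body <- apply(m$values, 2L, format_full)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(m$values))
  out <- cbind(sample_id = m$sample_ids, body)
  colnames(out) <- c("sample_id", m$metabolite_ids)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop poorly detected and listed metabolites
#'
#' Removes metabolites detected in strictly less than `min_frac` of samples
#' (the detection-rate exclusion rule; a metabolite detected in exactly
#' `min_frac` of samples is retained) and any metabolite named on
#' `exclusion_list` (e.g. preparation contaminants). The returned matrix
#' carries a `"filter_report"` attribute listing dropped metabolites with
#' the reason and detection fraction. The operation is idempotent.
#'
#' @param m a [concentration_matrix()].
#' @param min_frac minimum detection fraction in (0, 1]; default 0.8.
#' @param exclusion_list character vector of metabolite ids to drop outright.
#' @return filtered [concentration_matrix()] with attribute `"filter_report"`.
#' @export
filter_detection <- function(m, min_frac = 0.8, exclusion_list = character()) {
  stopifnot(inherits(m, "concentration_matrix"))
  stop_if_not_scalar_prob(min_frac, "min_frac", open_left = TRUE)
  det <- colMeans(!m$missing_mask)
  listed <- m$metabolite_ids %in% exclusion_list
  low <- det < min_frac
  drop <- listed | low
  report <- data.frame(
    metabolite = m$metabolite_ids[drop],
    reason = ifelse(listed[drop], "exclusion_list", "detection_rate"),
    detection_frac = unname(det[drop]),
    stringsAsFactors = FALSE
  )
  keep <- which(!drop)
  out <- concentration_matrix(m$values[, keep, drop = FALSE], m$compartment,
                              m$missing_mask[, keep, drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Construct a covariate table
#'
#' One row per dyad. Binary covariates are coded 0/1 (maternal education:
#' 1 = bachelor's degree or higher; race/ethnicity: 1 = White; metabolic
#' condition: 1 = prepregnancy BMI >= 25 or any diabetes or hypertensive
#' disorder). Missing covariate values are allowed and flagged by `NA`.
#'
#' @param df data.frame with a `dyad_id` column; remaining columns are
#'   covariates.
#' @return the validated data.frame, classed `covariate_table`.
#' @export
covariate_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"dyad_id" %in% names(df)) stop("covariate table needs a `dyad_id` column",
                                      call. = FALSE)
  if (anyDuplicated(df$dyad_id)) stop("one row per dyad required", call. = FALSE)
  binary <- setdiff(names(df), c("dyad_id", "birth_year",
                                 "gestational_age_at_collection",
                                 "gestational_age_at_delivery",
                                 "fasting_time"))
  for (v in binary) {
    x <- df[[v]]
    if (!all(is.na(x) | x %in% c(0, 1))) {
      stop(sprintf("binary covariate '%s' must be coded 0/1 (NA allowed)", v),
           call. = FALSE)
    }
  }
  class(df) <- c("covariate_table", "data.frame")
  df
}

OUTCOME_LEVELS <- c("TD", "ASD", "nonTD")

#' Construct a dyad cohort
#'
#' Bundles row-aligned compartment matrices, per-dyad covariates and the
#' three-level neurodevelopmental outcome (TD reference, ASD, nonTD;
#' `NA` = missing diagnosis). Each mother contributes at most one dyad.
#'
#' @param dyad_id,mother_id character vectors, one entry per dyad.
#' @param matrices named list of [concentration_matrix()] objects whose rows
#'   follow `dyad_id` order (sample ids must equal the dyad ids).
#' @param covariates optional [covariate_table()] covering all dyads.
#' @param outcome optional factor/character of outcome labels per dyad.
#' @return an object of class `dyad_cohort`.
#' @export
dyad_cohort <- function(dyad_id, mother_id, matrices,
                        covariates = NULL, outcome = NULL) {
  stopifnot(length(dyad_id) == length(mother_id))
  if (anyDuplicated(dyad_id)) stop("duplicate dyad ids", call. = FALSE)
  if (anyDuplicated(mother_id[!is.na(mother_id)])) {
    stop("each mother may appear at most once", call. = FALSE)
  }
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    stopifnot(inherits(m, "concentration_matrix"))
    if (!identical(m$sample_ids, as.character(dyad_id))) {
      stop(sprintf("compartment '%s' is not row-aligned to the dyads", nm),
           call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- covariate_table(as.data.frame(covariates))
    idx <- match(dyad_id, covariates$dyad_id)
    if (anyNA(idx)) stop("covariate table does not cover all dyads", call. = FALSE)
    covariates <- covariates[idx, , drop = FALSE]
    rownames(covariates) <- NULL
    class(covariates) <- c("covariate_table", "data.frame")
  }
  if (!is.null(outcome)) {
    outcome <- factor(as.character(outcome), levels = OUTCOME_LEVELS)
    stopifnot(length(outcome) == length(dyad_id))
  }
  structure(
    list(dyad_id = as.character(dyad_id),
         mother_id = as.character(mother_id),
         matrices = matrices,
         covariates = covariates,
         outcome = outcome),
    class = "dyad_cohort"
  )
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d dyads; compartments: %s\n",
              length(x$dyad_id), paste(names(x$matrices), collapse = ", ")))
  if (!is.null(x$outcome)) {
    tab <- table(x$outcome, useNA = "ifany")
    cat("  outcome:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of dyads in a cohort
#' @param cohort a [dyad_cohort()].
#' @export
n_dyads <- function(cohort) length(cohort$dyad_id)

#' Pair compartment samples into mother-infant dyads
#'
#' Builds the analysis cohort for a set of compartments from a sample
#' registry. Dyads lacking any required compartment are excluded; when a
#' mother has several qualifying pregnancies only the earliest is kept
#' (pregnancies must be independent within an analysis); and an infant
#' whose older sibling is already included is excluded, walking dyads in
#' pregnancy order.
#'
#' @param matrices named list of [concentration_matrix()] objects, one per
#'   compartment, with arbitrary per-compartment sample ids.
#' @param registry data.frame with columns `sample_id`, `compartment`,
#'   `dyad_id`, `mother_id`, `pregnancy_order` (integer; 1 = earliest) and
#'   optionally `older_sibling_dyad` (dyad id of an already-enrolled older
#'   sibling, NA if none). Every sample in `matrices` must appear.
#' @param required character vector of compartments a dyad must have
#'   (default: all compartments in `matrices`; at least 2 for a pairwise
#'   analysis).
#' @param covariates optional [covariate_table()] keyed by `dyad_id`.
#' @param outcome optional named vector of outcome labels keyed by dyad id.
#' @return a [dyad_cohort()] whose matrices are restricted to `required`,
#'   rows re-indexed by dyad id, with attribute `"pairing_report"`.
#' @export
pair_dyads <- function(matrices, registry, required = names(matrices),
                       covariates = NULL, outcome = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  need <- c("sample_id", "compartment", "dyad_id", "mother_id", "pregnancy_order")
  if (!all(need %in% names(registry))) {
    stop("registry must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"older_sibling_dyad" %in% names(registry)) {
    registry$older_sibling_dyad <- NA_character_
  }
  required <- match.arg(required, names(matrices), several.ok = TRUE)

  ## map each compartment's samples to dyads; all must be registered
  sample_dyad <- list()
  for (nm in names(matrices)) {
    ids <- matrices[[nm]]$sample_ids
    reg <- registry[registry$compartment == nm, , drop = FALSE]
    hit <- match(ids, reg$sample_id)
    if (anyNA(hit)) {
      stop(sprintf("sample(s) in '%s' absent from registry: %s", nm,
                   paste(utils::head(ids[is.na(hit)], 3L), collapse = ", ")),
           call. = FALSE)
    }
    sample_dyad[[nm]] <- stats::setNames(reg$dyad_id[hit], ids)
  }

  dyads <- unique(registry[, c("dyad_id", "mother_id", "pregnancy_order",
                               "older_sibling_dyad")])
  if (anyDuplicated(dyads$dyad_id)) {
    stop("registry gives inconsistent mother/pregnancy info for a dyad",
         call. = FALSE)
  }

  has_comp <- sapply(required, function(nm) dyads$dyad_id %in% sample_dyad[[nm]])
  if (!is.matrix(has_comp)) has_comp <- matrix(has_comp, nrow = nrow(dyads))
  qualifying <- dyads[rowSums(has_comp) == length(required), , drop = FALSE]

  ## earliest qualifying pregnancy per mother
  qualifying <- qualifying[order(qualifying$mother_id, qualifying$pregnancy_order,
                                 qualifying$dyad_id), , drop = FALSE]
  first <- qualifying[!duplicated(qualifying$mother_id), , drop = FALSE]

  ## sibling exclusion, oldest first
  first <- first[order(first$pregnancy_order, first$dyad_id), , drop = FALSE]
  included <- character(0)
  excluded_sibling <- character(0)
  for (i in seq_len(nrow(first))) {
    sib <- first$older_sibling_dyad[i]
    if (!is.na(sib) && sib %in% included) {
      excluded_sibling <- c(excluded_sibling, first$dyad_id[i])
    } else {
      included <- c(included, first$dyad_id[i])
    }
  }
  keep <- first[first$dyad_id %in% included, , drop = FALSE]
  keep <- keep[order(keep$dyad_id), , drop = FALSE]

  out_mats <- list()
  for (nm in required) {
    m <- matrices[[nm]]
    map <- sample_dyad[[nm]]
    sel <- match(keep$dyad_id, unname(map))
    vals <- m$values[sel, , drop = FALSE]
    mask <- m$missing_mask[sel, , drop = FALSE]
    rownames(vals) <- rownames(mask) <- keep$dyad_id
    out_mats[[nm]] <- concentration_matrix(vals, m$compartment, mask)
  }
  if (!is.null(outcome)) outcome <- unname(outcome[keep$dyad_id])
  cohort <- dyad_cohort(keep$dyad_id, keep$mother_id, out_mats,
                        covariates = if (is.null(covariates)) NULL else
                          covariates[covariates$dyad_id %in% keep$dyad_id, ,
                                     drop = FALSE],
                        outcome = outcome)
  attr(cohort, "pairing_report") <- list(
    n_candidate_dyads = nrow(dyads),
    n_with_required = nrow(qualifying),
    n_after_first_pregnancy = nrow(first),
    excluded_older_sibling = excluded_sibling,
    n_included = nrow(keep)
  )
  cohort
}

#' Restrict a cohort to complete covariate cases
#'
#' Keeps dyads with no missing value among the named covariates; the
#' number dropped is recorded in attribute `"n_dropped"`.
#'
#' @param cohort a [dyad_cohort()] with covariates attached.
#' @param covariate_set character vector of covariate column names.
#' @return the restricted [dyad_cohort()].
#' @export
complete_case <- function(cohort, covariate_set) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  if (is.null(cohort$covariates)) stop("cohort has no covariates", call. = FALSE)
  unknown <- setdiff(covariate_set, names(cohort$covariates))
  if (length(unknown)) {
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(covariate_set) == 0L) {
    attr(cohort, "n_dropped") <- 0L
    return(cohort)
  }
  ok <- stats::complete.cases(cohort$covariates[, covariate_set, drop = FALSE])
  out <- subset_cohort(cohort, which(ok))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

## Row-subset every aligned piece of a cohort.
subset_cohort <- function(cohort, idx) {
  mats <- lapply(cohort$matrices, function(m) {
    concentration_matrix(m$values[idx, , drop = FALSE], m$compartment,
                         m$missing_mask[idx, , drop = FALSE])
  })
  cov <- cohort$covariates
  if (!is.null(cov)) {
    cov <- cov[idx, , drop = FALSE]
    rownames(cov) <- NULL
    class(cov) <- c("covariate_table", "data.frame")
  }
  dyad_cohort(cohort$dyad_id[idx], cohort$mother_id[idx], mats,
              covariates = cov,
              outcome = if (is.null(cohort$outcome)) NULL else cohort$outcome[idx])
}
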