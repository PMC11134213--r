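test_that("concentration tables round-trip through text bit-exactly", {
  vals <- matrix(c(1.25, 30.7, 0.003, 150.2, 98.6, 7.771), 3, 2)
  m <- make_cm(vals, "maternal_serum")
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(m, path)
  m2 <- read_concentration_table(path, "maternal_serum")
  expect_identical(m2$values, m$values)
  expect_identical(m2$missing_mask, m$missing_mask)
  expect_identical(m2$metabolite_ids, m$metabolite_ids)
  expect_false(any(m2$missing_mask))

  # blank cell comes back as missing exactly there
  vals[2, 1] <- NA
  m <- make_cm(vals)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_concentration_table(m, path2)
  m3 <- read_concentration_table(path2, "placenta")
  expect_identical(which(m3$missing_mask), which(is.na(vals)))
  expect_identical(m3$values, m$values)
})

test_that("malformed concentration tables are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,metA,metA", "S1,1,2", "S2,3,4"), path)
  expect_error(read_concentration_table(path, "placenta"), "duplicate metabolite")

  writeLines(c("sample_id,metA,metB", "S1,1,2", "S1,3,4"), path)
  expect_error(read_concentration_table(path, "placenta"), "duplicate sample")

  writeLines(c("sample_id,metA,metB", "S1,1,oops", "S2,3,4"), path)
  expect_error(read_concentration_table(path, "placenta"), "non-numeric")

  writeLines(c("sample_id,metA,metB", "S1,1,-2", "S2,3,4"), path)
  expect_error(read_concentration_table(path, "placenta"), "negative")
})

test_that("detection filter drops below-threshold and listed metabolites", {
  # met01 detected 7/10 (dropped), met02 detected 8/10 (kept: boundary is
  # 'less than 80%' excluded), met03 fully detected
  vals <- matrix(1, 10, 3)
  vals[1:3, 1] <- NA
  vals[1:2, 2] <- NA
  m <- make_cm(vals)
  f <- filter_detection(m)
  expect_identical(f$metabolite_ids, c("met02", "met03"))
  rep <- attr(f, "filter_report")
  expect_identical(rep$metabolite, "met01")
  expect_equal(rep$detection_frac, 0.7)

  # exclusion list removes a fully detected metabolite
  f2 <- filter_detection(m, exclusion_list = "met03")
  expect_identical(f2$metabolite_ids, "met02")
  expect_true("exclusion_list" %in% attr(f2, "filter_report")$reason)

  expect_error(filter_detection(m, min_frac = 0), "min_frac")
  expect_error(filter_detection(m, min_frac = 1.2), "min_frac")
})

test_that("detection filter is idempotent", {
  withr::with_seed(42, {
    vals <- matrix(rlnorm(200), 20, 10)
    vals[sample(200, 45)] <- NA
  })
  m <- make_cm(vals)
  once <- filter_detection(m, 0.8)
  twice <- filter_detection(once, 0.8)
  expect_identical(twice$values, once$values)
  expect_identical(twice$metabolite_ids, once$metabolite_ids)
  expect_identical(nrow(attr(twice, "filter_report")), 0L)
})

test_that("pair_dyads keeps first pregnancy, drops younger siblings and incomplete dyads", {
  reg <- expand.grid(compartment = c("placenta", "cord_serum"),
                     dyad_id = c("D1", "D2", "D3", "D4"),
                     stringsAsFactors = FALSE)
  reg$sample_id <- paste0(reg$dyad_id, "_", substr(reg$compartment, 1, 2))
  # D1/D2: same mother, pregnancies 2010 and 2012; D3 younger sibling of D1;
  # D4 independent
  info <- data.frame(dyad_id = c("D1", "D2", "D3", "D4"),
                     mother_id = c("M1", "M1", "M3", "M4"),
                     pregnancy_order = c(1L, 2L, 2L, 1L),
                     older_sibling_dyad = c(NA, NA, "D1", NA))
  reg <- merge(reg, info)
  # D4 lacks a cord sample
  reg <- reg[!(reg$dyad_id == "D4" & reg$compartment == "cord_serum"), ]

  all_ids <- reg$sample_id
  mk <- function(comp) {
    ids <- reg$sample_id[reg$compartment == comp]
    make_cm(matrix(seq_along(ids) + 0.5, length(ids), 2), comp, samples = ids)
  }
  mats <- list(placenta = mk("placenta"), cord_serum = mk("cord_serum"))
  cohort <- pair_dyads(mats, reg, required = c("placenta", "cord_serum"))

  # D2 dropped (second pregnancy of M1), D3 dropped (older sibling D1 in),
  # D4 dropped (missing cord), leaving D1 only
  expect_identical(cohort$dyad_id, "D1")
  expect_identical(attr(cohort, "pairing_report")$excluded_older_sibling, "D3")
  expect_false(anyDuplicated(cohort$mother_id) > 0)

  # unregistered sample errors
  mats$placenta <- make_cm(matrix(1, 2, 2), "placenta",
                           samples = c("D1_pl", "GHOST"))
  expect_error(pair_dyads(mats, reg), "absent from registry")
})

test_that("pair_dyads mother-to-dyad mapping is injective on random registries", {
  for (seed in 1:5) {
    reg <- withr::with_seed(seed, {
      n <- 30
      d <- data.frame(dyad_id = sprintf("D%02d", 1:n),
                      mother_id = sprintf("M%02d", sample(1:18, n, TRUE)),
                      pregnancy_order = sample(1:3, n, TRUE),
                      older_sibling_dyad = NA_character_)
      comp <- lapply(1:n, function(i)
        sample(c("placenta", "cord_serum"),
               sample(1:2, 1, prob = c(0.2, 0.8))))
      do.call(rbind, lapply(1:n, function(i) {
        data.frame(sample_id = paste0(d$dyad_id[i], "_", comp[[i]]),
                   compartment = comp[[i]], d[i, ], row.names = NULL)
      }))
    })
    mats <- lapply(c(placenta = "placenta", cord_serum = "cord_serum"),
                   function(cc) {
      ids <- reg$sample_id[reg$compartment == cc]
      make_cm(matrix(1 + seq_along(ids), length(ids), 2), cc, samples = ids)
    })
    cohort <- pair_dyads(mats, reg)
    expect_equal(anyDuplicated(cohort$mother_id), 0)
    expect_identical(cohort$matrices$placenta$sample_ids, cohort$dyad_id)
  }
})

test_that("complete_case drops exactly the dyads with missing covariates", {
  gen <- generate_cohort(synthetic_cohort_config(
    n_dyads = 111, p_per_block = c(placenta = 6L, cord_serum = 5L),
    n_shared_factors = c("placenta:cord_serum" = 1L),
    n_missing_covariates = 4L, seed = 5))
  cohort <- gen$cohort
  model2 <- c("birth_year", "metabolic_condition", "maternal_education",
              "home_ownership", "race_ethnicity")
  cc <- complete_case(cohort, model2)
  expect_equal(n_dyads(cc), 107)
  expect_equal(attr(cc, "n_dropped"), 4L)
  # no missing left; unchanged when nothing is missing
  cc2 <- complete_case(cc, model2)
  expect_equal(n_dyads(cc2), 107)
  expect_equal(attr(cc2, "n_dropped"), 0L)
  expect_error(complete_case(cohort, "no_such_covariate"), "unknown covariate")
})
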