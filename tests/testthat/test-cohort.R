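make_toy_cohort <- function() {
  subjects <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    age = c(60, 70, 65), sex = c("male", "female", "female"),
    education_level = c(1, 2, 3), family_history = c(0, 1, 1),
    apoe4 = c(1, NA, 0)
  )
  visits <- tibble::tibble(
    subject_id = c("a", "b", "b", "c", "c", "c"),
    time_years = c(0, 0, 1, 0, 1, 2),
    cdrsb = c(0, 0.5, 1, 0, 0, 0.5),
    mmse = c(30L, 28L, 27L, 30L, 29L, 30L)
  )
  cohort_table(subjects, visits)
}

test_that("cohort construction validates ids and visit ordering", {
  co <- make_toy_cohort()
  expect_s3_class(co, "cohort_table")
  expect_error(
    cohort_table(
      tibble::tibble(subject_id = c("a", "a")),
      tibble::tibble(subject_id = "a", time_years = 0)
    ),
    "unique"
  )
  expect_error(
    cohort_table(
      tibble::tibble(subject_id = "a"),
      tibble::tibble(subject_id = "zz", time_years = 0)
    ),
    "known subject"
  )
  expect_error(
    cohort_table(
      tibble::tibble(subject_id = "a"),
      tibble::tibble(subject_id = c("a", "a"), time_years = c(1, 1))
    ),
    "strictly increasing"
  )
})

test_that("eligibility filtering keeps multi-visit subjects and logs counts", {
  co <- make_toy_cohort()
  f1 <- filter_eligible(co)
  expect_setequal(f1$subjects$subject_id, c("b", "c"))
  log <- attr(f1, "filter_log")
  expect_identical(log$n_removed, c(1L, 0L))
  # APOE requirement drops subject b
  f2 <- filter_eligible(co, require_apoe = TRUE)
  expect_identical(f2$subjects$subject_id, "c")
  expect_identical(attr(f2, "filter_log")$n_removed, c(1L, 1L))
  # idempotence
  f3 <- filter_eligible(f1)
  expect_identical(f3$subjects$subject_id, f1$subjects$subject_id)
  # empty result is legal
  empty <- cohort_table(
    tibble::tibble(subject_id = "a", apoe4 = NA),
    tibble::tibble(subject_id = "a", time_years = 0, cdrsb = 0, mmse = 30L)
  )
  expect_message(out <- filter_eligible(empty), "no subjects")
  expect_identical(nrow(out$subjects), 0L)
})

test_that("radiological dichotomisation follows the stated cut-offs", {
  subj <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    ptau_abeta = c(0.01, 0.03, 0.024, 0.0241, NA, 0.02),
    mta_avg = c(1.5, 0.5, 0, 1, NA, 2),
    fsd = c(2, 1, 0, 3, 2, NA),
    fspv = c(1, 0, 0, 2, 3, 1),
    arwmc_1 = c(1, 1, 0, 2, 1, 0), arwmc_2 = c(1, 0, 0, 1, 1, 0),
    arwmc_3 = c(1, 0, 0, 1, 1, 0), arwmc_4 = c(0, 1, 0, 0, 1, 1),
    arwmc_5 = c(0, 0, 0, 0, 1, NA),
    hv_baseline = c(5600, 5800, 6000, 5400, 5900, 5700),
    vv_baseline = c(30000, 35000, 28000, 40000, 31000, 33000),
    hv_last = c(5400, NA, 5950, 5100, 5880, 5650),
    vv_last = c(31000, NA, 28500, 42000, 31500, 33800),
    t_last_volume = c(2, NA, 1, 3, 2, 2)
  )
  p <- derive_profiles(subj)
  expect_identical(p$ad_positive, c(0L, 1L, 0L, 1L, NA, 0L)) # cut is > 0.024
  expect_identical(p$mta_flag,
                   c("positive", "inconclusive", "negative", "positive", NA, "positive"))
  expect_identical(p$mta_positive, c(1L, 0L, 0L, 1L, NA, 1L))
  expect_identical(p$fsd_positive, c(1L, 0L, 0L, 1L, 1L, NA)) # deep cut is 2
  expect_identical(p$fspv_positive, c(1L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(p$arwmc_count, c(3, 2, 0, 3, 5, NA))
  expect_identical(p$arwmc_positive, c(1L, 0L, 0L, 1L, 1L, NA))
  # annualised change then standardisation
  expect_equal(p$hv_rate_raw[1], -100)
  expect_equal(mean(p$hv, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(p$hv_rate, na.rm = TRUE), 1, tolerance = 1e-12)
  # region-permutation invariance of the combined ARWMC flag
  perm <- subj
  perm[paste0("arwmc_", 1:5)] <- subj[paste0("arwmc_", c(4, 2, 5, 1, 3))]
  expect_identical(derive_profiles(perm)$arwmc_positive, p$arwmc_positive)
})

test_that("cohort summaries reproduce reported percentage arithmetic", {
  # CDRSB distribution reconstructed from printed baseline counts
  cdrsb <- c(rep(0, 1162), rep(0.5, 214), rep(1.5, 196), rep(NA, 2))
  s <- summarise_cohort(data.frame(cdrsb = cdrsb), "cdrsb",
                        breaks = c(0, 0.5, 1, Inf), labels = c("0", "0.5", ">=1"))
  expect_equal(s$pct[s$category == ">=1"], 12.5)
  expect_equal(s$n_unknown[1], 2L)
  expect_equal(sum(s$pct), 100, tolerance = 0.1)
  # a variable with every value missing is degenerate but legal
  expect_warning(
    empty <- summarise_cohort(data.frame(x = c(NA, NA)), "x"),
    "percentages undefined"
  )
  expect_identical(nrow(empty), 0L)
  expect_error(summarise_cohort(data.frame(x = 1), "zz"), "unknown variable")
})

test_that("cohorts round-trip through CSV with empty cells as missing", {
  co <- make_toy_cohort()
  sf <- withr::local_tempfile(fileext = ".csv")
  vf <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(co$subjects, sf, row.names = FALSE, na = "")
  utils::write.csv(co$visits, vf, row.names = FALSE, na = "")
  back <- read_cohort(sf, vf)
  expect_equal(tibble::as_tibble(back$subjects), co$subjects)
  expect_equal(tibble::as_tibble(back$visits), co$visits)
  expect_true(is.na(back$subjects$apoe4[2]))
})

test_that("model data preparation transforms outcomes and encodes covariates", {
  co <- filter_eligible(make_toy_cohort())
  d <- prepare_mlcmm_data(co)
  expect_setequal(unique(d$outcomes$outcome), c("tcdrsb", "nmmse"))
  tc <- d$outcomes[d$outcomes$outcome == "tcdrsb" & d$outcomes$subject_id == "b", ]
  expect_equal(tc$value, transform_cdrsb(c(0.5, 1)))
  expect_identical(
    names(d$covariates),
    c("subject_id", "age", "sex_male", "edu2", "edu3", "family_history", "apoe4")
  )
  expect_identical(d$covariates$edu3, c(0L, 1L))
})
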