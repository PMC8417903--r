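#' Assemble a longitudinal cohort table
#'
#' Bundles the two tables every stage of the pipeline consumes: one row per
#' subject (baseline risk factors and biomarkers) and one row per visit
#' (times in years from baseline, CDRSB and MMSE scores).
#'
#' @param subjects Data frame with one row per subject. Required column
#'   `subject_id`; the modelling stages additionally use `age`, `sex`
#'   (`"male"`/`"female"`), `education_level` (1/2/3), `family_history`
#'   (0/1), `apoe4` (0/1, may be `NA`), and the biomarker columns
#'   `ptau_abeta`, `mta_avg`, `fsd`, `fspv`, `arwmc_1`..`arwmc_5`,
#'   `hv_baseline`, `vv_baseline`, `hv_last`, `vv_last`, `t_last_volume`.
#' @param visits Data frame with columns `subject_id`, `time_years` (>= 0,
#'   strictly increasing within subject), `cdrsb`, `mmse` (either may be `NA`).
#' @return An object of class `cohort_table`: a list with tibbles `subjects`
#'   and `visits`.
#' @export
cohort_table <- function(subjects, visits) {
  subjects <- tibble::as_tibble(subjects)
  visits <- tibble::as_tibble(visits)
  if (!"subject_id" %in% names(subjects)) abort("`subjects` needs a `subject_id` column")
  if (anyDuplicated(subjects$subject_id)) abort("subject ids must be unique")
  need <- c("subject_id", "time_years")
  if (!all(need %in% names(visits))) abort("`visits` needs `subject_id` and `time_years`")
  if (!all(visits$subject_id %in% subjects$subject_id)) {
    abort("every visit must belong to a known subject")
  }
  if (any(is.na(visits$time_years)) || any(visits$time_years < 0)) {
    abort("`time_years` must be non-negative and non-missing")
  }
  visits <- dplyr::arrange(visits, .data$subject_id, .data$time_years)
  dup <- visits |>
    dplyr::count(.data$subject_id, .data$time_years) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) abort("visit times must be strictly increasing within subject")
  structure(list(subjects = subjects, visits = visits), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d subjects, %d visits\n",
    nrow(x$subjects), nrow(x$visits)
  ))
  invisible(x)
}

#' Read a cohort from visit and subject CSV files
#'
#' Thin wrapper building a [cohort_table()] from the two standard tables:
#' `visits` (subject_id, time_years, cdrsb, mmse) and `subjects` (one row
#' per subject; see [cohort_table()] for the columns). Empty cells are read
#' as missing.
#'
#' @param subjects_file,visits_file Paths to CSV files.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(subjects_file, visits_file) {
  subjects <- utils::read.csv(subjects_file, na.strings = c("", "NA"))
  visits <- utils::read.csv(visits_file, na.strings = c("", "NA"))
  cohort_table(subjects, visits)
}

#' Restrict a cohort to analysis-eligible subjects
#'
#' Keeps subjects with at least two visits and, optionally, subjects with a
#' known APOE e4 carrier status (the class-membership covariates must be
#' complete for the mixed-model stage). Attaches a per-rule filter log.
#'
#' @param cohort A [cohort_table()].
#' @param min_visits Minimum number of visits to retain a subject (default 2).
#' @param require_apoe Drop subjects whose `apoe4` is missing?
#' @return A filtered `cohort_table`; `attr(, "filter_log")` is a tibble with
#'   columns `rule` and `n_removed`.
#' @export
filter_eligible <- function(cohort, min_visits = 2L, require_apoe = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  usable <- cohort$visits
  if (all(c("cdrsb", "mmse") %in% names(usable))) {
    usable <- dplyr::filter(usable, !is.na(.data$cdrsb) | !is.na(.data$mmse))
  }
  nv <- usable |> dplyr::count(.data$subject_id, name = "n_visits")
  keep1 <- nv$subject_id[nv$n_visits >= min_visits]
  removed_visits <- setdiff(cohort$subjects$subject_id, keep1)
  keep <- keep1
  removed_apoe <- character(0)
  if (require_apoe && "apoe4" %in% names(cohort$subjects)) {
    known <- cohort$subjects$subject_id[!is.na(cohort$subjects$apoe4)]
    removed_apoe <- setdiff(keep, known)
    keep <- intersect(keep, known)
  }
  log <- tibble::tibble(
    rule = c(sprintf("fewer than %d usable visits", min_visits), "missing APOE e4 status"),
    n_removed = c(length(removed_visits), length(removed_apoe))
  )
  if (length(keep) == 0L) inform("filter_eligible: no subjects remain")
  out <- cohort_table(
    dplyr::filter(cohort$subjects, .data$subject_id %in% keep),
    dplyr::filter(cohort$visits, .data$subject_id %in% keep)
  )
  attr(out, "filter_log") <- log
  out
}

#' Derive the biomarker profile covariates for profile regression
#'
#' Dichotomises the radiological reads, flags CSF AD positivity, annualises
#' the volumetric change, and standardises the four continuous volumetric
#' covariates over the non-missing entries:
#' * `ad_positive`: pTau/Abeta ratio > 0.024;
#' * `mta_flag`: `"negative"` (< 0.5), `"inconclusive"` (= 0.5), `"positive"`
#'   (>= 1); the binary covariate `mta_positive` is `mta_avg >= 1`
#'   (inconclusive counts as negative);
#' * `fsd_positive`: Fazekas deep >= 2; `fspv_positive`: Fazekas
#'   periventricular >= 1;
#' * `arwmc_count`: number of the five regional white-matter-change scores
#'   >= 1; `arwmc_positive`: count >= 3 (majority of regions);
#' * `hv`, `vv`, `hv_rate`, `vv_rate`: standardised baseline volumes and
#'   annualised changes (raw rates kept as `hv_rate_raw`, `vv_rate_raw`).
#'
#' @param subjects Subject table (see [cohort_table()]).
#' @return Tibble with one row per subject.
#' @export
derive_profiles <- function(subjects) {
  subjects <- tibble::as_tibble(subjects)
  arw_cols <- paste0("arwmc_", 1:5)
  need <- c(
    "subject_id", "ptau_abeta", "mta_avg", "fsd", "fspv", arw_cols,
    "hv_baseline", "vv_baseline", "hv_last", "vv_last", "t_last_volume"
  )
  miss <- setdiff(need, names(subjects))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  arw <- as.matrix(subjects[arw_cols])
  arw_count <- ifelse(rowSums(is.na(arw)) > 0, NA_real_, rowSums(arw >= 1))
  hv_rate <- annualised_change(subjects$hv_baseline, subjects$hv_last, subjects$t_last_volume)
  vv_rate <- annualised_change(subjects$vv_baseline, subjects$vv_last, subjects$t_last_volume)
  tibble::tibble(
    subject_id = subjects$subject_id,
    ad_positive = as.integer(subjects$ptau_abeta > 0.024),
    mta_flag = dplyr::case_when(
      is.na(subjects$mta_avg) ~ NA_character_,
      subjects$mta_avg >= 1 ~ "positive",
      subjects$mta_avg == 0.5 ~ "inconclusive",
      TRUE ~ "negative"
    ),
    mta_positive = as.integer(subjects$mta_avg >= 1),
    fsd_positive = as.integer(subjects$fsd >= 2),
    fspv_positive = as.integer(subjects$fspv >= 1),
    arwmc_count = arw_count,
    arwmc_positive = as.integer(arw_count >= 3),
    hv = standardise(subjects$hv_baseline),
    vv = standardise(subjects$vv_baseline),
    hv_rate_raw = hv_rate,
    vv_rate_raw = vv_rate,
    hv_rate = standardise(hv_rate),
    vv_rate = standardise(vv_rate)
  )
}

#' Tabulate a baseline variable the way cohort tables are reported
#'
#' Counts subjects per category of one variable, with percentages computed
#' among the non-missing entries and rounded to one decimal; the number of
#' unknowns is reported separately.
#'
#' @param data Data frame of subjects.
#' @param variable Column name (string).
#' @param breaks Optional cut points for a numeric variable; categories are
#'   formed with [cut()] using `right = FALSE` (left-closed intervals).
#' @param labels Optional labels for the cut categories.
#' @return Tibble with columns `variable`, `category`, `n`, `pct`,
#'   `n_unknown`. If every value is missing, `pct` is `NA` and a warning is
#'   raised.
#' @export
#' @examples
#' d <- data.frame(cdrsb = c(0, 0, 0.5, 1, 2, NA))
#' summarise_cohort(d, "cdrsb", breaks = c(0, 0.5, 1, Inf),
#'                  labels = c("0", "0.5", ">=1"))
summarise_cohort <- function(data, variable, breaks = NULL, labels = NULL) {
  if (!variable %in% names(data)) abort(sprintf("unknown variable `%s`", variable))
  x <- data[[variable]]
  n_unknown <- sum(is.na(x))
  if (!is.null(breaks)) {
    x <- cut(x, breaks = breaks, labels = labels, right = FALSE, include.lowest = TRUE)
  }
  x <- factor(x)
  counts <- table(x)
  denom <- sum(counts)
  if (denom == 0L) {
    warn(sprintf("`%s` has no non-missing values; percentages undefined", variable))
    return(tibble::tibble(
      variable = variable, category = character(0), n = integer(0),
      pct = numeric(0), n_unknown = n_unknown
    ))
  }
  tibble::tibble(
    variable = variable,
    category = names(counts),
    n = as.integer(counts),
    pct = round(100 * as.integer(counts) / denom, 1),
    n_unknown = n_unknown
  )
}

#' Prepare transformed outcomes and covariates for the mixed model
#'
#' Applies the CDRSB logistic transform and the MMSE normalisation, stacks
#' the two outcomes in long format, and builds the class-independent
#' covariate matrix (age, sex male, education levels 2 and 3, family history,
#' APOE e4). Visits where both outcomes are missing are dropped.
#'
#' @param cohort A [cohort_table()], normally after [filter_eligible()].
#' @param mmse_table Lookup passed to [normalise_mmse()].
#' @param centre_age Subtract the cohort mean age from `age`? Keeping the
#'   covariates near zero stabilises estimation; default `FALSE` to match
#'   raw-scale coefficient conventions.
#' @return List with `outcomes` (tibble: `subject_id`, `outcome`
#'   (`"tcdrsb"`/`"nmmse"`), `time_years`, `value`) and `covariates` (tibble:
#'   `subject_id` plus the six model covariates).
#' @export
prepare_mlcmm_data <- function(cohort, mmse_table = mmse_normalisation_table(),
                               centre_age = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  v <- cohort$visits
  long <- dplyr::bind_rows(
    tibble::tibble(
      subject_id = v$subject_id, outcome = "tcdrsb",
      time_years = v$time_years, value = transform_cdrsb(v$cdrsb)
    ),
    tibble::tibble(
      subject_id = v$subject_id, outcome = "nmmse",
      time_years = v$time_years, value = normalise_mmse(v$mmse, mmse_table)
    )
  ) |> dplyr::filter(!is.na(.data$value))
  s <- cohort$subjects
  age <- if (centre_age) s$age - mean(s$age, na.rm = TRUE) else s$age
  covariates <- tibble::tibble(
    subject_id = s$subject_id,
    age = age,
    sex_male = as.integer(s$sex == "male"),
    edu2 = as.integer(s$education_level == 2),
    edu3 = as.integer(s$education_level == 3),
    family_history = as.integer(s$family_history),
    apoe4 = as.integer(s$apoe4)
  )
  list(outcomes = long, covariates = covariates)
}
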