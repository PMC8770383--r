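#' Estimated GFR from serum creatinine (Japanese three-variable equation)
#'
#' Computes eGFR as `194 * SCr^-1.094 * age^-0.287`, multiplied by 0.739 for
#' females. This is the equation validated for the Japanese population and is
#' the basis of all renal-function handling in the package.
#'
#' @param scr Serum creatinine in mg/dL (positive).
#' @param age Age in years (positive; the equation is validated for adults).
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(1.0, 50, "male")    # 63.12
#' compute_egfr(1.0, 50, "female")  # 46.65
#' @export
compute_egfr <- function(scr, age, sex) {
  if (any(scr <= 0, na.rm = TRUE)) stopf("scr must be positive")
  if (any(age <= 0, na.rm = TRUE)) stopf("age must be positive")
  sex <- match_sex(sex)
  194 * scr^(-1.094) * age^(-0.287) * ifelse(sex == "female", 0.739, 1)
}

## inverse of compute_egfr; used by the simulator to emit serum creatinine
egfr_to_scr <- function(egfr, age, sex) {
  sex <- match_sex(sex)
  (egfr / (194 * age^(-0.287) * ifelse(sex == "female", 0.739, 1)))^(-1 / 1.094)
}

match_sex <- function(sex) {
  out <- tolower(as.character(sex))
  out[out %in% c("m", "male")] <- "male"
  out[out %in% c("f", "female")] <- "female"
  if (!all(out %in% c("male", "female")))
    stopf("sex must be 'male' or 'female'")
  out
}

#' Identify the index date from a dated eGFR series
#'
#' Scans the chronologically ordered eGFR measurements of one subject for the
#' first *consecutive* pair (adjacent measurements) in which a value
#' >= 60 mL/min/1.73 m^2 is followed by a value < 60, with the two dates at
#' most `max_gap_days` apart. The date of the second member of the pair is the
#' index date marking entry into impaired renal function.
#'
#' @param dates Measurement dates (`Date`), sorted ascending.
#' @param egfr eGFR values aligned with `dates`.
#' @param max_gap_days Maximum allowed spacing of the pair (default 730 days,
#'   i.e. the 2-year timeframe).
#' @return `NULL` if no qualifying pair, else a list with `pre_index_date`,
#'   `index_date`, `pre_index_egfr`, `index_egfr`.
#' @export
identify_index <- function(dates, egfr, max_gap_days = 730) {
  if (length(dates) < 2L) stopf("need at least 2 measurements")
  if (length(dates) != length(egfr)) stopf("dates and egfr lengths differ")
  if (is.unsorted(dates)) stopf("dates must be sorted ascending")
  n <- length(egfr)
  hit <- which(egfr[-n] >= 60 & egfr[-1L] < 60 &
                 as.numeric(dates[-1L] - dates[-n]) <= max_gap_days)
  if (length(hit) == 0L) return(NULL)
  j <- hit[1L]
  list(pre_index_date = dates[j], index_date = dates[j + 1L],
       pre_index_egfr = egfr[j], index_egfr = egfr[j + 1L])
}

#' Load an ICD-10 / treatment code map
#'
#' The map drives Charlson scoring, CV-history flags and the composite
#' cardiovascular endpoint. The default shipped map uses the Quan ICD-10
#' algorithm categories with the original Charlson weights and a minimal
#' illustrative CV-event code list; real analyses should supply their own.
#'
#' @param path Path to a JSON code map; `NULL` loads the packaged default.
#' @return Nested list with elements `cci` (categories: `codes`, `weight`),
#'   `hierarchy`, `cv_history_categories`, `cv_events`, `treatments`.
#' @export
load_code_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_map.json", package = "anemiaMSM")
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(map$cci) || is.null(map$cv_events)) stopf("malformed code map: %s", path)
  for (cat in names(map$cci)) {
    entry <- map$cci[[cat]]
    if (is.null(entry$codes) || is.null(entry$weight) || entry$weight < 0)
      stopf("malformed code map category '%s'", cat)
  }
  map
}

norm_icd10 <- function(x) toupper(gsub("[. ]", "", as.character(x)))

icd_match <- function(codes, prefixes) {
  prefixes <- norm_icd10(prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Charlson comorbidity score from ICD-10 claim codes
#'
#' Sums category weights over Charlson categories with at least one matching
#' claim, counting each category once and applying the standard hierarchy
#' rules (complicated diabetes supersedes uncomplicated; metastatic cancer
#' supersedes localized; severe liver disease supersedes mild).
#'
#' @param icd10 Character vector of ICD-10 codes observed in the scoring
#'   window (the caller restricts the window).
#' @param code_map Code map from [load_code_map()].
#' @return Non-negative integer score.
#' @export
charlson_score <- function(icd10, code_map = load_code_map()) {
  codes <- norm_icd10(icd10[!is.na(icd10)])
  present <- vapply(code_map$cci, function(entry) {
    any(icd_match(codes, entry$codes))
  }, logical(1))
  if (!is.null(code_map$hierarchy)) {
    hier <- code_map$hierarchy
    if (is.matrix(hier)) hier <- split(hier, row(hier))
    for (pair in hier) {
      pair <- unlist(pair)
      if (isTRUE(present[pair[1L]])) present[pair[2L]] <- FALSE
    }
  }
  wts <- vapply(code_map$cci, function(entry) as.numeric(entry$weight), numeric(1))
  as.integer(sum(wts[present]))
}

## categories with >= 1 matching code, before hierarchy (helper for flags)
cci_categories <- function(icd10, code_map) {
  codes <- norm_icd10(icd10[!is.na(icd10)])
  names(which(vapply(code_map$cci, function(entry)
    any(icd_match(codes, entry$codes)), logical(1))))
}

#' Cardiovascular-history and baseline-diabetes flags
#'
#' CV history is true when any of the four Charlson cardiovascular categories
#' (myocardial infarction, congestive heart failure, peripheral vascular
#' disease, cerebrovascular disease) appears in claims during the entire
#' pre-index period. Baseline diabetes is true when a Charlson diabetes
#' diagnosis appears pre-index, or an antidiabetic treatment claim occurs in
#' the `dm_rx_days` before index, or baseline HbA1c >= 6.5%.
#'
#' @param subject_claims Claims of one subject (`date`, `icd10`,
#'   `treatment_code`).
#' @param index_date Index date.
#' @param baseline_hba1c HbA1c (%) at index, possibly `NA`.
#' @param code_map Code map from [load_code_map()].
#' @param dm_rx_days Treatment lookback for the diabetes flag (default 90).
#' @return list(cv_history =, dm_baseline =)
#' @export
flag_subcohorts <- function(subject_claims, index_date, baseline_hba1c,
                            code_map = load_code_map(), dm_rx_days = 90) {
  pre <- subject_claims[subject_claims$date <= index_date, , drop = FALSE]
  cats <- cci_categories(pre$icd10, code_map)
  cv_cats <- code_map$cv_history_categories %||%
    c("mi", "chf", "pvd", "cevd")
  cv_history <- any(cats %in% cv_cats)
  dm_dx <- any(cats %in% c("diabetes_uncomplicated", "diabetes_complicated"))
  rx_window <- pre[as.numeric(index_date - pre$date) <= dm_rx_days, , drop = FALSE]
  dm_rx <- any(rx_window$treatment_code %in%
                 (code_map$treatments$antidiabetic %||%
                    c("SGLT2i", "GLP", "other_antidiabetic", "insulin")),
               na.rm = TRUE)
  dm_lab <- !is.na(baseline_hba1c) && baseline_hba1c >= 6.5
  list(cv_history = cv_history, dm_baseline = dm_dx || dm_rx || dm_lab)
}

#' Eligibility configuration defaults
#'
#' Day-count constants of the cohort definition: 2-year pair window
#' (730 days), 38 months (1156 days at 30.43 days/month), 1-year lookback,
#' 2-year minimum follow-up, Charlson lookback (1 year), malignancy window
#' (2 years) and diabetes-treatment window (90 days).
#'
#' @param ... Overrides of individual constants.
#' @return Named list of constants.
#' @export
eligibility_config <- function(...) {
  cfg <- list(pair_window_days = 730, post_egfr_days = 1156,
              lookback_days = 365, followup_days = 730,
              cci_lookback_days = 365, malignancy_window_days = 730,
              dm_rx_days = 90)
  utils::modifyList(cfg, list(...))
}

## per-subject eGFR series from checkups + enrollment demographics
egfr_series <- function(subject_checkups, birth_year, sex) {
  cu <- subject_checkups[!is.na(subject_checkups$scr), , drop = FALSE]
  cu <- cu[order(cu$date), , drop = FALSE]
  age <- as.integer(format(cu$date, "%Y")) - birth_year
  data.frame(date = cu$date, age = age,
             egfr = if (nrow(cu)) compute_egfr(cu$scr, age, rep(sex, nrow(cu))) else numeric(0))
}

PROTEINURIA_POSITIVE <- c("1+", "2+", "3+")

#' Build the eligible analysis cohort
#'
#' Applies the index-date rule and the full inclusion/exclusion battery to
#' raw checkup, claims and enrollment tables, returning one row per eligible
#' subject with baseline covariates, sub-cohort flags and follow-up window,
#' plus a tally of exclusions in a fixed precedence order (each subject is
#' counted under the first criterion it fails).
#'
#' Inclusion: a consecutive eGFR pair >= 60 then < 60 within the pair window;
#' age >= 18 at index; >= 1 year pre-index enrollment; >= 2 years follow-up
#' unless deceased; non-missing Hb and dipstick proteinuria at index.
#' Exclusion: first available eGFR already < 60; prior chronic dialysis or
#' kidney transplantation; eGFR < 6 at or before index; no eGFR within 38
#' months after index.
#'
#' @param checkups Checkup table (`subject_id`, `date`, `scr`, `hb`, `hct`,
#'   `bmi`, `hba1c`, `sbp`, `proteinuria`, `smoker`).
#' @param claims Claim table (`subject_id`, `date`, `icd10`, `record_type`,
#'   `treatment_code`).
#' @param enrollment Enrollment table (`subject_id`, `sex`, `birth_year`,
#'   `enroll_start`, `enroll_end`, `death`, `death_date`).
#' @param study_end Administrative end of follow-up (`Date`).
#' @param criteria Anemia criteria, see [anemia_criteria()].
#' @param code_map Code map, see [load_code_map()].
#' @param config Day-count constants, see [eligibility_config()].
#' @return list(cohort = data.frame of CohortEntry rows, tally = named
#'   integer vector of exclusion counts, n_input = candidate subject count).
#' @export
build_cohort <- function(checkups, claims, enrollment,
                         study_end = as.Date("2019-06-30"),
                         criteria = anemia_criteria(),
                         code_map = load_code_map(),
                         config = eligibility_config()) {
  checkups$date <- as.Date(checkups$date)
  claims$date <- as.Date(claims$date)
  enrollment$enroll_start <- as.Date(enrollment$enroll_start)
  enrollment$enroll_end <- as.Date(enrollment$enroll_end)
  enrollment$death_date <- as.Date(enrollment$death_date)

  reasons <- c("lt_2_measurements", "all_egfr_ge_60", "no_qualifying_pair",
               "first_egfr_below_60", "age_lt_18", "lookback_lt_1y",
               "followup_lt_2y", "missing_hb_at_index",
               "missing_proteinuria_at_index", "prior_dialysis",
               "prior_transplant", "egfr_lt_6_at_index",
               "no_post_index_egfr_38mo")
  tally <- stats::setNames(integer(length(reasons)), reasons)

  ids <- unique(checkups$subject_id)
  cu_by <- split(checkups, checkups$subject_id)
  cl_by <- split(claims, claims$subject_id)
  en <- enrollment[match(ids, enrollment$subject_id), , drop = FALSE]
  if (anyNA(en$subject_id)) stopf("missing enrollment record for a candidate")

  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    cu <- cu_by[[as.character(id)]]
    enr <- en[j, ]
    ser <- egfr_series(cu, enr$birth_year, enr$sex)
    fail <- function(reason) tally[reason] <<- tally[reason] + 1L

    if (nrow(ser) < 2L) { fail("lt_2_measurements"); next }
    if (all(ser$egfr >= 60)) { fail("all_egfr_ge_60"); next }
    idx <- identify_index(ser$date, ser$egfr, config$pair_window_days)
    if (is.null(idx)) { fail("no_qualifying_pair"); next }
    if (ser$egfr[1L] < 60) { fail("first_egfr_below_60"); next }

    index_date <- idx$index_date
    age_at_index <- as.integer(format(index_date, "%Y")) - enr$birth_year
    if (age_at_index < 18) { fail("age_lt_18"); next }
    if (as.numeric(index_date - enr$enroll_start) < config$lookback_days) {
      fail("lookback_lt_1y"); next
    }
    fu_end <- min(enr$enroll_end, study_end)
    deceased <- isTRUE(enr$death) && !is.na(enr$death_date) &&
      enr$death_date <= fu_end
    if (!deceased &&
        as.numeric(fu_end - index_date) < config$followup_days) {
      fail("followup_lt_2y"); next
    }
    index_row <- cu[cu$date == index_date, , drop = FALSE][1L, ]
    if (is.na(index_row$hb)) { fail("missing_hb_at_index"); next }
    if (is.na(index_row$proteinuria)) { fail("missing_proteinuria_at_index"); next }

    cl <- cl_by[[as.character(id)]] %||% claims[0, , drop = FALSE]
    pre_cl <- cl[cl$date <= index_date, , drop = FALSE]
    if (any(pre_cl$treatment_code %in% (code_map$treatments$dialysis %||% "chronic_dialysis"),
            na.rm = TRUE)) { fail("prior_dialysis"); next }
    if (any(pre_cl$treatment_code %in% (code_map$treatments$transplant %||% "kidney_transplant"),
            na.rm = TRUE)) { fail("prior_transplant"); next }
    if (any(ser$egfr[ser$date <= index_date] < 6)) { fail("egfr_lt_6_at_index"); next }
    post <- ser[ser$date > index_date, , drop = FALSE]
    if (!any(as.numeric(post$date - index_date) <= config$post_egfr_days)) {
      fail("no_post_index_egfr_38mo"); next
    }

    sex <- match_sex(enr$sex)
    cci_codes <- pre_cl$icd10[as.numeric(index_date - pre_cl$date) <= config$cci_lookback_days]
    flags <- flag_subcohorts(cl, index_date, index_row$hba1c, code_map,
                             config$dm_rx_days)
    rows[[j]] <- data.frame(
      subject_id = id,
      index_date = index_date,
      pre_index_egfr = idx$pre_index_egfr,
      index_egfr = idx$index_egfr,
      index_scr = index_row$scr,
      baseline_hb = index_row$hb,
      baseline_anemia = classify_anemia(index_row$hb, age_at_index, sex, criteria),
      proteinuria = index_row$proteinuria %in% PROTEINURIA_POSITIVE,
      baseline_hba1c = index_row$hba1c,
      baseline_sbp = index_row$sbp,
      baseline_bmi = index_row$bmi,
      smoker = index_row$smoker,
      age_at_index = age_at_index,
      sex = sex,
      cci_score = charlson_score(cci_codes, code_map),
      cv_history = flags$cv_history,
      dm_baseline = flags$dm_baseline,
      follow_up_end = fu_end,
      death_date = if (deceased) enr$death_date else as.Date(NA),
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cohort)) cohort <- data.frame()
  stopifnot(nrow(cohort) + sum(tally) == length(ids))
  list(cohort = cohort, tally = tally, n_input = length(ids))
}
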