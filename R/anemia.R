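#' Age-sex specific anemia criteria
#'
#' Loads the hemoglobin cutoff table (g/dL) keyed by sex and age band
#' (< 60, 60-69, >= 70 years). The shipped default follows the 2015 Japanese
#' Society for Dialysis Therapy renal-anemia guideline: males 13.5 / 12.0 /
#' 11.0 and females 11.5 / 10.5 / 10.5. Anemia is hemoglobin strictly below
#' the cutoff.
#'
#' @param path Path to a criteria JSON; `NULL` loads the packaged default.
#' @return List with `male` and `female` cutoff vectors
#'   (`lt60`, `60to69`, `ge70`).
#' @export
anemia_criteria <- function(path = NULL) {
  path <- path %||% system.file("extdata", "anemia_criteria.json",
                                package = "anemiaMSM")
  crit <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (s in c("male", "female")) {
    cut <- unlist(crit[[s]][c("lt60", "60to69", "ge70")])
    if (length(cut) != 3L || any(cut <= 0))
      stopf("malformed anemia criteria for %s", s)
  }
  crit[c("male", "female")]
}

anemia_cutoff <- function(age, sex, criteria = anemia_criteria()) {
  sex <- match_sex(sex)
  band <- ifelse(age < 60, "lt60", ifelse(age < 70, "60to69", "ge70"))
  mapply(function(s, b) criteria[[s]][[b]], sex, band, USE.NAMES = FALSE)
}

#' Classify anemia from hemoglobin, age and sex
#'
#' @param hb Hemoglobin in g/dL (must be present).
#' @param age Age in years (>= 18).
#' @param sex `"male"` or `"female"`.
#' @param criteria Cutoff table from [anemia_criteria()].
#' @return Logical: `TRUE` iff `hb` is strictly below the age-sex cutoff.
#' @examples
#' classify_anemia(13.4, 59, "male")  # TRUE  (cutoff 13.5)
#' classify_anemia(13.4, 60, "male")  # FALSE (cutoff 12.0)
#' @export
classify_anemia <- function(hb, age, sex, criteria = anemia_criteria()) {
  if (any(is.na(hb))) stopf("hb must be present to classify anemia")
  if (any(age < 18)) stopf("age must be >= 18")
  hb < anemia_cutoff(age, sex, criteria)
}

#' Per-checkup anemia exposure sequence
#'
#' Builds the exposure panel A_0..A_K of one subject: anemia status at the
#' index checkup and at every subsequent checkup with a non-missing
#' hemoglobin, ordered by date. Age is updated at each checkup, so a subject
#' can change status purely by crossing an age band. Missing hemoglobin
#' yields `NA` exposure; the weight module's imputation policy (last
#' observation carried forward) resolves these downstream.
#'
#' @param subject_checkups Checkups of one subject from the index date on
#'   (`date`, `hb` columns).
#' @param index_date Index date; checkups before it are dropped.
#' @param birth_year Birth year used to update age at each checkup.
#' @param sex `"male"` or `"female"`.
#' @param criteria Cutoff table from [anemia_criteria()].
#' @return data.frame(k, date, days, age, hb, anemia) with one row per
#'   checkup, `k` starting at 0.
#' @export
build_exposure_panel <- function(subject_checkups, index_date, birth_year, sex,
                                 criteria = anemia_criteria()) {
  cu <- subject_checkups[subject_checkups$date >= index_date, , drop = FALSE]
  cu <- cu[order(cu$date), , drop = FALSE]
  if (nrow(cu) == 0L || cu$date[1L] != index_date)
    stopf("index checkup missing from panel input")
  age <- as.integer(format(cu$date, "%Y")) - birth_year
  anemia <- ifelse(is.na(cu$hb), NA,
                   cu$hb < anemia_cutoff(age, rep(sex, nrow(cu)), criteria))
  if (is.na(anemia[1L])) stopf("baseline Hb missing: A_0 undefined")
  data.frame(k = seq_len(nrow(cu)) - 1L, date = cu$date,
             days = as.numeric(cu$date - index_date),
             age = age, hb = cu$hb, anemia = anemia)
}

#' Baseline prevalence as a percentage
#'
#' Recomputes a reported prevalence from its numerator and denominator.
#'
#' @param n_cases Numerator count.
#' @param n_total Denominator count (> 0).
#' @param digits Rounding digits (default 1, as in reported tables).
#' @return Percentage.
#' @export
prevalence_pct <- function(n_cases, n_total, digits = 1) {
  if (n_total <= 0) stopf("n_total must be positive")
  round(100 * n_cases / n_total, digits)
}
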