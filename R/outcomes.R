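#' Composite renal endpoint for one subject
#'
#' The composite renal outcome fires at the earliest of: (1) a post-index
#' eGFR <= 70% of the index eGFR measured within 3 years of index (>= 30%
#' reduction), (2) serum creatinine >= twice the index value, (3) first
#' chronic-dialysis claim, (4) first kidney-transplant claim, (5) any
#' post-index eGFR < 15 mL/min/1.73 m^2. Subjects with no component event
#' are censored at follow-up end (or death).
#'
#' @param entry One cohort row (needs `index_date`, `index_egfr`,
#'   `index_scr`, `follow_up_end`, `death_date`, `sex`) — see
#'   [build_cohort()].
#' @param series Post-index dated eGFR/SCr measurements
#'   (`date`, `egfr`, `scr`).
#' @param subject_claims Claims of the subject (`date`, `treatment_code`).
#' @param code_map Code map, see [load_code_map()].
#' @param pct_window_days Window for the 30%-reduction component
#'   (default 3 years = 1096 days).
#' @return data.frame(subject_id, outcome = "renal", event, time_days,
#'   component).
#' @export
derive_renal_outcome <- function(entry, series, subject_claims,
                                 code_map = load_code_map(),
                                 pct_window_days = 1096) {
  post <- series[series$date > entry$index_date, , drop = FALSE]
  if (nrow(post) == 0L) stopf("no post-index measurements for subject %s",
                              entry$subject_id)
  end_day <- follow_up_days(entry)
  days <- as.numeric(post$date - entry$index_date)
  keep <- days <= end_day
  post <- post[keep, , drop = FALSE]; days <- days[keep]

  comp <- c(
    egfr_decline_30pct = first_day(days[post$egfr <= 0.70 * entry$index_egfr &
                                          days <= pct_window_days]),
    scr_doubling = first_day(days[post$scr >= 2 * entry$index_scr]),
    dialysis = first_claim_day(subject_claims, entry,
                               code_map$treatments$dialysis %||% "chronic_dialysis",
                               end_day),
    transplant = first_claim_day(subject_claims, entry,
                                 code_map$treatments$transplant %||% "kidney_transplant",
                                 end_day),
    egfr_lt_15 = first_day(days[post$egfr < 15])
  )
  event_record(entry$subject_id, "renal", comp, end_day)
}

#' Composite cardiovascular endpoint for one subject
#'
#' Fires at the first post-index claim matching any of the four CV event
#' categories (unstable angina, myocardial infarction, heart failure,
#' cerebrovascular event). A death within `fatal_window_days` of a
#' qualifying claim is part of the same (fatal) episode; the event time is
#' the claim date either way.
#'
#' @inheritParams derive_renal_outcome
#' @param fatal_window_days Days after a qualifying claim within which a
#'   death counts as a fatal CV event (default 30).
#' @return data.frame(subject_id, outcome = "cv", event, time_days,
#'   component); `component` carries a `fatal_` prefix for fatal episodes.
#' @export
derive_cv_outcome <- function(entry, subject_claims,
                              code_map = load_code_map(),
                              fatal_window_days = 30) {
  if (is.null(code_map$cv_events)) stopf("code map lacks cv_events lists")
  end_day <- follow_up_days(entry)
  cl <- subject_claims[subject_claims$date > entry$index_date, , drop = FALSE]
  cl_days <- as.numeric(cl$date - entry$index_date)
  cl <- cl[cl_days <= end_day, , drop = FALSE]
  cl_days <- cl_days[cl_days <= end_day]
  codes <- norm_icd10(cl$icd10)
  comp <- vapply(code_map$cv_events, function(prefixes)
    first_day(cl_days[icd_match(codes, prefixes)]), numeric(1))
  rec <- event_record(entry$subject_id, "cv", comp, end_day)
  if (rec$event == 1L && !is.na(entry$death_date)) {
    death_day <- as.numeric(entry$death_date - entry$index_date)
    if (death_day - rec$time_days <= fatal_window_days)
      rec$component <- paste0("fatal_", rec$component)
  }
  rec
}

#' All-cause death endpoint for one subject
#'
#' @inheritParams derive_renal_outcome
#' @return data.frame(subject_id, outcome = "death", event, time_days,
#'   component).
#' @export
derive_death_outcome <- function(entry) {
  end_day <- follow_up_days(entry)
  if (!is.na(entry$death_date)) {
    data.frame(subject_id = entry$subject_id, outcome = "death", event = 1L,
               time_days = as.numeric(entry$death_date - entry$index_date),
               component = "death", stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = entry$subject_id, outcome = "death", event = 0L,
               time_days = end_day, component = NA_character_,
               stringsAsFactors = FALSE)
  }
}

## follow-up length in days from index; death truncates follow-up
follow_up_days <- function(entry) {
  end <- as.numeric(entry$follow_up_end - entry$index_date)
  if (!is.na(entry$death_date))
    end <- min(end, as.numeric(entry$death_date - entry$index_date))
  end
}

first_day <- function(days) if (length(days)) min(days) else Inf

first_claim_day <- function(subject_claims, entry, codes, end_day) {
  cl <- subject_claims[subject_claims$date > entry$index_date &
                         subject_claims$treatment_code %in% codes, , drop = FALSE]
  d <- as.numeric(cl$date - entry$index_date)
  first_day(d[d <= end_day])
}

## composite = earliest component; censored at end_day when none fires
event_record <- function(subject_id, outcome, component_days, end_day) {
  t <- min(component_days)
  if (is.finite(t)) {
    data.frame(subject_id = subject_id, outcome = outcome, event = 1L,
               time_days = t,
               component = names(component_days)[which.min(component_days)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = subject_id, outcome = outcome, event = 0L,
               time_days = end_day, component = NA_character_,
               stringsAsFactors = FALSE)
  }
}

#' Per-subject eGFR slope by simple linear regression
#'
#' Ordinary least-squares slope of eGFR on time in years. The stage-3
#' restricted sensitivity variant (subjects whose first two post-index eGFRs
#' are < 60) is a cohort filter applied by the caller, not a different
#' estimator.
#'
#' @param days Measurement times in days (from any common origin).
#' @param egfr eGFR values.
#' @return Slope in mL/min/1.73 m^2 per year.
#' @export
egfr_slope <- function(days, egfr) {
  ok <- !is.na(days) & !is.na(egfr)
  days <- days[ok]; egfr <- egfr[ok]
  if (length(days) < 2L) stopf("need >= 2 measurements for a slope")
  years <- days / DAYS_PER_YEAR
  if (max(years) == min(years)) stopf("zero time spread")
  unname(stats::coef(stats::lm(egfr ~ years))[2L])
}

#' Translate an eGFR slope difference into a percent hazard change
#'
#' Uses a reference mapping from treatment effects on the total eGFR slope to
#' hazard reductions for the clinical endpoint (default: a 0.75
#' mL/min/1.73 m^2/year slope benefit corresponds to a 27% lower hazard),
#' extended by proportional log-hazard scaling:
#' `percent = 100 * ((1/(1-ref_reduction))^(-delta/ref_slope) - 1)`.
#' A negative slope difference (faster decline) gives a positive percent
#' (higher hazard).
#'
#' @param delta_slope Slope difference in mL/min/1.73 m^2 per year.
#' @param ref_slope Reference slope benefit (default 0.75).
#' @param ref_reduction Hazard reduction at the reference slope (default 0.27).
#' @return Percent change in hazard.
#' @examples
#' round(slope_to_hazard(-0.7))   # 34
#' slope_to_hazard(-0.75)         # 36.99 (= 100 * (1/0.73 - 1))
#' @export
slope_to_hazard <- function(delta_slope, ref_slope = 0.75, ref_reduction = 0.27) {
  hr <- (1 / (1 - ref_reduction))^(-delta_slope / ref_slope)
  100 * (hr - 1)
}
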