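#' Assemble the person-period table for one outcome
#'
#' Turns the eligible cohort plus raw checkups/claims into the analysis unit
#' of the weight models: one row per subject per annual checkup interval,
#' from the index checkup to the subject's event or censoring time for the
#' given outcome. Exposure is the anemia classification at the checkup
#' opening the period; exposure history at period 0 is defined to be 0.
#' Covariates carried per period: eGFR, hemoglobin, HbA1c, dipstick
#' proteinuria (binary), smoking, anemia treatment (any anemia-treatment
#' claim in the `tx_window_days` ending at the checkup), with one-period
#' lags (period 0 lags take pre-index values where defined, otherwise 0),
#' plus baseline age, sex and Charlson score on every row.
#'
#' Missing hemoglobin and covariates are resolved by [simple_impute()] (last
#' observation carried forward, cohort median/mode fallback) before anemia
#' is classified, when `impute = TRUE`.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param checkups Raw checkup table.
#' @param claims Raw claim table.
#' @param outcome_table Event table for one outcome (`subject_id`, `event`,
#'   `time_days`).
#' @param criteria Anemia criteria, see [anemia_criteria()].
#' @param code_map Code map, see [load_code_map()].
#' @param tx_window_days Treatment lookback per checkup (default 90).
#' @param impute Impute missing covariates before classification.
#' @return Person-period data.frame ready for [fit_time_varying_ipw()].
#' @export
assemble_person_periods <- function(cohort, checkups, claims, outcome_table,
                                    criteria = anemia_criteria(),
                                    code_map = load_code_map(),
                                    tx_window_days = 90, impute = TRUE) {
  checkups$date <- as.Date(checkups$date)
  claims$date <- as.Date(claims$date)
  anemia_tx_codes <- code_map$treatments$anemia %||%
    c("ESA", "oral_iron", "IV_iron", "RBC_transfusion")
  cu_by <- split(checkups, checkups$subject_id)
  cl_by <- split(claims, claims$subject_id)
  ev <- outcome_table[match(cohort$subject_id, outcome_table$subject_id), ]

  rows <- vector("list", nrow(cohort))
  for (j in seq_len(nrow(cohort))) {
    entry <- cohort[j, ]
    cu <- cu_by[[as.character(entry$subject_id)]]
    cu <- cu[cu$date >= entry$index_date & !is.na(cu$scr), , drop = FALSE]
    cu <- cu[order(cu$date), , drop = FALSE]
    t_end <- ev$time_days[j]
    days <- as.numeric(cu$date - entry$index_date)
    keep <- days < t_end
    cu <- cu[keep, , drop = FALSE]; days <- days[keep]
    if (nrow(cu) == 0L) next
    np <- nrow(cu)
    age <- entry$age_at_index + floor(days / DAYS_PER_YEAR)
    egfr <- compute_egfr(cu$scr, age, rep(entry$sex, np))
    cl <- cl_by[[as.character(entry$subject_id)]]
    tx_dates <- if (is.null(cl)) as.Date(character(0)) else
      cl$date[cl$treatment_code %in% anemia_tx_codes]
    tx <- vapply(cu$date, function(d) {
      as.integer(any(tx_dates <= d & as.numeric(d - tx_dates) <= tx_window_days))
    }, integer(1))
    rows[[j]] <- data.frame(
      subject_id = entry$subject_id, k = seq_len(np) - 1L,
      start_day = days, end_day = c(days[-1L], t_end),
      hb = cu$hb, egfr = egfr,
      egfr_lag = c(entry$pre_index_egfr, egfr[-np]),
      hba1c = cu$hba1c,
      proteinuria = as.integer(cu$proteinuria %in% PROTEINURIA_POSITIVE),
      smoker = as.integer(cu$smoker),
      tx = tx, tx_lag = c(0L, tx[-np]),
      age = age, sex = entry$sex, cci = entry$cci_score,
      event = c(rep(0L, np - 1L), as.integer(ev$event[j] == 1L)),
      stringsAsFactors = FALSE
    )
  }
  pp <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (impute) {
    pp <- simple_impute(pp,
                        time_varying = c("hb", "egfr", "hba1c", "proteinuria",
                                         "smoker"),
                        id = "subject_id", time = "k",
                        required = c("start_day", "end_day"))$data
  }
  pp$exposure <- as.integer(classify_anemia(pp$hb, pp$age, pp$sex, criteria))
  lag1 <- function(x) c(0L, x[-length(x)])
  ord <- order(pp$subject_id, pp$k)
  pp <- pp[ord, , drop = FALSE]
  pp$exposure_lag <- unlist(lapply(split(pp$exposure, pp$subject_id), lag1),
                            use.names = FALSE)
  rownames(pp) <- NULL
  pp
}

#' Derive all three outcome tables for a cohort
#'
#' Convenience wrapper running [derive_renal_outcome()],
#' [derive_cv_outcome()] and [derive_death_outcome()] for every cohort
#' subject.
#'
#' @inheritParams assemble_person_periods
#' @return data.frame(subject_id, outcome, event, time_days, component).
#' @export
derive_outcomes <- function(cohort, checkups, claims,
                            code_map = load_code_map()) {
  checkups$date <- as.Date(checkups$date)
  claims$date <- as.Date(claims$date)
  cu_by <- split(checkups, checkups$subject_id)
  cl_by <- split(claims, claims$subject_id)
  empty_claims <- claims[0, , drop = FALSE]
  out <- vector("list", nrow(cohort))
  for (j in seq_len(nrow(cohort))) {
    entry <- cohort[j, ]
    cu <- cu_by[[as.character(entry$subject_id)]]
    cu <- cu[!is.na(cu$scr), , drop = FALSE]
    cu <- cu[order(cu$date), , drop = FALSE]
    age <- entry$age_at_index +
      floor(as.numeric(cu$date - entry$index_date) / DAYS_PER_YEAR)
    age <- pmax(age, 18L)
    series <- data.frame(date = cu$date, scr = cu$scr,
                         egfr = compute_egfr(cu$scr, age,
                                             rep(entry$sex, nrow(cu))))
    cl <- cl_by[[as.character(entry$subject_id)]] %||% empty_claims
    out[[j]] <- rbind(
      derive_renal_outcome(entry, series, cl, code_map),
      derive_cv_outcome(entry, cl, code_map),
      derive_death_outcome(entry)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
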