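#' Configuration for the synthetic longitudinal cohort generator
#'
#' Assembles and validates the generator settings. Defaults describe the
#' study conditions the package is developed against: annual checkups, true
#' marginal hazard ratios equal to the published MSM point estimates
#' (renal 2.56, cardiovascular 1.63, death 2.76), a working anemia
#' prevalence of 15% at cohort entry, a mean annual eGFR drift of
#' -1.0 mL/min/1.73 m^2 with an extra -0.75 per anemic year, 10% annual
#' disenrollment and 5% missingness in non-key checkup fields. The methods
#' vignette discusses each choice.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param n_years Number of annual post-index checkups / follow-up years
#'   (>= 3, required by the 3-year renal endpoint).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param true_log_hr Named vector of causal log hazard ratios of anemia on
#'   the latent renal, cv and death processes.
#' @param confounding_strength Non-negative scale on the effect of prior
#'   eGFR/treatment on anemia and of prior anemia on treatment; 0 removes
#'   time-dependent confounding.
#' @param baseline_anemia_prob Anemia probability at index for a subject at
#'   the cohort-median eGFR.
#' @param egfr_drift list(mean =, anemia_accel =): mean annual eGFR change
#'   and its additional change per prior anemic year.
#' @param censoring_rate Annual disenrollment probability.
#' @param missingness_rate Probability a non-key checkup field is missing.
#' @param baseline_hazard Named annual event hazards of the latent processes
#'   for a never-anemic subject.
#' @param frailty list(egfr_sd =, rho =): scale of the latent susceptibility
#'   on the eGFR level, and its loading on each outcome's event-time uniform
#'   (mortality's loading is 0 by default so death-censoring of the
#'   confounded endpoints stays non-informative).
#' @return Validated config list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 1000L,
                       n_years = 6L,
                       seed = 1L,
                       true_log_hr = c(renal = log(2.56), cv = log(1.63),
                                       death = log(2.76)),
                       confounding_strength = 1,
                       baseline_anemia_prob = 0.15,
                       egfr_drift = list(mean = -1.0, anemia_accel = -0.75),
                       censoring_rate = 0.10,
                       missingness_rate = 0.05,
                       baseline_hazard = c(renal = 0.02, cv = 0.03,
                                           death = 0.008),
                       frailty = list(egfr_sd = 4, rho = c(renal = 0.85,
                                                           cv = 0.85,
                                                           death = 0))) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_years = as.integer(n_years),
              seed = as.integer(seed), true_log_hr = true_log_hr,
              confounding_strength = confounding_strength,
              baseline_anemia_prob = baseline_anemia_prob,
              egfr_drift = egfr_drift, censoring_rate = censoring_rate,
              missingness_rate = missingness_rate,
              baseline_hazard = baseline_hazard, frailty = frailty)
  if (cfg$n_subjects <= 0L) stopf("n_subjects must be positive")
  if (cfg$n_years < 3L) stopf("n_years must be >= 3 (3-year renal endpoint)")
  probs <- c(cfg$baseline_anemia_prob, cfg$censoring_rate, cfg$missingness_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$confounding_strength < 0) stopf("confounding_strength must be >= 0")
  for (o in c("renal", "cv", "death")) {
    if (is.na(cfg$true_log_hr[o])) stopf("true_log_hr lacks '%s'", o)
    if (is.na(cfg$baseline_hazard[o])) stopf("baseline_hazard lacks '%s'", o)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a linked checkup / claims / enrollment cohort
#'
#' Generates a longitudinal cohort emulating annual health-checkup records
#' linked to medical and pharmacy claims, with known causal structure:
#'
#' * A latent susceptibility `z` shifts the subject's eGFR level and loads on
#'   the renal and cardiovascular event-time uniforms, so observed eGFR is a
#'   genuine confounder of the anemia-outcome relation.
#' * Anemia at period k follows a logistic model on eGFR at k-1, anemia at
#'   k-1 and anemia treatment at k-1; treatment at k follows a logistic model
#'   on anemia at k-1. Prior exposure thus alters future confounders —
#'   textbook time-dependent confounding.
#' * Event times come from piecewise-constant hazards
#'   `h0 * exp(log_hr * A_k)` crossed against the subject's uniform
#'   threshold, so the *marginal* structural Cox model in current anemia
#'   status holds exactly with the configured log hazard ratio, while the
#'   covariate-adjusted ("naive") time-dependent Cox is biased.
#'
#' Hemoglobin is drawn on the correct side of the age-sex cutoff so that
#' re-classifying anemia from the emitted checkups reproduces the latent
#' exposure sequence exactly; serum creatinine is the exact inverse of the
#' eGFR equation.
#'
#' @param config A [sim_config()].
#' @return list of class `"sim_cohort"` with `checkups`, `claims`,
#'   `enrollment` (the observable tables), `truth` (hidden per-subject and
#'   per-period ground truth for test assertions) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  K <- config$n_years
  cs <- config$confounding_strength

  ## --- subjects -----------------------------------------------------------
  id <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.273, "female", "male")
  age0 <- pmin(pmax(round(stats::rnorm(n, 52, 8)), 21), 73)
  smoker <- stats::runif(n) < 0.205
  dm <- stats::runif(n) < 0.15
  z <- stats::rnorm(n)
  index_date <- as.Date("2010-01-01") + sample.int(1096L, n, replace = TRUE)
  birth_year <- as.integer(format(index_date, "%Y")) - age0

  egfr_base <- 57 - config$frailty$egfr_sd * z
  egfr_pre <- 60 + abs(stats::rnorm(n, 2.5, 2))
  egfr0 <- pmin(pmax(egfr_base + stats::rnorm(n, 0, 1), 20), 59.9)

  ## --- exposure / treatment / eGFR processes ------------------------------
  b_egfr <- 0.15   # per mL/min below 57, on the anemia logit (scaled by cs)
  b_prev <- 1.25   # persistence of anemia
  b_tx <- -1.0     # treatment resolves anemia (scaled by cs)
  tx_base <- 0.03
  tx_or <- 2.0     # prior anemia -> treatment logit shift (scaled by cs)

  ## Event thresholds first: for each outcome, u ~ Uniform(0,1) marginally
  ## and independent of the exposure regime, so P(T > t | regime) =
  ## exp(-cumulative hazard): the marginal structural Cox model holds
  ## exactly. High z -> u near 1 -> small threshold -> early event, making
  ## eGFR (a z proxy) a genuine confounder.
  outs <- c("renal", "cv", "death")
  ethr <- sapply(outs, function(o) {
    rho <- config$frailty$rho[[o]]
    -log(stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n)))
  })

  A <- matrix(0L, n, K); TX <- matrix(0L, n, K); EG <- matrix(0, n, K)
  latent <- matrix(Inf, n, 3, dimnames = list(NULL, outs))
  cum <- matrix(0, n, 3, dimnames = list(NULL, outs))
  EG[, 1] <- egfr0
  A[, 1] <- stats::rbinom(n, 1, invlogit(logit(config$baseline_anemia_prob) +
                                           cs * b_egfr * (57 - egfr0)))
  TX[, 1] <- stats::rbinom(n, 1, invlogit(logit(tx_base)))
  for (k in seq_len(K)) {
    ## events during period k-1..k under the current exposure A_k
    for (o in outs) {
      rate <- config$baseline_hazard[[o]] * exp(config$true_log_hr[[o]] * A[, k])
      cross <- !is.finite(latent[, o]) & ethr[, o] <= cum[, o] + rate
      latent[cross, o] <- (k - 1L) + (ethr[cross, o] - cum[cross, o]) / rate[cross]
      cum[, o] <- cum[, o] + rate
    }
    if (k == K) break
    ## next-period covariates and exposure; a latent renal event manifests
    ## as accelerated observable decline from the next checkup on
    cumA <- rowSums(A[, seq_len(k), drop = FALSE])
    eg_next <- egfr_base + config$egfr_drift$mean * k +
      config$egfr_drift$anemia_accel * cumA + stats::rnorm(n, 0, 1.5)
    det <- latent[, "renal"] <= k
    eg_det <- 0.65 * egfr0 - 2 * (k - latent[, "renal"]) + stats::rnorm(n, 0, 1)
    eg_next[det] <- pmin(eg_next, eg_det)[det]
    EG[, k + 1L] <- pmin(pmax(eg_next, 4), 120)
    A[, k + 1L] <- stats::rbinom(n, 1, invlogit(logit(config$baseline_anemia_prob) +
                                                  cs * b_egfr * (57 - EG[, k]) +
                                                  b_prev * A[, k] +
                                                  cs * b_tx * TX[, k]))
    TX[, k + 1L] <- stats::rbinom(n, 1, invlogit(logit(tx_base) + cs * tx_or * A[, k]))
  }

  ## --- censoring ----------------------------------------------------------
  g <- stats::rgeom(n, config$censoring_rate)            # complete years
  censor <- pmin(g + stats::runif(n), K)
  death <- pmin(latent[, "death"], Inf)
  exit <- pmin(censor, death, K)                         # end of observation
  died <- death <= pmin(censor, K)

  obs_time <- function(o) {
    t_end <- if (o == "death") pmin(censor, K) else exit
    t <- pmin(latent[, o], t_end)
    list(time = t, event = as.integer(latent[, o] <= t_end))
  }
  obs <- lapply(stats::setNames(nm = c("renal", "cv", "death")), obs_time)

  truth_subjects <- data.frame(
    subject_id = id, sex = sex, age_at_index = age0, birth_year = birth_year,
    index_date = index_date, z = z, egfr_pre = egfr_pre, egfr_index = egfr0,
    smoker = smoker, dm = dm,
    latent_renal_years = latent[, "renal"], latent_cv_years = latent[, "cv"],
    latent_death_years = latent[, "death"], censor_years = censor,
    exit_years = exit, died = died,
    renal_time_years = obs$renal$time, renal_event = obs$renal$event,
    cv_time_years = obs$cv$time, cv_event = obs$cv$event,
    death_time_years = obs$death$time, death_event = obs$death$event,
    stringsAsFactors = FALSE
  )

  ## --- truth person-period panel (periods while under observation) --------
  n_periods <- pmax(ceiling(exit - 1e-9), 1L)
  sub_idx <- rep(seq_len(n), n_periods)
  k_idx <- unlist(lapply(n_periods, seq_len)) - 1L       # 0-based period
  egfr_lag <- cbind(egfr_pre, EG[, -K, drop = FALSE])
  truth_panel <- data.frame(
    subject_id = id[sub_idx], k = k_idx,
    start_year = k_idx, end_year = pmin(k_idx + 1, exit[sub_idx]),
    anemia = A[cbind(sub_idx, k_idx + 1L)],
    anemia_lag = ifelse(k_idx == 0L, 0L, A[cbind(sub_idx, pmax(k_idx, 1L))]),
    tx = TX[cbind(sub_idx, k_idx + 1L)],
    tx_lag = ifelse(k_idx == 0L, 0L, TX[cbind(sub_idx, pmax(k_idx, 1L))]),
    egfr = EG[cbind(sub_idx, k_idx + 1L)],
    egfr_lag = egfr_lag[cbind(sub_idx, k_idx + 1L)],
    age = age0[sub_idx] + k_idx, sex = sex[sub_idx],
    stringsAsFactors = FALSE
  )

  ## --- observable checkup table -------------------------------------------
  crit <- anemia_criteria()
  has_cu <- k_idx <= floor(exit[sub_idx] - 1e-9) | k_idx == 0L
  cu_sub <- sub_idx[has_cu]; cu_k <- k_idx[has_cu]
  cu_sub <- c(cu_sub, seq_len(n)); cu_k <- c(cu_k, rep(-1L, n))  # pre-index
  ord <- order(cu_sub, cu_k)
  cu_sub <- cu_sub[ord]; cu_k <- cu_k[ord]
  m <- length(cu_sub)
  cu_age <- age0[cu_sub] + pmax(cu_k, 0L)
  cu_egfr <- ifelse(cu_k < 0L, egfr_pre[cu_sub], EG[cbind(cu_sub, pmax(cu_k, 0L) + 1L)])
  cu_anemia <- ifelse(cu_k < 0L, 0L, A[cbind(cu_sub, pmax(cu_k, 0L) + 1L)])
  cutoff <- anemia_cutoff(cu_age, sex[cu_sub], crit)
  hb <- ifelse(cu_anemia == 1L,
               pmax(cutoff - 0.3 - abs(stats::rnorm(m, 0.9, 0.6)), 5.7),
               pmin(cutoff + 0.3 + abs(stats::rnorm(m, 1.2, 0.9)), 18.5))
  prot_p <- invlogit(logit(0.06) + 0.4 * z[cu_sub])
  prot_pos <- stats::runif(m) < prot_p
  prot <- ifelse(prot_pos,
                 sample(c("1+", "2+", "3+"), m, TRUE, c(0.7, 0.2, 0.1)),
                 sample(c("-", "+-"), m, TRUE, c(0.9, 0.1)))
  hba1c_base <- stats::rnorm(n, 5.6, 0.45) + ifelse(dm, 1.3, 0)
  checkups <- data.frame(
    subject_id = id[cu_sub],
    date = index_date[cu_sub] + round(cu_k * DAYS_PER_YEAR),
    scr = round(egfr_to_scr(cu_egfr, cu_age, sex[cu_sub]), 3),
    hb = round(hb, 1),
    hct = round(3 * hb + stats::rnorm(m, 0, 1), 1),
    bmi = round(stats::rnorm(n, 23.9, 3.7)[cu_sub] + stats::rnorm(m, 0, 0.4), 1),
    hba1c = round(hba1c_base[cu_sub] + stats::rnorm(m, 0, 0.15), 1),
    sbp = round(stats::rnorm(m, 125, 15)),
    proteinuria = prot,
    smoker = smoker[cu_sub],
    stringsAsFactors = FALSE
  )

  ## --- claims --------------------------------------------------------------
  claims <- list()
  ## anemia treatment (pharmacy) two weeks after a treated checkup
  tx_rows <- which(cu_k >= 0L & TX[cbind(cu_sub, pmax(cu_k, 0L) + 1L)] == 1L)
  if (length(tx_rows)) {
    claims$tx <- data.frame(
      subject_id = id[cu_sub[tx_rows]],
      date = index_date[cu_sub[tx_rows]] + round(cu_k[tx_rows] * DAYS_PER_YEAR) + 14,
      icd10 = "D50.1", record_type = "pharmacy",
      treatment_code = sample(c("oral_iron", "IV_iron", "RBC_transfusion", "ESA"),
                              length(tx_rows), TRUE, c(0.86, 0.08, 0.04, 0.02)),
      stringsAsFactors = FALSE)
  }
  ## antidiabetic prescriptions from one year pre-index, twice yearly
  dm_ids <- which(dm)
  if (length(dm_ids)) {
    reps <- lapply(dm_ids, function(i) {
      offs <- seq(-360, round(exit[i] * DAYS_PER_YEAR), by = 180)
      data.frame(subject_id = id[i], date = index_date[i] + offs,
                 icd10 = "E11.9", record_type = "pharmacy",
                 treatment_code = "other_antidiabetic", stringsAsFactors = FALSE)
    })
    claims$dm <- do.call(rbind, reps)
  }
  ## pre-index comorbidity claims (drive the Charlson score / CV history)
  com_p <- invlogit(-2.6 + 0.45 * z)
  com_ids <- which(stats::runif(n) < com_p)
  if (length(com_ids)) {
    claims$comorb <- data.frame(
      subject_id = id[com_ids],
      date = index_date[com_ids] - sample.int(330L, length(com_ids), TRUE),
      icd10 = sample(c("I21.0", "I50.0", "I63.9", "J44.9", "K74.6", "E11.9"),
                     length(com_ids), TRUE,
                     c(0.15, 0.2, 0.15, 0.2, 0.1, 0.2)),
      record_type = "outpatient", treatment_code = NA_character_,
      stringsAsFactors = FALSE)
  }
  ## cardiovascular event claims at the latent CV event time
  cv_ids <- which(obs$cv$event == 1L)
  if (length(cv_ids)) {
    claims$cv <- data.frame(
      subject_id = id[cv_ids],
      date = index_date[cv_ids] + round(obs$cv$time[cv_ids] * DAYS_PER_YEAR),
      icd10 = sample(c("I20.0", "I21.1", "I50.0", "I63.9"), length(cv_ids),
                     TRUE, c(0.1, 0.3, 0.35, 0.25)),
      record_type = "inpatient", treatment_code = NA_character_,
      stringsAsFactors = FALSE)
  }
  ## chronic dialysis once observed renal function is end-stage
  dial_rows <- which(cu_k >= 0L & cu_egfr < 10)
  if (length(dial_rows)) {
    claims$dialysis <- data.frame(
      subject_id = id[cu_sub[dial_rows]],
      date = index_date[cu_sub[dial_rows]] +
        round(cu_k[dial_rows] * DAYS_PER_YEAR) + 30,
      icd10 = "N18.6", record_type = "inpatient",
      treatment_code = "chronic_dialysis", stringsAsFactors = FALSE)
  }
  claims <- do.call(rbind, claims)
  if (is.null(claims)) {
    claims <- data.frame(subject_id = character(0), date = as.Date(character(0)),
                         icd10 = character(0), record_type = character(0),
                         treatment_code = character(0), stringsAsFactors = FALSE)
  }
  claims <- claims[order(claims$subject_id, claims$date), , drop = FALSE]
  rownames(claims) <- NULL

  ## --- enrollment ----------------------------------------------------------
  enroll_start <- index_date - 730L - sample.int(365L, n, replace = TRUE)
  end_day <- index_date + round(exit * DAYS_PER_YEAR)
  enrollment <- data.frame(
    subject_id = id, sex = sex, birth_year = birth_year,
    enroll_start = enroll_start, enroll_end = end_day,
    death = died, death_date = as.Date(ifelse(died, end_day, NA), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  if (config$missingness_rate > 0) {
    protect <- data.frame(subject_id = id, date = index_date)
    checkups <- inject_missingness(checkups, config$missingness_rate,
                                   seed = config$seed + 1L, protect = protect)
  }

  structure(list(checkups = checkups, claims = claims, enrollment = enrollment,
                 truth = list(subjects = truth_subjects, panel = truth_panel),
                 config = config),
            class = "sim_cohort")
}

#' Set checkup fields missing completely at random
#'
#' Sets the stated fraction of the non-key fields (hemoglobin, HbA1c, BMI,
#' smoking, SBP) to missing, completely at random. Serum creatinine and
#' proteinuria are never removed, nor is hemoglobin on protected
#' (subject, date) rows — eligibility requires Hb and proteinuria at index.
#'
#' @param checkups Checkup table.
#' @param rate Missingness probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param protect Optional data.frame(subject_id, date) of rows whose Hb is
#'   never removed (typically the index checkups).
#' @return Checkup table with injected missingness.
#' @export
inject_missingness <- function(checkups, rate, seed = 1L, protect = NULL) {
  if (rate < 0 || rate > 1) stopf("rate must lie in [0, 1]")
  if (rate == 0) return(checkups)
  set.seed(seed)
  out <- checkups
  fields <- c("hb", "hba1c", "bmi", "smoker", "sbp")
  keep_hb <- rep(FALSE, nrow(out))
  if (!is.null(protect)) {
    keep_hb <- paste(out$subject_id, out$date) %in%
      paste(protect$subject_id, as.Date(protect$date))
  }
  for (f in fields) {
    drop <- stats::runif(nrow(out)) < rate
    if (f == "hb") drop <- drop & !keep_hb
    out[[f]][drop] <- NA
  }
  out
}

#' Analysis-ready person-period panel from a simulated cohort
#'
#' Converts the generator's hidden truth panel into the person-period table
#' the weight and survival modules consume for one outcome: one row per
#' subject per annual period while at risk for that outcome, with interval
#' `[start_day, end_day)` in days from index, current and lagged exposure
#' and covariates, and the event indicator in the final period.
#'
#' @param sim A [simulate_cohort()] result.
#' @param outcome `"renal"`, `"cv"` or `"death"`.
#' @return Person-period data.frame.
#' @export
sim_person_periods <- function(sim, outcome = c("renal", "cv", "death")) {
  outcome <- match.arg(outcome)
  tt <- sim$truth$subjects
  pp <- sim$truth$panel
  t_end <- tt[[paste0(outcome, "_time_years")]]
  evt <- tt[[paste0(outcome, "_event")]]
  idx <- match(pp$subject_id, tt$subject_id)
  keep <- pp$start_year < t_end[idx]
  pp <- pp[keep, , drop = FALSE]; idx <- idx[keep]
  end_year <- pmin(pp$end_year, t_end[idx])
  last <- end_year >= t_end[idx] - 1e-12
  data.frame(
    subject_id = pp$subject_id, k = pp$k,
    start_day = round(pp$start_year * DAYS_PER_YEAR, 4),
    end_day = round(end_year * DAYS_PER_YEAR, 4),
    exposure = pp$anemia, exposure_lag = pp$anemia_lag,
    egfr = pp$egfr, egfr_lag = pp$egfr_lag,
    tx = pp$tx, tx_lag = pp$tx_lag,
    age = pp$age, sex = pp$sex,
    event = as.integer(last & evt[idx] == 1L),
    stringsAsFactors = FALSE
  )
}

#' Write simulated tables to CSV
#'
#' Writes `checkups.csv`, `claims.csv`, `enrollment.csv` and the hidden
#' ground truth (`truth_subjects.csv`, `truth_panel.csv`) as UTF-8 CSV with
#' ISO-8601 dates.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  wr(sim$checkups, "checkups.csv")
  wr(sim$claims, "claims.csv")
  wr(sim$enrollment, "enrollment.csv")
  wr(sim$truth$subjects, "truth_subjects.csv")
  wr(sim$truth$panel, "truth_panel.csv")
  invisible(dir)
}
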