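# Independent oracles used across tests. These deliberately re-derive the
# quantities from first principles rather than calling package internals.

## weighted Cox partial log-likelihood and score (Breslow ties), one covariate
oracle_cox_loglik <- function(b, start, stop, event, x, w) {
  dt <- sort(unique(stop[event == 1]))
  ll <- sum(w[event == 1] * x[event == 1] * b)
  for (s in dt) {
    at_risk <- start < s & stop >= s
    dsum <- sum(w[event == 1 & stop == s])
    ll <- ll - dsum * log(sum(w[at_risk] * exp(x[at_risk] * b)))
  }
  ll
}

oracle_cox_score <- function(b, start, stop, event, x, w) {
  dt <- sort(unique(stop[event == 1]))
  u <- sum(w[event == 1] * x[event == 1])
  for (s in dt) {
    at_risk <- start < s & stop >= s
    dsum <- sum(w[event == 1 & stop == s])
    ew <- w[at_risk] * exp(x[at_risk] * b)
    u <- u - dsum * sum(ew * x[at_risk]) / sum(ew)
  }
  u
}

## brute-force optimizer: root of the score equation
oracle_cox_fit <- function(start, stop, event, x, w, interval = c(-8, 8)) {
  stats::uniroot(oracle_cox_score, interval, start = start, stop = stop,
                 event = event, x = x, w = w, tol = 1e-13)$root
}

## Harrell's RCSPLINE macro formula, written out term by term
oracle_rcspline <- function(x, knots) {
  nk <- length(knots)
  tau <- (knots[nk] - knots[1])^2
  out <- matrix(NA_real_, length(x), nk - 2)
  for (j in 1:(nk - 2)) {
    xj <- numeric(length(x))
    for (i in seq_along(x)) {
      p1 <- max(x[i] - knots[j], 0)^3
      p2 <- max(x[i] - knots[nk - 1], 0)^3 *
        (knots[nk] - knots[j]) / (knots[nk] - knots[nk - 1])
      p3 <- max(x[i] - knots[nk], 0)^3 *
        (knots[nk - 1] - knots[j]) / (knots[nk] - knots[nk - 1])
      xj[i] <- (p1 - p2 + p3) / tau
    }
    out[, j] <- xj
  }
  out
}

## serum creatinine giving a target eGFR (inverts the Japanese equation)
scr_for_egfr <- function(egfr, age, female = FALSE) {
  (egfr / (194 * age^(-0.287) * if (female) 0.739 else 1))^(-1 / 1.094)
}

## hand product-limit estimator (unweighted)
oracle_km <- function(time, event, at) {
  dt <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in dt[dt <= at]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

## small synthetic survival fixture without ties
cox_fixture <- function(n = 16, seed = 42) {
  set.seed(seed)
  x <- rep(0:1, length.out = n)
  t_evt <- rexp(n, 0.1 * exp(0.8 * x))
  cens <- rexp(n, 0.05)
  data.frame(start = 0, stop = round(pmin(t_evt, cens), 6) +
               seq_len(n) * 1e-4,  # guarantee no ties
             event = as.integer(t_evt <= cens), x = x)
}

## ---- eligibility fixture battery ------------------------------------------
## One subject per inclusion/exclusion branch; dates chosen so that every
## branch is decided by exactly the intended rule.
eligibility_fixture <- function() {
  d <- function(x) as.Date(x)
  cu <- function(id, date, egfr, age, female = FALSE, hb = 14,
                 prot = "-", hba1c = 5.5) {
    data.frame(subject_id = id, date = d(date),
               scr = scr_for_egfr(egfr, age, female), hb = hb, hct = hb * 3,
               bmi = 23, hba1c = hba1c, sbp = 120, proteinuria = prot,
               smoker = FALSE, stringsAsFactors = FALSE)
  }
  en <- function(id, start = "2011-01-01", end = "2019-06-30",
                 death = FALSE, death_date = NA, birth_year = 1963) {
    data.frame(subject_id = id, sex = "male", birth_year = birth_year,
               enroll_start = d(start), enroll_end = d(end), death = death,
               death_date = d(death_date), stringsAsFactors = FALSE)
  }
  ## ages: born 1963 -> age 50 at the 2013 index
  checkups <- rbind(
    cu("ok", "2012-06-01", 65, 49), cu("ok", "2013-06-01", 58, 50),
    cu("ok", "2014-06-01", 57, 51),
    cu("death1y", "2012-06-01", 65, 49), cu("death1y", "2013-06-01", 58, 50),
    cu("death1y", "2013-12-01", 56, 50),
    cu("first_lt60", "2011-06-01", 55, 48), cu("first_lt60", "2012-06-01", 65, 49),
    cu("first_lt60", "2013-06-01", 58, 50), cu("first_lt60", "2014-06-01", 57, 51),
    cu("gap39", "2012-06-01", 65, 49), cu("gap39", "2013-06-01", 58, 50),
    cu("gap39", "2016-09-20", 50, 53),
    cu("lt2", "2013-06-01", 58, 50),
    cu("all_ge60", "2012-06-01", 65, 49), cu("all_ge60", "2013-06-01", 64, 50),
    cu("pair_gap", "2010-06-01", 65, 47), cu("pair_gap", "2013-06-01", 58, 50),
    cu("age17", "2012-06-01", 65, 18), cu("age17", "2013-06-01", 58, 18),
    cu("age17", "2014-06-01", 57, 19),
    cu("lookback", "2013-04-01", 65, 50), cu("lookback", "2013-06-01", 58, 50),
    cu("lookback", "2014-06-01", 57, 51),
    cu("fup", "2012-06-01", 65, 49), cu("fup", "2013-06-01", 58, 50),
    cu("fup", "2013-12-01", 57, 50),
    cu("no_hb", "2012-06-01", 65, 49), cu("no_hb", "2013-06-01", 58, 50, hb = NA),
    cu("no_hb", "2014-06-01", 57, 51),
    cu("no_prot", "2012-06-01", 65, 49),
    cu("no_prot", "2013-06-01", 58, 50, prot = NA),
    cu("no_prot", "2014-06-01", 57, 51),
    cu("dial", "2012-06-01", 65, 49), cu("dial", "2013-06-01", 58, 50),
    cu("dial", "2014-06-01", 57, 51),
    cu("transpl", "2012-06-01", 65, 49), cu("transpl", "2013-06-01", 58, 50),
    cu("transpl", "2014-06-01", 57, 51),
    cu("egfr5", "2012-06-01", 65, 49), cu("egfr5", "2013-06-01", 5, 50),
    cu("egfr5", "2014-06-01", 5, 51)
  )
  enrollment <- rbind(
    en("ok"), en("death1y", death = TRUE, death_date = "2014-06-01",
                 end = "2014-06-01"),
    en("first_lt60"), en("gap39"), en("lt2"), en("all_ge60"), en("pair_gap"),
    en("age17", birth_year = 1995),  # age 18 at 2013... adjust below
    en("lookback", start = "2013-01-01"), en("fup", end = "2014-06-01"),
    en("no_hb"), en("no_prot"), en("dial"), en("transpl"), en("egfr5")
  )
  enrollment$birth_year[enrollment$subject_id == "age17"] <- 1996  # 17 at index
  claims <- data.frame(
    subject_id = c("dial", "transpl"),
    date = as.Date(c("2013-01-15", "2013-02-15")),
    icd10 = c("N18.6", "Z94.0"), record_type = "inpatient",
    treatment_code = c("chronic_dialysis", "kidney_transplant"),
    stringsAsFactors = FALSE
  )
  list(checkups = checkups, claims = claims, enrollment = enrollment,
       expected = c(
         ok = "retained", death1y = "retained",
         first_lt60 = "first_egfr_below_60",
         gap39 = "no_post_index_egfr_38mo", lt2 = "lt_2_measurements",
         all_ge60 = "all_egfr_ge_60", pair_gap = "no_qualifying_pair",
         age17 = "age_lt_18", lookback = "lookback_lt_1y",
         fup = "followup_lt_2y", no_hb = "missing_hb_at_index",
         no_prot = "missing_proteinuria_at_index", dial = "prior_dialysis",
         transpl = "prior_transplant", egfr5 = "egfr_lt_6_at_index"))
}
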