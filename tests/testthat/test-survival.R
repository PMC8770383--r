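test_that("weighted Cox matches the brute-force partial-likelihood oracle", {
  for (seed in c(42, 43)) {
    d <- cox_fixture(16, seed)
    for (w in list(rep(1, 16), runif(16, 0.5, 3))) {
      fit <- fit_weighted_cox(survival::Surv(stop, event) ~ x, data = d,
                              weights = w, cluster = seq_len(16))
      oracle <- oracle_cox_fit(d$start, d$stop, d$event, d$x, w)
      expect_equal(unname(fit$coefficients[1]), oracle, tolerance = 1e-8)
    }
  }
})

test_that("halving weights while duplicating rows leaves the estimate unchanged", {
  d <- cox_fixture(14, 7)
  d$id <- seq_len(nrow(d))
  f1 <- fit_weighted_cox(survival::Surv(stop, event) ~ x, d,
                         weights = rep(1, nrow(d)), cluster = d$id)
  d2 <- rbind(d, d); d2$id <- c(d$id, d$id + 100)
  f2 <- fit_weighted_cox(survival::Surv(stop, event) ~ x, d2,
                         weights = rep(0.5, nrow(d2)), cluster = d2$id)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("robust intervals attain near-nominal coverage under the null", {
  set.seed(123)
  covered <- replicate(500, {
    n <- 150
    x <- rbinom(n, 1, 0.4)
    t_evt <- rexp(n, 0.1)          # hazard free of x: true HR = 1
    cens <- rexp(n, 0.07)
    d <- data.frame(time = pmin(t_evt, cens),
                    event = as.integer(t_evt <= cens), x = x)
    fit <- fit_weighted_cox(survival::Surv(time, event) ~ x, d,
                            cluster = seq_len(n))
    se <- sqrt(fit$robust_var[1, 1])
    abs(fit$coefficients[1]) < 1.96 * se
  })
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.98)
})

test_that("authored Breslow cumulative hazard agrees with survival::basehaz", {
  sim <- simulate_cohort(sim_config(n_subjects = 500, seed = 14))
  pp <- sim_person_periods(sim, "renal")
  w <- runif(nrow(pp), 0.5, 2)
  fit <- fit_weighted_cox(survival::Surv(start_day, end_day, event) ~ exposure,
                          data = pp, weights = w)
  bh <- survival::basehaz(fit$cox, centered = FALSE)
  ours <- fit$baseline_cumhaz
  ref <- bh$hazard[match(ours$time, bh$time)]
  expect_lt(max(abs(ours$cumhaz - ref)), 1e-8)
  ## non-decreasing step function starting at 0, jumps only at event times
  expect_true(all(diff(ours$cumhaz) >= 0))
  expect_true(all(ours$time %in% pp$end_day[pp$event == 1]))
})

test_that("regime curves obey the Breslow functional form", {
  sim <- simulate_cohort(sim_config(n_subjects = 800, seed = 15))
  pp <- sim_person_periods(sim, "renal")
  fit <- fit_weighted_cox(survival::Surv(start_day, end_day, event) ~ exposure,
                          data = pp)
  cv <- breslow_curves(fit, times = c(0, 365, 1095, 2191))
  always <- cv[cv$regime == "always_exposed", ]
  never <- cv[cv$regime == "never_exposed", ]
  expect_equal(always$survival[always$time == 0], 1)
  expect_equal(never$survival[never$time == 0], 1)
  expect_true(all(diff(always$survival) <= 0))
  expect_true(all(diff(never$survival) <= 0))
  ## S_always = S_never^{exp(beta)} exactly, so beta = 0 collapses the curves
  expect_equal(always$survival,
               never$survival^exp(unname(fit$coefficients[1])),
               tolerance = 1e-12)
})

test_that("bootstrap regime bands bracket the point curves", {
  sim <- simulate_cohort(sim_config(n_subjects = 400, seed = 25))
  pp <- sim_person_periods(sim, "renal")
  spec <- weight_spec(denominator = c("egfr", "egfr_lag", "tx", "tx_lag"))
  bc <- boot_regime_curves(pp, spec, times = c(365, 1095), reps = 25, seed = 2)
  expect_true(all(bc$ci_lower <= bc$survival + 1e-9))
  expect_true(all(bc$ci_upper >= bc$survival - 1e-9))
  expect_true(all(bc$ci_lower >= 0 & bc$ci_upper <= 1))
})

test_that("Kaplan-Meier estimator matches the hand product-limit calculation", {
  ## events at 1 and 2, censorings at 1.5 and 3: S(2) = (3/4)(1/2) = 0.375
  km <- km_estimator(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  at2 <- km_at(km, 2)
  expect_equal(at2$surv, 0.375)
  expect_equal(at2$surv, oracle_km(c(1, 1.5, 2, 3), c(1, 0, 1, 0), 2))
  ## no events: survival 1 everywhere
  km0 <- km_estimator(c(2, 3, 4), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  ## constant weights leave the curve unchanged
  tset <- c(1, 2, 2.5, 4, 6); eset <- c(1, 0, 1, 1, 0)
  kw <- km_estimator(tset, eset, weights = rep(3.7, 5))
  ku <- km_estimator(tset, eset)
  expect_equal(kw$surv, ku$surv, tolerance = 1e-12)
})

test_that("Fine-Gray reduces to cause-specific with no competing events", {
  set.seed(33)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  t_evt <- rexp(n, 0.08 * exp(0.5 * x))
  cens <- rexp(n, 0.05)
  d <- data.frame(subject_id = seq_len(n), time = pmin(t_evt, cens),
                  status = ifelse(t_evt <= cens, "renal", "censor"),
                  exposure = x)
  expect_message(ffg <- fit_fine_gray(d, ~exposure), "no competing")
  fcs <- fit_weighted_cox(survival::Surv(time, status == "renal") ~ exposure,
                          d, cluster = d$subject_id)
  expect_equal(unname(ffg$coefficients), unname(fcs$coefficients),
               tolerance = 1e-8)
})

test_that("Fine-Gray recovers a known sub-distribution hazard ratio", {
  ## direct simulation from the sub-distribution model:
  ## CIF1(t | x) = 1 - (1 - p(1 - exp(-t)))^exp(beta x)
  simulate_fg <- function(n, beta, p = 0.45, seed) {
    set.seed(seed)
    x <- rbinom(n, 1, 0.5)
    u <- runif(n)
    p1 <- 1 - (1 - p)^exp(beta * x)   # lifetime probability of cause 1
    cause1 <- u < p1
    t1 <- suppressWarnings(
      -log(1 - (1 - (1 - u)^(1 / exp(beta * x))) / p))  # inverse CIF
    t1[is.nan(t1)] <- Inf  # subjects destined for the competing cause
    t2 <- rexp(n, 0.35)
    time <- ifelse(cause1, t1, t2)
    cens <- runif(n, 0.5, 6)
    data.frame(subject_id = seq_len(n),
               time = pmin(time, cens),
               status = ifelse(time <= cens,
                               ifelse(cause1, "renal", "death"), "censor"),
               exposure = x)
  }
  beta <- log(1.8)
  ests <- ses <- numeric(6)
  for (r in 1:6) {
    d <- simulate_fg(900, beta, seed = 100 + r)
    f <- fit_fine_gray(d, ~exposure)
    ests[r] <- f$coefficients[1]
    ses[r] <- sqrt(f$robust_var[1, 1])
  }
  expect_lt(abs(mean(ests) - beta), 3 * mean(ses) / sqrt(6))
  ## independent cross-check of the implementation route on one replicate
  d <- simulate_fg(900, beta, seed = 107)
  f <- fit_fine_gray(d, ~exposure)
  fstat <- ifelse(d$status == "renal", 1, ifelse(d$status == "death", 2, 0))
  cr <- cmprsk::crr(d$time, fstat, cov1 = cbind(exposure = d$exposure),
                    failcode = 1, cencode = 0)
  expect_equal(unname(f$coefficients[1]), unname(cr$coef), tolerance = 0.02)
})

test_that("sub-distribution cumulative incidences stay within probability bounds", {
  set.seed(9)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.10 * exp(0.6 * x)); t2 <- rexp(n, 0.08)
  cens <- runif(n, 1, 10)
  d <- data.frame(subject_id = seq_len(n),
                  time = pmin(t1, t2, cens),
                  status = ifelse(pmin(t1, t2) > cens, "censor",
                                  ifelse(t1 <= t2, "renal", "death")),
                  exposure = x)
  f <- fit_fine_gray(d, ~exposure)
  cif1 <- 1 - exp(-f$baseline_cumhaz$cumhaz)  # never-exposed CIF of cause 1
  aj <- survival::survfit(survival::Surv(time, factor(status, c("censor", "renal", "death"))) ~ 1,
                          data = d)
  cif_death <- aj$pstate[, "death"]
  cd_at <- approx(aj$time, cif_death, xout = f$baseline_cumhaz$time,
                  method = "constant", rule = 2)$y
  expect_true(all(cif1 + cd_at <= 1 + 1e-8))
  expect_true(all(diff(cif1) >= 0))
})

test_that("greedy caliper matching is nearest-neighbor and deterministic", {
  ## identical distributions: every exposed subject finds a match
  ps <- rep(c(0.2, 0.4, 0.6), 4)
  ex <- rep(c(1, 0), each = 6)
  m <- ps_match(ps, ex, ids = sprintf("s%02d", 1:12))
  expect_equal(nrow(m$pairs), 6)
  expect_equal(m$n_unmatched, 0)
  ## nearest on the logit scale: candidate at -0.05 beats 0.1
  ps2 <- plogis(c(0, 0.1, -0.05))
  m2 <- ps_match(ps2, c(1, 0, 0), ids = c("e", "c1", "c2"),
                 caliper = 1, caliper_scale = "raw")
  expect_equal(m2$pairs$control_id, "c2")
  ## only candidate lies beyond the caliper: exposed stays unmatched
  ps3 <- plogis(c(0, 2))
  expect_warning(
    m3 <- ps_match(ps3, c(1, 0), ids = c("e", "c"), caliper = 0.25,
                   caliper_scale = "raw"), "no overlap")
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$n_unmatched, 1)
  ## caliper arithmetic in sd units: width = 0.25 * sd(logit ps)
  set.seed(4)
  ps4 <- plogis(rnorm(40))
  m4 <- ps_match(ps4, rep(c(1, 0), 20), caliper = 0.25)
  expect_equal(m4$caliper_used, 0.25 * sd(qlogis(ps4)))
  expect_true(all(m4$pairs$distance <= m4$caliper_used))
})

test_that("incidence rates use the exact Poisson interval", {
  r <- incidence_rate(210, 135303.4)
  expect_equal(round(r$rate, 2), 1.55)
  expect_equal(round(r$ci_lower, 2), 1.35)
  expect_equal(round(r$ci_upper, 2), 1.78)
  r0 <- incidence_rate(0, 1000)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_lower, 0)
  expect_equal(round(r0$ci_upper, 2), 3.69)
  expect_equal(round(incidence_rate(48, 5881.8)$rate, 2), 8.16)
  expect_error(incidence_rate(5, 0), "positive")
  expect_error(incidence_rate(-1, 10), "non-negative")
})

test_that("person-time sums follow-up days by group", {
  pt <- person_time(c(365.25, 365.25), c("a", "a"))
  expect_equal(pt$person_years, 2)
  expect_equal(person_time(numeric(0))$person_years, numeric(0))
  ## brute-force oracle on simulated follow-up
  sim <- simulate_cohort(sim_config(n_subjects = 200, seed = 8))
  tt <- sim$truth$subjects
  pt2 <- person_time(tt$renal_time_years * 365.25,
                     ifelse(tt$renal_event == 1, "case", "noncase"))
  expect_equal(sum(pt2$person_years), sum(tt$renal_time_years),
               tolerance = 1e-9)
  expect_error(person_time(-1), "negative")
})
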