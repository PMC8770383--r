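#' Incidence rate per 1000 patient-years with exact Poisson CI
#'
#' `rate = 1000 * events / person_years`; the 95% confidence interval is the
#' exact Poisson interval by chi-square inversion
#' (`lower = qchisq(alpha/2, 2E)/2`, `upper = qchisq(1-alpha/2, 2E+2)/2`)
#' scaled to the same denominator. Zero events give a lower bound of 0.
#'
#' @param events Event count (>= 0).
#' @param person_years Person-years at risk (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @param per Denominator scale (default 1000).
#' @return data.frame(events, person_years, rate, ci_lower, ci_upper).
#' @examples
#' incidence_rate(210, 135303.4)  # 1.55 [1.35, 1.78]
#' @export
incidence_rate <- function(events, person_years, conf_level = 0.95,
                           per = 1000) {
  if (any(person_years <= 0)) stopf("person_years must be positive")
  if (any(events < 0)) stopf("events must be non-negative")
  alpha <- 1 - conf_level
  lo <- ifelse(events == 0, 0, stats::qchisq(alpha / 2, 2 * events) / 2)
  hi <- stats::qchisq(1 - alpha / 2, 2 * events + 2) / 2
  data.frame(events = events, person_years = person_years,
             rate = per * events / person_years,
             ci_lower = per * lo / person_years,
             ci_upper = per * hi / person_years)
}

#' Person-years of follow-up, overall or by group
#'
#' Sums event-or-censoring times (days / 365.25) per group.
#'
#' @param time_days Follow-up days per subject (non-negative).
#' @param group Optional group labels.
#' @return data.frame(group, n, person_years).
#' @export
person_time <- function(time_days, group = NULL) {
  if (any(time_days < 0)) stopf("negative follow-up time")
  if (length(time_days) == 0L)
    return(data.frame(group = character(0), n = integer(0),
                      person_years = numeric(0)))
  g <- if (is.null(group)) rep("all", length(time_days)) else as.character(group)
  py <- tapply(time_days / DAYS_PER_YEAR, g, sum)
  py[is.na(py)] <- 0
  data.frame(group = names(py), n = as.integer(table(g)[names(py)]),
             person_years = as.numeric(py), row.names = NULL)
}
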