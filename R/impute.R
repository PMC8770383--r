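#' Simple imputation of missing covariates
#'
#' Fills missing values with the simplest defensible rules: baseline
#' continuous covariates take the cohort median, baseline categorical
#' covariates the cohort mode, and time-varying covariates the subject's
#' last observed value (carried forward from baseline), falling back to the
#' cohort median/mode when the subject has no observed value at all. Every
#' imputed cell is recorded.
#'
#' @param data Cohort or person-period table.
#' @param baseline_continuous,baseline_categorical Column names imputed with
#'   the cohort median / mode.
#' @param time_varying Column names imputed by last observation carried
#'   forward within subject.
#' @param id,time Column names identifying the subject and the within-subject
#'   order (used only for `time_varying`).
#' @param required Column names that must not be missing on input (key
#'   fields such as the index eGFR, baseline Hb and proteinuria).
#' @return list(data = completed table, log = data.frame(row, column,
#'   method, value) with one row per imputed cell).
#' @export
simple_impute <- function(data,
                          baseline_continuous = character(0),
                          baseline_categorical = character(0),
                          time_varying = character(0),
                          id = "subject_id", time = "k",
                          required = character(0)) {
  for (col in required) {
    if (anyNA(data[[col]])) stopf("required column '%s' has missing values", col)
  }
  log <- list()
  note <- function(rows, col, method, value) {
    if (length(rows))
      log[[length(log) + 1L]] <<- data.frame(row = rows, column = col,
                                             method = method,
                                             value = as.character(value),
                                             stringsAsFactors = FALSE)
  }
  fill_pooled <- function(col, method_label) {
    x <- data[[col]]
    if (all(is.na(x))) stopf("column '%s' is fully missing", col)
    val <- if (method_label == "median") stats::median(x, na.rm = TRUE)
           else stat_mode(x)
    rows <- which(is.na(x))
    data[[col]][rows] <<- val
    note(rows, col, method_label, val)
  }
  for (col in baseline_continuous) fill_pooled(col, "median")
  for (col in baseline_categorical) fill_pooled(col, "mode")
  if (length(time_varying)) {
    ord <- order(data[[id]], data[[time]])
    for (col in time_varying) {
      x <- data[[col]][ord]
      filled <- unlist(lapply(split(x, data[[id]][ord]), locf), use.names = FALSE)
      rows_locf <- ord[which(is.na(x) & !is.na(filled))]
      data[[col]][ord] <- filled
      note(rows_locf, col, "locf", NA)
      if (anyNA(data[[col]])) {
        lbl <- if (is.numeric(data[[col]])) "median" else "mode"
        fill_pooled(col, lbl)
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(row = integer(0), column = character(0), method = character(0),
               value = character(0), stringsAsFactors = FALSE)
  list(data = data, log = log)
}
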