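#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

## most frequent value; ties broken by first occurrence in sorted order
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- sort(table(x), decreasing = TRUE)
  val <- names(tab)[1L]
  if (is.logical(x)) as.logical(val)
  else if (is.numeric(x)) as.numeric(val)
  else val
}

## last observation carried forward within a vector (assumed time-ordered)
locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  out <- x
  filled <- c(NA, x[ok])[idx + 1L]
  out[is.na(x)] <- filled[is.na(x)]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

DAYS_PER_YEAR <- 365.25
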