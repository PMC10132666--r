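#' Floor a date to the Monday starting its week
#'
#' Weekly aggregation throughout the package uses Monday-start weeks, matching
#' the convention of the UK coronavirus dashboard's weekly MSOA series.
#'
#' @param dates a `Date` vector (or something coercible to one).
#' @return a `Date` vector of Mondays, one per input date.
#' @examples
#' week_start(as.Date("2019-01-13")) # Sunday -> Monday 2019-01-07
#' @export
week_start <- function(dates) {
  dates <- as.Date(dates)
  dates - (as.integer(format(dates, "%u")) - 1L)
}

is_monday <- function(d) format(as.Date(d), "%u") == "1"

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mobflow <- function(...) stop(..., call. = FALSE)

# population-SD z-score; constant input maps to all zeros rather than NaN so
# degenerate weeks propagate as "no signal", not as errors
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(rep(0, length(x)))
  (x - m) / s
}
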