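# Internal helpers shared across modules.

# All year arithmetic in the package runs through a single day count so that
# person-time, ages and lags are mutually consistent.
DAYS_PER_YEAR <- 365.25

#' Convert a day difference to years
#' @noRd
days_to_years <- function(days) days / DAYS_PER_YEAR

#' @noRd
years_to_days <- function(years) years * DAYS_PER_YEAR

#' Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' @noRd
as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

#' 5-year age group lower bound (0, 5, ..., capped at 85+)
#' @noRd
age_group_of <- function(age_years) pmin(floor(age_years / 5) * 5, 85)

#' 5-year calendar period lower bound
#' @noRd
period_of <- function(year) floor(year / 5) * 5

#' @noRd
calendar_year_of_day <- function(day_num) {
  as.integer(format(as.Date(day_num, origin = "1970-01-01"), "%Y"))
}

#' @noRd
stopifnot_probability <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must be a probability in [0, 1]", what), call. = FALSE)
  invisible(x)
}

#' Format observed counts with disclosure suppression
#'
#' Counts strictly between zero and the suppression threshold are replaced by
#' the marker \code{"d.s."}, mirroring the disclosure-control convention for
#' small subcohort cells.
#'
#' @param x integer vector of observed counts.
#' @param threshold suppression threshold; counts in (0, threshold) are masked.
#' @return character vector.
#' @export
suppress_counts <- function(x, threshold = 10) {
  out <- as.character(x)
  out[x > 0 & x < threshold] <- "d.s."
  out
}
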