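# Time-dependent exposure metrics: lagged cumulative exposure (ppm-years),
# average intensity of exposure (AIE, ppm), and categorisation against fixed
# cut points. These are evaluated both when splitting person-time and at the
# event times of nested case-control risk sets.

#' Exposure history constructor
#'
#' An exposure history is a set of non-overlapping, chronologically ordered
#' work segments, each with a constant exposure intensity in ppm.
#'
#' @param start,end segment boundary dates (`Date` or coercible); segments are
#'   half-open `[start, end)`.
#' @param intensity exposure intensity in ppm for each segment; must be >= 0.
#' @return a `data.frame` of class `exposure_history`.
#' @examples
#' h <- exposure_history(as.Date("2000-01-01"), as.Date("2001-01-01"), 2)
#' cumulative_exposure(h, as.Date("2011-01-01"), lag = 10)
#' @export
exposure_history <- function(start, end, intensity) {
  start <- as_date(start); end <- as_date(end)
  if (length(start) != length(end) || length(start) != length(intensity))
    stop("start, end and intensity must have equal length")
  if (any(intensity < 0)) stop("exposure intensity must be >= 0")
  if (any(end <= start)) stop("each segment must satisfy start < end")
  o <- order(start)
  start <- start[o]; end <- end[o]; intensity <- intensity[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("exposure segments must not overlap")
  structure(
    data.frame(start = start, end = end, intensity = intensity),
    class = c("exposure_history", "data.frame")
  )
}

#' Lagged cumulative exposure
#'
#' Integrates intensity over time up to `at - lag`, i.e. exposure accrued more
#' than `lag` years before the evaluation date is counted, more recent
#' exposure is discarded (disease latency).
#'
#' @param history an [exposure_history()] (or data.frame with columns
#'   `start`, `end`, `intensity`).
#' @param at evaluation date(s).
#' @param lag lag in years; must be >= 0.
#' @return cumulative exposure in ppm-years, one value per `at`.
#' @export
cumulative_exposure <- function(history, at, lag = 0) {
  if (lag < 0) stop("lag must be >= 0")
  if (is.null(history) || nrow(history) == 0) return(rep(0, length(at)))
  cutoff <- as.numeric(as_date(at)) - years_to_days(lag)
  s <- as.numeric(as_date(history$start))
  e <- as.numeric(as_date(history$end))
  i <- history$intensity
  vapply(cutoff, function(ct) {
    sum(i * pmax(0, pmin(e, ct) - s)) / DAYS_PER_YEAR
  }, numeric(1))
}

#' Lagged average intensity of exposure (AIE)
#'
#' Lagged cumulative exposure divided by the lagged total exposed duration in
#' years; zero when no exposure lies outside the lag window.
#'
#' @inheritParams cumulative_exposure
#' @return average intensity in ppm, one value per `at`.
#' @export
average_intensity <- function(history, at, lag = 0) {
  if (lag < 0) stop("lag must be >= 0")
  if (is.null(history) || nrow(history) == 0) return(rep(0, length(at)))
  cutoff <- as.numeric(as_date(at)) - years_to_days(lag)
  s <- as.numeric(as_date(history$start))
  e <- as.numeric(as_date(history$end))
  i <- history$intensity
  vapply(cutoff, function(ct) {
    dur <- sum(pmax(0, pmin(e, ct) - s)) / DAYS_PER_YEAR
    if (dur <= 0) return(0)
    sum(i * pmax(0, pmin(e, ct) - s)) / DAYS_PER_YEAR / dur
  }, numeric(1))
}

#' Exposure category specification
#'
#' Defines how a continuous exposure metric is cut into ordered categories.
#' Intervals are right-closed above the origin: `[0, c1], (c1, c2], ...,
#' (cK, Inf)`, matching the convention of printed category labels such as
#' "0-0.09" followed by ">0.09-0.64". When `separate_unexposed` is set,
#' never-exposed workers and the observation time of exposed workers before
#' their first exposure form an extra "unexposed" category (index 0), and the
#' lowest cut-point category is the baseline for workers already exposed.
#'
#' @param kind `"cumulative"` (ppm-years) or `"average_intensity"` (ppm).
#' @param cutpoints strictly increasing positive category bounds.
#' @param lag exposure lag in years.
#' @param separate_unexposed keep a distinct unexposed category (index 0)?
#' @return object of class `category_spec`.
#' @examples
#' an_cumulative_spec()  # the cohort's lagged cumulative quintile cut points
#' @export
category_spec <- function(kind = c("cumulative", "average_intensity"),
                          cutpoints, lag = 10, separate_unexposed = TRUE) {
  kind <- match.arg(kind)
  if (lag < 0) stop("lag must be >= 0")
  if (any(cutpoints <= 0) || any(diff(cutpoints) <= 0))
    stop("cutpoints must be strictly increasing and positive")
  structure(
    list(kind = kind, cutpoints = as.numeric(cutpoints), lag = lag,
         separate_unexposed = isTRUE(separate_unexposed)),
    class = "category_spec"
  )
}

#' Cumulative-exposure quintile specification (lagged 10 years)
#'
#' Cut points 0.09, 0.64, 2.30 and 12.08 ppm-years.
#' @param lag lag in years (default 10).
#' @export
an_cumulative_spec <- function(lag = 10) {
  category_spec("cumulative", c(0.09, 0.64, 2.30, 12.08), lag = lag)
}

#' Average-intensity category specification
#'
#' Cut points 0.06, 0.14, 0.37 and 1.46 ppm. The lag defaults to the same
#' 10 years used for cumulative exposure.
#' @param lag lag in years (default 10).
#' @export
an_intensity_spec <- function(lag = 10) {
  category_spec("average_intensity", c(0.06, 0.14, 0.37, 1.46), lag = lag)
}

#' Classify an exposure value into a category index
#'
#' @param value exposure metric value(s); must be >= 0.
#' @param spec a [category_spec()].
#' @param ever_exposed logical (recycled): has the worker's first exposure
#'   occurred by the evaluation date? Workers not yet exposed fall in the
#'   unexposed category when the spec keeps one.
#' @return integer category index: 0 for unexposed (when separated), then
#'   1..K+1 over the cut-point intervals.
#' @export
classify_exposure <- function(value, spec, ever_exposed = TRUE) {
  if (any(value < 0)) stop("exposure values must be >= 0")
  n <- max(length(value), length(ever_exposed))
  value <- rep_len(value, n)
  ever_exposed <- rep_len(ever_exposed, n)
  cat <- 1L + rowSums(outer(value, spec$cutpoints, `>`))
  if (spec$separate_unexposed) cat[!ever_exposed] <- 0L
  as.integer(cat)
}

#' Category labels in the printed-table style
#' @param spec a [category_spec()].
#' @return character vector of labels aligned with category indices
#'   (starting at 0 when the spec separates unexposed time).
#' @export
category_labels <- function(spec) {
  cp <- format(spec$cutpoints, trim = TRUE)
  k <- length(cp)
  lab <- c(paste0("0-", cp[1]),
           if (k > 1) paste0(">", cp[-k], "-", cp[-1]),
           paste0(">", cp[k]))
  if (spec$separate_unexposed) lab <- c("unexposed", lab)
  lab
}

# Dates (integer day numbers) at which a worker's category index changes,
# within [window_start, window_end). Returned breakpoints guarantee that the
# category is constant on each subinterval at daily resolution; spurious
# breakpoints (no actual change) are harmless for tabulation.
#' @noRd
category_breakpoints <- function(history, spec, window) {
  if (is.null(history) || nrow(history) == 0) return(numeric(0))
  s <- as.numeric(as_date(history$start))
  e <- as.numeric(as_date(history$end))
  i <- history$intensity
  lag_d <- years_to_days(spec$lag)
  bp <- numeric(0)
  if (spec$separate_unexposed) bp <- c(bp, s[1])

  # cumulative exposure (years) and exposed duration (years) at segment starts
  seg_len <- (e - s) / DAYS_PER_YEAR
  cum0 <- cumsum(c(0, i * seg_len))[seq_along(s)]
  dur0 <- cumsum(c(0, seg_len))[seq_along(s)]

  for (k in seq_along(s)) {
    len_k <- seg_len[k]
    for (cp in spec$cutpoints) {
      if (spec$kind == "cumulative") {
        if (i[k] <= 0) next
        tau <- (cp - cum0[k]) / i[k]              # years into segment
      } else {
        if (abs(i[k] - cp) < 1e-12) next
        tau <- (cp * dur0[k] - cum0[k]) / (i[k] - cp)
      }
      if (is.finite(tau) && tau >= 0 && tau <= len_k) {
        t_cal <- s[k] + years_to_days(tau) + lag_d  # calendar crossing time
        bp <- c(bp, floor(t_cal), floor(t_cal) + 1, floor(t_cal) + 2)
      }
    }
    # slope changes at (lagged) segment boundaries; split there too so each
    # subinterval is linear in the metric
    bp <- c(bp, ceiling(s[k] + lag_d), ceiling(e[k] + lag_d) + 1)
  }
  bp <- sort(unique(bp))
  bp[bp > window[1] & bp < window[2]]
}
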