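# Reference mortality rate tables: death rates per person-year by cause,
# race, sex, 5-year age group and 5-year calendar period. These play the role
# of the external (national or regional) comparison rates in indirect
# standardization.

AN_CAUSES <- c("lung", "bladder", "mesothelioma", "pneumonitis", "copd", "other")
RACES <- c("white", "nonwhite")
SEXES <- c("male", "female")

#' Reference rate table constructor
#'
#' @param rates data.frame with columns `cause`, `race`, `sex`, `age_group`
#'   (5-year lower bound, 0..85), `period` (5-year lower bound) and `rate`
#'   (deaths per person-year, >= 0).
#' @param label short label, e.g. `"US"` or `"regional-plant4"`.
#' @return object of class `rate_table` (a data.frame).
#' @export
rate_table <- function(rates, label = "rates") {
  need <- c("cause", "race", "sex", "age_group", "period", "rate")
  if (!all(need %in% names(rates)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  if (any(rates$rate < 0)) stop("rates must be >= 0")
  rates <- rates[need]
  attr(rates, "label") <- label
  class(rates) <- c("rate_table", "data.frame")
  rates
}

# Smooth parametric mortality schedules used by the synthetic reference
# population. Gompertz-type age curves with cause-specific levels and slopes;
# magnitudes are in the range of mid/late 20th century US male rates for
# never-smokers (the generator layers smoking/asbestos multipliers on top of
# these within the cohort).
#' @noRd
baseline_rate_schedule <- function(cause, age_mid, sex, period) {
  pars <- switch(cause,
    lung         = c(a = 2.0e-5, b = 0.095, ref = 40),
    copd         = c(a = 2.0e-5, b = 0.095, ref = 40),
    bladder      = c(a = 4.0e-6, b = 0.090, ref = 45),
    mesothelioma = c(a = 2.0e-6, b = 0.080, ref = 40),
    pneumonitis  = c(a = 4.0e-6, b = 0.090, ref = 50),
    other        = c(a = 5.0e-4, b = 0.082, ref = 35),
    stop("unknown cause: ", cause)
  )
  fem <- switch(cause, lung = 0.5, copd = 0.7, bladder = 0.35,
                mesothelioma = 0.2, pneumonitis = 0.8, other = 0.6)
  r <- pars["a"] * exp(pars["b"] * (age_mid - pars["ref"]))
  r <- r * ifelse(sex == "female", fem, 1)
  # mild secular trend so period is a real stratifier
  r <- r * exp(0.002 * (period - 1980))
  pmax(unname(r), 1e-8)
}

#' Generate a complete synthetic reference rate table
#'
#' Produces strictly positive rates for every cause x race x sex x 5-year age
#' group x 5-year period cell spanning the follow-up window, so downstream
#' expected-death lookups never hit a missing cell. The table is a
#' deterministic function of the configuration (no randomness).
#'
#' @param config a [sim_config()]; only the study window is used.
#' @param label label for the resulting table.
#' @return a [rate_table()].
#' @export
generate_reference_rates <- function(config = sim_config(), label = "US") {
  periods <- seq(1940, period_of(as.integer(format(config$study_end, "%Y"))), by = 5)
  grid <- expand.grid(
    cause = AN_CAUSES, race = RACES, sex = SEXES,
    age_group = seq(0, 85, by = 5), period = periods,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$rate <- mapply(
    function(cause, age, sex, period)
      baseline_rate_schedule(cause, age + 2.5, sex, period),
    grid$cause, grid$age_group, grid$sex, grid$period
  )
  rate_table(grid, label = label)
}

#' Derive a rate table from a person-time table's own deaths
#'
#' Stratum-specific rates are observed deaths divided by person-years,
#' aggregated over exposure categories. Feeding these rates back into the SMR
#' engine yields an overall SMR of exactly 1 for every cause, which is the
#' standard self-consistency check of indirect standardization.
#'
#' @param pt a [tabulate_person_time()] result.
#' @param causes causes to include (default: all causes with recorded deaths).
#' @return a [rate_table()] labelled `"self"`.
#' @export
rates_from_person_time <- function(pt, causes = NULL) {
  d <- pt$deaths
  if (is.null(causes)) causes <- unique(d$cause)
  py <- stats::aggregate(pyr ~ race + sex + age_group + period, data = pt$pyr, sum)
  out <- list()
  for (cs in causes) {
    dc <- d[d$cause == cs, , drop = FALSE]
    if (nrow(dc)) {
      dd <- stats::aggregate(deaths ~ race + sex + age_group + period, data = dc, sum)
      m <- merge(py, dd, all.x = TRUE)
      m$deaths[is.na(m$deaths)] <- 0
    } else {
      m <- py; m$deaths <- 0
    }
    m$cause <- cs
    m$rate <- ifelse(m$pyr > 0, m$deaths / m$pyr, 0)
    out[[cs]] <- m[c("cause", "race", "sex", "age_group", "period", "rate")]
  }
  rate_table(do.call(rbind, out), label = "self")
}

#' Read / write rate tables as CSV
#'
#' @param path file path.
#' @param label label attached on read.
#' @rdname rate_table_io
#' @export
read_rate_table <- function(path, label = basename(path)) {
  rate_table(utils::read.csv(path, stringsAsFactors = FALSE), label = label)
}

#' @param x a [rate_table()].
#' @rdname rate_table_io
#' @export
write_rate_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
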