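# Nested case-control risk sets: one set per death from the index cause,
# matched on exact attained age (in days) with a year-of-birth caliper.
# Controls are all cohort members under follow-up at that attained age
# (incidence-density sampling), whatever their eventual outcome; a member who
# later dies of the index cause may serve as a control in earlier sets.
# Time-dependent exposures are evaluated for every member at the date they
# reach the case's event age, with the configured lag.

#' Build nested case-control risk sets for one cause of death
#'
#' @param cohort an `an_cohort`.
#' @param cause index cause of death.
#' @param caliper year-of-birth matching caliper (years, default 1).
#' @param spec a [category_spec()] for exposure categorisation at event times.
#' @param follow_up two dates bounding eligible events.
#' @param sample_controls optional integer m: draw a seeded random sample of
#'   at most m controls per set (all eligible controls are used when NULL).
#' @param seed RNG seed for control sampling.
#' @return data.frame of class `risk_sets`: columns `set`, `case` (logical),
#'   `worker_id`, `event_age`, `category`, `cum`, `aie`, `race`, `sex`,
#'   `pay_type`, `plant`. Attributes: `n_sets`, `n_empty` (flagged sets with
#'   zero eligible controls, excluded), `cause`, `caliper`.
#' @export
build_risk_sets <- function(cohort, cause, caliper = 1,
                            spec = an_cumulative_spec(),
                            follow_up = c(as.Date("1942-01-01"),
                                          cohort$study_end),
                            sample_controls = NULL, seed = 1) {
  w <- cohort$workers
  follow_up <- as_date(follow_up)
  fu0 <- as.numeric(follow_up[1]); fu1 <- as.numeric(follow_up[2])

  birth <- as.numeric(w$birth_date)
  hire <- as.numeric(w$hire_date)
  death <- as.numeric(w$death_date)
  by <- as.integer(format(w$birth_date, "%Y"))
  end_day <- pmin(ifelse(is.na(death), Inf, death), as.numeric(cohort$study_end))
  is_index <- w$vital_status == "dead" & !is.na(w$cause) & w$cause == cause

  case_rows <- which(is_index & death >= fu0 & death <= fu1)
  if (!length(case_rows)) stop("no deaths from cause '", cause, "' in window")
  case_rows <- case_rows[order(death[case_rows], w$worker_id[case_rows])]

  wide <- exposure_wide(cohort)

  out <- vector("list", length(case_rows))
  n_empty <- 0; empty_ids <- character(0)

  with_seed(seed, {
    for (si in seq_along(case_rows)) {
      cr <- case_rows[si]
      age_days <- death[cr] - birth[cr]
      d <- birth + age_days  # date each member reaches the case's event age
      elig <- d >= hire & d <= end_day & d >= fu0 & d <= fu1 &
        abs(by - by[cr]) <= caliper & seq_along(birth) != cr &
        !(is_index & !is.na(death) & death == d)
      ctl <- which(elig)
      if (!length(ctl)) {
        n_empty <- n_empty + 1
        empty_ids <- c(empty_ids, w$worker_id[cr])
        out[[si]] <- NULL
        next
      }
      ctl <- ctl[order(w$worker_id[ctl])]
      if (!is.null(sample_controls) && length(ctl) > sample_controls)
        ctl <- sort(sample(ctl, sample_controls))
      rows <- c(cr, ctl)
      ex <- cum_at_wide(wide, rows, d[rows], spec$lag)
      everexp <- d[rows] >= wide$first[rows]
      val <- if (spec$kind == "cumulative") ex$cum
             else ifelse(ex$dur > 0, ex$cum / ex$dur, 0)
      out[[si]] <- data.frame(
        set = si, case = c(TRUE, rep(FALSE, length(ctl))),
        worker_id = w$worker_id[rows],
        event_age = age_days / DAYS_PER_YEAR,
        category = classify_exposure(val, spec, everexp),
        cum = ex$cum,
        aie = ifelse(ex$dur > 0, ex$cum / ex$dur, 0),
        race = w$race[rows], sex = w$sex[rows], pay_type = w$pay_type[rows],
        plant = w$plant[rows], stringsAsFactors = FALSE
      )
    }
  })

  keep <- !vapply(out, is.null, logical(1))
  rs <- do.call(rbind, out[keep])
  if (is.null(rs)) {
    # every case lacked eligible controls: flagged, excluded, empty result
    rs <- data.frame(set = integer(0), case = logical(0),
                     worker_id = character(0), event_age = numeric(0),
                     category = integer(0), cum = numeric(0), aie = numeric(0),
                     race = character(0), sex = character(0),
                     pay_type = character(0), plant = integer(0),
                     stringsAsFactors = FALSE)
  }
  rs$set <- match(rs$set, unique(rs$set))
  rownames(rs) <- NULL
  attr(rs, "n_sets") <- length(unique(rs$set))
  attr(rs, "n_empty") <- n_empty
  attr(rs, "empty_case_ids") <- empty_ids
  attr(rs, "cause") <- cause
  attr(rs, "caliper") <- caliper
  attr(rs, "spec") <- spec
  class(rs) <- c("risk_sets", "data.frame")
  rs
}

#' Write risk sets as an audit TSV
#' @param rs a `risk_sets` data.frame.
#' @param path output path.
#' @export
write_risk_sets <- function(rs, path) {
  out <- as.data.frame(rs)
  out$role <- ifelse(out$case, "case", "control")
  out$event_age <- sprintf("%.4f", out$event_age)
  out$cum <- sprintf("%.4f", out$cum)
  out$aie <- sprintf("%.4f", out$aie)
  utils::write.table(
    out[c("set", "role", "worker_id", "event_age", "category", "cum", "aie",
          "race", "sex", "pay_type", "plant")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
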