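# Person-time tabulation: each worker's follow-up is split at every 5-year
# age-group boundary, 5-year calendar-period boundary and exposure-category
# transition date, and the resulting sub-intervals are accumulated into
# stratum x category person-year cells. Deaths are assigned to the cell
# active at the death date. Intervals are half-open [start, end) at daily
# resolution; person-years are days / 365.25.

#' Tabulate person-years and deaths by stratum and exposure category
#'
#' @param cohort an `an_cohort`.
#' @param spec a [category_spec()] defining the exposure axis.
#' @param follow_up two dates: first and last day of follow-up (inclusive).
#' @param causes causes of death to tabulate.
#' @return object of class `person_time_table`: list with `pyr` (data.frame
#'   `race, sex, age_group, period, category, pyr`), `deaths` (`..., cause,
#'   deaths`), the `spec`, the follow-up window and `total_pyr`.
#' @export
tabulate_person_time <- function(cohort, spec = an_cumulative_spec(),
                                 follow_up = c(as.Date("1942-01-01"),
                                               cohort$study_end),
                                 causes = AN_CAUSES) {
  w <- cohort$workers
  follow_up <- as_date(follow_up)
  if (follow_up[1] > follow_up[2]) stop("follow_up start must precede end")
  fu0 <- as.numeric(follow_up[1])
  fu1 <- as.numeric(follow_up[2]) + 1  # exclusive end

  dead <- w$vital_status == "dead"
  if (any(dead & !is.na(w$death_date) & w$death_date < w$hire_date)) {
    bad <- w$worker_id[dead & !is.na(w$death_date) & w$death_date < w$hire_date]
    stop("validation error: death before hire for worker(s) ",
         paste(bad, collapse = ", "))
  }

  seg_by_worker <- split(cohort$exposure, cohort$exposure$worker_id)
  birth <- as.numeric(w$birth_date)
  hire <- as.numeric(w$hire_date)
  death <- as.numeric(w$death_date)

  keys <- list(); pyrs <- list(); n_chunk <- 0
  dkeys <- character(0); dcauses <- character(0)

  for (r in seq_len(nrow(w))) {
    entry <- max(hire[r], fu0)
    exit <- if (dead[r] && !is.na(death[r])) min(death[r], fu1) else fu1
    hist <- seg_by_worker[[w$worker_id[r]]]

    if (exit > entry) {
      # age-band boundaries
      ages <- seq(5, 120, by = 5)
      age_bp <- birth[r] + ceiling(years_to_days(ages))
      # calendar 5-year period boundaries
      yrs <- seq(1940, 2035, by = 5)
      per_bp <- as.numeric(as.Date(paste0(yrs, "-01-01")))
      cat_bp <- if (!is.null(hist))
        category_breakpoints(hist, spec, c(entry, exit)) else numeric(0)
      bp <- c(age_bp, per_bp, cat_bp)
      bp <- sort(unique(bp[bp > entry & bp < exit]))
      a <- c(entry, bp); b <- c(bp, exit)

      age_grp <- age_group_of((a - birth[r]) / DAYS_PER_YEAR)
      period <- period_of(calendar_year_of_day(a))
      if (!is.null(hist)) {
        val <- if (spec$kind == "cumulative")
          cumulative_exposure(hist, as.Date(a, origin = "1970-01-01"), spec$lag)
        else
          average_intensity(hist, as.Date(a, origin = "1970-01-01"), spec$lag)
        everexp <- a >= as.numeric(min(hist$start))
      } else {
        val <- rep(0, length(a)); everexp <- rep(FALSE, length(a))
      }
      cat_i <- classify_exposure(val, spec, everexp)
      n_chunk <- n_chunk + 1
      keys[[n_chunk]] <- paste(w$race[r], w$sex[r], age_grp, period, cat_i,
                               sep = "|")
      pyrs[[n_chunk]] <- (b - a) / DAYS_PER_YEAR
    }

    if (dead[r] && !is.na(death[r]) && death[r] >= fu0 && death[r] < fu1 &&
        !is.na(w$cause[r]) && w$cause[r] %in% causes) {
      dd <- death[r]
      age_grp <- age_group_of((dd - birth[r]) / DAYS_PER_YEAR)
      period <- period_of(calendar_year_of_day(dd))
      if (!is.null(hist)) {
        val <- if (spec$kind == "cumulative")
          cumulative_exposure(hist, as.Date(dd, origin = "1970-01-01"), spec$lag)
        else
          average_intensity(hist, as.Date(dd, origin = "1970-01-01"), spec$lag)
        everexp <- dd >= as.numeric(min(hist$start))
      } else {
        val <- 0; everexp <- FALSE
      }
      cat_i <- classify_exposure(val, spec, everexp)
      dkeys <- c(dkeys, paste(w$race[r], w$sex[r], age_grp, period, cat_i,
                              sep = "|"))
      dcauses <- c(dcauses, w$cause[r])
    }
  }

  key <- unlist(keys); pyr <- unlist(pyrs)
  agg <- rowsum(pyr, key)
  parts <- strsplit(rownames(agg), "|", fixed = TRUE)
  pyr_df <- data.frame(
    race = vapply(parts, `[`, "", 1), sex = vapply(parts, `[`, "", 2),
    age_group = as.integer(vapply(parts, `[`, "", 3)),
    period = as.integer(vapply(parts, `[`, "", 4)),
    category = as.integer(vapply(parts, `[`, "", 5)),
    pyr = as.numeric(agg[, 1]), stringsAsFactors = FALSE
  )
  pyr_df <- pyr_df[order(pyr_df$race, pyr_df$sex, pyr_df$age_group,
                         pyr_df$period, pyr_df$category), ]
  rownames(pyr_df) <- NULL

  if (length(dkeys)) {
    dk <- paste(dkeys, dcauses, sep = "|")
    dagg <- rowsum(rep(1L, length(dk)), dk)
    dparts <- strsplit(rownames(dagg), "|", fixed = TRUE)
    deaths_df <- data.frame(
      race = vapply(dparts, `[`, "", 1), sex = vapply(dparts, `[`, "", 2),
      age_group = as.integer(vapply(dparts, `[`, "", 3)),
      period = as.integer(vapply(dparts, `[`, "", 4)),
      category = as.integer(vapply(dparts, `[`, "", 5)),
      cause = vapply(dparts, `[`, "", 6),
      deaths = as.integer(dagg[, 1]), stringsAsFactors = FALSE
    )
  } else {
    deaths_df <- data.frame(race = character(0), sex = character(0),
                            age_group = integer(0), period = integer(0),
                            category = integer(0), cause = character(0),
                            deaths = integer(0), stringsAsFactors = FALSE)
  }

  structure(list(pyr = pyr_df, deaths = deaths_df, spec = spec,
                 follow_up = follow_up, total_pyr = sum(pyr_df$pyr)),
            class = "person_time_table")
}

#' @export
print.person_time_table <- function(x, ...) {
  cat("Person-time table:", format(round(x$total_pyr, 1), big.mark = ","),
      "person-years in", nrow(x$pyr), "cells;",
      sum(x$deaths$deaths), "deaths\n")
  cat("  exposure axis:", x$spec$kind, "(lag", x$spec$lag, "y), categories:",
      paste(category_labels(x$spec), collapse = ", "), "\n")
  invisible(x)
}

#' Write a person-time table as tidy TSV
#'
#' One row per stratum x category cell, with death counts per cause in wide
#' columns.
#' @param pt a `person_time_table`.
#' @param path output path.
#' @export
write_person_time <- function(pt, path) {
  out <- pt$pyr
  for (cs in unique(pt$deaths$cause)) {
    dc <- pt$deaths[pt$deaths$cause == cs,
                    c("race", "sex", "age_group", "period", "category", "deaths")]
    names(dc)[6] <- paste0("deaths_", cs)
    out <- merge(out, dc, all.x = TRUE)
  }
  out[is.na(out)] <- 0
  out <- out[order(out$race, out$sex, out$age_group, out$period, out$category), ]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
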