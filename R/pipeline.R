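# Cohort file schemas, validation and recoding rules, subset filters, and
# the end-to-end pipeline driver. The interchange format is a pair of CSV
# files: one row per worker, and a companion exposure-segment file keyed by
# worker_id, all dates ISO-8601.

#' Read / write a cohort as CSV
#'
#' @param workers_path CSV with one row per worker.
#' @param exposure_path CSV with one exposure segment per row
#'   (`worker_id, start, end, intensity`).
#' @param study_end end of follow-up.
#' @rdname cohort_io
#' @export
read_cohort <- function(workers_path, exposure_path, study_end = "2011-12-31") {
  w <- utils::read.csv(workers_path, stringsAsFactors = FALSE)
  e <- utils::read.csv(exposure_path, stringsAsFactors = FALSE)
  an_cohort(w, e, study_end)
}

#' @param cohort an `an_cohort`.
#' @param dir output directory; writes `workers.csv` and `exposure.csv`.
#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$workers, file.path(dir, "workers.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$exposure, file.path(dir, "exposure.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Validate a cohort and apply recode rules
#'
#' Checks structural invariants row by row, rejects malformed workers (with
#' reasons), and recodes deaths dated after the end of follow-up to the end
#' date itself (the convention for deaths reported just past the closing
#' date of a study). Aborts if more than `max_malformed` of rows are
#' rejected.
#'
#' @param cohort an `an_cohort`.
#' @param follow_up_end end of follow-up (default: the cohort's study end).
#' @param max_malformed maximum tolerated malformed-row fraction (default 1%).
#' @return list with `cohort` (clean, recoded), and `report`: counts of rows
#'   in/out, recodes, and a data.frame of rejected workers with reasons.
#' @export
validate_and_recode <- function(cohort, follow_up_end = cohort$study_end,
                                max_malformed = 0.01) {
  w <- cohort$workers
  e <- cohort$exposure
  follow_up_end <- as_date(follow_up_end)
  reasons <- character(nrow(w))

  need <- c("worker_id", "birth_date", "hire_date", "termination_date",
            "vital_status")
  miss <- !stats::complete.cases(w[need])
  reasons[miss] <- "missing required field"

  bad_order <- !miss & (w$birth_date >= w$hire_date |
                          w$termination_date < w$hire_date)
  reasons[bad_order] <- "birth/hire/termination out of order"

  dead <- w$vital_status == "dead"
  bad_death <- !miss & dead & (is.na(w$death_date) | is.na(w$cause) |
                                 w$death_date < w$hire_date)
  reasons[bad_death & !is.na(w$death_date) & !is.na(w$hire_date) &
            w$death_date < w$hire_date] <- "death before hire"
  reasons[bad_death & (is.na(w$death_date) | is.na(w$cause))] <-
    "dead without death date/cause"
  bad_alive <- !miss & !dead & !is.na(w$death_date)
  reasons[bad_alive] <- "alive with death date"

  if (nrow(e)) {
    bad_seg_ids <- unique(e$worker_id[e$intensity < 0 | e$end <= e$start])
    ovl <- unlist(lapply(split(e, e$worker_id), function(s) {
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(as.numeric(s$start[-1]) <
                               as.numeric(s$end[-nrow(s)])))
        s$worker_id[1] else NULL
    }))
    bad_seg_ids <- union(bad_seg_ids, ovl)
    bseg <- w$worker_id %in% bad_seg_ids & reasons == ""
    reasons[bseg] <- "invalid exposure segments"
  }

  rejected <- reasons != ""
  frac <- mean(rejected)
  report_rejected <- data.frame(worker_id = w$worker_id[rejected],
                                reason = reasons[rejected],
                                stringsAsFactors = FALSE)
  if (frac > max_malformed)
    stop(sprintf(
      "validation aborted: %.1f%% of rows malformed (threshold %.1f%%); %s",
      100 * frac, 100 * max_malformed,
      paste(utils::head(paste0(report_rejected$worker_id, ": ",
                               report_rejected$reason), 5), collapse = "; ")))

  w2 <- w[!rejected, , drop = FALSE]
  recode <- !is.na(w2$death_date) & w2$death_date > follow_up_end
  n_recoded <- sum(recode)
  w2$death_date[recode] <- follow_up_end
  e2 <- e[e$worker_id %in% w2$worker_id, , drop = FALSE]

  out <- cohort
  out$workers <- w2
  out$exposure <- e2
  list(cohort = out,
       report = list(n_in = nrow(w), n_out = nrow(w2),
                     n_rejected = sum(rejected),
                     n_deaths_recoded_to_end = n_recoded,
                     rejected = report_rejected))
}

#' Drop workers from selected plants
#'
#' Sensitivity-analysis subset filter (e.g. omitting a plant with suspected
#' extraneous asbestos exposure).
#'
#' @param cohort an `an_cohort`.
#' @param exclude plant ids to drop.
#' @export
filter_plants <- function(cohort, exclude) {
  keep <- !(cohort$workers$plant %in% exclude)
  out <- cohort
  out$workers <- cohort$workers[keep, , drop = FALSE]
  out$exposure <- cohort$exposure[
    cohort$exposure$worker_id %in% out$workers$worker_id, , drop = FALSE]
  out
}

#' Pipeline configuration
#'
#' @param cohort an `an_cohort`, or NULL to generate one from `sim`.
#' @param sim a [sim_config()] used when `cohort` is NULL.
#' @param rates named list of [rate_table()]s (>= 1).
#' @param follow_up two dates (inclusive).
#' @param spec exposure [category_spec()].
#' @param causes causes of death to analyse.
#' @param nco_causes named list mapping confounders to their negative control
#'   outcome cause.
#' @param exclude_plants plants to drop before analysis.
#' @param suppression_threshold disclosure threshold for written reports.
#' @param sample_controls optional m:1 control sampling in risk sets.
#' @param output_dir directory for report files (NULL: nothing written).
#' @param seed RNG seed for control sampling.
#' @export
pipeline_config <- function(cohort = NULL, sim = sim_config(),
                            rates = NULL,
                            follow_up = c(as.Date("1942-01-01"),
                                          as.Date("2011-12-31")),
                            spec = an_cumulative_spec(),
                            causes = c("lung", "bladder", "mesothelioma",
                                       "pneumonitis", "copd"),
                            nco_causes = list(smoking = "copd",
                                              asbestos = "mesothelioma"),
                            exclude_plants = integer(0),
                            suppression_threshold = 10,
                            sample_controls = NULL,
                            output_dir = NULL, seed = 1) {
  follow_up <- as_date(follow_up)
  if (follow_up[1] < as.Date("1942-01-01"))
    stop("follow_up must start no earlier than 1942-01-01")
  if (suppression_threshold < 0) stop("suppression_threshold must be >= 0")
  structure(list(cohort = cohort, sim = sim, rates = rates,
                 follow_up = follow_up, spec = spec, causes = causes,
                 nco_causes = nco_causes, exclude_plants = exclude_plants,
                 suppression_threshold = suppression_threshold,
                 sample_controls = sample_controls,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' generate/load -> validate & recode -> person-time -> SMRs per rate table
#' -> risk sets -> rate-ratio models -> NCO adjustments, with all written
#' outputs under the disclosure-suppression rule and a manifest recording
#' the configuration and seed. Stage failures abort with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result` (named list of stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = config)

  cohort <- stage("load", {
    if (is.null(config$cohort)) generate_cohort(config$sim) else config$cohort
  })
  message("[load] ", nrow(cohort$workers), " workers in")

  if (length(config$exclude_plants)) {
    cohort <- stage("filter", filter_plants(cohort, config$exclude_plants))
    message("[filter] excluded plant(s) ",
            paste(config$exclude_plants, collapse = ","), "; ",
            nrow(cohort$workers), " workers remain")
  }

  val <- stage("validate", validate_and_recode(cohort, config$follow_up[2]))
  cohort <- val$cohort
  res$validation <- val$report
  message("[validate] ", val$report$n_out, " workers out, ",
          val$report$n_rejected, " rejected, ",
          val$report$n_deaths_recoded_to_end, " deaths recoded to end date")

  rates <- config$rates
  if (is.null(rates))
    rates <- list(US = generate_reference_rates(
      if (is.null(cohort$config)) sim_config() else cohort$config))

  pt <- stage("persontime", tabulate_person_time(
    cohort, config$spec, config$follow_up, causes = AN_CAUSES))
  res$person_time <- pt
  message("[persontime] ", round(pt$total_pyr), " person-years")

  res$smr <- list()
  for (lbl in names(rates)) {
    res$smr[[lbl]] <- stage(paste0("smr:", lbl), {
      out <- lapply(config$causes, function(cs)
        smr_table(pt, rates[[lbl]], cs,
                  suppress_below = config$suppression_threshold))
      names(out) <- config$causes
      out
    })
  }

  obs_causes <- table(cohort$workers$cause[
    cohort$workers$vital_status == "dead"])
  rs_causes <- intersect(config$causes, names(obs_causes)[obs_causes >= 2])
  res$risk_sets <- list()
  res$rr <- list()
  for (cs in rs_causes) {
    res$risk_sets[[cs]] <- stage(paste0("risksets:", cs), build_risk_sets(
      cohort, cs, spec = config$spec, follow_up = config$follow_up,
      sample_controls = config$sample_controls, seed = config$seed))
    res$rr[[cs]] <- stage(paste0("rr:", cs), fit_conditional(
      res$risk_sets[[cs]], exposure_terms = "exposed"))
    message("[rr:", cs, "] ", attr(res$risk_sets[[cs]], "n_sets"),
            " risk sets")
  }

  res$nco <- list()
  outcome_cs <- "lung"
  if (outcome_cs %in% names(res$rr)) {
    for (conf_name in names(config$nco_causes)) {
      nc <- config$nco_causes[[conf_name]]
      if (nc %in% names(res$rr)) {
        o <- res$rr[[outcome_cs]]$estimates
        n <- res$rr[[nc]]$estimates
        if (o$identifiable[o$term == "exposed"] &&
            n$identifiable[n$term == "exposed"]) {
          res$nco[[conf_name]] <- stage(paste0("nco:", conf_name), nco_adjust(
            rr_term(res$rr[[outcome_cs]], "exposed"),
            rr_term(res$rr[[nc]], "exposed")))
        }
      }
    }
  }

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    stage("write", {
      write_person_time(pt, file.path(out, "person_time.tsv"))
      for (lbl in names(res$smr))
        for (cs in names(res$smr[[lbl]]))
          write_smr_report(res$smr[[lbl]][[cs]],
                           file.path(out, sprintf("smr_%s_%s.tsv", lbl, cs)),
                           threshold = config$suppression_threshold)
      for (cs in names(res$risk_sets))
        write_risk_sets(res$risk_sets[[cs]],
                        file.path(out, sprintf("risksets_%s.tsv", cs)))
      for (cs in names(res$rr))
        write_rr_report(res$rr[[cs]], file.path(out, sprintf("rr_%s.json", cs)))
      manifest <- list(
        package = "occbias",
        version = as.character(utils::packageVersion("occbias")),
        seed = config$seed,
        follow_up = format(config$follow_up),
        causes = config$causes,
        exclude_plants = config$exclude_plants,
        suppression_threshold = config$suppression_threshold,
        n_workers = nrow(cohort$workers),
        sim_seed = if (!is.null(cohort$config)) cohort$config$seed else NULL
      )
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
    message("[write] reports in ", out)
  }

  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", x$validation$n_out, "workers;",
      round(x$person_time$total_pyr), "person-years;",
      length(x$rr), "rate-ratio models;", length(x$nco),
      "NCO adjustments\n")
  invisible(x)
}
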