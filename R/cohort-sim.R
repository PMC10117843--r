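# Synthetic multi-plant occupational cohort generator. The generator emulates
# the structure of a large AN-exposed production cohort: ~8 plants, hiring
# from 1942 onward, follow-up through 2011, plant-specific ever-smoking
# prevalences, a strong smoking effect on lung cancer (RR ~ 19.1) and COPD,
# a weaker one on bladder cancer (RR ~ 3.5), and an asbestos-confounded
# subcohort at one plant. Exposure effects of the agent under study default
# to the null so that confounding-adjustment methods can be evaluated against
# a known truth.

#' Simulation configuration
#'
#' @param n_workers number of workers.
#' @param n_plants number of plants.
#' @param hire_year_range two calendar years; hiring is uniform over the range.
#'   Must lie within 1942..study end.
#' @param study_end end of follow-up (`Date`).
#' @param plant_smoking_prevalence ever-smoking prevalence per plant
#'   (recycled to `n_plants`).
#' @param rr_smoking_lung,rr_smoking_copd,rr_smoking_bladder multiplicative
#'   smoking effects on the cause-specific hazards. COPD defaults to the lung
#'   value so that smoking confounds the outcome and its negative control by
#'   the same factor (the equi-confounding structure the adjustment assumes).
#' @param mixing probability that an ever-smoker holds an exposed job; the
#'   main knob that induces smoking-exposure confounding.
#' @param p_exposed probability that a never-smoker holds an exposed job.
#' @param intensity_smoking_gradient strength of the rank coupling between
#'   smoking and job exposure intensity among exposed workers (0 = none).
#'   Intensity draws keep their marginal distribution but the higher draws go
#'   preferentially to ever-smokers, putting the smoking-exposure
#'   association on the continuous (ppm, ppm-year) scale as well as the
#'   exposed/unexposed one (smokers concentrated in the dustier,
#'   higher-exposure jobs).
#' @param asbestos_plant plant index carrying extraneous asbestos exposure
#'   (NULL to disable).
#' @param p_asbestos_exposed,p_asbestos_unexposed probability of individual
#'   asbestos exposure within that plant, by AN exposure status.
#' @param rr_asbestos_lung,rr_asbestos_mesothelioma asbestos hazard ratios.
#' @param an_effect_lung lung hazard ratio per exposure category (length =
#'   number of cut-point categories); defaults to the null (all 1).
#' @param intensity_meanlog,intensity_sdlog log-normal parameters of job
#'   exposure intensity (ppm).
#' @param duration_meanlog,duration_sdlog log-normal parameters of employment
#'   duration (years).
#' @param spec [category_spec()] used to evaluate `an_effect_lung` on the
#'   lagged cumulative exposure scale.
#' @param baseline_rates a [rate_table()] of cause-specific baseline rates;
#'   defaults to [generate_reference_rates()] over the study window.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_workers = 5000,
                       n_plants = 8,
                       hire_year_range = c(1942, 1980),
                       study_end = as.Date("2011-12-31"),
                       plant_smoking_prevalence =
                         c(0.71, 0.53, 0.62, 0.78, 0.71, 0.68, 0.67, 0.65),
                       rr_smoking_lung = 19.1,
                       rr_smoking_copd = rr_smoking_lung,
                       rr_smoking_bladder = 3.5,
                       mixing = 0.75,
                       p_exposed = 0.55,
                       intensity_smoking_gradient = 1.0,
                       asbestos_plant = 4,
                       p_asbestos_exposed = 0.5,
                       p_asbestos_unexposed = 0.15,
                       rr_asbestos_lung = 3.0,
                       rr_asbestos_mesothelioma = 10.0,
                       an_effect_lung = rep(1, 5),
                       intensity_meanlog = log(0.5),
                       intensity_sdlog = 1.1,
                       duration_meanlog = log(6),
                       duration_sdlog = 1.1,
                       spec = an_cumulative_spec(),
                       baseline_rates = NULL,
                       seed = 1) {
  study_end <- as_date(study_end)
  if (n_workers < 1) stop("configuration error: n_workers must be >= 1")
  end_year <- as.integer(format(study_end, "%Y"))
  if (hire_year_range[1] < 1942 || hire_year_range[2] > end_year ||
      hire_year_range[1] > hire_year_range[2])
    stop("hire_year_range must lie within [1942, study end year]")
  prev <- rep_len(plant_smoking_prevalence, n_plants)
  stopifnot_probability(prev, "plant_smoking_prevalence")
  stopifnot_probability(c(mixing, p_exposed, p_asbestos_exposed,
                          p_asbestos_unexposed), "assignment probabilities")
  ratios <- c(rr_smoking_lung, rr_smoking_copd, rr_smoking_bladder,
              rr_asbestos_lung, rr_asbestos_mesothelioma, an_effect_lung)
  if (intensity_smoking_gradient < 0)
    stop("intensity_smoking_gradient must be >= 0")
  if (any(ratios <= 0)) stop("all rate ratios must be > 0")
  if (length(an_effect_lung) != length(spec$cutpoints) + 1)
    stop("an_effect_lung must have one ratio per cut-point category")
  cfg <- list(
    n_workers = as.integer(n_workers), n_plants = as.integer(n_plants),
    hire_year_range = hire_year_range, study_end = study_end,
    plant_smoking_prevalence = prev,
    rr_smoking_lung = rr_smoking_lung, rr_smoking_copd = rr_smoking_copd,
    rr_smoking_bladder = rr_smoking_bladder,
    mixing = mixing, p_exposed = p_exposed,
    intensity_smoking_gradient = intensity_smoking_gradient,
    asbestos_plant = asbestos_plant,
    p_asbestos_exposed = p_asbestos_exposed,
    p_asbestos_unexposed = p_asbestos_unexposed,
    rr_asbestos_lung = rr_asbestos_lung,
    rr_asbestos_mesothelioma = rr_asbestos_mesothelioma,
    an_effect_lung = an_effect_lung,
    intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
    duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
    spec = spec, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg$baseline_rates <- if (is.null(baseline_rates))
    generate_reference_rates(cfg) else baseline_rates
  if (nrow(cfg$baseline_rates) == 0)
    stop("configuration error: baseline_rates is empty")
  cfg
}

# rate lookup arrays: one [race, sex, age_group, period] array per cause
#' @noRd
rate_lookup_arrays <- function(rates) {
  ages <- seq(0, 85, by = 5)
  periods <- sort(unique(rates$period))
  out <- list(periods = periods, ages = ages, arr = list())
  for (cs in unique(rates$cause)) {
    a <- array(0, dim = c(2, 2, length(ages), length(periods)))
    rc <- rates[rates$cause == cs, ]
    idx <- cbind(match(rc$race, RACES), match(rc$sex, SEXES),
                 match(rc$age_group, ages), match(rc$period, periods))
    a[idx] <- rc$rate
    out$arr[[cs]] <- a
  }
  out
}

#' Generate a synthetic cohort
#'
#' Runs a yearly discrete-time competing-risks simulation: in each calendar
#' year each surviving worker faces cause-specific hazards equal to the
#' baseline stratum rate times the worker's smoking, asbestos and exposure
#' category multipliers; death and its cause are drawn from the combined
#' hazard. Follow-up continues after termination of employment.
#'
#' @param config a [sim_config()].
#' @return object of class `an_cohort`: a list with `workers` (one row per
#'   worker), `exposure` (one row per exposure segment), `study_end` and the
#'   generating `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$baseline_rates) == 0)
    stop("configuration error: baseline_rates is empty")
  with_seed(config$seed, generate_cohort_impl(config))
}

#' @noRd
generate_cohort_impl <- function(config) {
  n <- config$n_workers
  end_day <- as.numeric(config$study_end)
  end_year <- as.integer(format(config$study_end, "%Y"))

  plant <- sample.int(config$n_plants, n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < 0.88, "male", "female")
  race <- ifelse(stats::runif(n) < 0.84, "white", "nonwhite")
  pay_type <- ifelse(stats::runif(n) < 0.70, "wage", "salary")

  hire_year <- sample(seq(config$hire_year_range[1], config$hire_year_range[2]),
                      n, replace = TRUE)
  year_start <- as.numeric(as.Date(paste0(hire_year, "-01-01")))
  year_len <- as.numeric(as.Date(paste0(hire_year + 1, "-01-01"))) - year_start
  hire_day <- year_start + floor(stats::runif(n) * year_len)

  age_at_hire <- pmin(18 + stats::rgamma(n, shape = 2.5, scale = 4), 62)
  birth_day <- hire_day - round(years_to_days(age_at_hire))

  dur_years <- pmax(0.1, stats::rlnorm(n, config$duration_meanlog,
                                       config$duration_sdlog))

  smoker <- as.integer(stats::runif(n) <
                         config$plant_smoking_prevalence[plant])
  p_exp <- ifelse(smoker == 1, config$mixing, config$p_exposed)
  exposed_job <- stats::runif(n) < p_exp

  # rank coupling of smoking with the exposed career's duration: marginal
  # duration distribution among exposed workers is untouched, but the longer
  # careers go preferentially to ever-smokers, so the smoking-exposure
  # association spans the full cumulative (ppm-year) range
  if (config$intensity_smoking_gradient > 0 && any(exposed_job)) {
    ei <- which(exposed_job)
    v <- stats::runif(length(ei)) +
      config$intensity_smoking_gradient * smoker[ei]
    dur_years[ei] <- sort(dur_years[ei])[rank(v, ties.method = "first")]
  }

  term_day <- pmin(hire_day + round(years_to_days(dur_years)), end_day)
  term_day <- pmax(term_day, hire_day + 30)  # at least a month on the books

  asbestos <- integer(n)
  if (!is.null(config$asbestos_plant)) {
    in_plant <- plant == config$asbestos_plant
    p_asb <- ifelse(exposed_job, config$p_asbestos_exposed,
                    config$p_asbestos_unexposed)
    asbestos[in_plant] <- as.integer(stats::runif(sum(in_plant)) <
                                       p_asb[in_plant])
  }

  # exposure segments: exposed jobs span employment at log-normal intensity;
  # half the workers switch jobs once, giving a second independent intensity
  s1 <- e1 <- i1 <- s2 <- e2 <- i2 <- rep(NA_real_, n)
  exp_idx <- which(exposed_job)
  if (length(exp_idx)) {
    inten_a <- stats::rlnorm(length(exp_idx), config$intensity_meanlog,
                             config$intensity_sdlog)
    # rank coupling: the marginal intensity distribution is untouched, but
    # higher draws are routed preferentially to ever-smokers
    u <- stats::runif(length(exp_idx)) +
      config$intensity_smoking_gradient * smoker[exp_idx]
    inten_a <- sort(inten_a)[rank(u, ties.method = "first")]
    split <- stats::runif(length(exp_idx)) < 0.5
    frac <- 0.2 + 0.6 * stats::runif(length(exp_idx))
    mid <- hire_day[exp_idx] +
      round(frac * (term_day[exp_idx] - hire_day[exp_idx]))
    s1[exp_idx] <- hire_day[exp_idx]
    e1[exp_idx] <- ifelse(split, mid, term_day[exp_idx])
    i1[exp_idx] <- inten_a
    long_enough <- split & (term_day[exp_idx] - mid >= 1)
    k <- which(long_enough)
    if (length(k)) {
      s2[exp_idx[k]] <- mid[k]
      e2[exp_idx[k]] <- term_day[exp_idx[k]]
      i2_draw <- stats::rlnorm(length(k), config$intensity_meanlog,
                               config$intensity_sdlog)
      i2[exp_idx[k]] <- sort(i2_draw)[rank(u[k], ties.method = "first")]
    }
    e1[exp_idx][e1[exp_idx] <= s1[exp_idx]] <-
      s1[exp_idx][e1[exp_idx] <= s1[exp_idx]] + 1
  }

  lk <- rate_lookup_arrays(config$baseline_rates)
  race_i <- match(race, RACES); sex_i <- match(sex, SEXES)
  rr_s <- c(lung = config$rr_smoking_lung, bladder = config$rr_smoking_bladder,
            mesothelioma = 1, pneumonitis = 1, copd = config$rr_smoking_copd,
            other = 1)
  rr_a <- c(lung = config$rr_asbestos_lung, bladder = 1,
            mesothelioma = config$rr_asbestos_mesothelioma,
            pneumonitis = 1, copd = 1, other = 1)
  an_null <- all(config$an_effect_lung == 1)
  lag_d <- years_to_days(config$spec$lag)

  alive <- rep(TRUE, n)
  death_day <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)

  for (y in seq(min(hire_year), end_year)) {
    y0 <- as.numeric(as.Date(paste0(y, "-01-01")))
    y1 <- min(as.numeric(as.Date(paste0(y + 1, "-01-01"))), end_day + 1)
    idx <- which(alive & hire_day < y1)
    if (!length(idx)) next
    a0 <- pmax(hire_day[idx], y0)
    frac <- (y1 - a0) / DAYS_PER_YEAR
    mid <- (a0 + y1) / 2
    age_mid <- (mid - birth_day[idx]) / DAYS_PER_YEAR
    ai <- pmin(floor(age_mid / 5), 17) + 1
    pi <- match(period_of(y), lk$periods)
    if (is.na(pi)) pi <- if (y < lk$periods[1]) 1L else length(lk$periods)
    sub <- cbind(race_i[idx], sex_i[idx], ai, rep(pi, length(idx)))

    h <- matrix(0, length(idx), length(AN_CAUSES),
                dimnames = list(NULL, AN_CAUSES))
    for (cs in AN_CAUSES) {
      base <- lk$arr[[cs]][sub]
      m <- ifelse(smoker[idx] == 1, rr_s[[cs]], 1) *
        ifelse(asbestos[idx] == 1, rr_a[[cs]], 1)
      h[, cs] <- base * m
    }
    if (!an_null) {
      ct <- mid - lag_d
      cum <- (ifelse(is.na(s1[idx]), 0,
                     pmax(0, pmin(e1[idx], ct) - s1[idx]) *
                       ifelse(is.na(i1[idx]), 0, i1[idx])) +
              ifelse(is.na(s2[idx]), 0,
                     pmax(0, pmin(e2[idx], ct) - s2[idx]) *
                       ifelse(is.na(i2[idx]), 0, i2[idx]))) / DAYS_PER_YEAR
      cat_i <- 1L + rowSums(outer(cum, config$spec$cutpoints, `>`))
      h[, "lung"] <- h[, "lung"] * config$an_effect_lung[cat_i]
    }
    h_tot <- rowSums(h)
    p_die <- 1 - exp(-h_tot * frac)
    u <- stats::runif(length(idx))
    dies <- which(u < p_die & h_tot > 0)
    if (length(dies)) {
      cum_h <- h[dies, , drop = FALSE]
      cum_h <- t(apply(cum_h, 1, cumsum))
      r <- stats::runif(length(dies)) * h_tot[dies]
      cause_i <- 1L + rowSums(cum_h < r)
      w <- idx[dies]
      alive[w] <- FALSE
      cause[w] <- AN_CAUSES[pmin(cause_i, length(AN_CAUSES))]
      death_day[w] <- a0[dies] + floor(stats::runif(length(dies)) *
                                         pmax(1, y1 - a0[dies]))
    }
  }

  workers <- data.frame(
    worker_id = sprintf("W%05d", seq_len(n)),
    plant = plant, race = race, sex = sex, pay_type = pay_type,
    birth_date = as.Date(birth_day, origin = "1970-01-01"),
    hire_date = as.Date(hire_day, origin = "1970-01-01"),
    termination_date = as.Date(term_day, origin = "1970-01-01"),
    ever_smoker = smoker, asbestos_exposed = asbestos,
    vital_status = ifelse(alive, "alive", "dead"),
    death_date = as.Date(ifelse(alive, NA, death_day), origin = "1970-01-01"),
    cause = ifelse(alive, NA_character_, cause),
    stringsAsFactors = FALSE
  )
  seg <- rbind(
    data.frame(worker_id = workers$worker_id, start = s1, end = e1, intensity = i1),
    data.frame(worker_id = workers$worker_id, start = s2, end = e2, intensity = i2)
  )
  seg <- seg[!is.na(seg$start), , drop = FALSE]
  seg$start <- as.Date(seg$start, origin = "1970-01-01")
  seg$end <- as.Date(seg$end, origin = "1970-01-01")
  seg <- seg[order(seg$worker_id, seg$start), , drop = FALSE]
  rownames(seg) <- NULL

  structure(list(workers = workers, exposure = seg,
                 study_end = config$study_end, config = config),
            class = "an_cohort")
}

#' Assemble a cohort object from worker and exposure tables
#'
#' @param workers data.frame, one row per worker (see [generate_cohort()] for
#'   the column schema).
#' @param exposure data.frame of exposure segments (`worker_id`, `start`,
#'   `end`, `intensity`).
#' @param study_end end of follow-up.
#' @export
an_cohort <- function(workers, exposure, study_end) {
  for (col in c("birth_date", "hire_date", "termination_date", "death_date"))
    if (col %in% names(workers)) workers[[col]] <- as_date(workers[[col]])
  if (nrow(exposure)) {
    exposure$start <- as_date(exposure$start)
    exposure$end <- as_date(exposure$end)
  }
  structure(list(workers = workers, exposure = exposure,
                 study_end = as_date(study_end), config = NULL),
            class = "an_cohort")
}

#' @export
print.an_cohort <- function(x, ...) {
  w <- x$workers
  cat("Synthetic occupational cohort:", nrow(w), "workers,",
      length(unique(w$plant)), "plants\n")
  cat("  follow-up through", format(x$study_end), "\n")
  cat("  deaths:", sum(w$vital_status == "dead"), "   exposed workers:",
      length(unique(x$exposure$worker_id)), "\n")
  invisible(x)
}

#' Small deterministic cohort for examples and tests
#'
#' @param n number of workers (default 200).
#' @param seed RNG seed.
#' @param ... further arguments to [sim_config()].
#' @export
cohort_fixture <- function(n = 200, seed = 42, ...) {
  generate_cohort(sim_config(n_workers = n, seed = seed, ...))
}

# wide per-worker segment matrices (row order = workers row order) for fast
# vectorised exposure evaluation
#' @noRd
exposure_wide <- function(cohort) {
  w <- cohort$workers
  seg <- cohort$exposure
  n <- nrow(w)
  if (nrow(seg) == 0) {
    return(list(s = matrix(NA_real_, n, 1), e = matrix(NA_real_, n, 1),
                i = matrix(NA_real_, n, 1), first = rep(Inf, n)))
  }
  seg <- seg[order(seg$worker_id, seg$start), ]
  row <- match(seg$worker_id, w$worker_id)
  k <- stats::ave(seq_len(nrow(seg)), row, FUN = seq_along)
  kmax <- max(k)
  s <- e <- i <- matrix(NA_real_, n, kmax)
  s[cbind(row, k)] <- as.numeric(seg$start)
  e[cbind(row, k)] <- as.numeric(seg$end)
  i[cbind(row, k)] <- seg$intensity
  first <- rep(Inf, n)
  tt <- tapply(as.numeric(seg$start), row, min)
  first[as.integer(names(tt))] <- as.vector(tt)
  list(s = s, e = e, i = i, first = first)
}

# vectorised lagged cumulative exposure / AIE at one date per worker row
#' @noRd
cum_at_wide <- function(wide, rows, at_day, lag) {
  ct <- at_day - years_to_days(lag)
  s <- wide$s[rows, , drop = FALSE]
  e <- wide$e[rows, , drop = FALSE]
  i <- wide$i[rows, , drop = FALSE]
  ov <- pmin(e, ct) - s
  ov[is.na(ov) | ov < 0] <- 0
  ii <- i; ii[is.na(ii)] <- 0
  list(cum = rowSums(ii * ov) / DAYS_PER_YEAR,
       dur = rowSums(ov) / DAYS_PER_YEAR)
}
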