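# Synthetic cohort generator.

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(sim_config(n_workers = 300, seed = 1))
  b <- generate_cohort(sim_config(n_workers = 300, seed = 1))
  expect_identical(a$workers, b$workers)
  expect_identical(a$exposure, b$exposure)
  c2 <- generate_cohort(sim_config(n_workers = 300, seed = 2))
  expect_false(identical(a$workers, c2$workers))
  # reference tables are a deterministic function of the configuration
  expect_identical(generate_reference_rates(sim_config(seed = 1)),
                   generate_reference_rates(sim_config(seed = 1)))
})

test_that("structural invariants hold on generated cohorts", {
  ch <- generate_cohort(sim_config(n_workers = 400, seed = 3))
  w <- ch$workers
  expect_true(all(w$birth_date < w$hire_date))
  expect_true(all(w$hire_date < w$termination_date))
  expect_true(all(w$termination_date <= ch$study_end))
  dead <- w$vital_status == "dead"
  expect_true(all(!is.na(w$cause[dead])))
  expect_true(all(is.na(w$cause[!dead])))
  expect_true(all(w$death_date[dead] >= w$hire_date[dead]))
  expect_true(all(w$death_date[dead] <= ch$study_end))

  e <- ch$exposure
  expect_true(all(e$intensity >= 0))
  expect_true(all(e$end > e$start))
  m <- merge(e, w[c("worker_id", "hire_date", "termination_date")])
  expect_true(all(m$start >= m$hire_date & m$end <= m$termination_date))
  for (id in unique(e$worker_id)) {
    s <- e[e$worker_id == id, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1)
      expect_true(all(as.numeric(s$start[-1]) >= as.numeric(s$end[-nrow(s)])))
  }
  # a fraction of workers is never exposed
  expect_gt(sum(!(w$worker_id %in% e$worker_id)), 0)
})

test_that("null hazards leave every worker alive at study end", {
  cfg <- sim_config(n_workers = 200, seed = 5)
  null_rates <- cfg$baseline_rates
  null_rates$rate <- 0
  cfg0 <- sim_config(n_workers = 200, seed = 5, baseline_rates = null_rates)
  ch <- generate_cohort(cfg0)
  expect_true(all(ch$workers$vital_status == "alive"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_workers = 0), "n_workers")
  expect_error(sim_config(hire_year_range = c(1930, 1980)), "1942")
  expect_error(sim_config(plant_smoking_prevalence = c(0.5, 1.4)),
               "probability")
  expect_error(sim_config(rr_smoking_lung = -2), "> 0")
  expect_error(sim_config(an_effect_lung = rep(1, 3)), "per cut-point")
  cfg <- sim_config(n_workers = 50)
  cfg$baseline_rates <- cfg$baseline_rates[0, ]
  expect_error(generate_cohort(cfg), "baseline_rates is empty")
})

test_that("per-plant smoker shares track the configured prevalences", {
  cfg <- sim_config(n_workers = 5000, seed = 8)
  ch <- generate_cohort(cfg)
  w <- ch$workers
  for (p in seq_len(cfg$n_plants)) {
    n_p <- sum(w$plant == p)
    phat <- mean(w$ever_smoker[w$plant == p])
    p0 <- cfg$plant_smoking_prevalence[p]
    expect_lt(abs(phat - p0), 4 * sqrt(p0 * (1 - p0) / n_p))
  }
})

test_that("the smoking-lung hazard ratio is recovered from the generated data", {
  # null exposure effect, no asbestos: the ever/never-smoker lung death rate
  # ratio, age-stratified (Mantel-Haenszel), should sit near the configured
  # 19.1 within Monte Carlo error
  cfg <- sim_config(n_workers = 20000, seed = 13,
                    rr_asbestos_lung = 1, rr_asbestos_mesothelioma = 1)
  ch <- generate_cohort(cfg)
  w <- ch$workers
  fu_end <- as.numeric(ch$study_end)

  strata_of <- function(rows) {
    # person-years and lung deaths by 5-year age band for a subgroup
    entry <- as.numeric(w$hire_date[rows])
    exit <- ifelse(w$vital_status[rows] == "dead",
                   as.numeric(w$death_date[rows]), fu_end + 1)
    birth <- as.numeric(w$birth_date[rows])
    is_lung <- w$vital_status[rows] == "dead" & !is.na(w$cause[rows]) &
      w$cause[rows] == "lung"
    bands <- seq(0, 100, by = 5)
    py <- deaths <- numeric(length(bands))
    for (b in seq_along(bands)) {
      a0 <- birth + bands[b] * 365.25
      a1 <- birth + (bands[b] + 5) * 365.25
      ov <- pmax(0, pmin(exit, a1) - pmax(entry, a0))
      py[b] <- sum(ov) / 365.25
      age_death <- (as.numeric(w$death_date[rows]) - birth) / 365.25
      deaths[b] <- sum(is_lung & !is.na(age_death) &
                         age_death >= bands[b] & age_death < bands[b] + 5)
    }
    list(py = py, deaths = deaths)
  }
  sm <- strata_of(which(w$ever_smoker == 1))
  ns <- strata_of(which(w$ever_smoker == 0))
  mh <- bf_mh_rate_ratio(sm$deaths, sm$py, ns$deaths, ns$py)
  se_log <- sqrt(1 / sum(sm$deaths) + 1 / sum(ns$deaths))
  expect_lt(abs(log(mh) - log(19.1)), 3 * se_log)
})
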