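# Shared fixtures and independent (brute-force) oracles. Everything here is
# deliberately naive: plain loops and first-principles formulas, so the
# implementations under test are checked against a second, unrelated route.

# hand-checkable toy cohort: three workers, one lung death at an exact age
toy_cohort <- function(birth_years = c(1940, 1940, 1941)) {
  birth <- as.Date(paste0(birth_years, "-01-15"))
  hire <- as.Date(c("1965-03-01", "1966-05-01", "1964-07-01"))
  death_a <- birth[1] + round(60 * 365.25)  # A dies of lung at age 60 exactly
  workers <- data.frame(
    worker_id = c("A", "B", "C"),
    plant = c(1L, 1L, 2L),
    race = "white", sex = "male",
    pay_type = c("wage", "wage", "salary"),
    birth_date = birth,
    hire_date = hire,
    termination_date = as.Date(c("1990-01-01", "1992-01-01", "1988-01-01")),
    ever_smoker = c(1L, 0L, 1L),
    asbestos_exposed = 0L,
    vital_status = c("dead", "alive", "alive"),
    death_date = c(death_a, NA, NA),
    cause = c("lung", NA, NA),
    stringsAsFactors = FALSE
  )
  exposure <- data.frame(
    worker_id = c("A", "B"),
    start = as.Date(c("1965-03-01", "1966-05-01")),
    end = as.Date(c("1980-01-01", "1985-01-01")),
    intensity = c(1.2, 0.4),
    stringsAsFactors = FALSE
  )
  an_cohort(workers, exposure, as.Date("2011-12-31"))
}

# independent conditional log-likelihood (naive loops)
bf_clogit_loglik <- function(beta, X, set, case) {
  ll <- 0
  for (s in unique(set)) {
    rows <- which(set == s)
    eta <- as.vector(X[rows, , drop = FALSE] %*% beta)
    ll <- ll + eta[case[rows]] - log(sum(exp(eta)))
  }
  ll
}

# brute-force risk-set membership from first principles
bf_risk_set_members <- function(cohort, cause, caliper, fu = NULL) {
  w <- cohort$workers
  if (is.null(fu)) fu <- c(as.Date("1942-01-01"), cohort$study_end)
  birth <- as.numeric(w$birth_date); hire <- as.numeric(w$hire_date)
  death <- as.numeric(w$death_date)
  by <- as.integer(format(w$birth_date, "%Y"))
  end_day <- pmin(ifelse(is.na(death), Inf, death), as.numeric(cohort$study_end))
  is_index <- w$vital_status == "dead" & !is.na(w$cause) & w$cause == cause
  cases <- which(is_index & death >= as.numeric(fu[1]) & death <= as.numeric(fu[2]))
  cases <- cases[order(death[cases], w$worker_id[cases])]
  lapply(cases, function(cr) {
    age_days <- death[cr] - birth[cr]
    members <- character(0)
    for (j in seq_len(nrow(w))) {
      if (j == cr) next
      d <- birth[j] + age_days
      ok <- d >= hire[j] && d <= end_day[j] &&
        d >= as.numeric(fu[1]) && d <= as.numeric(fu[2]) &&
        abs(by[j] - by[cr]) <= caliper &&
        !(is_index[j] && !is.na(death[j]) && death[j] == d)
      if (ok) members <- c(members, w$worker_id[j])
    }
    list(case = w$worker_id[cr], controls = sort(members))
  })
}

# direct Mantel-Haenszel rate ratio over age strata (person-year data)
bf_mh_rate_ratio <- function(d1, y1, d0, y0) {
  keep <- (y1 > 0 & y0 > 0)
  num <- sum(d1[keep] * y0[keep] / (y1[keep] + y0[keep]))
  den <- sum(d0[keep] * y1[keep] / (y1[keep] + y0[keep]))
  num / den
}

# build matched risk-set data directly (no cohort): n_sets sets of given size,
# case drawn with probability proportional to exp(x' beta_true)
simulate_risk_sets <- function(n_sets, size, xfun, beta_true, seed) {
  set.seed(seed)
  out <- lapply(seq_len(n_sets), function(s) {
    X <- xfun(size)
    eta <- as.vector(X %*% beta_true)
    p <- exp(eta - max(eta)); p <- p / sum(p)
    case_row <- sample.int(size, 1, prob = p)
    data.frame(set = s, case = seq_len(size) == case_row, X)
  })
  do.call(rbind, out)
}
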