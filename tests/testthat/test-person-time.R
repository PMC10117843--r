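# Person-time splitting and conservation.

test_that("a worker inside one cell contributes exactly that cell", {
  # age 50.0x, period 2000-2004, never exposed, one year of follow-up
  w <- data.frame(
    worker_id = "W1", plant = 1L, race = "white", sex = "male",
    pay_type = "wage", birth_date = as.Date("1951-01-06"),
    hire_date = as.Date("2001-02-01"), termination_date = as.Date("2002-02-01"),
    ever_smoker = 0L, asbestos_exposed = 0L, vital_status = "alive",
    death_date = as.Date(NA), cause = NA_character_, stringsAsFactors = FALSE)
  ch <- an_cohort(w, data.frame(worker_id = character(0), start = as.Date(character(0)),
                                end = as.Date(character(0)), intensity = numeric(0)),
                  as.Date("2002-01-31"))
  pt <- tabulate_person_time(ch, follow_up = c(as.Date("2001-02-01"),
                                               as.Date("2002-01-31")))
  expect_identical(nrow(pt$pyr), 1L)
  expect_identical(pt$pyr$age_group, 50L)
  expect_identical(pt$pyr$period, 2000L)
  expect_identical(pt$pyr$category, 0L)
  expect_equal(pt$pyr$pyr, 365 / 365.25)   # one year of days, half-open
  expect_equal(pt$total_pyr, pt$pyr$pyr)
})

test_that("person-time is conserved across the cell partition", {
  ch <- cohort_fixture(n = 150, seed = 5)
  fu <- c(as.Date("1942-01-01"), ch$study_end)
  pt <- tabulate_person_time(ch, follow_up = fu)
  w <- ch$workers
  entry <- pmax(as.numeric(w$hire_date), as.numeric(fu[1]))
  exit <- ifelse(w$vital_status == "dead",
                 pmin(as.numeric(w$death_date), as.numeric(fu[2]) + 1),
                 as.numeric(fu[2]) + 1)
  expect_equal(pt$total_pyr, sum(pmax(0, exit - entry)) / 365.25,
               tolerance = 1e-6)
  expect_true(all(pt$pyr$pyr >= 0))
  # every death maps to exactly one cell
  expect_identical(sum(pt$deaths$deaths),
                   sum(w$vital_status == "dead" &
                         w$death_date >= fu[1] & w$death_date <= fu[2]))
})

test_that("an age-group boundary splits the interval at the boundary date", {
  birth <- as.Date("1941-06-15")
  w <- data.frame(
    worker_id = "W1", plant = 1L, race = "white", sex = "male",
    pay_type = "wage", birth_date = birth,
    hire_date = as.Date("2001-01-01"), termination_date = as.Date("2002-01-01"),
    ever_smoker = 0L, asbestos_exposed = 0L, vital_status = "alive",
    death_date = as.Date(NA), cause = NA_character_, stringsAsFactors = FALSE)
  ch <- an_cohort(w, data.frame(worker_id = character(0), start = as.Date(character(0)),
                                end = as.Date(character(0)), intensity = numeric(0)),
                  as.Date("2001-12-31"))
  fu <- c(as.Date("2001-01-01"), as.Date("2001-12-31"))
  pt <- tabulate_person_time(ch, follow_up = fu)
  # turns 60 mid-2001: split at birth + ceiling(60 * 365.25) days
  boundary <- as.numeric(birth) + ceiling(60 * 365.25)
  expect_identical(nrow(pt$pyr), 2L)
  expect_identical(sort(pt$pyr$age_group), c(55L, 60L))
  expect_equal(sum(pt$pyr$pyr), 365 / 365.25, tolerance = 1e-9)
  expect_equal(pt$pyr$pyr[pt$pyr$age_group == 55],
               (boundary - as.numeric(fu[1])) / 365.25, tolerance = 1e-9)
})

test_that("cells agree with a brute-force daily traversal", {
  ch <- cohort_fixture(n = 15, seed = 9, hire_year_range = c(1960, 1980))
  fu <- c(as.Date("1942-01-01"), ch$study_end)
  for (spec in list(an_cumulative_spec(), an_intensity_spec())) {
    pt <- tabulate_person_time(ch, spec, follow_up = fu)
    seg <- split(ch$exposure, ch$exposure$worker_id)
    acc <- new.env()
    for (r in seq_len(nrow(ch$workers))) {
      w <- ch$workers[r, ]
      entry <- max(as.numeric(w$hire_date), as.numeric(fu[1]))
      exit <- if (w$vital_status == "dead") as.numeric(w$death_date)
              else as.numeric(fu[2]) + 1
      if (exit <= entry) next
      days <- seq(entry, exit - 1)
      dts <- as.Date(days, origin = "1970-01-01")
      h <- seg[[w$worker_id]]
      val <- if (is.null(h)) rep(0, length(days))
             else if (spec$kind == "cumulative") cumulative_exposure(h, dts, spec$lag)
             else average_intensity(h, dts, spec$lag)
      everexp <- if (is.null(h)) rep(FALSE, length(days))
                 else days >= as.numeric(min(h$start))
      cat_i <- classify_exposure(val, spec, everexp)
      age_grp <- pmin(floor(((days - as.numeric(w$birth_date)) / 365.25) / 5) * 5, 85)
      period <- floor(as.integer(format(dts, "%Y")) / 5) * 5
      key <- paste(w$race, w$sex, age_grp, period, cat_i, sep = "|")
      for (kk in unique(key)) {
        prev <- if (is.null(acc[[kk]])) 0 else acc[[kk]]
        acc[[kk]] <- prev + sum(key == kk)
      }
    }
    got <- pt$pyr
    got_key <- paste(got$race, got$sex, got$age_group, got$period, got$category,
                     sep = "|")
    expect_setequal(got_key, ls(acc))
    for (kk in got_key) {
      expect_equal(got$pyr[got_key == kk] * 365.25, acc[[kk]], tolerance = 1e-8,
                   label = paste("cell", kk, "(", spec$kind, ")"))
    }
  }
})

test_that("a death before hire is a named validation error", {
  ch <- toy_cohort()
  ch$workers$death_date[1] <- ch$workers$hire_date[1] - 10
  expect_error(tabulate_person_time(ch), "death before hire.*A")
})
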