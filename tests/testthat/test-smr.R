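# Indirect standardization: expected deaths, exact Poisson limits, ratios,
# trend.

make_pt <- function(pyr_df, deaths_df, spec = an_cumulative_spec()) {
  structure(list(pyr = pyr_df, deaths = deaths_df, spec = spec,
                 follow_up = as.Date(c("1942-01-01", "2011-12-31")),
                 total_pyr = sum(pyr_df$pyr)),
            class = "person_time_table")
}

test_that("expected deaths are person-years times rates, summed over strata", {
  pyr <- data.frame(race = "white", sex = "male", age_group = 60L,
                    period = 1990L, category = 1L, pyr = 1000)
  deaths <- data.frame(race = character(0), sex = character(0),
                       age_group = integer(0), period = integer(0),
                       category = integer(0), cause = character(0),
                       deaths = integer(0))
  rt <- rate_table(data.frame(cause = "lung", race = "white", sex = "male",
                              age_group = 60L, period = 1990L, rate = 0.002))
  ed <- expected_deaths(make_pt(pyr, deaths), rt, "lung")
  expect_equal(ed$expected, 2.0)

  # zero person-years: zero expected
  pyr0 <- pyr; pyr0$pyr <- 0
  expect_equal(expected_deaths(make_pt(pyr0, deaths), rt, "lung")$expected, 0)

  # random multi-cell table against a brute-force loop
  set.seed(3)
  g <- expand.grid(race = c("white", "nonwhite"), sex = c("male", "female"),
                   age_group = c(50L, 55L), period = c(1980L, 1985L),
                   stringsAsFactors = FALSE)
  g$category <- rep(1:2, length.out = nrow(g))
  g$pyr <- runif(nrow(g), 10, 500)
  rt2 <- g[c("race", "sex", "age_group", "period")]
  rt2 <- unique(rt2); rt2$cause <- "lung"; rt2$rate <- runif(nrow(rt2), 0, 0.01)
  ed2 <- expected_deaths(make_pt(g, deaths), rate_table(rt2), "lung")
  for (k in unique(g$category)) {
    bf <- 0
    for (i in which(g$category == k)) {
      j <- which(rt2$race == g$race[i] & rt2$sex == g$sex[i] &
                   rt2$age_group == g$age_group[i] & rt2$period == g$period[i])
      bf <- bf + g$pyr[i] * rt2$rate[j]
    }
    expect_equal(ed2$expected[ed2$category == k], bf, tolerance = 1e-10)
  }

  # a stratum with person-time but no rate is an error naming the stratum
  rt3 <- rate_table(rt2[-1, ])
  expect_error(expected_deaths(make_pt(g, deaths), rt3, "lung"),
               "missing rate cell")
})

test_that("exact Poisson limits reproduce a published SMR row and the
           chi-square formulation", {
  # printed row: O = 808, SMR 0.86 -> CI (0.80-0.92) at two decimals
  E <- 808 / 0.86
  r <- smr_with_ci(808, E)
  expect_equal(round(r$smr, 2), 0.86)
  expect_equal(round(r$ci_low, 2), 0.80)
  expect_equal(round(r$ci_high, 2), 0.92)

  r0 <- smr_with_ci(0, 5)
  expect_identical(r0$smr, 0)
  expect_identical(r0$ci_low, 0)

  # equivalence with the chi-square/2 closed form at O = 4, E = 2
  r4 <- smr_with_ci(4, 2)
  expect_equal(r4$ci_low, qchisq(0.025, 2 * 4) / 2 / 2, tolerance = 1e-12)
  expect_equal(r4$ci_high, qchisq(0.975, 2 * (4 + 1)) / 2 / 2, tolerance = 1e-12)

  expect_error(smr_with_ci(4, 0), "expected")
  expect_true(smr_with_ci(4, 2)$suppressed)
  expect_false(smr_with_ci(40, 20)$suppressed)
})

test_that("SMR ratios reproduce the in-text internal/external contrasts", {
  expect_equal(round(smr_ratio(1.00, 0.72), 2), 1.39)
  expect_equal(smr_ratio(0.87, 0.87), 1.0)
  # the pneumonitis contrast: 0.94 over a (suppressed) baseline of 0.25
  expect_equal(round(smr_ratio(0.94, 0.25), 2), 3.76)
  expect_error(smr_ratio(1, 0), "> 0")
})

test_that("the Poisson trend test is flat at the null and sharp with signal", {
  flat <- data.frame(observed = rep(50L, 5), expected = rep(50, 5))
  expect_gt(smr_trend_test(flat)$p_value, 0.99)

  inj <- data.frame(observed = round(50 * exp(0.5 * (1:5))),
                    expected = rep(50, 5))
  expect_lt(smr_trend_test(inj)$p_value, 0.01)

  # permutation oracle: the monotone ordering is extreme among score
  # permutations of the injected-trend data
  set.seed(8)
  slope_obs <- abs(smr_trend_test(inj)$slope)
  perms <- replicate(100, sample(5))
  slopes <- apply(perms, 2, function(sc)
    abs(smr_trend_test(inj, scores = sc)$slope))
  expect_gte(mean(slope_obs >= slopes), 0.95)

  expect_error(smr_trend_test(flat[1:2, ]), ">= 3")
})

test_that("self-derived rates give SMR exactly 1 and rates scale inversely", {
  ch <- cohort_fixture(n = 250, seed = 12)
  pt <- tabulate_person_time(ch)
  self_rates <- rates_from_person_time(pt)
  for (cs in unique(pt$deaths$cause)) {
    tab <- smr_table(pt, self_rates, cs)
    all_row <- tab[tab$category == "all", ]
    expect_equal(all_row$smr, 1.0, tolerance = 1e-9)
  }
  # multiplying all rates by c divides every SMR by c
  doubled <- self_rates; doubled$rate <- doubled$rate * 2
  cs <- unique(pt$deaths$cause)[1]
  t1 <- smr_table(pt, self_rates, cs)
  t2 <- smr_table(pt, rate_table(as.data.frame(doubled)), cs)
  expect_equal(t2$smr, t1$smr / 2, tolerance = 1e-12)
})
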