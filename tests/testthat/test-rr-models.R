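# Conditional-likelihood rate-ratio models.

test_that("matched discordant pairs reproduce the closed form log(n10/n01)", {
  # 8 pairs with the case exposed, 2 with the control exposed -> RR = 4
  pairs <- do.call(rbind, lapply(1:10, function(s) {
    case_exposed <- s <= 8
    data.frame(set = s, case = c(TRUE, FALSE),
               exposed = if (case_exposed) c(1, 0) else c(0, 1))
  }))
  fit <- fit_conditional(pairs, exposure_terms = "exposed", covariates = NULL)
  expect_equal(fit$estimates$beta, log(8 / 2), tolerance = 1e-8)
  expect_equal(fit$estimates$rr, 4.0, tolerance = 1e-7)
  # rr = exp(beta) exactly, CI brackets the estimate
  expect_identical(fit$estimates$rr, exp(fit$estimates$beta))
  expect_true(fit$estimates$ci_low < 4 && 4 < fit$estimates$ci_high)
})

test_that("fits match brute-force maximization on small instances", {
  for (seed in 1:10) {
    set.seed(seed)
    n_sets <- sample(3:6, 1)
    p <- sample(1:2, 1)
    rs <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
      size <- sample(2:4, 1)
      X <- matrix(round(runif(size * p, 0, 3), 1), size, p)
      d <- data.frame(set = s, case = seq_len(size) == sample.int(size, 1))
      d$x1 <- X[, 1]; if (p == 2) d$x2 <- X[, 2]
      d
    }))
    terms <- if (p == 2) c("x1", "x2") else "x1"
    fit <- fit_conditional(rs, exposure_terms = terms, covariates = NULL)
    if (!all(fit$estimates$identifiable) || fit$separated) next
    X <- as.matrix(rs[terms])
    bf <- optim(rep(0, p), function(b) -bf_clogit_loglik(b, X, rs$set, rs$case),
                method = if (p == 1) "Brent" else "Nelder-Mead",
                lower = if (p == 1) -10 else -Inf,
                upper = if (p == 1) 10 else Inf,
                control = list(reltol = 1e-12, maxit = 5000))
    skip_large <- max(abs(bf$par)) > 8  # near-separated instance
    if (!skip_large)
      expect_equal(fit$estimates$beta, bf$par, tolerance = 1e-3,
                   label = paste("seed", seed))
    # likelihood at the optimum dominates 1000 random draws
    ll_hat <- bf_clogit_loglik(fit$estimates$beta, X, rs$set, rs$case)
    draws <- matrix(runif(1000 * p, -3, 3), ncol = p)
    ll_draws <- apply(draws, 1, function(b)
      bf_clogit_loglik(b, X, rs$set, rs$case))
    expect_true(all(ll_hat >= ll_draws - 1e-9))
  }
})

test_that("the fit agrees with survival::clogit on a moderate data set", {
  skip_if_not_installed("survival")
  library(survival)
  ch <- cohort_fixture(n = 400, seed = 23)
  rs <- build_risk_sets(ch, "lung", sample_controls = 10, seed = 2)
  fit <- fit_conditional(rs, exposure_terms = "exposed")
  d <- as.data.frame(rs)
  d$exposed <- as.numeric(d$category > 0)
  cl <- survival::clogit(
    case ~ exposed + I(race == "white") + I(sex == "male") +
      I(pay_type == "wage") + strata(set), data = d)
  # term order differs; compare the exposure coefficient and its SE
  expect_equal(unname(coef(cl)["exposed"]),
               fit$estimates$beta[fit$estimates$term == "exposed"],
               tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(cl)))["exposed"]),
               fit$estimates$se[fit$estimates$term == "exposed"],
               tolerance = 1e-6)
})

test_that("within-set constant shifts leave the fit unchanged", {
  set.seed(44)
  rs <- simulate_risk_sets(30, 4, function(m) matrix(runif(m, 0, 5)), 0.3,
                           seed = 44)
  names(rs)[3] <- "x"
  f1 <- fit_conditional(rs, "x", covariates = NULL)
  rs2 <- rs
  shift <- rnorm(30)[rs2$set]
  rs2$x <- rs2$x + shift
  f2 <- fit_conditional(rs2, "x", covariates = NULL)
  expect_equal(f1$estimates$beta, f2$estimates$beta, tolerance = 1e-7)
  expect_equal(f1$estimates$se, f2$estimates$se, tolerance = 1e-6)
})

test_that("degenerate and separated designs are flagged, not fitted", {
  # no within-set contrast anywhere: non-identifiable
  rs <- data.frame(set = rep(1:4, each = 3),
                   case = rep(c(TRUE, FALSE, FALSE), 4),
                   exposed = rep(c(1, 1, 1), 4))
  fit <- fit_conditional(rs, "exposed", covariates = NULL)
  expect_false(fit$estimates$identifiable)
  expect_true(is.na(fit$estimates$beta))

  # case always the sole exposed member: complete separation
  rs2 <- data.frame(set = rep(1:6, each = 3),
                    case = rep(c(TRUE, FALSE, FALSE), 6),
                    exposed = rep(c(1, 0, 0), 6))
  fit2 <- fit_conditional(rs2, "exposed", covariates = NULL)
  expect_true(fit2$separated)
  expect_true(is.infinite(fit2$estimates$variance) ||
                is.infinite(fit2$estimates$ci_high))
})

test_that("the log-linear-quadratic model recovers a known slope", {
  rs <- simulate_risk_sets(500, 4, function(m) {
    x <- runif(m, 0, 50); cbind(x, x^2)
  }, c(0.02, 0), seed = 7)
  names(rs)[3:4] <- c("cum", "cumsq")
  m <- fit_log_linear_quadratic(rs, covariates = NULL)
  se1 <- sqrt(m$covariance[1, 1])
  expect_lt(abs(m$beta1 - 0.02), 2 * se1)
  expect_equal(rr_curve(m, 0), 1.0)

  # all exposures zero: flagged non-identifiable, null curve
  rs0 <- rs; rs0$cum <- 0; rs0$cumsq <- 0
  m0 <- fit_log_linear_quadratic(rs0, covariates = NULL)
  expect_false(m0$identifiable)
  expect_equal(rr_curve(m0, c(0, 5, 50)), c(1, 1, 1))
})

test_that("the ordinal trend test is calibrated at the null and powered", {
  # null: case position independent of category
  set.seed(2)
  rej <- vapply(1:200, function(r) {
    rs <- do.call(rbind, lapply(1:60, function(s) {
      data.frame(set = s, case = seq_len(4) == sample.int(4, 1),
                 category = sample(0:4, 4, replace = TRUE))
    }))
    rr_trend_test(rs, covariates = NULL)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # strong injected trend
  rs_sig <- simulate_risk_sets(80, 4, function(m)
    matrix(sample(0:4, m, replace = TRUE)), 0.5, seed = 5)
  names(rs_sig)[3] <- "category"
  expect_lt(rr_trend_test(rs_sig, covariates = NULL)$p_value, 0.01)

  # single-category data cannot carry a trend
  rs1 <- data.frame(set = rep(1:3, each = 2), case = rep(c(TRUE, FALSE), 3),
                    category = 1L)
  expect_error(rr_trend_test(rs1, covariates = NULL), "categories")
})
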