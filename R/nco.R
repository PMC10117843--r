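# Negative control outcome (NCO) adjustment: an outcome caused by the
# unmeasured confounder but (by assumption) not by the exposure under study
# carries the confounding signal; subtracting its log rate ratio from the
# outcome's log rate ratio removes shared confounding under the
# equi-confounding assumption. Variances add, treating the two estimates as
# independent, so adjusted intervals widen (they are conservative).

#' Rate-ratio estimate as a (beta, variance) pair
#'
#' @param term label of the exposure term/category.
#' @param beta log rate ratio.
#' @param variance variance of `beta`.
#' @return object of class `rr_estimate`.
#' @export
rr_estimate <- function(term, beta, variance) {
  if (variance < 0) stop("variance must be >= 0")
  structure(list(term = term, beta = beta, variance = variance,
                 rr = exp(beta)), class = "rr_estimate")
}

#' Rate-ratio estimate from a published RR and confidence interval
#'
#' Back-solves the variance from the CI half-width on the log scale, so the
#' adjustment can be applied to printed table rows.
#'
#' @param term label.
#' @param rr point estimate.
#' @param ci_low,ci_high 95% confidence limits.
#' @param level confidence level of the interval.
#' @export
rr_estimate_from_ci <- function(term, rr, ci_low, ci_high, level = 0.95) {
  if (rr <= 0 || ci_low <= 0 || ci_high < ci_low)
    stop("need 0 < ci_low <= ci_high and rr > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  rr_estimate(term, log(rr), se^2)
}

#' Extract one term of an `rr_fit` as an `rr_estimate`
#' @param fit an [fit_conditional()] result.
#' @param term term name in the fit.
#' @export
rr_term <- function(fit, term) {
  e <- fit$estimates[fit$estimates$term == term, ]
  if (nrow(e) != 1) stop("term '", term, "' not found in fit")
  if (!e$identifiable) stop("term '", term, "' is non-identifiable")
  rr_estimate(term, e$beta, e$variance)
}

#' @noRd
as_rr_estimate <- function(x) {
  if (inherits(x, "rr_estimate")) return(x)
  stop("expected an rr_estimate (see rr_estimate(), rr_estimate_from_ci())")
}

#' @noRd
nco_combine <- function(outcome, ncos, level = 0.95) {
  outcome <- as_rr_estimate(outcome)
  ncos <- lapply(ncos, as_rr_estimate)
  for (nc in ncos)
    if (!identical(nc$term, outcome$term))
      stop("mismatched terms: outcome '", outcome$term, "' vs NCO '",
           nc$term, "'")
  beta_adj <- outcome$beta - sum(vapply(ncos, `[[`, 0, "beta"))
  var_adj <- outcome$variance + sum(vapply(ncos, `[[`, 0, "variance"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    outcome = outcome, nco = ncos, term = outcome$term,
    beta_adj = beta_adj, variance_adj = var_adj,
    rr_adj = exp(beta_adj),
    ci_low = exp(beta_adj - z * sqrt(var_adj)),
    ci_high = exp(beta_adj + z * sqrt(var_adj))
  ), class = "nco_adjustment")
}

#' Adjust an outcome rate ratio with a single negative control outcome
#'
#' beta_adj = beta_outcome - beta_nco, variance_adj = sum of variances, so
#' rr_adj = rr_outcome / rr_nco exactly.
#'
#' @param outcome an [rr_estimate()] for the outcome of interest.
#' @param nco an [rr_estimate()] for the negative control outcome, same term.
#' @param level confidence level.
#' @return object of class `nco_adjustment`.
#' @examples
#' lung <- rr_estimate_from_ci("exposed", 1.08, 0.92, 1.26)
#' copd <- rr_estimate_from_ci("exposed", 1.05, 0.81, 1.34)
#' nco_adjust(lung, copd)$rr_adj  # 1.03
#' @export
nco_adjust <- function(outcome, nco, level = 0.95) {
  nco_combine(outcome, list(nco), level)
}

#' Adjust for two unmeasured confounders with two negative controls
#'
#' Subtracts both NCO log rate ratios (e.g. COPD for smoking and
#' mesothelioma for asbestos); the result does not depend on their order.
#'
#' @param outcome,nco1,nco2 [rr_estimate()]s on the same term.
#' @param level confidence level.
#' @export
nco_adjust_double <- function(outcome, nco1, nco2, level = 0.95) {
  nco_combine(outcome, list(nco1, nco2), level)
}

#' @export
print.nco_adjustment <- function(x, ...) {
  cat(sprintf("NCO-adjusted RR [%s]: %.3f (%.3f-%.3f)\n", x$term, x$rr_adj,
              x$ci_low, x$ci_high))
  cat(sprintf("  outcome RR %.3f / NCO product %.3f\n", x$outcome$rr,
              prod(vapply(x$nco, `[[`, 0, "rr"))))
  invisible(x)
}

#' Adjust a continuous dose-response model with an NCO model
#'
#' Coefficient-wise subtraction with covariance summation; the adjusted RR
#' curve equals the outcome curve divided by the NCO curve at every exposure.
#'
#' @param outcome,nco [fit_log_linear_quadratic()] models on the same
#'   exposure scale.
#' @return a `dose_response` with `adjusted = TRUE`.
#' @export
nco_adjust_continuous <- function(outcome, nco) {
  if (!identical(outcome$exposure, nco$exposure))
    stop("dose-response models are on different exposure scales: '",
         outcome$exposure, "' vs '", nco$exposure, "'")
  structure(list(beta1 = outcome$beta1 - nco$beta1,
                 beta2 = outcome$beta2 - nco$beta2,
                 covariance = outcome$covariance + nco$covariance,
                 exposure = outcome$exposure,
                 identifiable = outcome$identifiable && nco$identifiable,
                 adjusted = TRUE, fit = NULL),
            class = "dose_response")
}
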