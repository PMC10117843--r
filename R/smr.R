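# Indirect standardization: expected deaths from reference rates applied to
# stratum-specific person-years, SMRs with exact Poisson (gamma-quantile)
# confidence limits, SMR ratios, and a Poisson log-linear trend test across
# ordered exposure categories.

#' Expected deaths per exposure category
#'
#' E(category) = sum over strata of person-years x reference rate. Every
#' stratum carrying person-time must be present in the rate table; a missing
#' cell is an error naming the stratum.
#'
#' @param pt a [tabulate_person_time()] result.
#' @param rates a [rate_table()].
#' @param cause cause of death.
#' @return data.frame with `category`, `pyr`, `observed`, `expected`.
#' @export
expected_deaths <- function(pt, rates, cause) {
  rc <- rates[rates$cause == cause, , drop = FALSE]
  m <- merge(pt$pyr, rc[c("race", "sex", "age_group", "period", "rate")],
             by = c("race", "sex", "age_group", "period"), all.x = TRUE)
  miss <- is.na(m$rate) & m$pyr > 0
  if (any(miss)) {
    mm <- unique(m[miss, c("race", "sex", "age_group", "period")])
    stop("missing rate cell(s) for cause '", cause, "': ",
         paste(apply(mm, 1, paste, collapse = "/"), collapse = "; "))
  }
  m$expected <- m$pyr * m$rate
  agg <- stats::aggregate(cbind(pyr, expected) ~ category, data = m, sum)
  dd <- pt$deaths[pt$deaths$cause == cause, , drop = FALSE]
  if (nrow(dd)) {
    od <- stats::aggregate(deaths ~ category, data = dd, sum)
    agg <- merge(agg, od, all.x = TRUE)
    agg$deaths[is.na(agg$deaths)] <- 0
  } else agg$deaths <- 0L
  data.frame(category = agg$category, pyr = agg$pyr,
             observed = as.integer(agg$deaths), expected = agg$expected)
}

#' SMR with exact Poisson confidence limits
#'
#' SMR = O / E. Exact limits via gamma quantiles: lower = qgamma(alpha/2, O)/E
#' (0 when O = 0), upper = qgamma(1 - alpha/2, O + 1)/E; equivalent to the
#' chi-square/2 formulation with 2O and 2(O+1) degrees of freedom.
#'
#' @param observed observed death count.
#' @param expected expected deaths; must be > 0.
#' @param level confidence level (default 0.95).
#' @param cause,category optional labels carried through.
#' @param suppress_below counts in (0, threshold) are flagged `suppressed`.
#' @return object of class `smr_result` (a one-row data.frame with `observed`,
#'   `expected`, `smr`, `ci_low`, `ci_high`, `suppressed`).
#' @export
smr_with_ci <- function(observed, expected, level = 0.95,
                        cause = NA_character_, category = NA,
                        suppress_below = 10) {
  if (any(expected <= 0)) stop("expected must be > 0")
  alpha <- 1 - level
  smr <- observed / expected
  lo <- ifelse(observed == 0, 0,
               stats::qgamma(alpha / 2, shape = observed) / expected)
  hi <- stats::qgamma(1 - alpha / 2, shape = observed + 1) / expected
  out <- data.frame(cause = cause, category = category,
                    observed = observed, expected = expected, smr = smr,
                    ci_low = lo, ci_high = hi,
                    suppressed = observed > 0 & observed < suppress_below)
  class(out) <- c("smr_result", "data.frame")
  out
}

#' Ratio of two SMRs
#'
#' The internal-comparison reading of two external SMRs: the rate ratio
#' implied by comparing an exposed-category SMR to the baseline-category SMR.
#'
#' @param smr_a,smr_b `smr_result` rows or bare SMR values; `smr_b` must be
#'   positive.
#' @return numeric ratio a / b.
#' @export
smr_ratio <- function(smr_a, smr_b) {
  a <- if (is.data.frame(smr_a)) smr_a$smr else smr_a
  b <- if (is.data.frame(smr_b)) smr_b$smr else smr_b
  if (any(b <= 0)) stop("denominator SMR must be > 0")
  a / b
}

#' SMR trend test across ordered exposure categories
#'
#' Wald p-value (two-sided) for the slope of a Poisson log-linear model
#' O_k ~ offset(log E_k) + score_k. Scores default to category ranks 1..K;
#' exposure midpoints can be supplied instead.
#'
#' @param results data.frame with `observed` and `expected` per ordered
#'   category (e.g. [expected_deaths()] output), or an `smr_result` stack.
#' @param scores optional numeric scores, one per category.
#' @return list with `p_value`, `slope`, `se`.
#' @export
smr_trend_test <- function(results, scores = NULL) {
  ok <- results$expected > 0
  o <- results$observed[ok]; e <- results$expected[ok]
  k <- length(o)
  if (k < 3) stop("trend test needs >= 3 categories with expected > 0")
  sc <- if (is.null(scores)) seq_len(k) else scores[ok]
  fit <- stats::glm(o ~ sc + offset(log(e)), family = stats::poisson())
  co <- summary(fit)$coefficients
  slope <- co["sc", "Estimate"]; se <- co["sc", "Std. Error"]
  p <- 2 * stats::pnorm(-abs(slope / se))
  list(p_value = p, slope = slope, se = se)
}

#' SMR table for one cause across exposure categories
#'
#' Computes per-category and overall SMRs with exact confidence limits, in
#' the layout of a printed SMR table.
#'
#' @inheritParams expected_deaths
#' @param level confidence level.
#' @param suppress_below suppression threshold for the `suppressed` flag.
#' @return `smr_result` data.frame, one row per category plus an `"all"` row.
#' @export
smr_table <- function(pt, rates, cause, level = 0.95, suppress_below = 10) {
  ed <- expected_deaths(pt, rates, cause)
  # categories with no expected deaths carry no SMR (reported as NA)
  pos <- ed$expected > 0
  rows <- smr_with_ci(ed$observed[pos], ed$expected[pos], level = level,
                      cause = cause, category = ed$category[pos],
                      suppress_below = suppress_below)
  if (any(!pos)) {
    na_rows <- data.frame(cause = cause, category = ed$category[!pos],
                          observed = ed$observed[!pos],
                          expected = ed$expected[!pos], smr = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          suppressed = FALSE)
    rows <- rbind(rows, na_rows)
    rows <- rows[order(rows$category), ]
  }
  tot <- smr_with_ci(sum(ed$observed), sum(ed$expected), level = level,
                     cause = cause, category = NA, suppress_below = suppress_below)
  tot$category <- "all"
  rows$category <- as.character(rows$category)
  out <- rbind(rows, tot)
  class(out) <- c("smr_result", "data.frame")
  out
}

#' Write an SMR report as TSV with disclosure suppression
#'
#' Observed counts below the suppression threshold are printed as `"d.s."`
#' and their SMR and confidence limits are masked.
#'
#' @param x an `smr_result` data.frame.
#' @param path output path.
#' @param threshold suppression threshold.
#' @export
write_smr_report <- function(x, path, threshold = 10) {
  out <- data.frame(
    cause = x$cause, category = x$category,
    observed = suppress_counts(x$observed, threshold),
    expected = sprintf("%.2f", x$expected),
    smr = sprintf("%.2f", x$smr),
    ci = sprintf("(%.2f-%.2f)", x$ci_low, x$ci_high),
    stringsAsFactors = FALSE
  )
  masked <- out$observed == "d.s."
  out$expected[masked] <- out$smr[masked] <- out$ci[masked] <- "d.s."
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
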