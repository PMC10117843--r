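# Conditional-likelihood rate-ratio models on explicit risk sets. With a
# single case per set the exact conditional likelihood and the Cox partial
# likelihood coincide: L(beta) = prod over sets of exp(x_case' beta) /
# sum_{j in set} exp(x_j' beta). The log-likelihood is concave; it is
# maximised by Newton-Raphson with step-halving from beta = 0, with the
# variance taken from the inverse observed information. Terms without
# within-set variation are reported as non-identifiable rather than fitted;
# complete separation is flagged, not fatal.

# design matrix from a risk_sets frame
#' @noRd
rr_design <- function(rs, exposure_terms, covariates) {
  cols <- list()
  for (term in exposure_terms) {
    if (term == "category") {
      cats <- sort(unique(rs$category))
      for (k in cats[cats > 0])
        cols[[paste0("cat", k)]] <- as.numeric(rs$category == k)
    } else if (term == "exposed") {
      cols[["exposed"]] <- if ("exposed" %in% names(rs)) as.numeric(rs$exposed)
                           else as.numeric(rs$category > 0)
    } else if (term == "cum") {
      cols[["cum"]] <- rs$cum
    } else if (term == "cumsq") {
      cols[["cumsq"]] <- rs$cum^2
    } else if (term == "aie") {
      cols[["aie"]] <- rs$aie
    } else if (term %in% names(rs)) {
      cols[[term]] <- as.numeric(rs[[term]])
    } else stop("unknown exposure term: ", term)
  }
  for (cv in covariates) {
    v <- rs[[cv]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1]) cols[[paste0(cv, l)]] <- as.numeric(v == l)
    } else cols[[cv]] <- as.numeric(v)
  }
  do.call(cbind, cols)
}

# core Newton-Raphson fit; X numeric matrix, set integer ids, case logical
#' @noRd
clogit_newton <- function(X, set, case, tol = 1e-8, max_iter = 100) {
  set <- match(set, unique(set))
  n_sets <- max(set)
  p <- ncol(X)
  beta <- rep(0, p)

  loglik_parts <- function(beta) {
    eta <- drop(X %*% beta)
    shift <- as.vector(tapply(eta, set, max))[set]
    ew <- exp(eta - shift)
    W <- rowsum(ew, set)
    prob <- ew / W[set]
    ll <- sum((eta - shift)[case]) - sum(log(W))
    list(ll = ll, prob = prob)
  }

  lp <- loglik_parts(beta)
  converged <- FALSE; separated <- FALSE; iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    prob <- lp$prob
    grad <- colSums(X[case, , drop = FALSE]) - colSums(X * prob)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    Xp <- X * prob
    S <- rowsum(Xp, set)
    info <- crossprod(X, Xp) - crossprod(S)
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) { separated <- TRUE; break }
    # step-halving to guarantee ascent
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      lp_new <- loglik_parts(cand)
      if (lp_new$ll >= lp$ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    beta <- cand; lp <- lp_new
    if (max(abs(beta)) > 25) { separated <- TRUE; break }
  }

  # a coefficient drifting to +/- infinity (monotone likelihood) means the
  # data are separated even if the gradient has flattened out numerically
  if (max(abs(beta)) > 15) separated <- TRUE
  prob <- lp$prob
  Xp <- X * prob
  S <- rowsum(Xp, set)
  info <- crossprod(X, Xp) - crossprod(S)
  vcov <- tryCatch(solve(info), error = function(e)
    matrix(Inf, p, p, dimnames = dimnames(info)))
  if (separated) vcov[] <- Inf
  list(beta = beta, vcov = vcov, loglik = lp$ll, converged = converged,
       separated = separated, iterations = iter, n_sets = n_sets)
}

#' Fit a conditional-likelihood rate-ratio model to risk sets
#'
#' @param risk_sets a [build_risk_sets()] result (or any data.frame with
#'   `set`, `case` and the referenced columns).
#' @param exposure_terms character vector naming exposure terms: `"category"`
#'   (indicator per cut-point category, unexposed baseline), `"exposed"`
#'   (any-exposure indicator), `"cum"`, `"cumsq"`, `"aie"`, or any numeric
#'   column of `risk_sets`.
#' @param covariates covariate columns entered as indicator contrasts
#'   (default race, sex and pay type).
#' @param level confidence level.
#' @return object of class `rr_fit`: `estimates` data.frame (`term`, `beta`,
#'   `se`, `variance`, `rr`, `ci_low`, `ci_high`, `identifiable`), plus
#'   `vcov`, `loglik`, `converged`, `separated`, `n_sets`.
#' @export
fit_conditional <- function(risk_sets, exposure_terms = "category",
                            covariates = c("race", "sex", "pay_type"),
                            level = 0.95) {
  if (nrow(risk_sets) == 0)
    stop("no non-empty risk sets to fit")
  covariates <- intersect(covariates, names(risk_sets))
  X <- rr_design(risk_sets, exposure_terms, covariates)
  set <- risk_sets$set
  case <- risk_sets$case

  # identifiability: total within-set variation per column
  wvar <- vapply(seq_len(ncol(X)), function(j) {
    m <- tapply(X[, j], set, mean)[match(set, sort(unique(set)))]
    sum((X[, j] - m)^2)
  }, numeric(1))
  ident <- wvar > 1e-12
  terms <- colnames(X)

  if (!any(ident)) {
    est <- data.frame(term = terms, beta = NA_real_, se = NA_real_,
                      variance = NA_real_, rr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, identifiable = FALSE)
    out <- list(estimates = est, vcov = NULL, loglik = NA_real_,
                converged = FALSE, separated = FALSE,
                n_sets = length(unique(set)),
                n_empty = attr(risk_sets, "n_empty") %||% 0)
    class(out) <- "rr_fit"
    return(out)
  }

  fit <- clogit_newton(X[, ident, drop = FALSE], set, case)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- data.frame(term = terms, beta = NA_real_, se = NA_real_,
                    variance = NA_real_, rr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, identifiable = ident,
                    stringsAsFactors = FALSE)
  est$beta[ident] <- fit$beta
  est$variance[ident] <- diag(fit$vcov)
  est$se[ident] <- sqrt(diag(fit$vcov))
  est$rr[ident] <- exp(fit$beta)
  est$ci_low[ident] <- exp(fit$beta - z * est$se[ident])
  est$ci_high[ident] <- exp(fit$beta + z * est$se[ident])
  out <- list(estimates = est, vcov = fit$vcov, loglik = fit$loglik,
              converged = fit$converged, separated = fit$separated,
              iterations = fit$iterations, n_sets = fit$n_sets,
              n_empty = attr(risk_sets, "n_empty") %||% 0)
  class(out) <- "rr_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rr_fit <- function(x, ...) {
  cat("Conditional-likelihood rate-ratio fit:", x$n_sets, "risk sets")
  if (x$n_empty > 0) cat(" (", x$n_empty, " empty sets excluded)", sep = "")
  cat("\n")
  if (isTRUE(x$separated)) cat("  WARNING: complete separation detected\n")
  e <- x$estimates
  e$rr <- round(e$rr, 3); e$ci_low <- round(e$ci_low, 3)
  e$ci_high <- round(e$ci_high, 3)
  print(e[c("term", "beta", "se", "rr", "ci_low", "ci_high", "identifiable")],
        row.names = FALSE)
  invisible(x)
}

#' Fit the two-parameter log-linear-quadratic dose-response model
#'
#' RR(x) = exp(beta1 x + beta2 x^2) on continuous lagged cumulative exposure,
#' fitted by the same conditional likelihood. RR(0) = 1 by construction.
#'
#' @param risk_sets a [build_risk_sets()] result.
#' @param exposure column holding the continuous exposure (default `"cum"`).
#' @param covariates covariates as in [fit_conditional()].
#' @return object of class `dose_response`: `beta1`, `beta2`, `covariance`
#'   (2x2), `exposure`, plus the underlying `fit`.
#' @export
fit_log_linear_quadratic <- function(risk_sets, exposure = "cum",
                                     covariates = c("race", "sex", "pay_type")) {
  rs <- risk_sets
  rs$.x <- rs[[exposure]]
  rs$.x2 <- rs[[exposure]]^2
  fit <- fit_conditional(rs, exposure_terms = c(".x", ".x2"),
                         covariates = covariates)
  e <- fit$estimates
  b1 <- e$beta[e$term == ".x"]; b2 <- e$beta[e$term == ".x2"]
  identifiable <- e$identifiable[e$term == ".x"] | e$identifiable[e$term == ".x2"]
  if (!identifiable) { b1 <- 0; b2 <- 0 }
  cv <- matrix(0, 2, 2, dimnames = list(c("beta1", "beta2"), c("beta1", "beta2")))
  if (identifiable && !is.null(fit$vcov)) {
    keep <- intersect(c(".x", ".x2"), rownames(fit$vcov))
    cv[seq_along(keep), seq_along(keep)] <- fit$vcov[keep, keep]
  }
  structure(list(beta1 = ifelse(is.na(b1), 0, b1),
                 beta2 = ifelse(is.na(b2), 0, b2),
                 covariance = cv, exposure = exposure,
                 identifiable = identifiable, fit = fit),
            class = "dose_response")
}

#' Evaluate a dose-response RR curve
#' @param model a `dose_response`.
#' @param x exposure values.
#' @return RR(x) = exp(beta1 x + beta2 x^2); exactly 1 at x = 0.
#' @export
rr_curve <- function(model, x) exp(model$beta1 * x + model$beta2 * x^2)

#' @export
print.dose_response <- function(x, ...) {
  cat("Log-linear-quadratic dose-response model on", x$exposure, "\n")
  cat(sprintf("  beta1 = %.6g  beta2 = %.6g%s\n", x$beta1, x$beta2,
              if (!x$identifiable) "  (non-identifiable, null curve)" else ""))
  invisible(x)
}

#' Ordinal trend test from risk sets
#'
#' Wald p-value for a single ordinal score term fitted by the conditional
#' likelihood. Scores default to category ranks; category-specific scores
#' (e.g. exposure midpoints) can be supplied.
#'
#' @param risk_sets a [build_risk_sets()] result.
#' @param scores optional numeric scores indexed by category (position 1 =
#'   category 0); defaults to the category index itself.
#' @param covariates covariates as in [fit_conditional()].
#' @return list with `p_value`, `beta`, `se`.
#' @export
rr_trend_test <- function(risk_sets, scores = NULL,
                          covariates = c("race", "sex", "pay_type")) {
  cats <- sort(unique(risk_sets$category))
  if (length(cats) < 3) stop("trend test needs >= 3 exposure categories")
  rs <- risk_sets
  rs$.score <- if (is.null(scores)) as.numeric(rs$category)
               else scores[rs$category + 1]
  fit <- fit_conditional(rs, exposure_terms = ".score", covariates = covariates)
  e <- fit$estimates[fit$estimates$term == ".score", ]
  if (!e$identifiable) stop("trend score has no within-set variation")
  list(p_value = 2 * stats::pnorm(-abs(e$beta / e$se)),
       beta = e$beta, se = e$se, fit = fit)
}

#' Export a fitted model as a JSON report
#' @param fit an `rr_fit`.
#' @param path output path.
#' @export
write_rr_report <- function(fit, path) {
  jsonlite::write_json(
    list(estimates = fit$estimates, loglik = fit$loglik,
         converged = fit$converged, separated = fit$separated,
         n_sets = fit$n_sets, n_empty_sets_dropped = fit$n_empty),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
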