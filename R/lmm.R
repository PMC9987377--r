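# Linear mixed models with participant-specific random intercept and slope.
# Estimation is REML via lme4, with Satterthwaite p-values (lmerTest) and
# Wald 95% confidence intervals. Marginal/conditional R-squared follow
# Nakagawa & Schielzeth with Johnson's random-slope extension: the random
# variance is the mean over observations of z' G z, so observation-varying
# slope variance is averaged over the design.

#' Fit a random-intercept, random-slope linear mixed model
#'
#' Builds `outcome ~ fixed terms + (1 + random_slope | participant_id)` and
#' fits it by REML. A singular random-effect covariance triggers a refit
#' with a diagonal (uncorrelated) covariance, flagged in the result.
#' Non-convergence is reported explicitly, never silently.
#'
#' @param data long-format data.frame/data.table of observations
#' @param outcome name of the outcome column
#' @param fixed character vector of fixed-effect terms (model-formula
#'   syntax, e.g. `c("t_months", "indicator", "indicator:t_months")`);
#'   the intercept is always included
#' @param random_slope name of the variable carrying the random slope
#'   (default `"t_months"`)
#' @param group grouping column (default `"participant_id"`)
#' @return object of class `als_lmm` with elements `fixed` (term, estimate,
#'   ci_lo, ci_hi, p), `G` (2x2 random-effect covariance), `sigma2`
#'   (residual variance), `conditional` (per-participant conditional
#'   intercept and slope on `random_slope`), `r2m`, `r2c`, `converged`,
#'   `singular`, `diagonal_refit`, and the underlying `model`
#' @export
fit_lmm <- function(data, outcome, fixed = "t_months",
                    random_slope = "t_months", group = "participant_id") {
  data <- as.data.frame(data)
  stopifnot(outcome %in% names(data), group %in% names(data))
  n_per <- table(as.character(data[[group]]))
  if (length(n_per) < 2L)
    stop("mixed model needs at least 2 participants", call. = FALSE)
  if (!any(n_per >= 2L))
    stop("mixed model needs repeated observations for some participants",
         call. = FALSE)

  Xf <- stats::model.matrix(
    stats::as.formula(paste("~", paste(fixed, collapse = " + "))), data)
  if (qr(Xf)$rank < ncol(Xf))
    stop("fixed-effect design is rank deficient: ",
         paste(fixed, collapse = " + "), call. = FALSE)

  fml <- stats::as.formula(sprintf(
    "%s ~ %s + (1 + %s | %s)", outcome, paste(fixed, collapse = " + "),
    random_slope, group))
  fml_diag <- stats::as.formula(sprintf(
    "%s ~ %s + (1 + %s || %s)", outcome, paste(fixed, collapse = " + "),
    random_slope, group))

  fit_one <- function(f) {
    warns <- character()
    m <- withCallingHandlers(
      suppressMessages(lmerTest::lmer(
        f, data = data, REML = TRUE,
        control = lme4::lmerControl(optimizer = "bobyqa"))),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(model = m, warnings = warns)
  }

  res <- fit_one(fml)
  m <- res$model
  if (any(grepl("rank deficient", res$warnings, fixed = TRUE)))
    stop("fixed-effect design is rank deficient: ",
         paste(fixed, collapse = " + "), call. = FALSE)
  diagonal_refit <- FALSE
  if (lme4::isSingular(m, tol = 1e-5)) {
    res2 <- fit_one(fml_diag)
    m <- res2$model
    diagonal_refit <- TRUE
    res$warnings <- c(res$warnings, res2$warnings)
  }
  converged <- !any(grepl("failed to converge", res$warnings))
  singular <- lme4::isSingular(m, tol = 1e-5)

  smry <- suppressMessages(summary(m))
  co <- smry$coefficients
  p <- if ("Pr(>|t|)" %in% colnames(co)) co[, "Pr(>|t|)"] else
    2 * stats::pnorm(-abs(co[, "t value"]))
  ci <- suppressMessages(stats::confint(m, parm = "beta_", method = "Wald"))
  fixed_dt <- data.table::data.table(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lo = ci[, 1], ci_hi = ci[, 2],
    p = as.numeric(p))

  vc <- lme4::VarCorr(m)
  G <- matrix(0, 2, 2,
              dimnames = list(c("(Intercept)", random_slope),
                              c("(Intercept)", random_slope)))
  for (g in vc) {
    nms <- rownames(g)
    G[nms, nms] <- G[nms, nms] + g[, , drop = FALSE]
  }
  sigma2 <- stats::sigma(m)^2

  cf <- stats::coef(m)[[group]]
  conditional <- data.table::data.table(
    participant_id = rownames(cf),
    intercept = cf[["(Intercept)"]],
    slope = cf[[random_slope]])

  out <- structure(list(
    outcome = outcome, fixed_terms = fixed, random_slope = random_slope,
    fixed = fixed_dt, G = G, sigma2 = sigma2,
    conditional = conditional,
    converged = converged, singular = singular,
    diagonal_refit = diagonal_refit,
    n_obs = nrow(data), n_participants = length(n_per),
    model = m), class = "als_lmm")
  r2 <- r2_nakagawa(out)
  out$r2m <- r2[["r2m"]]; out$r2c <- r2[["r2c"]]
  out
}

#' Marginal and conditional R-squared for a fitted mixed model
#'
#' `r2m` is the share of total variance attributable to the fixed effects;
#' `r2c` adds the random effects. Fixed variance is the variance of the
#' fixed-effect linear predictor over the observed design; random variance
#' is the mean over observations of z' G z with z = (1, slope variable);
#' the denominator adds the residual variance. NA when the total is zero.
#'
#' @param fit an `als_lmm`
#' @return named vector `c(r2m = , r2c = )`
#' @export
r2_nakagawa <- function(fit) {
  m <- fit$model
  X <- stats::model.matrix(m)
  beta <- lme4::fixef(m)
  eta <- as.numeric(X[, names(beta), drop = FALSE] %*% beta)
  var_f <- mean((eta - mean(eta))^2)
  z <- cbind(1, X[, fit$random_slope])
  var_r <- mean(rowSums((z %*% fit$G) * z))
  tot <- var_f + var_r + fit$sigma2
  if (!is.finite(tot) || tot <= 0)
    return(c(r2m = NA_real_, r2c = NA_real_))
  c(r2m = var_f / tot, r2c = (var_f + var_r) / tot)
}

#' Percentage of participants with a meaningful model-implied change
#'
#' From the fitted conditional means (empirical BLUP trajectories), computes
#' each participant's relative change over `horizon` months,
#' (m(h) - m(0)) / m(0), and returns the percentage whose absolute relative
#' change is at least `threshold` and whose direction matches the sign of
#' the population slope. Participants with a conditional baseline of 0 are
#' excluded from both numerator and denominator (with a message).
#'
#' @param fit an `als_lmm` whose random slope is on time
#' @param horizon months (default 6)
#' @param threshold minimum relative change (default 0.10)
#' @return percentage in [0, 100]
#' @export
pct_relative_change <- function(fit, horizon = 6, threshold = 0.10) {
  stopifnot(inherits(fit, "als_lmm"))
  beta1 <- fit$fixed$estimate[fit$fixed$term == fit$random_slope]
  if (!length(beta1))
    stop("fit has no population slope term", call. = FALSE)
  m0 <- fit$conditional$intercept
  mh <- m0 + fit$conditional$slope * horizon
  keep <- m0 != 0
  if (any(!keep))
    message(sum(!keep), " participant(s) with conditional baseline 0 excluded")
  rel <- (mh[keep] - m0[keep]) / m0[keep]
  change <- mh[keep] - m0[keep]
  hit <- abs(rel) >= threshold & sign(change) == sign(beta1)
  100 * sum(hit) / sum(keep)
}

#' @export
print.als_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s ~ %s + (1 + %s | participant)\n",
              x$outcome, paste(x$fixed_terms, collapse = " + "),
              x$random_slope))
  cat(sprintf("  %d obs, %d participants; REML; converged: %s%s\n",
              x$n_obs, x$n_participants, x$converged,
              if (x$diagonal_refit) " (diagonal G refit)" else ""))
  print(x$fixed, digits = 4)
  cat(sprintf("  R2m = %.3f, R2c = %.3f, residual SD = %.4g\n",
              x$r2m, x$r2c, sqrt(x$sigma2)))
  invisible(x)
}
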