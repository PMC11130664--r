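#' One-sample Mendelian randomization by two-stage least squares
#'
#' Estimates the causal effect of the exposure (BMI) on a metabolite trait
#' using the polygenic score as instrument. Stage 1 regresses the exposure on
#' the instrument and covariables; stage 2 regresses the outcome on the
#' fitted exposure and the same covariables. Standard errors use the proper
#' 2SLS variance: residuals are formed with the observed exposure,
#' \eqn{y - \hat\alpha - \hat\beta_{IV} x - \hat\gamma' C}, not the naive
#' stage-2 residuals. Sampling weights, when used, enter both stages
#' identically. A heteroskedasticity-robust (HC0 sandwich) variance is
#' available behind `robust`.
#'
#' A first-stage partial F below 10 flags a weak instrument (warning
#' attribute, result still returned).
#'
#' @param outcome Numeric vector (normally rank-normal transformed).
#' @param cohort Cohort table with exposure, instrument, covariable and
#'   weight columns.
#' @param exposure,instrument Column names (defaults `"bmi"`, `"pgs"`).
#' @param covariates Covariable column names (same set as the observational
#'   model).
#' @param weighted Use `cohort$sample_weight` in both stages.
#' @param robust Use the HC0 sandwich variance instead of the homoskedastic
#'   2SLS variance.
#' @return An object of class `mr_fit`: list with `result` (data.frame
#'   `beta_iv`, `se_iv`, `p_iv`, `n`, `f_stat`, `f_p`, `dwh_stat`, `dwh_p`,
#'   `bp_p`, `weak_instrument`) and the internal design pieces.
#' @examples
#' n <- 500; g <- rnorm(n); x <- 2 * g + rnorm(n); y <- 3 * x + rnorm(n)
#' cohort <- data.frame(bmi = x, pgs = g, sample_weight = 1)
#' fit_2sls(y, cohort, covariates = character(0))$result$beta_iv
#' @export
fit_2sls <- function(outcome, cohort, exposure = "bmi", instrument = "pgs",
                     covariates = c("visit_date", "subpopulation", "age", "sex"),
                     weighted = TRUE, robust = FALSE) {
  stopifnot(length(outcome) == nrow(cohort))
  w_all <- if (weighted) cohort$sample_weight else rep(1, nrow(cohort))
  dat <- cohort[, unique(c(covariates, exposure, instrument)), drop = FALSE]
  dat$.y <- outcome
  dat$.w <- w_all
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (stats::var(dat[[instrument]]) == 0) stop("instrument has zero variance")

  # covariable design (with intercept)
  C <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = dat)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  x <- dat[[exposure]]
  g <- dat[[instrument]]
  y <- dat$.y
  w <- dat$.w

  # stage 1: exposure on instrument + covariables
  Z <- cbind(C, instrument = g)
  s1 <- wls_fit(Z, x, w)
  xhat <- s1$fitted

  # weak-instrument partial F
  s0 <- wls_fit(C, x, w)
  f_stat <- (s0$rss - s1$rss) / (s1$rss / (n - ncol(Z)))
  f_capped <- FALSE
  if (!is.finite(f_stat) || f_stat > 1e12) {
    f_stat <- 1e12
    f_capped <- TRUE
  }
  f_p <- stats::pf(f_stat, 1, n - ncol(Z), lower.tail = FALSE)

  # stage 2 on the fitted exposure
  X2 <- cbind(C, exposure = xhat)
  s2 <- wls_fit(X2, y, w)
  beta <- s2$coef
  # 2SLS variance: residuals with the OBSERVED exposure
  Xobs <- cbind(C, exposure = x)
  resid_iv <- y - drop(Xobs %*% beta)
  k <- ncol(X2)
  bread <- s2$XtWX_inv
  if (robust) {
    meat <- crossprod(X2 * (w * resid_iv))
    vc <- bread %*% meat %*% bread
  } else {
    sigma2 <- sum(w * resid_iv^2) / (n - k)
    vc <- sigma2 * bread
  }
  se <- sqrt(diag(vc))
  if (se[[k]] < 1e-10 && abs(beta[["exposure"]]) < 1e-10) {
    z <- 0  # constant outcome: no effect, no evidence
  } else {
    z <- beta[["exposure"]] / se[[k]]
  }
  p_iv <- z_p(z)

  # Durbin-Wu-Hausman: outcome on exposure + covariables + stage-1 residuals
  dwh <- dwh_from_pieces(y, x, C, s1$residuals, w)

  # Breusch-Pagan on the IV residuals against the structural design
  bp <- bp_from_pieces(Xobs, resid_iv, w)

  res <- data.frame(beta_iv = beta[["exposure"]], se_iv = se[[k]], p_iv = p_iv,
                    n = n, f_stat = f_stat, f_p = f_p,
                    dwh_stat = dwh[["statistic"]], dwh_p = dwh[["p"]],
                    bp_p = bp[["p"]], weak_instrument = f_stat < 10)
  if (res$weak_instrument)
    warning("weak instrument: first-stage F = ", signif(f_stat, 4))
  if (f_capped) attr(res, "f_capped") <- TRUE
  out <- list(result = res, stage1 = s1, stage2 = s2, vcov = vc,
              residuals_iv = resid_iv)
  class(out) <- "mr_fit"
  out
}

dwh_from_pieces <- function(y, x, C, s1_resid, w) {
  if (all(abs(s1_resid) < 1e-12))  # perfect first stage: test undefined
    return(c(statistic = NA_real_, p = NA_real_))
  Xa <- cbind(C, exposure = x, s1resid = s1_resid)
  fa <- wls_fit(Xa, y, w)
  if (fa$se[["s1resid"]] == 0) {
    stat <- if (fa$coef[["s1resid"]] == 0) 0 else Inf
  } else {
    stat <- (fa$coef[["s1resid"]] / fa$se[["s1resid"]])^2
  }
  c(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

bp_from_pieces <- function(X, resid, w) {
  e2 <- (sqrt(w) * resid)^2
  aux <- stats::lm.fit(X, e2)
  tss <- sum((e2 - mean(e2))^2)
  r2 <- if (tss <= 1e-12 * (sum(e2^2) + 1e-300)) 0
        else min(max(1 - sum(aux$residuals^2) / tss, 0), 1)
  stat <- nrow(X) * r2
  c(statistic = stat, p = stats::pchisq(stat, ncol(X) - 1L, lower.tail = FALSE))
}

#' Weak-instrument partial F statistic
#'
#' Partial F for the instrument in the first-stage regression of the
#' exposure on instrument plus covariables:
#' \eqn{F = \Delta SS / (SS_{full} / (n - k))}, referred to F(1, n - k).
#'
#' @inheritParams fit_2sls
#' @return Named numeric vector `f_stat`, `f_p`.
#' @export
weak_instrument_f <- function(cohort, exposure = "bmi", instrument = "pgs",
                              covariates = c("visit_date", "subpopulation",
                                             "age", "sex"),
                              weighted = TRUE) {
  w <- if (weighted) cohort$sample_weight else rep(1, nrow(cohort))
  dat <- cohort[, unique(c(covariates, exposure, instrument)), drop = FALSE]
  dat$.w <- w
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  C <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = dat)
  else matrix(1, n, 1)
  Z <- cbind(C, instrument = dat[[instrument]])
  s1 <- wls_fit(Z, dat[[exposure]], dat$.w)
  s0 <- wls_fit(C, dat[[exposure]], dat$.w)
  f_stat <- (s0$rss - s1$rss) / (s1$rss / (n - ncol(Z)))
  if (!is.finite(f_stat) || f_stat > 1e12) f_stat <- 1e12
  c(f_stat = f_stat,
    f_p = stats::pf(f_stat, 1, n - ncol(Z), lower.tail = FALSE))
}

#' Durbin-Wu-Hausman endogeneity test
#'
#' Augmented-regression form: the outcome is regressed on the exposure, the
#' covariables and the stage-1 residuals; the statistic is the squared t of
#' the residual term, referred to \eqn{\chi^2_1}. A small p suggests the
#' exposure is endogenous and OLS and IV estimands differ.
#'
#' @inheritParams fit_2sls
#' @return Named numeric vector `statistic`, `p`.
#' @export
durbin_wu_hausman <- function(outcome, cohort, exposure = "bmi",
                              instrument = "pgs",
                              covariates = c("visit_date", "subpopulation",
                                             "age", "sex"),
                              weighted = TRUE) {
  fit <- fit_2sls(outcome, cohort, exposure = exposure,
                  instrument = instrument, covariates = covariates,
                  weighted = weighted)
  c(statistic = fit$result$dwh_stat, p = fit$result$dwh_p)
}
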