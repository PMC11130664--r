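#' Weighted multivariable association of a trait with BMI
#'
#' Fits the Gaussian identity-link model
#' `outcome ~ visit_date + subpopulation + age + sex + bmi` by weighted least
#' squares with the cohort's sampling weights (all ones when
#' `weighted = FALSE`), on complete cases. The exposure enters last so the
#' sequential (type I) variance decomposition attributes to BMI only the
#' variance it explains beyond the covariables.
#'
#' @param outcome Numeric vector aligned with `cohort` rows (normally a
#'   rank-normal transformed trait, so the effect is in SD units per BMI
#'   unit).
#' @param cohort Cohort table with `bmi`, `sample_weight` and the covariable
#'   columns.
#' @param weighted Use `cohort$sample_weight` (default `TRUE`).
#' @param covariates Character vector of covariable column names fitted
#'   before BMI.
#' @return An object of class `assoc_fit`: the fitted [stats::lm()] plus a
#'   `result` data.frame with `beta`, `se`, `p`, `n`, `eta2_model`,
#'   `eta2_bmi`, `bp_p` for the BMI term.
#' @export
fit_weighted_glm <- function(outcome, cohort, weighted = TRUE,
                             covariates = c("visit_date", "subpopulation",
                                            "age", "sex")) {
  stopifnot(length(outcome) == nrow(cohort))
  w <- if (weighted) cohort$sample_weight else rep(1, nrow(cohort))
  dat <- cohort[, c(covariates, "bmi"), drop = FALSE]
  dat$.y <- outcome
  dat$.w <- w
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  form <- stats::reformulate(c(covariates, "bmi"), response = ".y")
  fit <- stats::lm(form, data = dat, weights = .w)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  eta <- anova_eta_squared_lm(fit)
  bp <- breusch_pagan_lm(fit)
  out <- list(
    lm = fit,
    result = data.frame(beta = sm["bmi", 1], se = sm["bmi", 2],
                        p = sm["bmi", 4], n = nrow(dat),
                        eta2_model = eta[["eta2_model"]],
                        eta2_bmi = eta[["eta2_bmi"]],
                        bp_p = bp[["p"]]))
  class(out) <- "assoc_fit"
  out
}

# Sequential (type I) eta^2 from a fitted lm: BMI must be the last term.
anova_eta_squared_lm <- function(fit) {
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  terms <- rownames(av)
  tot <- sum(ss)
  if (tot == 0) stop("zero total sum of squares")
  model_ss <- sum(ss[terms != "Residuals"])
  bmi_ss <- ss[match("bmi", terms)]
  c(eta2_model = model_ss / tot, eta2_bmi = unname(bmi_ss) / tot)
}

#' Sequential eta-squared variance decomposition
#'
#' Type I (sequential) sums of squares from the fitted association model,
#' expressed as fractions of the total sum of squares: `eta2_bmi` is the
#' fraction attributed to BMI fitted after all covariables, `eta2_model` the
#' fraction explained by the full model. Weighted fits use weighted sums of
#' squares.
#'
#' @param fit An `assoc_fit` from [fit_weighted_glm()] or a plain lm.
#' @return Named numeric vector `eta2_model`, `eta2_bmi`.
#' @export
anova_eta_squared <- function(fit) {
  if (inherits(fit, "assoc_fit")) fit <- fit$lm
  anova_eta_squared_lm(fit)
}

breusch_pagan_lm <- function(fit) {
  X <- stats::model.matrix(fit)
  w <- stats::weights(fit) %||% rep(1, nrow(X))
  e2 <- (sqrt(w) * stats::resid(fit))^2
  aux <- stats::lm.fit(X, e2)
  tss <- sum((e2 - mean(e2))^2)
  # near-constant squared residuals carry no heteroskedasticity information
  r2 <- if (tss <= 1e-12 * (sum(e2^2) + 1e-300)) 0
        else min(max(1 - sum(aux$residuals^2) / tss, 0), 1)
  n <- nrow(X)
  df <- ncol(X) - 1L
  lm_stat <- n * r2
  c(statistic = lm_stat, df = df,
    p = stats::pchisq(lm_stat, df, lower.tail = FALSE))
}

#' Breusch-Pagan test of homoskedasticity
#'
#' Lagrange-multiplier form: the squared (weighted) residuals are regressed
#' on the mean model's design matrix; the statistic is \eqn{n R^2} with a
#' \eqn{\chi^2} reference on (number of regressors) degrees of freedom.
#'
#' @param fit An `assoc_fit` or fitted lm with residuals.
#' @return Named numeric vector `statistic`, `df`, `p`.
#' @export
breusch_pagan <- function(fit) {
  if (inherits(fit, "assoc_fit")) fit <- fit$lm
  breusch_pagan_lm(fit)
}

#' Describe fasting versus postprandial abundances
#'
#' Per trait: a paired Student t test of whether mean abundance differs
#' between the dietary states, the mean postprandial-minus-fasting change,
#' and the 2.5/97.5 percentile interval of the per-individual change
#' distribution. Significance is flagged at `alpha` Bonferroni-corrected for
#' the number of traits.
#'
#' @param fasting,postprandial Numeric matrices with shared dimnames.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data.frame with `trait`, `n`, `t`, `p`, `mean_delta`, `ci_low`,
#'   `ci_high` (percentiles of the delta distribution), `significant`, and
#'   `zero_variance` flag for degenerate differences.
#' @export
describe_states <- function(fasting, postprandial, alpha = 0.05) {
  stopifnot(identical(dim(fasting), dim(postprandial)))
  nt <- ncol(fasting)
  thr <- alpha / nt
  rows <- lapply(seq_len(nt), function(j) {
    d <- postprandial[, j] - fasting[, j]
    d <- d[!is.na(d)]
    n <- length(d)
    zero_var <- n > 1 && stats::sd(d) < 1e-12 * (abs(mean(d)) + 1)
    if (n < 2 || zero_var) {
      # a constant shift has an undefined t; a constant zero shift is "no change"
      t_stat <- if (zero_var && abs(mean(d)) < 1e-12) 0 else NA_real_
      p <- if (zero_var && abs(mean(d)) < 1e-12) 1 else NA_real_
    } else {
      t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
      p <- 2 * stats::pt(-abs(t_stat), n - 1)
    }
    q <- if (n) stats::quantile(d, c(0.025, 0.975), names = FALSE) else c(NA, NA)
    data.frame(trait = colnames(fasting)[j] %||% as.character(j), n = n,
               t = t_stat, p = p, mean_delta = if (n) mean(d) else NA_real_,
               ci_low = q[1], ci_high = q[2],
               significant = !is.na(p) && p < thr,
               zero_variance = zero_var, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Screen covariables for confounding potential
#'
#' Univariable association of every candidate covariable with BMI and with
#' the PGS instrument (overall model F test, so categorical covariables are
#' handled), flagged at `alpha` divided by the effective covariable count.
#' Covariables associated with the PGS — potential violations of the
#' exchangeability assumption — are additionally tested against each
#' metabolite trait.
#'
#' @param cohort Cohort table with `bmi` and `pgs` columns.
#' @param metabolites Numeric matrix of (transformed) traits, or `NULL` to
#'   skip the third pass.
#' @param covariables Character vector of cohort column names to screen.
#' @param m_eff Effective number of covariables for the Bonferroni threshold.
#' @param alpha Family-wise level (default 0.05).
#' @return A list with `covariables` (per-covariable `p_bmi`, `p_pgs`,
#'   flags), `metabolite_p` (matrix of p values for PGS-associated
#'   covariables, or `NULL`), `threshold`, and `skipped` (non-varying
#'   covariables).
#' @export
covariable_screen <- function(cohort, metabolites = NULL, covariables,
                              m_eff = length(covariables), alpha = 0.05) {
  thr <- alpha / m_eff
  uni_p <- function(y, x) {
    ok <- stats::complete.cases(y, x)
    if (length(unique(x[ok])) < 2) return(NA_real_)
    f <- summary(stats::lm(y[ok] ~ x[ok]))$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  p_bmi <- vapply(covariables, function(v) uni_p(cohort$bmi, cohort[[v]]), 0)
  p_pgs <- vapply(covariables, function(v) uni_p(cohort$pgs, cohort[[v]]), 0)
  skipped <- covariables[is.na(p_bmi) & is.na(p_pgs)]
  if (length(skipped))
    message("covariable screen skipped non-varying: ",
            paste(skipped, collapse = ", "))
  tab <- data.frame(covariable = covariables, p_bmi = unname(p_bmi),
                    p_pgs = unname(p_pgs),
                    flag_bmi = !is.na(p_bmi) & p_bmi < thr,
                    flag_pgs = !is.na(p_pgs) & p_pgs < thr,
                    stringsAsFactors = FALSE)
  met_p <- NULL
  flagged <- tab$covariable[tab$flag_pgs]
  if (!is.null(metabolites) && length(flagged)) {
    met_p <- sapply(flagged, function(v) {
      apply(metabolites, 2, function(y) uni_p(y, cohort[[v]]))
    })
    met_p <- matrix(met_p, ncol = length(flagged),
                    dimnames = list(colnames(metabolites), flagged))
  }
  list(covariables = tab, metabolite_p = met_p, threshold = thr,
       skipped = skipped)
}
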