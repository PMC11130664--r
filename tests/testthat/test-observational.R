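# Weighted observational association, diagnostics and descriptives.

test_that("weighted fit reduces to the unweighted fit under unit weights", {
  sim <- tiny_sim()
  co <- sim$cohort
  co$sample_weight <- 1
  y <- rint(sim$metabolites$fasting[, 1], seed = 1)
  a <- fit_weighted_glm(y, co, weighted = TRUE)$result
  b <- fit_weighted_glm(y, co, weighted = FALSE)$result
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("beta and se agree with an independent normal-equations solver", {
  sim <- tiny_sim()
  co <- sim$cohort
  set.seed(9)
  for (i in 1:5) {
    y <- 0.05 * co$bmi + rnorm(nrow(co))
    f <- fit_weighted_glm(y, co)$result
    X <- model.matrix(~ visit_date + subpopulation + age + sex + bmi, co)
    W <- diag(co$sample_weight)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
    e <- y - X %*% beta
    s2 <- sum(co$sample_weight * e^2) / (nrow(X) - ncol(X))
    se <- sqrt(diag(solve(t(X) %*% W %*% X)) * s2)
    expect_equal(f$beta, unname(beta["bmi", 1]), tolerance = 1e-8)
    expect_equal(f$se, unname(se["bmi"]), tolerance = 1e-8)
  }
})

test_that("perfect-fit and null limits behave", {
  sim <- tiny_sim()
  co <- sim$cohort
  f <- suppressWarnings(
    fit_weighted_glm(co$bmi, co, weighted = FALSE, covariates = character(0)))$result
  expect_lt(f$p, 1e-200)
  expect_gt(f$eta2_bmi, 0.999)
  adj <- suppressWarnings(fit_weighted_glm(co$bmi, co, weighted = FALSE))$result
  expect_gt(adj$eta2_bmi, 0.5)  # covariables absorb part of the BMI variance
  expect_gt(adj$eta2_model, 0.999)

  set.seed(10)
  nulls <- replicate(300, fit_weighted_glm(rnorm(nrow(co)), co)$result$p)
  expect_gt(ks.test(nulls, "punif")$p.value, 0.01)
})

test_that("rank-deficient designs raise a named error", {
  sim <- tiny_sim()
  co <- sim$cohort
  co$dup <- co$age
  expect_error(
    fit_weighted_glm(rnorm(nrow(co)), co,
                     covariates = c("visit_date", "subpopulation", "age",
                                    "dup", "sex")),
    "collinear.*dup")
})

test_that("sequential eta-squared decomposes hand-built designs", {
  # two orthonormal predictors, equal coefficients, no noise: 0.5 each
  n <- 128
  x1 <- rep(c(-1, 1), n / 2) / sqrt(n)
  bmi <- rep(c(-1, 1, 1, -1), n / 4) / sqrt(n)
  y <- 3 * x1 + 3 * bmi
  fit <- lm(y ~ x1 + bmi, data = data.frame(x1 = x1, bmi = bmi, y = y))
  eta <- suppressWarnings(anova_eta_squared(fit))  # noiseless by construction
  expect_equal(unname(eta["eta2_bmi"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(eta["eta2_model"]), 1, tolerance = 1e-10)

  # independence: both near zero
  sim <- tiny_sim()
  f0 <- fit_weighted_glm(rnorm(nrow(sim$cohort), sd = 1), sim$cohort)$result
  expect_lt(f0$eta2_bmi, 0.03)
})

test_that("breusch-pagan has the right size, power and degenerate value", {
  # degenerate: squared residuals constant -> LM = 0, p = 1
  x <- rep(c(-1, 1), 50)
  y <- rep(c(1, -1, -1, 1), 25)
  bp0 <- breusch_pagan(lm(y ~ x))
  expect_equal(unname(bp0["statistic"]), 0, tolerance = 1e-20)
  expect_equal(unname(bp0["p"]), 1)

  set.seed(12)
  n <- 400
  size <- replicate(300, {
    x <- rnorm(n); y <- x + rnorm(n)
    breusch_pagan(lm(y ~ x))["p"]
  })
  expect_gt(mean(size < 0.05), 0.02)
  expect_lt(mean(size < 0.05), 0.08)

  power <- replicate(50, {
    x <- runif(n, 1, 3); y <- x + rnorm(n, sd = x^2 / 3)
    breusch_pagan(lm(y ~ x))["p"]
  })
  expect_lt(median(power), 0.001)
})

test_that("describe_states summarizes paired differences", {
  set.seed(13)
  f <- matrix(rnorm(400 * 3), 400, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- f
  p[, "a"] <- f[, "a"] + 1                  # exact unit shift
  p[, "c"] <- f[, "c"] + rnorm(400) + 0.5   # delta ~ N(0.5, 1)
  d <- describe_states(f, p)
  expect_equal(d$mean_delta[d$trait == "a"], 1)
  expect_true(d$zero_variance[d$trait == "a"])
  expect_equal(d$t[d$trait == "b"], 0)
  expect_equal(d$p[d$trait == "b"], 1)
  expect_lt(abs(d$t[d$trait == "c"] - 10), 3)  # E[t] = 0.5 / (1/20)
  expect_equal(attr(d, "threshold"), 0.05 / 3)
})

test_that("covariable screen flags constructed confounders at 0.05/m_eff", {
  sim <- mid_sim()
  co <- sim$cohort
  set.seed(14)
  co$conf <- co$bmi + rnorm(nrow(co), sd = 2)   # BMI-associated
  co$indep <- rnorm(nrow(co))                   # independent
  co$flat <- 1                                  # non-varying
  expect_message(
    sc <- covariable_screen(co, sim$metabolites$fasting,
                            covariables = c("conf", "indep", "flat"),
                            m_eff = 54),
    "non-varying")
  expect_equal(sc$threshold, 9.26e-4, tolerance = 1e-3)
  tab <- sc$covariables
  expect_true(tab$flag_bmi[tab$covariable == "conf"])
  expect_false(tab$flag_bmi[tab$covariable == "indep"])
  expect_false(tab$flag_pgs[tab$covariable == "indep"])
  expect_true("flat" %in% sc$skipped)
})

test_that("date adjustment removes the generator's confounding", {
  sim <- mid_sim()
  co <- sim$cohort
  met <- sim$metabolites
  jf <- which(met$truth$type == "fasting" &
                abs(met$truth$beta_fasting) == max(abs(met$truth$beta_fasting)))[1]
  y <- rint(met$fasting[, jf], seed = 2)
  truth <- met$truth$beta_fasting[jf]
  with_date <- fit_weighted_glm(y, co)$result
  # dropping the sampling-structure terms leaves the date->trait path open
  no_date <- fit_weighted_glm(y, co, covariates = c("age", "sex"))$result
  expect_lt(abs(with_date$beta - truth), 3 * with_date$se)
  expect_gt(abs(no_date$beta - with_date$beta), with_date$se)
})
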