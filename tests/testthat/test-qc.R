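# Metabolite matrix quality control.

test_that("zeros become missing and nothing else changes", {
  m <- cbind(a = c(0, 1.2, 0, 3), b = c(1, 2, 3, 4), c = c(0, 0, 0, 0))
  out <- zeros_to_missing(m)
  expect_equal(out[, "a"], c(NA, 1.2, NA, 3), ignore_attr = TRUE)
  expect_equal(out[, "b"], m[, "b"], ignore_attr = TRUE)
  expect_true(all(is.na(out[, "c"])))
  expect_equal(unname(attr(out, "n_zeroed")), c(2L, 0L, 4L))
})

test_that("the 10-IQR filter removes exactly the gross values", {
  x <- c(1:101, 1e6)
  m <- cbind(t = x)
  out <- iqr_filter(m, k = 10)
  expect_true(is.na(out[102, 1]))
  expect_equal(sum(is.na(out)), 1L)

  # strict inequality: a value at 9.9 IQR stays
  set.seed(1)
  y <- c(rnorm(200), NA)
  med <- median(y, na.rm = TRUE); iqr <- IQR(y, na.rm = TRUE)
  y[1] <- med + 9.9 * iqr
  kept <- iqr_filter(cbind(y = y), k = 10)
  expect_equal(sum(is.na(kept)), 1L)  # only the original NA

  expect_warning(iqr_filter(cbind(const = rep(5, 10))), "zero IQR")
})

test_that("bivariate filter removes relationship outliers in both states", {
  set.seed(11)
  x <- rnorm(200, 10)
  y <- 2 * x + 1            # perfectly collinear
  f <- cbind(t = x); p <- cbind(t = y)
  # inject one pair far off the line (residual IQR is 0 for exact collinearity,
  # so add minute noise to give the residuals an IQR)
  p[, 1] <- p[, 1] + rnorm(200, sd = 0.01)
  res_iqr <- IQR(p[, 1] - (1 + 2 * x))
  p[7, 1] <- p[7, 1] + 40 * res_iqr
  out <- bivariate_outlier_filter(f, p, k = 10)
  expect_true(is.na(out$fasting[7, 1]) && is.na(out$postprandial[7, 1]))
  expect_equal(out$report$n_removed, 1L)
  expect_equal(sum(is.na(out$fasting)), 1L)

  # fewer than 10 complete pairs: skipped with a warning
  expect_warning(
    sk <- bivariate_outlier_filter(cbind(a = c(1:5, rep(NA, 5))),
                                   cbind(a = c(2 * (1:5) + 0.1 * rnorm(5), rep(NA, 5)))),
    "skipped")
  expect_true(sk$report$skipped[1])

  # calibration: on clean generator output the removal fraction is tiny
  met <- mid_sim()$metabolites
  clean <- bivariate_outlier_filter(met$fasting, met$postprandial, k = 10)
  expect_lt(sum(clean$report$n_removed) / length(met$fasting), 0.005)
})

test_that("feature-then-sample missingness filter follows its thresholds", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  expect_identical(sample_feature_filter(m)$matrix, m)

  m2 <- m
  m2[1:4, 2] <- c(NA, NA, NA, 1)  # feature f2 75% missing
  out <- sample_feature_filter(m2, 0.2, 0.2)
  expect_equal(out$removed_features, "f2")

  # after the feature pass, sample s1 misses 2 of 2 remaining features
  m3 <- m
  m3[, 3] <- NA            # f3 fully missing -> removed first
  m3[1, 1:2] <- NA         # s1 then 100% missing
  out3 <- sample_feature_filter(m3, 0.5, 0.5)
  expect_equal(out3$removed_features, "f3")
  expect_equal(out3$removed_samples, "s1")
  expect_equal(out3$report$order, c("features", "samples"))

  m4 <- matrix(NA_real_, 3, 2)
  expect_error(sample_feature_filter(m4), "all features removed")
})

test_that("the QC chain is idempotent and reconciles its counts", {
  sim <- suppressWarnings(simulate_cohort(
    tiny_cfg(missing_rate = 0.02, outlier_rate = 0.005), inject = TRUE))
  f <- sim$metabolites$fasting
  p <- sim$metabolites$postprandial
  once <- suppressWarnings(run_metabolite_qc(f, p))
  twice <- suppressWarnings(run_metabolite_qc(once$fasting, once$postprandial))
  expect_identical(once$fasting, twice$fasting)
  expect_identical(once$postprandial, twice$postprandial)

  # counts reconcile: missingness delta equals the per-rule cell totals
  rep1 <- once$report
  delta_f <- rep1$missing_after_rules[["fasting"]] - rep1$missing_before[["fasting"]]
  expect_equal(delta_f,
               unname(rep1$cells_zeroed["fasting"] + rep1$cells_univariate["fasting"] +
                        rep1$cells_bivariate_pairs))
})

test_that("QC has full recall on injected outliers and few false flags", {
  sim <- suppressWarnings(simulate_cohort(
    tiny_cfg(missing_rate = 0, outlier_rate = 0.01), inject = TRUE))
  inj <- sim$injection$fasting
  out <- suppressWarnings(run_metabolite_qc(sim$metabolites$fasting,
                                            sim$metabolites$postprandial))
  outliers <- inj[inj$kind == "outlier", ]
  ids <- rownames(sim$metabolites$fasting)[outliers$row]
  traits <- colnames(sim$metabolites$fasting)[outliers$col]
  flagged <- vapply(seq_len(nrow(outliers)), function(i) {
    !(ids[i] %in% rownames(out$fasting)) || !(traits[i] %in% colnames(out$fasting)) ||
      is.na(out$fasting[ids[i], traits[i]])
  }, logical(1))
  expect_true(all(flagged))  # recall = 1

  # false-flag rate on clean Gaussian data < 0.1% per rule
  set.seed(21)
  clean <- matrix(rnorm(500 * 40), 500, 40,
                  dimnames = list(NULL, paste0("t", 1:40)))
  expect_equal(sum(is.na(iqr_filter(clean, k = 10))), 0L)
  bi <- bivariate_outlier_filter(clean, clean + matrix(rnorm(500 * 40), 500), k = 10)
  expect_lt(sum(bi$report$n_removed) / length(clean), 0.001)
})
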