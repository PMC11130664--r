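# Synthetic cohort generator: genotypes, BMI, weights, metabolites, injection.

test_that("genotype dosages respect frequencies, bounds and the seed", {
  cfg <- synth_config(n_random = 5000, n_oversampled = 5000, n_snps = 1,
                      maf_range = c(0.5, 0.5), n_metabolites = 4, seed = 1)
  g <- generate_genotypes(cfg)
  expect_true(all(g$dosages >= 0 & g$dosages <= 2))
  expect_gt(mean(g$dosages), 0.95)   # binomial expectation 1.0 at maf 0.5
  expect_lt(mean(g$dosages), 1.05)

  cfg2 <- synth_config(n_random = 600, n_oversampled = 600, n_snps = 30,
                       n_metabolites = 4, seed = 5)
  g2 <- generate_genotypes(cfg2)
  emp <- colMeans(g2$dosages) / 2
  expect_true(all(abs(emp - g2$variants$frequency) < 0.05))
  expect_false(anyDuplicated(g2$variants$id) > 0)

  expect_error(synth_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(synth_config(n_snps = 0), "positive count")

  expect_identical(generate_genotypes(cfg2)$dosages, g2$dosages)
})

test_that("BMI generation hits the PGS and date variance targets", {
  sim <- mid_sim()
  co <- sim$cohort
  r2 <- attr(co, "realized_pgs_r2")
  expect_gt(r2, 0.03)
  expect_lt(r2, 0.06)
  expect_gt(attr(co, "realized_date_r2"), 0.12)
  expect_lt(attr(co, "realized_date_r2"), 0.28)
  expect_gt(min(co$bmi[co$subpopulation == "oversampled"]), 27)
  expect_false(anyNA(co$bmi))

  # null construction: no PGS signal
  cfg0 <- synth_config(n_random = 1000, n_oversampled = 1000, n_snps = 25,
                       n_metabolites = 4, pgs_variance_explained = 0, seed = 8)
  g0 <- generate_genotypes(cfg0)
  w0 <- generate_variant_weights(cfg0, g0)
  co0 <- generate_bmi(cohort_skeleton(cfg0), g0, w0, cfg0)
  expect_lt(abs(cor(co0$bmi, co0$pgs)), 0.05)
})

test_that("visit dates are nondecreasing within each subpopulation batch", {
  sk <- cohort_skeleton(tiny_cfg())
  for (sp in c("random", "oversampled")) {
    d <- sk$visit_date[sk$subpopulation == sp]
    expect_true(all(diff(d) >= 0))
  }
})

test_that("sample weights are the binned density ratio", {
  # identical BMI distributions in both strata: weights ~ 1. The stratum
  # size must dominate the bin count for the per-bin density ratio to
  # concentrate (with 20 bins and n per stratum the max deviation shrinks
  # like sqrt(2 * 20 / n)), so this property needs a large n.
  set.seed(3)
  n_half <- 100000
  bmi <- rnorm(2 * n_half, 28, 3)
  co <- data.frame(individual_id = as.character(seq_len(2 * n_half)),
                   subpopulation = rep(c("random", "oversampled"), each = n_half),
                   bmi = bmi, sample_weight = 1)
  co <- derive_sample_weights(co)
  w_o <- co$sample_weight[co$subpopulation == "oversampled"]
  expect_lt(max(abs(w_o - 1)), 0.1)
  expect_lt(abs(weighted.mean(co$bmi[co$subpopulation == "oversampled"], w_o) -
                  mean(co$bmi[co$subpopulation == "random"])), 0.5)

  # two-bin toy: random 50/50, oversampled 25/75 -> raw weights 2.0, 0.667
  toy <- data.frame(individual_id = as.character(1:80),
                    subpopulation = rep(c("random", "oversampled"), each = 40),
                    bmi = c(rep(c(20, 30), each = 20),
                            rep(20, 10), rep(30, 30)),
                    sample_weight = 1)
  toy_w <- derive_sample_weights(toy, n_bins = 2L)
  bins <- attr(toy_w, "weight_bins")
  expect_equal(bins$raw_weight, c(2, 2 / 3), tolerance = 1e-12)

  # default world: density-ratio weights equalize the shared support
  co2 <- mid_sim()$cohort
  over <- co2$subpopulation == "oversampled"
  shared <- co2$bmi > 27
  wm <- weighted.mean(co2$bmi[over], co2$sample_weight[over])
  expect_lt(abs(wm - mean(co2$bmi[!over & shared])), 0.5)
})

test_that("missing/outlier injection is bookkept and bounded", {
  m <- mid_sim()$metabolites$fasting
  cfg0 <- tiny_cfg(missing_rate = 0, outlier_rate = 0)
  expect_identical(inject_missing_and_outliers(m, cfg0)$matrix, m)

  cfg1 <- tiny_cfg(missing_rate = 0.05, outlier_rate = 0)
  out <- inject_missing_and_outliers(m, cfg1)
  frac <- with(out, sum(injected$kind %in% c("zero", "na")) / length(m))
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  expect_true(all(out$matrix[cbind(out$injected$row, out$injected$col)] == 0 |
                    is.na(out$matrix[cbind(out$injected$row, out$injected$col)])))

  # gross outliers land beyond the 10-IQR fence: recall 1 under iqr_filter
  cfg2 <- tiny_cfg(missing_rate = 0, outlier_rate = 0.01)
  out2 <- inject_missing_and_outliers(m, cfg2)
  filtered <- iqr_filter(out2$matrix, k = 10)
  hit <- is.na(filtered[cbind(out2$injected$row, out2$injected$col)])
  expect_true(all(hit))
})

test_that("metabolite matrices have the stated correlation structure", {
  sim <- mid_sim()
  met <- sim$metabolites
  fp_cor <- diag(cor(met$fasting, met$postprandial))
  expect_true(all(fp_cor > 0.3))

  # unit-variance calibration in both states
  expect_true(all(abs(apply(met$fasting, 2, sd) - 1) < 0.12))
  expect_true(all(abs(apply(met$postprandial, 2, sd) - 1) < 0.12))

  # traits within a class correlate more than across classes
  cm <- abs(cor(met$fasting))
  cls <- sim$metabolites$annotation$size_rank
  same <- outer(cls, cls, "==") & upper.tri(cm)
  diff <- outer(cls, cls, "!=") & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[diff]))

  expect_error(generate_metabolites(data.frame(bmi = NA), tiny_cfg()),
               "missing BMI")
})

test_that("the generator is byte-identical under a fixed config and seed", {
  a <- suppressWarnings(simulate_cohort(tiny_cfg(), inject = TRUE))
  b <- suppressWarnings(simulate_cohort(tiny_cfg(), inject = TRUE))
  expect_identical(a$cohort$bmi, b$cohort$bmi)
  expect_identical(a$metabolites$fasting, b$metabolites$fasting)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$injection, b$injection)
})

test_that("response effect is recovered from the generating value", {
  # causal-chain recovery within 3 SE at n = 2000 for the mid cohort
  sim <- mid_sim()
  co <- sim$cohort
  met <- sim$metabolites
  resp <- build_response_matrix(met$fasting, met$postprandial)
  rr <- rint_matrix(resp$response, seed = 7)
  jr <- which(met$truth$type == "response" &
                abs(met$truth$beta_response) == max(abs(met$truth$beta_response)))[1]
  o <- fit_weighted_glm(rr[, jr], co)$result
  expect_lt(abs(o$beta - met$truth$beta_response[jr]), 3 * o$se)
})
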