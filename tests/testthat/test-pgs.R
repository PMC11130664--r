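# Polygenic score: harmonization, alignment, scoring.

# Minimal two-variant cohort for allele bookkeeping tests.
toy_geno <- function(d1 = c(2, 1, 0, 1), d2 = c(1, 1, 2, 0),
                     ea = c("A", "C"), oa = c("G", "T")) {
  d <- cbind(rs1 = d1, rs2 = d2)
  rownames(d) <- paste0("id", 1:4)
  out <- list(dosages = d,
              variants = data.frame(id = c("rs1", "rs2"),
                                    effect_allele = ea, other_allele = oa,
                                    frequency = colMeans(d) / 2,
                                    stringsAsFactors = FALSE))
  class(out) <- "genotype_dosage"
  out
}

test_that("harmonize keeps, swaps and drops as the matching rule dictates", {
  g <- toy_geno()
  f1 <- mean(g$dosages[, 1]) / 2
  w <- data.frame(id = c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "T", "A"),
                  other_allele = c("G", "C", "C"),
                  beta = c(0.03, 0.05, 0.02),
                  eaf = c(f1 + 0.02, 0.5, 0.3),
                  stringsAsFactors = FALSE)
  h <- harmonize(w, g)
  expect_equal(h$log$action, c("keep", "swap", "drop"))
  expect_equal(h$weights$beta, c(0.03, -0.05))
  expect_equal(h$weights$effect_allele[2], "C")  # restored to cohort orientation
  expect_false(any(h$weights$flipped))  # negation alone re-orients the effect
  # the harmonized score matches scoring the published row on its own allele
  s_harm <- compute_pgs(h$weights[2, ], g)$score
  s_pub <- 0.05 * (2 - g$dosages[, "rs2"])
  expect_equal(unname(s_harm - s_pub), rep(mean(s_harm - s_pub), 4),
               tolerance = 1e-12)

  # MAF difference beyond 0.1 drops the variant
  w2 <- w[1, ]
  w2$eaf <- pmin(f1, 1 - f1) + 0.15
  expect_error(harmonize(w2, g), "no variants survived")
  w3 <- rbind(w[1, ], w2); w3$id[2] <- "rs2"; w3$other_allele[2] <- "T"
  w3$effect_allele[2] <- "C"
  h3 <- harmonize(w3, g)
  expect_equal(h3$log$action[2], "drop")
  expect_equal(h3$log$reason[2], "maf_mismatch")

  # every drop carries exactly one recorded cause
  expect_true(all(h$log$reason[h$log$action == "drop"] != ""))
})

test_that("harmonization is order-independent over variants", {
  sim <- tiny_sim()
  w <- sim$gwas_weights
  h1 <- harmonize(w, sim$genotypes)
  h2 <- harmonize(w[rev(seq_len(nrow(w))), ], sim$genotypes)
  o1 <- h1$weights[order(h1$weights$id), ]
  o2 <- h2$weights[order(h2$weights$id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("align_positive flips signs without changing the ranking", {
  g <- toy_geno()
  w <- data.frame(id = c("rs1", "rs2"), effect_allele = c("A", "C"),
                  other_allele = c("G", "T"), beta = c(-0.02, 0.04),
                  eaf = c(0.3, 0.6), flipped = c(FALSE, FALSE),
                  stringsAsFactors = FALSE)
  a <- align_positive(w)
  expect_true(all(a$beta > 0))
  expect_equal(a$beta[1], 0.02)
  expect_equal(a$effect_allele[1], "G")

  pos <- data.frame(id = "rs1", effect_allele = "A", other_allele = "G",
                    beta = 0.1, eaf = 0.2, flipped = FALSE,
                    stringsAsFactors = FALSE)
  expect_identical(align_positive(pos), pos)

  s_after <- compute_pgs(a, g)$score
  expect_equal(cor(rank(compute_pgs(w, g)$score), rank(s_after)), 1)

  wz <- w; wz$beta[1] <- 0
  expect_warning(az <- align_positive(wz), "zero-effect")
  expect_equal(nrow(az), 1L)
})

test_that("compute_pgs is the weighted dosage sum with mean imputation", {
  g <- toy_geno(d1 = c(2, 0, 0, 0), d2 = c(1, 0, 0, 0))
  w <- data.frame(id = c("rs1", "rs2"), effect_allele = c("A", "C"),
                  other_allele = c("G", "T"), beta = c(0.03, 0.05),
                  eaf = c(0.25, 0.4), flipped = c(FALSE, FALSE),
                  stringsAsFactors = FALSE)
  s <- compute_pgs(w, g)
  expect_equal(unname(s$score[1]), 0.11)       # 0.03*2 + 0.05*1
  expect_equal(unname(s$score[2]), 0)          # all dosages zero

  gna <- g; gna$dosages[3, "rs2"] <- NA
  sna <- compute_pgs(w, gna)
  expect_equal(sna$n_imputed_cells, 1L)
  expect_equal(unname(sna$score[3]), 0.05 * 2 * 0.4)

  # invariance to variant ordering; linearity in weights
  s_rev <- compute_pgs(w[2:1, ], g)
  expect_equal(s_rev$score, s$score)
  w2 <- w; w2$beta <- 2 * w$beta
  expect_equal(compute_pgs(w2, g)$score, 2 * s$score)
})

test_that("the harmonized PGS explains the configured share of BMI variance", {
  sim <- mid_sim()
  h <- harmonize(sim$gwas_weights, sim$genotypes)
  a <- align_positive(h$weights)
  s <- compute_pgs(a, sim$genotypes)
  r2 <- summary(lm(sim$cohort$bmi ~ s$score))$r.squared
  expect_gt(r2, 0.03)
  expect_lt(r2, 0.06)
  # mismatched rows were dropped, swapped rows recovered
  expect_equal(sort(h$log$id[h$log$action == "drop"]),
               sort(attr(sim$gwas_weights, "mismatched")))
})
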