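#' Build the cohort skeleton
#'
#' Creates individual ids, subpopulation labels, visit dates, age and sex,
#' before BMI is generated. The randomly sampled subpopulation is visited in a
#' late, compressed window of the study period while the oversampled
#' subpopulation is visited throughout, reproducing the date-by-subpopulation
#' structure that makes visit date a BMI covariate. Visit dates are ordinal
#' day indices, nondecreasing within each subpopulation batch.
#'
#' @param cfg A [synth_config()].
#' @return A data.frame with `individual_id`, `subpopulation`, `visit_date`,
#'   `age`, `sex`.
#' @export
cohort_skeleton <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_random + cfg$n_oversampled
  withr_seed(stage_seed(cfg$seed, "skeleton"), {
    study_days <- 1460L  # a four-year study window
    subpop <- rep(c("random", "oversampled"), c(cfg$n_random, cfg$n_oversampled))
    date <- integer(n)
    date[subpop == "random"] <-
      sort(sample.int(round(0.3 * study_days), cfg$n_random, replace = TRUE) +
             round(0.7 * study_days))
    date[subpop == "oversampled"] <-
      sort(sample.int(study_days, cfg$n_oversampled, replace = TRUE))
    data.frame(individual_id = sprintf("id%05d", seq_len(n)),
               subpopulation = subpop,
               visit_date = date,
               age = round(stats::runif(n, 45, 65), 1),
               sex = sample(c("female", "male"), n, replace = TRUE,
                            prob = c(0.52, 0.48)),
               stringsAsFactors = FALSE)
  })
}

#' Generate BMI from the polygenic score, visit date and covariates
#'
#' BMI is a linear combination of the true PGS, a visit-date trend, sex and
#' age, plus Gaussian noise. Two internal coefficients are calibrated by a
#' deterministic fixed-point loop (the noise stream is held fixed across
#' iterations) so that, in the realized pooled cohort, the PGS explains
#' `cfg$pgs_variance_explained` and visit date explains
#' `cfg$date_structure_r2` of BMI variance by univariable regression. For the
#' oversampled subpopulation the noise term is drawn from its truncated
#' conditional distribution (inverse-CDF form, equivalent to rejection
#' sampling the noise until BMI exceeds the threshold), so every oversampled
#' BMI exceeds `cfg$oversample_threshold`.
#'
#' @param skeleton Output of [cohort_skeleton()].
#' @param genotypes Output of [generate_genotypes()].
#' @param weights Output of [generate_variant_weights()]; its
#'   `"true_weights"` attribute defines the generating PGS.
#' @param cfg A [synth_config()].
#' @return `skeleton` with columns `bmi`, `pgs` (the true generating score)
#'   and `sample_weight` (all 1, until [derive_sample_weights()] is run).
#'   Attributes `realized_pgs_r2` and `realized_date_r2` record the
#'   calibration outcome.
#' @examples
#' cfg <- synth_config(n_random = 300, n_oversampled = 700, n_snps = 30,
#'                     n_metabolites = 5, seed = 2)
#' geno <- generate_genotypes(cfg)
#' w <- generate_variant_weights(cfg, geno)
#' cohort <- generate_bmi(cohort_skeleton(cfg), geno, w, cfg)
#' min(cohort$bmi[cohort$subpopulation == "oversampled"]) > 27
#' @export
generate_bmi <- function(skeleton, genotypes, weights, cfg) {
  validate_synth_config(cfg)
  if (cfg$pgs_variance_explained >= 1)
    stop("pgs_variance_explained must be < 1")
  n <- nrow(skeleton)
  if (nrow(genotypes$dosages) != n)
    stop("genotype matrix and cohort skeleton have incompatible row counts")
  true_w <- attr(weights, "true_weights") %||% weights
  pgs_raw <- drop(genotypes$dosages[, true_w$id, drop = FALSE] %*% true_w$beta)
  g_z <- zscore(pgs_raw)
  d_z <- zscore(skeleton$visit_date)
  sex_f <- as.numeric(skeleton$sex == "female") - 0.5
  age_z <- zscore(skeleton$age)
  over <- skeleton$subpopulation == "oversampled"
  vb <- cfg$bmi_sd^2

  withr_seed(stage_seed(cfg$seed, "bmi"), {
    u <- stats::runif(n)  # fixed noise stream reused across calibration passes
  })

  draw <- function(b_g, b_d) {
    sys_var <- b_g^2 + (b_d * stats::sd(d_z))^2 + 0.5^2 * 0.25 + 0.4^2
    sigma_e <- sqrt(max(vb - sys_var, 1))
    lp <- cfg$bmi_mean + b_g * g_z - b_d * d_z +
      0.5 * sex_f + 0.4 * age_z
    e <- numeric(n)
    e[!over] <- sigma_e * stats::qnorm(u[!over])
    # truncated-normal noise: BMI = lp + e > threshold
    p0 <- stats::pnorm((cfg$oversample_threshold - lp[over]) / sigma_e)
    e[over] <- sigma_e * stats::qnorm(p0 + u[over] * (1 - p0) * 0.999999)
    lp + e
  }

  r2_of <- function(x, y) summary(stats::lm(y ~ x))$r.squared

  b_g <- sqrt(cfg$pgs_variance_explained * vb)
  b_d <- sqrt(0.5 * cfg$date_structure_r2 * vb)
  bmi <- draw(b_g, b_d)
  for (i in seq_len(6)) {
    r2_g <- r2_of(g_z, bmi)
    r2_d <- r2_of(d_z, bmi)
    if (cfg$pgs_variance_explained > 0)
      b_g <- b_g * sqrt(cfg$pgs_variance_explained / max(r2_g, 1e-8))
    else b_g <- 0
    if (cfg$date_structure_r2 > 0)
      b_d <- b_d * sqrt(cfg$date_structure_r2 / max(r2_d, 1e-8))
    else b_d <- 0
    bmi <- draw(b_g, b_d)
  }

  cohort <- skeleton
  cohort$bmi <- bmi
  cohort$pgs <- pgs_raw
  cohort$sample_weight <- 1
  attr(cohort, "realized_pgs_r2") <- r2_of(g_z, bmi)
  attr(cohort, "realized_date_r2") <- r2_of(d_z, bmi)
  cohort
}

#' Derive sampling weights equalizing the BMI distributions
#'
#' Computes per-individual weights so that the weighted BMI distribution of
#' the oversampled subpopulation emulates that of the randomly sampled one.
#' Random-subpopulation weights are 1. Oversampled weights are the
#' random-to-oversampled density ratio over BMI bins (equal-count bins of the
#' random stratum restricted to the shared BMI support), renormalized to mean
#' 1 within the oversampled stratum.
#'
#' @param cohort A cohort table with `bmi` and `subpopulation`.
#' @param n_bins Number of equal-count BMI bins (default 20).
#' @return `cohort` with `sample_weight` filled in. The attribute
#'   `"weight_bins"` records the bin table (breaks, stratum densities, raw
#'   and renormalized weights).
#' @export
derive_sample_weights <- function(cohort, n_bins = 20L) {
  over <- cohort$subpopulation == "oversampled"
  if (!any(over) || !all(c("random", "oversampled") %in% cohort$subpopulation))
    stop("both subpopulations must be nonempty")
  if (anyNA(cohort$bmi)) stop("missing BMI")
  b_r <- cohort$bmi[!over]
  b_o <- cohort$bmi[over]
  breaks <- unique(stats::quantile(b_r, probs = seq(0, 1, length.out = n_bins + 1)))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  bin_r <- cut(b_r, breaks)
  bin_o <- cut(b_o, breaks)
  p_r <- as.numeric(table(bin_r)) / length(b_r)
  p_o <- as.numeric(table(bin_o)) / length(b_o)
  raw_w <- ifelse(p_o > 0, p_r / p_o, 0)
  if (any(p_o == 0 & p_r > 0))
    warning("empty oversampled BMI bin with random-stratum mass; weight set to 0")
  w_o <- raw_w[as.integer(bin_o)]
  norm <- mean(w_o)
  if (norm <= 0) stop("all oversampled weights are zero")
  cohort$sample_weight[!over] <- 1
  cohort$sample_weight[over] <- w_o / norm
  attr(cohort, "weight_bins") <-
    data.frame(bin = levels(bin_r), p_random = p_r, p_oversampled = p_o,
               raw_weight = raw_w, weight = raw_w / norm)
  cohort
}
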