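#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every tunable of the synthetic world: a cohort of two
#' subpopulations (one sampled at random, one oversampled for BMI above a
#' threshold), genotype dosages with GWAS effect weights feeding a polygenic
#' score (PGS), BMI built from the PGS plus a sampling-date trend, and paired
#' fasting/postprandial metabolite matrices carrying BMI effects on the
#' fasting level, the postprandial level, and the meal response.
#'
#' Defaults reproduce the study design the pipeline targets: 1406 random and
#' 4111 oversampled individuals, an oversampling threshold of BMI 27, 656
#' candidate variants, a PGS explaining ~4.5% of BMI variance, a sampling-date
#' structure explaining ~20% of BMI variance, and 229 metabolite traits in 14
#' correlated classes.
#'
#' @param n_random Number of individuals in the randomly sampled subpopulation.
#' @param n_oversampled Number of individuals in the high-BMI subpopulation.
#' @param oversample_threshold BMI (kg/m^2) above which the oversampled
#'   subpopulation is recruited.
#' @param n_snps Number of variants in the dosage matrix.
#' @param maf_range Length-2 numeric, the minor allele frequency range in
#'   (0, 0.5] from which per-variant frequencies are drawn.
#' @param pgs_variance_explained Target fraction of pooled BMI variance
#'   explained by the true PGS (univariable regression R^2).
#' @param n_metabolites Number of metabolite traits.
#' @param n_classes Number of correlated metabolite classes (blocks).
#' @param beta_fasting,beta_postprandial,beta_response Per-trait BMI effect
#'   sizes, in trait-SD units per BMI unit, assigned to the traits carrying
#'   the corresponding effect type (see [generate_metabolites()]).
#' @param date_structure_r2 Target fraction of pooled BMI variance explained
#'   by visit date.
#' @param class_correlation Fraction of the non-BMI latent variance shared
#'   within a metabolite class.
#' @param effect_multipliers Numeric levels from which each effect-carrying
#'   trait's per-trait multiplier is drawn (scales the state's beta), giving
#'   the cohort a spread of effect sizes with both signs. Use `1` for
#'   constant full-strength effects.
#' @param date_effect BMI-independent visit-date loading on the latent
#'   metabolite component (SD units); creates genuine date confounding.
#' @param missing_rate Fraction of cells set missing by
#'   [inject_missing_and_outliers()].
#' @param outlier_rate Fraction of cells turned into gross outliers.
#' @param bmi_mean,bmi_sd Mean and SD of the base (random-subpopulation) BMI
#'   distribution.
#' @param seed Integer seed; every generator consumes a stream derived from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_random = 100, n_oversampled = 300, n_snps = 20,
#'                     n_metabolites = 12, seed = 1)
#' @export
synth_config <- function(n_random = 1406,
                         n_oversampled = 4111,
                         oversample_threshold = 27,
                         n_snps = 656,
                         maf_range = c(0.05, 0.5),
                         pgs_variance_explained = 0.045,
                         n_metabolites = 229,
                         n_classes = 14,
                         beta_fasting = 0.07,
                         beta_postprandial = 0.04,
                         beta_response = -0.08,
                         date_structure_r2 = 0.20,
                         class_correlation = 0.35,
                         effect_multipliers = c(-1, -0.5, 0.5, 1),
                         date_effect = 0.10,
                         missing_rate = 0.01,
                         outlier_rate = 0.002,
                         bmi_mean = 26.2,
                         bmi_sd = 4.4,
                         seed = 1L) {
  cfg <- list(n_random = as.integer(n_random),
              n_oversampled = as.integer(n_oversampled),
              oversample_threshold = oversample_threshold,
              n_snps = as.integer(n_snps),
              maf_range = as.numeric(maf_range),
              pgs_variance_explained = pgs_variance_explained,
              n_metabolites = as.integer(n_metabolites),
              n_classes = as.integer(n_classes),
              beta_fasting = beta_fasting,
              beta_postprandial = beta_postprandial,
              beta_response = beta_response,
              date_structure_r2 = date_structure_r2,
              class_correlation = class_correlation,
              effect_multipliers = as.numeric(effect_multipliers),
              date_effect = date_effect,
              missing_rate = missing_rate,
              outlier_rate = outlier_rate,
              bmi_mean = bmi_mean,
              bmi_sd = bmi_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c("n_random", "n_oversampled", "n_snps", "n_metabolites", "n_classes")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("synth_config: '", nm, "' must be a positive count")
  }
  fracs <- c("pgs_variance_explained", "date_structure_r2", "missing_rate",
             "outlier_rate", "class_correlation")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (length(v) != 1L || is.na(v) || v < 0 || v >= 1)
      stop("synth_config: '", nm, "' must lie in [0, 1)")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2L || any(is.na(mr)) || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5)
    stop("synth_config: 'maf_range' must be within (0, 0.5]")
  if (cfg$bmi_sd <= 0) stop("synth_config: 'bmi_sd' must be positive")
  if (!length(cfg$effect_multipliers) || anyNA(cfg$effect_multipliers))
    stop("synth_config: 'effect_multipliers' must be nonempty and finite")
  invisible(cfg)
}

# Derive an independent, reproducible sub-seed for a named generator stage.
# Kept below 2^31 so it is a valid R integer for any base seed.
stage_seed <- function(seed, stage) {
  offsets <- c(genotypes = 11L, weights = 23L, skeleton = 37L, bmi = 53L,
               metabolites = 71L, inject = 89L, ties = 101L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2001L + offsets[[stage]]
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic cohort configuration\n")
  cat(sprintf("  individuals : %d random + %d oversampled (BMI > %g)\n",
              x$n_random, x$n_oversampled, x$oversample_threshold))
  cat(sprintf("  variants    : %d, MAF in [%.2f, %.2f]\n",
              x$n_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  PGS R2      : %.3f   date R2: %.3f\n",
              x$pgs_variance_explained, x$date_structure_r2))
  cat(sprintf("  metabolites : %d in %d classes; betas (f/p/r) = %g / %g / %g\n",
              x$n_metabolites, x$n_classes, x$beta_fasting,
              x$beta_postprandial, x$beta_response))
  invisible(x)
}
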