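#' Generate a genotype dosage matrix
#'
#' Draws per-variant allele frequencies uniformly from `cfg$maf_range` and
#' dosages as binomial(2, maf) counts with a small uniform jitter, clipped to
#' \[0, 2\], mimicking imputed dosage data. Variants are biallelic with
#' single-base alleles.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `genotype_dosage`: a list with `dosages`
#'   (individuals x variants numeric matrix, rownames = individual ids,
#'   colnames = variant ids) and `variants` (data.frame with `id`,
#'   `effect_allele`, `other_allele`, `frequency`).
#' @examples
#' g <- generate_genotypes(synth_config(n_random = 50, n_oversampled = 50,
#'                                      n_snps = 10, seed = 1))
#' range(g$dosages)
#' @export
generate_genotypes <- function(cfg) {
  validate_synth_config(cfg)
  n <- cfg$n_random + cfg$n_oversampled
  p <- cfg$n_snps
  withr_seed(stage_seed(cfg$seed, "genotypes"), {
    maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    hard <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), nrow = n)
    jitter <- matrix(stats::runif(n * p, -0.05, 0.05), nrow = n)
    dosages <- pmin(pmax(hard + jitter, 0), 2)
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, p, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
    ids <- sprintf("rs%06d", seq_len(p))
    rownames(dosages) <- sprintf("id%05d", seq_len(n))
    colnames(dosages) <- ids
    out <- list(dosages = dosages,
                variants = data.frame(id = ids, effect_allele = ea,
                                      other_allele = oa, frequency = maf,
                                      stringsAsFactors = FALSE))
    class(out) <- "genotype_dosage"
    out
  })
}

# Evaluate `expr` under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a GWAS-style variant weight table
#'
#' Produces effect-allele weights for the cohort's variants, as an external
#' GWAS would publish them: effect sizes on the BMI scale, a fraction of rows
#' stored with the allele pair swapped (effect size negated), and a small
#' fraction with an incompatible allele pair that harmonization must drop.
#' With the default 656 variants and 1.5% mismatch rate, roughly 646 variants
#' survive harmonization.
#'
#' @param cfg A [synth_config()].
#' @param genotypes The matching [generate_genotypes()] output.
#' @param swap_fraction Fraction of rows stored on the opposite allele
#'   orientation (recoverable by harmonization).
#' @param mismatch_fraction Fraction of rows given an allele pair incompatible
#'   with the cohort (dropped by harmonization).
#' @return A data.frame with columns `id`, `effect_allele`, `other_allele`,
#'   `beta`, `eaf`. The attribute `"true_weights"` holds the unperturbed,
#'   cohort-aligned table used to build the generating PGS.
#' @export
generate_variant_weights <- function(cfg, genotypes,
                                     swap_fraction = 0.3,
                                     mismatch_fraction = 10 / 656) {
  stopifnot(inherits(genotypes, "genotype_dosage"))
  v <- genotypes$variants
  p <- nrow(v)
  withr_seed(stage_seed(cfg$seed, "weights"), {
    # GWAS-like magnitudes (kg/m^2 per allele), all aligned BMI-increasing
    beta <- abs(stats::rnorm(p, 0, 0.03)) + 0.005
    true <- data.frame(id = v$id, effect_allele = v$effect_allele,
                       other_allele = v$other_allele, beta = beta,
                       eaf = v$frequency, stringsAsFactors = FALSE)
    pub <- true
    swap <- stats::runif(p) < swap_fraction
    pub$effect_allele[swap] <- true$other_allele[swap]
    pub$other_allele[swap] <- true$effect_allele[swap]
    pub$beta[swap] <- -true$beta[swap]
    pub$eaf[swap] <- 1 - true$eaf[swap]
    mism <- stats::runif(p) < mismatch_fraction
    if (any(mism)) {
      bases <- c("A", "C", "G", "T")
      pub$other_allele[mism] <- vapply(pub$effect_allele[mism], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
      # guarantee the pair cannot be matched even after swapping
      same <- pub$other_allele == true$other_allele | pub$other_allele == true$effect_allele
      redo <- mism & same
      pub$other_allele[redo] <- vapply(seq_len(sum(redo)), function(i) {
        j <- which(redo)[i]
        setdiff(bases, c(true$effect_allele[j], true$other_allele[j], pub$effect_allele[j]))[1]
      }, character(1))
    }
    attr(pub, "true_weights") <- true
    attr(pub, "mismatched") <- v$id[mism]
    pub
  })
}
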