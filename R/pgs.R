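#' Harmonize GWAS variant weights against cohort genotypes
#'
#' Matches each GWAS weight row to the cohort's variant metadata. Per
#' variant: if effect/other alleles match as-is the row is kept; if they
#' match after swapping, the row is kept re-oriented to the cohort (effect
#' size negated, alleles and frequency restored to the cohort's effect
#' allele, which is equivalent to the dosage map \eqn{d \to 2 - d} up to a
#' per-individual constant); any other allele configuration is dropped. Rows whose folded minor allele frequency differs from the
#' cohort's by more than `maf_tol` are dropped as well (frequency is the only
#' guard against mis-mapped palindromic A/T and C/G variants, since no strand
#' flipping is attempted). Multi-allelic or non-ACGT rows are rejected.
#'
#' @param weights Data.frame with `id`, `effect_allele`, `other_allele`,
#'   `beta`, `eaf` (GWAS effect-allele frequency).
#' @param genotypes A `genotype_dosage` object ([generate_genotypes()] or
#'   [read_genotypes_tsv()]); cohort allele frequency is recomputed from the
#'   dosages.
#' @param maf_tol Maximum tolerated folded-MAF difference (default 0.1).
#' @return A list with `weights` (harmonized rows: `id`, `effect_allele`,
#'   `other_allele`, `beta`, `eaf`, `flipped`) and `log` (per input variant:
#'   `id`, `action` in \{keep, swap, drop\}, `reason`).
#' @export
harmonize <- function(weights, genotypes, maf_tol = 0.1) {
  req <- c("id", "effect_allele", "other_allele", "beta", "eaf")
  if (!all(req %in% names(weights)))
    stop("weight table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(weights$id)) stop("variant ids must be unique")
  ok_allele <- weights$effect_allele %in% c("A", "C", "G", "T") &
    weights$other_allele %in% c("A", "C", "G", "T") &
    weights$effect_allele != weights$other_allele
  v <- genotypes$variants
  cohort_freq <- colMeans(genotypes$dosages, na.rm = TRUE) / 2
  idx <- match(weights$id, v$id)

  action <- rep("drop", nrow(weights))
  reason <- rep("not_in_cohort", nrow(weights))
  reason[!ok_allele] <- "invalid_alleles"
  present <- !is.na(idx) & ok_allele

  ea_c <- v$effect_allele[idx]
  oa_c <- v$other_allele[idx]
  same <- present & weights$effect_allele == ea_c & weights$other_allele == oa_c
  swap <- present & weights$effect_allele == oa_c & weights$other_allele == ea_c
  mism <- present & !same & !swap
  reason[mism] <- "allele_mismatch"

  fold <- function(f) pmin(f, 1 - f)
  maf_gwas <- fold(weights$eaf)
  maf_cohort <- fold(cohort_freq[match(weights$id, names(cohort_freq))])
  freq_bad <- (same | swap) & abs(maf_gwas - maf_cohort) > maf_tol
  reason[freq_bad] <- "maf_mismatch"
  same <- same & !freq_bad
  swap <- swap & !freq_bad

  action[same] <- "keep"; reason[same] <- "match"
  action[swap] <- "swap"; reason[swap] <- "allele_swap"

  out <- weights[same | swap, req, drop = FALSE]
  if (nrow(out) == 0) stop("no variants survived harmonization")
  swapped <- swap[same | swap]
  # restore cohort orientation: negating beta re-expresses the effect per
  # cohort-effect-allele dosage, so no dosage remapping is needed
  out$beta[swapped] <- -out$beta[swapped]
  ea <- out$effect_allele
  out$effect_allele[swapped] <- out$other_allele[swapped]
  out$other_allele[swapped] <- ea[swapped]
  out$eaf[swapped] <- 1 - out$eaf[swapped]
  out$flipped <- FALSE  # set by align_positive when rows are sign-flipped
  rownames(out) <- NULL
  list(weights = out,
       log = data.frame(id = weights$id, action = action, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Align all effect estimates to be positive
#'
#' Rows with a negative effect size are flipped so that the effect allele is
#' always the trait-increasing allele: alleles are swapped, the effect size
#' negated, the effect-allele frequency complemented, and the dosage map
#' \eqn{d \to 2 - d} recorded in the `flipped` column. Zero effects are
#' dropped with a warning. Alignment adds a per-individual constant
#' (\eqn{2\sum |w|} over flipped variants) to the score, so rankings are
#' unchanged.
#'
#' @param weights Harmonized weight table (from [harmonize()]).
#' @return The weight table with every `beta > 0`.
#' @export
align_positive <- function(weights) {
  zero <- weights$beta == 0
  if (any(zero)) {
    warning(sum(zero), " zero-effect variant(s) dropped")
    weights <- weights[!zero, , drop = FALSE]
  }
  neg <- weights$beta < 0
  if (any(neg)) {
    ea <- weights$effect_allele
    weights$effect_allele[neg] <- weights$other_allele[neg]
    weights$other_allele[neg] <- ea[neg]
    weights$beta[neg] <- -weights$beta[neg]
    weights$eaf[neg] <- 1 - weights$eaf[neg]
    weights$flipped <- xor(weights$flipped %||% FALSE, neg)
  }
  weights
}

#' Compute the weighted polygenic score
#'
#' The score is the weighted sum of trait-increasing allele dosages,
#' \eqn{\mathrm{PGS}_i = \sum_j w_j d_{ij}}, where for rows flagged
#' `flipped` the dosage is mapped \eqn{d \to 2 - d}. A missing dosage
#' contributes the variant's Hardy-Weinberg expectation
#' \eqn{2 \times} effect-allele frequency (logged).
#'
#' @param weights Aligned weight table ([align_positive()]).
#' @param genotypes A `genotype_dosage` object covering every retained
#'   variant.
#' @return A list with `score` (named numeric vector, one value per
#'   individual), `n_variants_used`, and `n_imputed_cells` (missing dosages
#'   mean-imputed).
#' @export
compute_pgs <- function(weights, genotypes) {
  miss <- setdiff(weights$id, colnames(genotypes$dosages))
  if (length(miss))
    stop("dosages unavailable for variant(s): ", paste(miss, collapse = ", "))
  d <- genotypes$dosages[, weights$id, drop = FALSE]
  flip <- weights$flipped %||% rep(FALSE, nrow(weights))
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  n_imputed <- sum(is.na(d))
  if (n_imputed > 0) {
    ev <- 2 * weights$eaf
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- ev[j]
  }
  score <- drop(d %*% weights$beta)
  names(score) <- rownames(genotypes$dosages)
  list(score = score, n_variants_used = nrow(weights),
       n_imputed_cells = n_imputed)
}
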