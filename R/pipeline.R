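#' Run the full analysis pipeline
#'
#' Orchestrates the analysis end to end on an in-memory data bundle:
#' metabolite QC, response-trait derivation, rank-normal transformation, PGS
#' construction, observational and MR association per trait and dietary
#' state, effective-test estimation on the pooled trait matrix, and
#' state/framework comparisons.
#'
#' Analysis variants follow the study design: `wNEO` (weighted, all samples;
#' the primary analysis), `unweighted`, `subpop_random`/`subpop_oversampled`
#' (single-subpopulation, unweighted covariable-reduced models), `female` /
#' `male` (weighted, sex-reduced models), `untransformed` (no rank-normal
#' transformation) and `extra_covariables`.
#'
#' @param data A bundle as produced by [simulate_cohort()]: list with
#'   `cohort`, `genotypes`, `gwas_weights` and `metabolites` (fasting +
#'   postprandial matrices and annotation).
#' @param analysis_tag One of `"wNEO"`, `"unweighted"`, `"subpop_random"`,
#'   `"subpop_oversampled"`, `"female"`, `"male"`, `"untransformed"`,
#'   `"extra_covariables"`.
#' @param extra_covariables Character vector of additional cohort columns
#'   (used when `analysis_tag = "extra_covariables"`).
#' @param iqr_k,bivar_k,sample_missing_max,feature_missing_max QC parameters
#'   (see [run_metabolite_qc()]).
#' @param lambda Deming error-variance ratio.
#' @param response_method `"deming"` or `"delta"`.
#' @param cut_height,linkage Principal-variable clustering parameters.
#' @param tie_seed Seed for rank-normal tie randomization.
#' @param alpha Family-wise significance level.
#' @param run_qc Set `FALSE` to skip the QC chain (clean simulated input).
#' @return A list of class `ppmr_run`: `observational` and `mr`
#'   (EstimateTable data.frames over trait x state), `response_fits`,
#'   `qc_report`, `pgs` (scores and harmonization log), `multiplicity`
#'   (`pv_cluster` + thresholds), `comparisons` (state and obs-vs-MR
#'   z-tests, vector correlations, shared/unique counts), `provenance`.
#' @export
run_pipeline <- function(data, analysis_tag = "wNEO",
                         extra_covariables = character(0),
                         iqr_k = 10, bivar_k = 10,
                         sample_missing_max = 0.2, feature_missing_max = 0.2,
                         lambda = 1, response_method = "deming",
                         cut_height = 0.5, linkage = "average",
                         tie_seed = 1L, alpha = 0.05, run_qc = TRUE) {
  tags <- c("wNEO", "unweighted", "subpop_random", "subpop_oversampled",
            "female", "male", "untransformed", "extra_covariables")
  analysis_tag <- match.arg(analysis_tag, tags)
  cohort <- data$cohort
  met <- data$metabolites

  gids <- rownames(data$genotypes$dosages)
  offenders <- c(setdiff(cohort$individual_id, gids),
                 setdiff(gids, cohort$individual_id))
  if (length(offenders))
    stop("id mismatch between genotype and phenotype tables: ",
         paste(utils::head(offenders, 10), collapse = ", "))

  # ---- QC ----
  if (run_qc) {
    qc <- run_metabolite_qc(met$fasting, met$postprandial, iqr_k = iqr_k,
                            bivar_k = bivar_k,
                            sample_missing_max = sample_missing_max,
                            feature_missing_max = feature_missing_max)
  } else {
    qc <- list(fasting = met$fasting, postprandial = met$postprandial,
               report = list(skipped = TRUE))
  }
  keep <- rownames(qc$fasting)
  cohort <- cohort[match(keep, cohort$individual_id), , drop = FALSE]

  # ---- response traits ----
  resp <- build_response_matrix(qc$fasting, qc$postprandial,
                                method = response_method, lambda = lambda)

  # ---- PGS ----
  harm <- harmonize(data$gwas_weights, data$genotypes)
  aligned <- align_positive(harm$weights)
  pgs <- compute_pgs(aligned, data$genotypes)
  cohort$pgs <- pgs$score[match(cohort$individual_id, names(pgs$score))]

  # ---- transformation ----
  transformed <- analysis_tag != "untransformed"
  state_mats <- list(fasting = qc$fasting, postprandial = qc$postprandial,
                     response = resp$response)
  if (transformed)
    state_mats <- lapply(seq_along(state_mats), function(i) {
      rint_matrix(state_mats[[i]], seed = tie_seed + 1000L * i)
    })
  names(state_mats) <- c("fasting", "postprandial", "response")

  # ---- analysis subset, weights and covariables ----
  weighted <- !analysis_tag %in% c("unweighted", "subpop_random",
                                   "subpop_oversampled")
  rows <- switch(analysis_tag,
                 subpop_random = cohort$subpopulation == "random",
                 subpop_oversampled = cohort$subpopulation == "oversampled",
                 female = cohort$sex == "female",
                 male = cohort$sex == "male",
                 rep(TRUE, nrow(cohort)))
  sub <- cohort[rows, , drop = FALSE]
  covariates <- c("visit_date", "subpopulation", "age", "sex")
  if (analysis_tag == "extra_covariables")
    covariates <- c(covariates, extra_covariables)
  varies <- vapply(covariates, function(v) length(unique(sub[[v]])) > 1,
                   logical(1))
  if (any(!varies))
    message("dropping non-varying covariable(s): ",
            paste(covariates[!varies], collapse = ", "))
  covariates <- covariates[varies]

  # ---- per-trait association, observational and MR ----
  fit_state <- function(state) {
    mat <- state_mats[[state]][rows, , drop = FALSE]
    obs <- vector("list", ncol(mat)); mr <- vector("list", ncol(mat))
    for (j in seq_len(ncol(mat))) {
      o <- fit_weighted_glm(mat[, j], sub, weighted = weighted,
                            covariates = covariates)
      m <- suppressWarnings(
        fit_2sls(mat[, j], sub, covariates = covariates, weighted = weighted))
      obs[[j]] <- cbind(trait = colnames(mat)[j], state = state,
                        o$result, analysis_tag = analysis_tag)
      mr[[j]] <- cbind(trait = colnames(mat)[j], state = state,
                       m$result, analysis_tag = analysis_tag)
    }
    list(obs = do.call(rbind, obs), mr = do.call(rbind, mr))
  }
  fits <- lapply(names(state_mats), fit_state)
  observational <- do.call(rbind, lapply(fits, `[[`, "obs"))
  mr_table <- do.call(rbind, lapply(fits, `[[`, "mr"))
  rownames(observational) <- rownames(mr_table) <- NULL

  # ---- effective number of tests on the pooled (3-state) matrix ----
  pooled <- do.call(cbind, lapply(names(state_mats), function(s) {
    m <- state_mats[[s]]
    colnames(m) <- paste0(colnames(m), "_", substr(s, 1, 1))
    m
  }))
  pv <- pv_cluster(pooled, cut_height = cut_height, linkage = linkage)
  threshold <- bonferroni_threshold(alpha, pv$n_effective)

  # ---- comparisons ----
  tab <- function(df, st) df[df$state == st, , drop = FALSE]
  obs_f <- tab(observational, "fasting"); obs_p <- tab(observational, "postprandial")
  shared_fp <- intersect(obs_f$trait, obs_p$trait)
  fp_z <- z_diff(obs_f$beta[match(shared_fp, obs_f$trait)],
                 obs_f$se[match(shared_fp, obs_f$trait)],
                 obs_p$beta[match(shared_fp, obs_p$trait)],
                 obs_p$se[match(shared_fp, obs_p$trait)])
  fp_z <- cbind(trait = shared_fp, context = "fasting_vs_postprandial", fp_z)

  obs_vs_mr <- lapply(names(state_mats), function(s) {
    a <- tab(observational, s)
    b <- tab(mr_table, s)
    b$beta <- b$beta_iv; b$se <- b$se_iv; b$p <- b$p_iv
    list(vector = estimate_vector_comparison(a, b),
         counts = classify_associations(a, b, threshold))
  })
  names(obs_vs_mr) <- names(state_mats)
  all_obs <- observational
  all_mr <- within(mr_table, {beta <- beta_iv; se <- se_iv; p <- p_iv})
  all_obs$trait2 <- paste0(all_obs$trait, "_", substr(all_obs$state, 1, 1))
  all_mr$trait2 <- paste0(all_mr$trait, "_", substr(all_mr$state, 1, 1))
  overall <- estimate_vector_comparison(
    data.frame(trait = all_obs$trait2, beta = all_obs$beta),
    data.frame(trait = all_mr$trait2, beta = all_mr$beta))

  out <- list(observational = observational, mr = mr_table,
              response_fits = resp$fits, qc_report = qc$report,
              pgs = list(score = pgs$score, log = harm$log,
                         n_variants_used = pgs$n_variants_used),
              multiplicity = list(clusters = pv, n_effective = pv$n_effective,
                                  threshold = threshold),
              comparisons = list(state_z = fp_z, obs_vs_mr = obs_vs_mr,
                                 obs_vs_mr_overall = overall),
              cohort = sub,
              provenance = list(analysis_tag = analysis_tag,
                                weighted = weighted,
                                covariates = covariates,
                                n_individuals_in = nrow(data$cohort),
                                n_individuals_analyzed = nrow(sub),
                                n_traits = ncol(state_mats$fasting),
                                tie_seed = tie_seed, lambda = lambda,
                                transformed = transformed,
                                threshold = threshold))
  class(out) <- "ppmr_run"
  out
}

#' @export
print.ppmr_run <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("pipeline run [%s]: %d individuals, %d traits x 3 states\n",
              pr$analysis_tag, pr$n_individuals_analyzed, pr$n_traits))
  cat(sprintf("  effective tests: %d (threshold %.3g)\n",
              x$multiplicity$n_effective, x$multiplicity$threshold))
  cat(sprintf("  obs-vs-MR overall Pearson r: %.3f\n",
              x$comparisons$obs_vs_mr_overall$r))
  invisible(x)
}

#' Run the sensitivity-analysis suite
#'
#' Executes the primary weighted analysis plus the requested variants and
#' compares each variant's observational beta vector with the primary run's.
#' Variants whose analyzed sample would fall below `min_n` are skipped with
#' a warning.
#'
#' @param data Data bundle (see [run_pipeline()]).
#' @param tags Variant analysis tags to run (default: unweighted, the two
#'   subpopulations, both sexes).
#' @param min_n Minimum analyzed sample size per variant (default 50).
#' @param ... Passed to [run_pipeline()].
#' @return A list with `primary` (the wNEO run), `variants` (named list of
#'   runs) and `comparison` (per-variant Pearson r, intercept, slope against
#'   the primary observational estimates).
#' @export
run_sensitivity_suite <- function(data,
                                  tags = c("unweighted", "subpop_random",
                                           "subpop_oversampled", "female",
                                           "male"),
                                  min_n = 50, ...) {
  primary <- run_pipeline(data, analysis_tag = "wNEO", ...)
  primary$observational$trait2 <- paste0(primary$observational$trait, "_",
                                         substr(primary$observational$state, 1, 1))
  variants <- list()
  rows <- list()
  for (tag in tags) {
    n_tag <- switch(tag,
                    subpop_random = sum(data$cohort$subpopulation == "random"),
                    subpop_oversampled = sum(data$cohort$subpopulation == "oversampled"),
                    female = sum(data$cohort$sex == "female"),
                    male = sum(data$cohort$sex == "male"),
                    nrow(data$cohort))
    if (n_tag < min_n) {
      warning("variant '", tag, "' skipped: n = ", n_tag, " < ", min_n)
      next
    }
    run <- run_pipeline(data, analysis_tag = tag, ...)
    run$observational$trait2 <- paste0(run$observational$trait, "_",
                                       substr(run$observational$state, 1, 1))
    cmp <- estimate_vector_comparison(
      data.frame(trait = primary$observational$trait2,
                 beta = primary$observational$beta),
      data.frame(trait = run$observational$trait2,
                 beta = run$observational$beta))
    variants[[tag]] <- run
    rows[[tag]] <- data.frame(analysis_tag = tag, r = cmp$r,
                              intercept = cmp$intercept, slope = cmp$slope,
                              n = cmp$n, stringsAsFactors = FALSE)
  }
  list(primary = primary, variants = variants,
       comparison = do.call(rbind, rows))
}
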