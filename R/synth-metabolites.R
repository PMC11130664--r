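#' Generate paired fasting and postprandial metabolite matrices
#'
#' Each trait is built from a latent biological component shared by the two
#' dietary states, measured twice with independent error — the
#' errors-in-both-variables structure that motivates a Deming regression for
#' the response phenotype. For trait \eqn{k} with centered BMI \eqn{B}:
#' \deqn{x^*_k = \beta_{f,k} B + \gamma_k d + \sqrt{w_k} f_{c(k)} + u_k}
#' \deqn{\mathrm{fasting}_k = \mu_k + x^*_k + m_1,\qquad
#'       \mathrm{postprandial}_k = 1.05\,\mu_k + s_k x^*_k +
#'       (\beta_{p,k}+\beta_{r,k}) B + m_2}
#' where \eqn{d} is the standardized visit date, \eqn{f_{c(k)}} a class-level
#' latent factor and \eqn{m_1, m_2} state-specific measurement errors.
#'
#' The per-trait variances are calibrated in closed form so that, in the
#' generating population, both states have unit variance and the Deming
#' (\eqn{\lambda = 1}) residual of postprandial on fasting also has unit
#' variance (latent variance 0.5, measurement variance 0.5, between-state
#' covariance 0.5). Under this calibration the configured betas are exactly
#' trait-SD units per BMI unit for the state they act on, which is what the
#' downstream rank-normalized association models estimate.
#'
#' Effect types are assigned cyclically: trait 1 carries a fasting effect,
#' trait 2 a postprandial effect, trait 3 a response effect, trait 4 none,
#' and so on; each effect-carrying trait is scaled by a per-trait multiplier
#' drawn from \{-1, -0.5, 0.5, 1\} so the cohort exhibits a spread of effect
#' sizes with both signs.
#'
#' @param cohort Output of [generate_bmi()] (needs `bmi`, `visit_date`).
#' @param cfg A [synth_config()].
#' @return A list of class `metabolite_states` with numeric matrices
#'   `fasting` and `postprandial` (individuals x traits, dimnames set), an
#'   `annotation` data.frame (`trait`, `class`, `size_rank`, `component`) and
#'   a `truth` data.frame recording each trait's effect type and generating
#'   beta.
#' @examples
#' cfg <- synth_config(n_random = 200, n_oversampled = 200, n_snps = 10,
#'                     n_metabolites = 8, seed = 3)
#' geno <- generate_genotypes(cfg)
#' w <- generate_variant_weights(cfg, geno)
#' cohort <- generate_bmi(cohort_skeleton(cfg), geno, w, cfg)
#' met <- generate_metabolites(cohort, cfg)
#' cor(met$fasting[, 1], met$postprandial[, 1])
#' @export
generate_metabolites <- function(cohort, cfg) {
  validate_synth_config(cfg)
  if (anyNA(cohort$bmi)) stop("cohort has missing BMI")
  n <- nrow(cohort)
  k <- cfg$n_metabolites
  if (k <= 0) stop("n_metabolites must be positive")

  bc <- cohort$bmi - mean(cohort$bmi)
  vb <- mean(bc^2)
  dz <- zscore(cohort$visit_date)
  cbd <- mean(bc * dz)

  type_cycle <- c("fasting", "postprandial", "response", "null")
  type <- rep(type_cycle, length.out = k)
  class_idx <- rep(seq_len(cfg$n_classes), length.out = k)

  withr_seed(stage_seed(cfg$seed, "metabolites"), {
    lv <- cfg$effect_multipliers
    mult <- if (length(lv) == 1L) rep(lv, k) else sample(lv, k, replace = TRUE)
    bf <- ifelse(type == "fasting", cfg$beta_fasting * mult, 0)
    bp <- ifelse(type == "postprandial", cfg$beta_postprandial * mult, 0)
    br <- ifelse(type == "response", cfg$beta_response * mult, 0)
    bpb <- bp + br  # direct BMI effect on the postprandial state
    gam <- rep(cfg$date_effect, k)

    v <- 0.5   # latent variance
    m <- 0.5   # per-state measurement variance
    sys_var <- bf^2 * vb + gam^2 + 2 * bf * gam * cbd
    if (any(sys_var >= v - 0.05))
      stop("systematic variance exceeds the latent budget; reduce betas or date_effect")
    wf <- cfg$class_correlation * (v - sys_var)
    su2 <- v - sys_var - wf
    cxb <- bf * vb + gam * cbd
    s <- (v - bpb * cxb) / v                 # enforces cov(fasting, post) = 0.5
    sy2 <- 1 - (s^2 * v + bpb^2 * vb + 2 * s * bpb * cxb)
    if (any(sy2 < 0.05)) {
      warning("postprandial noise floor reached for ", sum(sy2 < 0.05), " trait(s)")
      sy2 <- pmax(sy2, 0.05)
    }
    mu <- stats::runif(k, 3, 8)

    fac <- matrix(stats::rnorm(n * cfg$n_classes), n)
    xstar <- tcrossprod(bc, bf) + tcrossprod(dz, gam) +
      sweep(fac[, class_idx, drop = FALSE], 2, sqrt(wf), "*") +
      sweep(matrix(stats::rnorm(n * k), n), 2, sqrt(su2), "*")
    fasting <- sweep(xstar + matrix(stats::rnorm(n * k, sd = sqrt(m)), n), 2, mu, "+")
    post <- sweep(xstar, 2, s, "*") + tcrossprod(bc, bpb) +
      sweep(matrix(stats::rnorm(n * k), n), 2, sqrt(sy2), "*")
    post <- sweep(post, 2, 1.05 * mu, "+")

    traits <- sprintf("met%03d", seq_len(k))
    dimnames(fasting) <- dimnames(post) <- list(cohort$individual_id, traits)

    classes <- c("VLDL", "LDL", "IDL", "HDL", "amino acids", "fatty acids",
                 "glycolysis", "ketone bodies", "fluid balance", "inflammation",
                 "apolipoproteins", "cholesterol", "fatty acid ratios",
                 "lipoprotein particle size")
    comps <- c("total lipids", "cholesterol", "triglycerides", "phospholipids")
    annotation <- data.frame(
      trait = traits,
      class = classes[(class_idx - 1L) %% length(classes) + 1L],
      size_rank = class_idx,
      component = comps[(seq_len(k) - 1L) %% length(comps) + 1L],
      stringsAsFactors = FALSE)
    truth <- data.frame(trait = traits, type = type,
                        beta_fasting = bf, beta_postprandial = bp,
                        beta_response = br, slope = s, mu = mu,
                        stringsAsFactors = FALSE)
    out <- list(fasting = fasting, postprandial = post,
                annotation = annotation, truth = truth)
    class(out) <- "metabolite_states"
    out
  })
}

#' Inject missing cells and gross outliers
#'
#' Corrupts a metabolite matrix the way raw assay data arrive: a fraction of
#' cells becomes missing (half recorded as exact zeros, half as `NA`) and a
#' fraction becomes gross outliers placed at least 12 interquartile ranges
#' from the trait median, beyond the default 10-IQR quality-control fence.
#' The returned bookkeeping makes QC recall computable.
#'
#' @param mat Numeric individuals x traits matrix.
#' @param cfg A [synth_config()] supplying `missing_rate` and `outlier_rate`.
#' @param seed Optional integer overriding the config-derived stream (so the
#'   fasting and postprandial matrices can be corrupted independently).
#' @return A list with `matrix` (corrupted copy) and `injected` (data.frame
#'   `row`, `col`, `kind` in \{"zero", "na", "outlier"\}).
#' @export
inject_missing_and_outliers <- function(mat, cfg, seed = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1 ||
      cfg$outlier_rate < 0 || cfg$outlier_rate >= 1)
    stop("rates must lie in [0, 1)")
  seed <- seed %||% stage_seed(cfg$seed, "inject")
  withr_seed(seed, {
    n_cells <- length(mat)
    book <- data.frame(row = integer(0), col = integer(0),
                       kind = character(0), stringsAsFactors = FALSE)
    if (cfg$outlier_rate > 0) {
      idx <- which(stats::runif(n_cells) < cfg$outlier_rate)
      if (length(idx)) {
        cols <- (idx - 1L) %/% nrow(mat) + 1L
        med <- apply(mat, 2, stats::median, na.rm = TRUE)
        iqr <- apply(mat, 2, stats::IQR, na.rm = TRUE)
        sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
        mat[idx] <- med[cols] + sgn * (12 + stats::runif(length(idx), 0, 6)) * iqr[cols]
        book <- rbind(book, data.frame(row = (idx - 1L) %% nrow(mat) + 1L,
                                       col = cols, kind = "outlier"))
      }
    }
    if (cfg$missing_rate > 0) {
      pool <- setdiff(seq_len(n_cells), which(book$kind == "outlier"))
      idx <- pool[stats::runif(length(pool)) < cfg$missing_rate]
      if (length(idx)) {
        zero <- idx[seq_along(idx) %% 2L == 0L]
        nas <- setdiff(idx, zero)
        mat[zero] <- 0
        mat[nas] <- NA_real_
        book <- rbind(book,
                      data.frame(row = (zero - 1L) %% nrow(mat) + 1L,
                                 col = (zero - 1L) %/% nrow(mat) + 1L, kind = "zero"),
                      data.frame(row = (nas - 1L) %% nrow(mat) + 1L,
                                 col = (nas - 1L) %/% nrow(mat) + 1L, kind = "na"))
      }
    }
    list(matrix = mat, injected = book)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running the full generative chain: genotypes, GWAS
#' weight table, cohort skeleton, BMI, sampling weights, metabolite matrices
#' and (optionally) missingness/outlier corruption.
#'
#' @param cfg A [synth_config()].
#' @param inject Corrupt the metabolite matrices with missing cells and gross
#'   outliers (default `TRUE`).
#' @return A list with `cohort`, `genotypes`, `gwas_weights`, `metabolites`
#'   (a `metabolite_states` list whose matrices are corrupted when
#'   `inject = TRUE`), and `injection` bookkeeping (or `NULL`).
#' @export
simulate_cohort <- function(cfg, inject = TRUE) {
  genotypes <- generate_genotypes(cfg)
  gwas <- generate_variant_weights(cfg, genotypes)
  cohort <- generate_bmi(cohort_skeleton(cfg), genotypes, gwas, cfg)
  cohort <- derive_sample_weights(cohort)
  met <- generate_metabolites(cohort, cfg)
  injection <- NULL
  if (inject) {
    f <- inject_missing_and_outliers(met$fasting, cfg,
                                     seed = stage_seed(cfg$seed, "inject"))
    p <- inject_missing_and_outliers(met$postprandial, cfg,
                                     seed = stage_seed(cfg$seed, "inject") + 1L)
    met$fasting <- f$matrix
    met$postprandial <- p$matrix
    injection <- list(fasting = f$injected, postprandial = p$injected)
  }
  list(cohort = cohort, genotypes = genotypes, gwas_weights = gwas,
       metabolites = met, injection = injection)
}
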