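#' Convert exact zeros to missing values
#'
#' Assay software commonly records below-detection measurements as exact
#' zeros; these are not informative abundances and are set missing before any
#' statistic is computed.
#'
#' @param mat Numeric matrix (individuals x traits).
#' @return The matrix with every exact zero replaced by `NA`; all other cells
#'   untouched. The attribute `"n_zeroed"` counts conversions per trait.
#' @export
zeros_to_missing <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  zero <- !is.na(mat) & mat == 0
  mat[zero] <- NA_real_
  attr(mat, "n_zeroed") <- colSums(zero)
  mat
}

#' Univariate gross-outlier filter
#'
#' Per trait, any value more than `k` interquartile ranges from the median
#' (both computed on nonmissing values) is set missing. Traits with zero IQR
#' are left untouched with a warning.
#'
#' @param mat Numeric matrix.
#' @param k IQR multiplier (default 10).
#' @return Filtered matrix; attribute `"n_removed"` counts removals per trait.
#' @export
iqr_filter <- function(mat, k = 10) {
  stopifnot(is.matrix(mat), is.numeric(mat), k > 0)
  removed <- integer(ncol(mat))
  degenerate <- character(0)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    med <- stats::median(x[ok])
    iqr <- stats::IQR(x[ok])
    if (iqr == 0) {
      degenerate <- c(degenerate, colnames(mat)[j] %||% as.character(j))
      next
    }
    out <- ok & abs(x - med) > k * iqr
    mat[out, j] <- NA_real_
    removed[j] <- sum(out)
  }
  if (length(degenerate))
    warning("zero IQR, no filtering for trait(s): ",
            paste(degenerate, collapse = ", "))
  attr(mat, "n_removed") <- removed
  mat
}

#' Bivariate fasting/postprandial outlier filter
#'
#' Uses the expected correlation between the fasting and postprandial
#' measurements of the same trait to flag pairs that violate that
#' relationship. Per trait, a preliminary Deming regression
#' (\eqn{\lambda = 1}) of postprandial on fasting is fitted on complete
#' pairs; pairs whose vertical residual lies more than `k` residual-IQRs from
#' the residual median are set missing in both states. Traits with fewer than
#' 10 complete pairs are skipped with a warning.
#'
#' @param fasting,postprandial Numeric matrices sharing individuals (rows)
#'   and traits (columns).
#' @param k Residual IQR multiplier (default 10, matching the univariate
#'   rule).
#' @return A list with the filtered `fasting` and `postprandial` matrices and
#'   a `report` data.frame (`trait`, `n_pairs`, `n_removed`, `skipped`).
#' @export
bivariate_outlier_filter <- function(fasting, postprandial, k = 10) {
  stopifnot(identical(dim(fasting), dim(postprandial)), k > 0)
  nt <- ncol(fasting)
  report <- data.frame(trait = colnames(fasting) %||% as.character(seq_len(nt)),
                       n_pairs = integer(nt), n_removed = integer(nt),
                       skipped = logical(nt), stringsAsFactors = FALSE)
  skipped <- character(0)
  for (j in seq_len(nt)) {
    x <- fasting[, j]
    y <- postprandial[, j]
    ok <- !is.na(x) & !is.na(y)
    report$n_pairs[j] <- sum(ok)
    if (sum(ok) < 10) {
      report$skipped[j] <- TRUE
      skipped <- c(skipped, report$trait[j])
      next
    }
    fit <- tryCatch(deming_fit(x[ok], y[ok], lambda = 1),
                    error = function(e) NULL)
    if (is.null(fit)) {
      report$skipped[j] <- TRUE
      skipped <- c(skipped, report$trait[j])
      next
    }
    res <- y - (fit$intercept + fit$slope * x)
    med <- stats::median(res[ok])
    iqr <- stats::IQR(res[ok])
    if (iqr == 0) next
    bad <- ok & abs(res - med) > k * iqr
    fasting[bad, j] <- NA_real_
    postprandial[bad, j] <- NA_real_
    report$n_removed[j] <- sum(bad)
  }
  if (length(skipped))
    warning("bivariate filter skipped trait(s): ", paste(skipped, collapse = ", "))
  list(fasting = fasting, postprandial = postprandial, report = report)
}

#' Sample and feature missingness filter
#'
#' Removes features (traits) whose missingness exceeds `feature_missing_max`,
#' then samples whose missingness — computed on the retained features —
#' exceeds `sample_missing_max`, in that order.
#'
#' @param mat Numeric matrix (individuals x traits).
#' @param sample_missing_max,feature_missing_max Maximum tolerated
#'   missingness fractions in (0, 1\] (defaults 0.2, after common
#'   metabolomics-QC practice).
#' @return A list with `matrix` (filtered), `removed_samples`,
#'   `removed_features` (character vectors) and `report` (named list of
#'   parameters and counts; `order` documents feature-then-sample).
#' @export
sample_feature_filter <- function(mat, sample_missing_max = 0.2,
                                  feature_missing_max = 0.2) {
  stopifnot(is.matrix(mat))
  if (sample_missing_max <= 0 || sample_missing_max > 1 ||
      feature_missing_max <= 0 || feature_missing_max > 1)
    stop("missingness thresholds must lie in (0, 1]")
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("V%d", seq_len(ncol(mat)))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("r%d", seq_len(nrow(mat)))
  feat_miss <- colMeans(is.na(mat))
  drop_feat <- feat_miss > feature_missing_max
  if (all(drop_feat)) stop("all features removed by the missingness filter")
  kept <- mat[, !drop_feat, drop = FALSE]
  samp_miss <- rowMeans(is.na(kept))
  drop_samp <- samp_miss > sample_missing_max
  out <- kept[!drop_samp, , drop = FALSE]
  list(matrix = out,
       removed_samples = rownames(mat)[drop_samp],
       removed_features = colnames(mat)[drop_feat],
       report = list(order = c("features", "samples"),
                     feature_missing_max = feature_missing_max,
                     sample_missing_max = sample_missing_max,
                     n_features_removed = sum(drop_feat),
                     n_samples_removed = sum(drop_samp)))
}

#' Run the full metabolite QC chain
#'
#' Applies, in order: zero-to-missing conversion, the univariate `k`-IQR
#' filter (per state), the bivariate fasting/postprandial outlier filter, and
#' the feature/sample missingness filter (feature and sample sets are made
#' consistent across the two states).
#'
#' @param fasting,postprandial Numeric matrices sharing dimnames.
#' @param iqr_k,bivar_k IQR multipliers for the univariate and bivariate
#'   rules (default 10 each).
#' @param sample_missing_max,feature_missing_max Missingness thresholds.
#' @return A list with the cleaned `fasting` and `postprandial` matrices and
#'   `report`, a list of per-rule counts whose cell totals reconcile exactly
#'   with the missingness deltas of the matrices.
#' @export
run_metabolite_qc <- function(fasting, postprandial, iqr_k = 10, bivar_k = 10,
                              sample_missing_max = 0.2,
                              feature_missing_max = 0.2) {
  stopifnot(identical(dim(fasting), dim(postprandial)))
  na0 <- c(fasting = sum(is.na(fasting)), postprandial = sum(is.na(postprandial)))

  f <- zeros_to_missing(fasting)
  p <- zeros_to_missing(postprandial)
  zeroed <- c(fasting = sum(attr(f, "n_zeroed")), postprandial = sum(attr(p, "n_zeroed")))

  f <- iqr_filter(f, k = iqr_k)
  p <- iqr_filter(p, k = iqr_k)
  univariate <- c(fasting = sum(attr(f, "n_removed")),
                  postprandial = sum(attr(p, "n_removed")))

  bi <- bivariate_outlier_filter(f, p, k = bivar_k)
  bivariate <- sum(bi$report$n_removed)

  ff <- sample_feature_filter(bi$fasting, sample_missing_max, feature_missing_max)
  pf_keep_feat <- setdiff(colnames(bi$postprandial), ff$removed_features)
  pf <- sample_feature_filter(bi$postprandial[, pf_keep_feat, drop = FALSE],
                              sample_missing_max, feature_missing_max)
  drop_samples <- union(ff$removed_samples, pf$removed_samples)
  drop_features <- union(ff$removed_features, pf$removed_features)
  keep_s <- setdiff(rownames(fasting), drop_samples)
  keep_f <- setdiff(colnames(fasting), drop_features)
  f_out <- bi$fasting[keep_s, keep_f, drop = FALSE]
  p_out <- bi$postprandial[keep_s, keep_f, drop = FALSE]

  report <- list(
    cells_zeroed = zeroed,
    cells_univariate = univariate,
    cells_bivariate_pairs = bivariate,
    samples_removed = drop_samples,
    features_removed = drop_features,
    missing_before = na0,
    missing_after_rules = c(fasting = sum(is.na(bi$fasting)),
                            postprandial = sum(is.na(bi$postprandial))),
    parameters = list(iqr_k = iqr_k, bivar_k = bivar_k,
                      sample_missing_max = sample_missing_max,
                      feature_missing_max = feature_missing_max))
  list(fasting = f_out, postprandial = p_out, report = report)
}
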