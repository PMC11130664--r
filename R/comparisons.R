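#' z test for a difference between two estimates
#'
#' \eqn{z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}} with a two-sided normal p
#' value, treating the two estimates as independent. Vectorized.
#'
#' @param b1,se1 First estimate(s) and standard error(s).
#' @param b2,se2 Second estimate(s) and standard error(s).
#' @return Data.frame with `z` and `p`.
#' @examples
#' z_diff(0.1, 0.03, 0, 0.04)$z  # 2
#' @export
z_diff <- function(b1, se1, b2, se2) {
  if (any(se1 <= 0, na.rm = TRUE) || any(se2 <= 0, na.rm = TRUE))
    stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  data.frame(z = z, p = z_p(z))
}

#' Compare two estimate vectors
#'
#' Pearson correlation of the two beta vectors plus the OLS intercept and
#' slope of B regressed on A, the summary used to ask how well one analysis
#' framework (e.g., observational) predicts another (e.g., MR).
#'
#' @param tableA,tableB Data.frames with `trait` and `beta` columns (aligned
#'   by trait).
#' @return A list with `r`, `r_p`, `intercept`, `slope`, `n`.
#' @export
estimate_vector_comparison <- function(tableA, tableB) {
  shared <- intersect(tableA$trait, tableB$trait)
  if (length(shared) < 3) stop("fewer than 3 shared traits")
  a <- tableA$beta[match(shared, tableA$trait)]
  b <- tableB$beta[match(shared, tableB$trait)]
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("fewer than 3 shared traits with estimates")
  ct <- stats::cor.test(a, b)
  fit <- stats::lm(b ~ a)
  list(r = unname(ct$estimate), r_p = ct$p.value,
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), n = length(a))
}

#' Classify shared and unique associations
#'
#' Partitions the common trait universe into associations significant in
#' both analyses, in only one, or in neither, at the supplied p-value
#' threshold.
#'
#' @param tableA,tableB Data.frames with `trait` and `p` columns over the
#'   same trait universe.
#' @param threshold Significance threshold applied to both tables.
#' @return Named integer vector `shared`, `A_only`, `B_only`, `neither`;
#'   always sums to the number of traits.
#' @export
classify_associations <- function(tableA, tableB, threshold) {
  traits <- union(tableA$trait, tableB$trait)
  pa <- tableA$p[match(traits, tableA$trait)]
  pb <- tableB$p[match(traits, tableB$trait)]
  sa <- !is.na(pa) & pa < threshold
  sb <- !is.na(pb) & pb < threshold
  c(shared = sum(sa & sb), A_only = sum(sa & !sb),
    B_only = sum(!sa & sb), neither = sum(!sa & !sb))
}

#' Lipoprotein profile summary table
#'
#' Organizes per-trait effect estimates by lipoprotein class, particle size
#' and measured component, the long-format table behind tile/profile plots
#' of the atherogenic lipoprotein gradient. Traits without an annotation row
#' are placed in class `"other"` (logged).
#'
#' @param estimates Data.frame with `trait`, `beta`, `p` (and optionally
#'   `state`).
#' @param annotation Data.frame with `trait`, `class`, `size_rank`,
#'   `component`.
#' @param threshold Significance threshold for the flag column (default
#'   0.05).
#' @return Long-format data.frame sorted by class and size rank, with
#'   `trait`, `class`, `size_rank`, `component`, `beta`, `p`, `significant`.
#' @export
lipoprotein_profile <- function(estimates, annotation, threshold = 0.05) {
  if (nrow(estimates) == 0) {
    warning("empty estimate table")
    return(data.frame(trait = character(0), class = character(0),
                      size_rank = integer(0), component = character(0),
                      beta = numeric(0), p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  idx <- match(estimates$trait, annotation$trait)
  unann <- estimates$trait[is.na(idx)]
  if (length(unann))
    message("unannotated trait(s) placed in class 'other': ",
            paste(unann, collapse = ", "))
  out <- data.frame(
    trait = estimates$trait,
    class = ifelse(is.na(idx), "other", annotation$class[idx]),
    size_rank = ifelse(is.na(idx), NA_integer_, annotation$size_rank[idx]),
    component = ifelse(is.na(idx), NA_character_, annotation$component[idx]),
    beta = estimates$beta, p = estimates$p,
    significant = !is.na(estimates$p) & estimates$p < threshold,
    stringsAsFactors = FALSE)
  out[order(out$class, out$size_rank, out$trait), , drop = FALSE]
}
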