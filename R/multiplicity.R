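#' Principal-variable clustering of correlated traits
#'
#' Estimates the effective number of independent traits by hierarchical
#' clustering on the correlation-based distance \eqn{1 - |r|} and a fixed
#' tree cut. Within each cluster the representative ("principal") variable
#' is the medoid — the trait with minimal summed distance to its cluster
#' co-members — with lexicographic trait-id tie-breaking; a singleton
#' represents itself. The cluster count is the effective number of tests.
#'
#' @param mat Numeric individuals x traits matrix.
#' @param cut_height Tree cut height in (0, 1) on the \eqn{1 - |r|} scale
#'   (default 0.5: traits merging below absolute correlation 0.5 share a
#'   cluster).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param corr Correlation type, `"spearman"` (default) or `"pearson"`,
#'   computed on pairwise-complete observations.
#' @param min_obs Traits with fewer nonmissing observations are excluded
#'   (logged).
#' @return An object of class `pv_cluster`: list with `clusters` (named
#'   integer vector), `representatives` (one trait id per cluster),
#'   `n_effective`, `cut_height`, `linkage`, `excluded`.
#' @examples
#' set.seed(1)
#' m <- cbind(a = rnorm(50), b = rnorm(50))
#' m <- cbind(m, a2 = m[, "a"] + rnorm(50, sd = 0.05))
#' pv_cluster(m)$n_effective
#' @export
pv_cluster <- function(mat, cut_height = 0.5, linkage = "average",
                       corr = c("spearman", "pearson"), min_obs = 10L) {
  corr <- match.arg(corr)
  if (cut_height <= 0 || cut_height >= 1)
    stop("cut_height must lie in (0, 1)")
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("V%d", seq_len(ncol(mat)))
  n_obs <- colSums(!is.na(mat))
  excluded <- colnames(mat)[n_obs < min_obs]
  if (length(excluded)) {
    message("pv_cluster excluded trait(s) with < ", min_obs,
            " observations: ", paste(excluded, collapse = ", "))
    mat <- mat[, n_obs >= min_obs, drop = FALSE]
  }
  if (ncol(mat) == 0) stop("no traits left to cluster")
  if (ncol(mat) == 1) {
    out <- list(clusters = stats::setNames(1L, colnames(mat)),
                representatives = colnames(mat), n_effective = 1L,
                cut_height = cut_height, linkage = linkage, excluded = excluded)
    class(out) <- "pv_cluster"
    return(out)
  }
  cm <- suppressWarnings(stats::cor(mat, method = corr,
                                    use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0  # undefined pairs (e.g. a constant trait) treated as independent
  d <- 1 - abs(cm)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  cl <- stats::cutree(hc, h = cut_height)
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- names(cl)[cl == k]
    if (length(members) == 1) return(members)
    sums <- rowSums(d[members, members, drop = FALSE])
    members[order(sums, members)][1]  # medoid, lexicographic tie-break
  }, character(1))
  out <- list(clusters = cl, representatives = unname(reps),
              n_effective = length(reps), cut_height = cut_height,
              linkage = linkage, excluded = excluded)
  class(out) <- "pv_cluster"
  out
}

#' @export
print.pv_cluster <- function(x, ...) {
  cat(sprintf("principal-variable clustering: %d traits -> %d effective (cut %.2f, %s linkage)\n",
              length(x$clusters), x$n_effective, x$cut_height, x$linkage))
  invisible(x)
}

#' Bonferroni threshold for the effective number of tests
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_effective Effective number of independent tests, >= 1.
#' @return `alpha / n_effective`.
#' @examples
#' signif(bonferroni_threshold(0.05, 43), 4)  # 1.163e-3
#' @export
bonferroni_threshold <- function(alpha, n_effective) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_effective < 1) stop("n_effective must be >= 1")
  alpha / n_effective
}
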