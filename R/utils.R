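#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Weighted least squares on a prebuilt design matrix.
# Returns coefficients, their SEs, residuals (observed scale), sigma2 and
# the unscaled covariance inverse so callers can form derived statistics.
wls_fit <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  if (any(w < 0)) stop("negative weights")
  keep <- stats::complete.cases(X, y, w)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  w <- w[keep]
  n <- length(y)
  k <- ncol(X)
  qr_x <- qr(sqrt(w) * X)
  if (qr_x$rank < k) {
    bad <- colnames(X)[qr_x$pivot[seq_len(k) > qr_x$rank]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, sqrt(w) * y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(w * resid^2)
  sigma2 <- rss / (n - k)
  XtWX_inv <- solve(crossprod(sqrt(w) * X))
  se <- sqrt(diag(XtWX_inv) * sigma2)
  names(se) <- colnames(X)
  list(coef = beta, se = se, residuals = resid, fitted = fitted,
       sigma2 = sigma2, XtWX_inv = XtWX_inv, n = n, k = k,
       rss = rss, y = y, X = X, w = w, keep = keep)
}

# Two-sided normal p value.
z_p <- function(z) 2 * stats::pnorm(-abs(z))

# Quantile-normalizing offset (Blom by default).
rint_quantiles <- function(r, n, offset) stats::qnorm((r - offset) / (n - 2 * offset + 1))

# Standardize a numeric vector (population sd via stats::sd).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)
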