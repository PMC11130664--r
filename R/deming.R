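#' Deming (errors-in-both-variables) regression
#'
#' Closed-form Deming regression of `y` on `x`, allowing measurement error in
#' both variables. `lambda` is the ratio of the `y`-error variance to the
#' `x`-error variance; with `lambda = 1` the fit is orthogonal (total least
#' squares), and as `lambda` grows the slope converges to the ordinary least
#' squares slope of `y` on `x`.
#'
#' With centered sums of squares `sxx`, `syy` and cross-product `sxy`
#' computed on complete pairs, the slope is
#' \deqn{\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy} - \lambda s_{xx})^2 + 4 \lambda s_{xy}^2}}{2 s_{xy}}}
#' and the intercept is \eqn{\bar y - \hat\beta \bar x}. A zero
#' cross-product carries no orientation information and is an error.
#'
#' @param x,y Paired numeric vectors (fasting and postprandial abundance).
#' @param lambda Error-variance ratio, > 0 (default 1).
#' @return An object of class `deming_fit`: list with `intercept`, `slope`,
#'   `lambda`, `n_used`.
#' @examples
#' deming_fit(c(1, 2, 3), c(2, 4, 6))$slope  # collinear: exactly 2
#' @export
deming_fit <- function(x, y, lambda = 1) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("x and y must be numeric vectors of equal length")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  syy <- sum((y - ym)^2)
  sxy <- sum((x - xm) * (y - ym))
  if (sxx == 0) stop("var(x) is zero")
  if (sxy == 0) stop("degenerate fit: zero covariance carries no orientation")
  slope <- (syy - lambda * sxx +
              sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  out <- list(intercept = ym - slope * xm, slope = slope,
              lambda = lambda, n_used = n)
  class(out) <- "deming_fit"
  out
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (lambda = %g, n = %d): slope %.6g, intercept %.6g\n",
              x$lambda, x$n_used, x$slope, x$intercept))
  invisible(x)
}

#' Vertical residuals from a Deming fit
#'
#' Residuals are vertical (postprandial-scale):
#' \eqn{r_i = y_i - (a + b x_i)}, so a positive residual means a higher
#' postprandial abundance than the fasting level predicts. Missingness in
#' either input propagates.
#'
#' @param fit A [deming_fit()].
#' @param x,y The paired vectors the fit applies to.
#' @return Numeric residual vector, `NA` where either input is missing.
#' @export
deming_residuals <- function(fit, x, y) {
  stopifnot(inherits(fit, "deming_fit"))
  y - (fit$intercept + fit$slope * x)
}

#' Simple delta response
#'
#' The elementwise postprandial-minus-fasting difference, the simplest
#' response summary. Missingness propagates.
#'
#' @param x,y Paired numeric vectors (fasting, postprandial).
#' @return `y - x`.
#' @export
delta_response <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  y - x
}

#' Build the response matrix for all traits
#'
#' Derives the per-individual response phenotype for each metabolite trait,
#' either as the residuals of a trait-wise Deming regression of postprandial
#' on fasting abundance (`method = "deming"`) or as the simple difference
#' (`method = "delta"`, which ignores `lambda`). Traits whose Deming fit is
#' degenerate (fewer than 3 complete pairs, zero fasting variance or zero
#' covariance) are skipped and logged.
#'
#' @param fasting,postprandial QC'd numeric matrices with shared dimnames.
#' @param method `"deming"` (default) or `"delta"`.
#' @param lambda Error-variance ratio for the Deming fits (default 1).
#' @return A list with `response` (individuals x retained traits matrix,
#'   attribute `"method"` set), `fits` (data.frame `trait`, `intercept`,
#'   `slope`, `lambda`, `n_used`; `NA` rows for delta), and `skipped`
#'   (character vector of degenerate traits).
#' @export
build_response_matrix <- function(fasting, postprandial,
                                  method = c("deming", "delta"), lambda = 1) {
  method <- match.arg(method)
  stopifnot(identical(dim(fasting), dim(postprandial)))
  nt <- ncol(fasting)
  traits <- colnames(fasting) %||% sprintf("V%d", seq_len(nt))
  response <- matrix(NA_real_, nrow(fasting), nt,
                     dimnames = list(rownames(fasting), traits))
  fits <- data.frame(trait = traits, intercept = NA_real_, slope = NA_real_,
                     lambda = if (method == "deming") lambda else NA_real_,
                     n_used = NA_integer_, stringsAsFactors = FALSE)
  skipped <- character(0)
  for (j in seq_len(nt)) {
    x <- fasting[, j]; y <- postprandial[, j]
    if (method == "delta") {
      response[, j] <- delta_response(x, y)
      fits$n_used[j] <- sum(!is.na(x) & !is.na(y))
      next
    }
    fit <- tryCatch(deming_fit(x, y, lambda = lambda), error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, traits[j])
      next
    }
    response[, j] <- deming_residuals(fit, x, y)
    fits$intercept[j] <- fit$intercept
    fits$slope[j] <- fit$slope
    fits$n_used[j] <- fit$n_used
  }
  if (length(skipped)) {
    message("response skipped for degenerate trait(s): ",
            paste(skipped, collapse = ", "))
    response <- response[, setdiff(traits, skipped), drop = FALSE]
  }
  attr(response, "method") <- method
  list(response = response, fits = fits, skipped = skipped)
}
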