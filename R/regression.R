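#' Simple linear regression of deletion rate on a covariate
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], returning the
#' quantities the screens report: slope, intercept, R-squared and the
#' two-sided slope p-value. A response with zero variance is a valid
#' degenerate case (flat fit): slope 0, R-squared 0, p-value 1.
#'
#' @param y Numeric response (deletion rate).
#' @param x Numeric covariate (age, BMI, alcohol intake, SNP dosage, ...).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
ols_regression <- function(y, x) {
  if (length(y) != length(x)) stop("'y' and 'x' must have the same length")
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]
  x <- x[keep]
  if (length(y) < 3L) stop("at least three paired observations are required")
  if (length(unique(x)) < 2L) stop("covariate is constant")
  if (stats::var(y) == 0) {
    res <- list(slope = 0, intercept = y[1L], r_squared = 0, p_value = 1,
                n = length(y))
    class(res) <- "regression_result"
    return(res)
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  res <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = s$r.squared,
              p_value = unname(s$coefficients[2L, 4L]),
              n = length(y))
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS (n = %d): slope = %.4g, R^2 = %.4g, p = %.4g\n",
              x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

# Column-wise OLS slope p-values for a matrix of responses against one
# fixed regressor. Used by the power simulations, where fitting
# thousands of lm() objects would dominate run time.
.ols_pvalues <- function(y, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ybar <- colMeans(y)
  sxy <- crossprod(xc, y)[1L, ]
  slope <- sxy / sxx
  sst <- colSums(y^2) - n * ybar^2
  sse <- pmax(sst - slope^2 * sxx, 0)
  se <- sqrt(sse / ((n - 2) * sxx))
  t <- ifelse(se > 0, slope / se, 0)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  # zero-variance response columns carry no evidence
  p[sst == 0] <- 1
  p
}

# Column-wise Spearman rank-correlation p-values (t approximation, the
# standard large-sample treatment in the presence of ties).
.spearman_pvalues <- function(y, x) {
  n <- length(x)
  rx <- rank(x)
  ry <- apply(y, 2L, rank)
  rho <- suppressWarnings(stats::cor(rx, ry))[1L, ]
  rho[is.na(rho)] <- 0
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(t), df = n - 2)
}
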