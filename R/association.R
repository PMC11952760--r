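#' Kendall rank correlation between two test statistics
#'
#' Tau-b rank correlation (via [stats::cor()]), used to quantify agreement
#' between conformity statistics computed across several cases.  With no
#' ties tau-b reduces to the plain concordant-minus-discordant pair count
#' over C(n,2) pairs.  The normal-approximation Z uses the null variance
#' n(n-1)(2n+5)/18 of the S statistic; it is reported for orientation
#' only, as small-sample tie-free tau calls for exact tables.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `tau`, `n`, and `z` (normal approximation).
#' @examples
#' kendall_tau(c(1, 2, 3), c(10, 20, 30))$tau  # 1
#' @export
kendall_tau <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("`x` and `y` must be numeric")
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  n <- length(x)
  tau <- cor(x, y, method = "kendall")
  # S recovered from tau-b; exact for tie-free data
  s <- tau * sqrt(choose(n, 2) - tie_correction(x)) *
    sqrt(choose(n, 2) - tie_correction(y))
  z <- s / sqrt(n * (n - 1) * (2 * n + 5) / 18)
  list(tau = tau, n = n, z = z)
}

tie_correction <- function(v) {
  t <- table(v)
  sum(choose(t[t > 1], 2))
}

#' Log-log ordinary least squares power-law fit
#'
#' Fits \eqn{y = a x^b} by OLS on \eqn{(\log_{10} x, \log_{10} y)}: the
#' exponent is the slope and the coefficient is 10^intercept.  The
#' correlation and R^2 reported are those of the log-log regression (the
#' convention of spreadsheet power trendlines).
#'
#' @param x,y Strictly positive numeric vectors of equal length >= 3.
#' @return An object of class `power_fit`: list with `coefficient` (a),
#'   `exponent` (b), `r_loglog`, `r_squared_loglog`, `n_points`, and the
#'   underlying `lm` fit as `model`.
#' @examples
#' fit <- loglog_power_fit(1:9, 2 * (1:9)^3)
#' c(fit$coefficient, fit$exponent)  # 2, 3
#' @export
loglog_power_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 points for a power-law fit")
  bad <- !is.finite(x) | !is.finite(y) | x <= 0 | y <= 0
  if (any(bad))
    stop("power-law fitting requires positive finite values; offending ",
         "pair(s) at position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  lx <- log10(x)
  ly <- log10(y)
  fit <- lm(ly ~ lx)
  r <- cor(lx, ly)
  structure(list(
    coefficient = 10^coef(fit)[[1]],
    exponent = coef(fit)[[2]],
    r_loglog = r,
    r_squared_loglog = r^2,
    n_points = length(x),
    model = fit), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: y = %.4g * x^%.4g  (log-log R^2 = %.3f, n = %d)\n",
              x$coefficient, x$exponent, x$r_squared_loglog, x$n_points))
  invisible(x)
}

#' Mean and variance of measurements partitioned by first digit
#'
#' Splits a set of positive measurements into the nine first-digit
#' classes and computes each class's member count, mean, and sample
#' variance (n-1 denominator).  Classes with fewer than two members get
#' `NA` variance and are excluded from downstream mean-variance
#' (Taylor's power law) fits.  The per-class members are kept as the
#' `"members"` attribute.
#'
#' @param values Numeric vector of positive measurements.
#' @return Data frame with columns `digit`, `n`, `mean`, `variance`.
#' @examples
#' digit_partition_stats(c(0.07, 0.73, 0.76, 70.18))
#' @export
digit_partition_stats <- function(values) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric vector")
  values <- values[is.finite(values) & values != 0]
  values <- abs(values)
  if (length(values) == 0L) stop("no usable values after preprocessing")
  fsd <- first_significant_digit(values)
  members <- split(values, factor(fsd, levels = 1:9))
  out <- data.frame(
    digit = 1:9,
    n = vapply(members, length, integer(1)),
    mean = vapply(members, function(v) if (length(v)) mean(v) else NA_real_,
                  numeric(1)),
    variance = vapply(members, function(v) if (length(v) >= 2L) var(v)
                      else NA_real_, numeric(1)),
    row.names = NULL)
  attr(out, "members") <- members
  out
}

#' Taylor's power law on digit-partitioned data
#'
#' Convenience wrapper: partitions measurements by first digit with
#' [digit_partition_stats()] and fits the mean-variance power law
#' \eqn{V = a M^b} with [loglog_power_fit()] over the digit classes with a
#' defined variance.  An exponent near 2 indicates an aggregated spatial
#' pattern.
#'
#' @inheritParams digit_partition_stats
#' @return A `power_fit` (see [loglog_power_fit()]) with the partition
#'   table attached as attribute `"partition"`.
#' @export
taylor_power_law <- function(values) {
  parts <- digit_partition_stats(values)
  ok <- !is.na(parts$variance) & parts$variance > 0 & parts$mean > 0
  if (sum(ok) < 3L)
    stop("fewer than 3 digit classes with a defined positive variance")
  fit <- loglog_power_fit(parts$mean[ok], parts$variance[ok])
  attr(fit, "partition") <- parts
  fit
}
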