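#' The Benford first-digit reference distribution
#'
#' Expected probabilities of the nine first significant digits under the
#' Newcomb-Benford law, \eqn{P(d) = \log_{10}(1 + 1/d)}.  The terms
#' telescope (\eqn{\prod_d (d+1)/d = 10}), so the nine probabilities sum to
#' one and decrease strictly from 0.30103 (digit 1) to 0.04576 (digit 9).
#'
#' @return Named numeric vector of length 9 (names `"1"` to `"9"`).
#' @examples
#' benford_probs()
#' sum(benford_probs())
#' @export
benford_probs <- function() {
  d <- 1:9
  setNames(log10(1 + 1 / d), as.character(d))
}

#' Expected first-digit counts under the Benford law
#'
#' @param n Non-negative total sample size.
#' @return Named numeric vector of length 9, element `d` equal to
#'   `n * log10(1 + 1/d)`.
#' @examples
#' round(benford_expected(141), 1)
#' @export
benford_expected <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("`n` must be a single non-negative number, got ", deparse(n))
  n * benford_probs()
}

#' First significant digit of a positive number
#'
#' Extracts the leading non-zero decimal digit, which is invariant to
#' scaling by powers of ten.  Extraction goes through the decimal string
#' representation at 15 significant digits rather than repeated
#' division, so values such as 0.07 (stored in binary as
#' 0.0699999...) map to digit 7, never 6.
#'
#' @param x Numeric vector of strictly positive, finite values.
#' @return Integer vector of digits in 1..9.
#' @examples
#' first_significant_digit(c(0.061, 0.14, 9.21, 20.2, 23.0, 723.0, 3345.0))
#' first_significant_digit(0.07)
#' @export
first_significant_digit <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("first significant digits are defined only for positive finite ",
         "values; offending value(s): ",
         paste(utils::head(format(x[bad]), 5L), collapse = ", "))
  # leading character of the scientific representation at 15 sig. digits
  as.integer(substr(formatC(x, format = "e", digits = 14L), 1L, 1L))
}

#' Construct a first-digit tally
#'
#' A `digit_tally` holds nine non-negative integer counts indexed by first
#' digit, plus the total `n`.  It is the unit of analysis for every
#' conformity statistic in the package.
#'
#' @param counts Numeric vector of 9 non-negative counts for digits 1..9.
#' @return An object of class `digit_tally`: named integer vector with
#'   attribute `n`.
#' @examples
#' digit_tally(c(47, 27, 18, 14, 10, 11, 4, 4, 6))
#' @export
digit_tally <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 9L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("`counts` must be 9 non-negative integers (digits 1..9)")
  structure(setNames(as.integer(counts), as.character(1:9)),
            n = as.integer(sum(counts)), class = "digit_tally")
}

#' @export
print.digit_tally <- function(x, ...) {
  cat("First-digit tally (n =", attr(x, "n"), ")\n")
  print(setNames(as.integer(x), names(x)))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && sum(unlist(dropped)) > 0)
    cat("dropped during preprocessing:",
        paste(names(dropped), unlist(dropped), sep = " = ", collapse = ", "),
        "\n")
  invisible(x)
}

#' Tally the first significant digits of a set of measurements
#'
#' Applies the preprocessing policy (zeros are always dropped; negative
#' values either contribute their absolute value or are dropped), extracts
#' first digits, and tabulates them.  The numbers of values dropped by each
#' rule are kept as the `"dropped"` attribute so the policy's effect is
#' always visible.
#'
#' @param values Numeric vector of measurements.
#' @param negatives Either `"abs"` (default: use the absolute value) or
#'   `"drop"`.  The packaged ecological case data are strictly positive, so
#'   the choice never affects them; it exists so the policy is explicit for
#'   user data.
#' @return A [digit_tally()] whose counts sum to the number of retained
#'   values.
#' @examples
#' tally_digits(c(0.061, 0.14, 9.21, 20.2, 23.0, 723.0, 3345.0))
#' @export
tally_digits <- function(values, negatives = c("abs", "drop")) {
  negatives <- match.arg(negatives)
  if (!is.numeric(values)) stop("`values` must be numeric")
  n_na <- sum(!is.finite(values))
  values <- values[is.finite(values)]
  n_zero <- sum(values == 0)
  values <- values[values != 0]
  n_neg <- sum(values < 0)
  values <- if (negatives == "abs") abs(values) else values[values > 0]
  if (length(values) == 0L)
    stop("no values left after preprocessing (dropped: ", n_na,
         " non-finite, ", n_zero, " zero",
         if (negatives == "drop") paste0(", ", n_neg, " negative"), ")")
  tally <- digit_tally(tabulate(first_significant_digit(values), nbins = 9L))
  attr(tally, "dropped") <- list(
    non_finite = n_na, zero = n_zero,
    negative = if (negatives == "drop") n_neg else 0L)
  tally
}

#' Observed first-digit probabilities
#'
#' Coerces a tally, a 9-vector of counts, or a 9-vector of probabilities to
#' a digit probability distribution (nine non-negative reals summing to 1).
#'
#' @param x A `digit_tally`, 9 counts, or 9 probabilities.
#' @return Named numeric vector of 9 probabilities.
#' @export
digit_probs <- function(x) {
  if (inherits(x, "digit_tally")) {
    n <- attr(x, "n")
    if (n == 0L) stop("cannot form probabilities from an empty tally")
    return(setNames(as.numeric(x) / n, as.character(1:9)))
  }
  x <- as.numeric(x)
  if (length(x) != 9L || anyNA(x) || any(x < 0))
    stop("expected a digit_tally or 9 non-negative numbers")
  s <- sum(x)
  if (s == 0) stop("all-zero digit vector has no probability distribution")
  if (abs(s - 1) > 1e-9) x <- x / s
  setNames(x, as.character(1:9))
}

#' Dataset diagnostics for first-digit analysis
#'
#' Checks the assessment preconditions for a meaningful first-digit
#' conformity test: the data should span at least one order of magnitude
#' (the more the better; up to six have been recommended), populate all
#' nine digit categories, and have a sample size inside the 80-500 range
#' for which the Morrow critical values were simulated.  A sample size
#' outside that range triggers a warning, not an error: the distance is
#' well defined at any n and the aggregation theorem motivates applying it
#' to larger pooled samples.
#'
#' @param values Numeric vector of positive measurements.
#' @param negatives Passed to [tally_digits()].
#' @return An object of class `benford_diagnostics`: list with elements
#'   `n`, `orders_of_magnitude` (integer, `floor(log10(max/min))`),
#'   `log10_span` (the exact ratio on the log10 scale), `digits_populated`
#'   (0-9), and `morrow_valid` (`TRUE` iff `80 <= n <= 500`).
#' @examples
#' d <- dataset_diagnostics(load_case("fish_ewh")$raw_values)
#' d$orders_of_magnitude
#' @export
dataset_diagnostics <- function(values, negatives = c("abs", "drop")) {
  tally <- tally_digits(values, negatives)
  values <- abs(values[is.finite(values) & values != 0])
  values <- values[values > 0]
  n <- attr(tally, "n")
  span <- log10(max(values) / min(values))
  out <- structure(list(
    n = n,
    orders_of_magnitude = as.integer(floor(span)),
    log10_span = span,
    digits_populated = sum(tally > 0L),
    morrow_valid = n >= 80L && n <= 500L,
    tally = tally), class = "benford_diagnostics")
  if (!out$morrow_valid)
    warning("sample size n = ", n, " lies outside the 80..500 range for ",
            "which the Morrow critical values were simulated; treat the ",
            "Morrow verdict with caution", call. = FALSE)
  out
}

#' @export
print.benford_diagnostics <- function(x, ...) {
  cat("First-digit dataset diagnostics\n")
  cat("  n                  :", x$n, "\n")
  cat("  orders of magnitude:", x$orders_of_magnitude,
      sprintf("(log10 span %.2f)", x$log10_span), "\n")
  cat("  digits populated   :", x$digits_populated, "of 9\n")
  cat("  Morrow range 80-500:", if (x$morrow_valid) "yes" else "NO", "\n")
  invisible(x)
}

#' Read measurements or a digit tally from a delimited text file
#'
#' `read_measurements()` reads a numeric column from a CSV/TSV file (header
#' required).  `read_digit_tally()` reads a 9-row `digit,count` file into a
#' [digit_tally()].
#'
#' @param path File path.
#' @param column Name of the numeric column to read.
#' @param sep Field separator, `","` by default (use `"\t"` for TSV).
#' @return `read_measurements()`: numeric vector. `read_digit_tally()`: a
#'   `digit_tally`.
#' @export
read_measurements <- function(path, column, sep = ",") {
  df <- read.csv(path, sep = sep, header = TRUE)
  if (!column %in% names(df))
    stop("column '", column, "' not found in ", path,
         " (columns: ", paste(names(df), collapse = ", "), ")")
  as.numeric(df[[column]])
}

#' @rdname read_measurements
#' @export
read_digit_tally <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, header = TRUE)
  if (!all(c("digit", "count") %in% names(df)))
    stop("expected columns 'digit' and 'count' in ", path)
  counts <- integer(9)
  counts[df$digit] <- df$count
  digit_tally(counts)
}
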