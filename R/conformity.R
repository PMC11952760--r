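#' Morrow sample-size-scaled Euclidean distance
#'
#' The nine-dimensional Euclidean distance between observed and Benford
#' first-digit probabilities, scaled by the square root of the sample
#' size:
#' \deqn{d^*_n = \sqrt{n}\,\sqrt{\sum_{d=1}^{9} (OBS(d) - EXP(d))^2}.}
#' Critical values from Monte-Carlo simulation for n between 80 and 500
#' are 1.22 (alpha 0.10), 1.33 (alpha 0.05) and 1.57 (alpha 0.01); see
#' [benford_thresholds()].  Algebraically \eqn{(d^*_n)^2 = n \cdot SSD
#' \cdot 10^{-4}} with [kossovsky_ssd()].
#'
#' @param tally A [digit_tally()] (or 9 counts) with positive total.
#' @param ref Reference probabilities, Benford by default.
#' @return The distance, a non-negative scalar.
#' @examples
#' morrow_distance(load_case("fish_ewh")$tally)  # 0.638
#' @export
morrow_distance <- function(tally, ref = benford_probs()) {
  if (!inherits(tally, "digit_tally")) tally <- digit_tally(tally)
  n <- attr(tally, "n")
  if (n == 0L) stop("Morrow distance is undefined for an empty tally (n = 0)")
  sqrt(n) * sqrt(sum((digit_probs(tally) - ref)^2))
}

#' Kossovsky sum of squared deviations (SSD)
#'
#' Sum of squared deviations between observed and Benford digit
#' probabilities, scaled by 10^4; a descriptive distance that does not
#' involve the sample size.  SSD <= 25 indicates moderate-to-strong
#' conformity, SSD >= 100 non-conformity, and the open window 75-100 is
#' read as a transition signal.
#'
#' @param obs A `digit_tally`, 9 counts, or 9 observed probabilities.
#' @inheritParams morrow_distance
#' @return Non-negative scalar on the 10^4 probability scale.
#' @examples
#' kossovsky_ssd(load_case("succession_early")$tally)  # 38.4
#' @export
kossovsky_ssd <- function(obs, ref = benford_probs()) {
  sum((digit_probs(obs) - ref)^2) * 1e4
}

#' Cohen-W effect size for digit conformity
#'
#' Sample-size-independent effect size of the departure of observed digit
#' probabilities from the Benford reference:
#' \deqn{W = \sqrt{\sum_{d=1}^{9} (OBS(d) - EXP(d))^2 / EXP(d)},}
#' i.e. the square root of the chi-square statistic divided by n.
#' Conventional descriptive thresholds are 0.1 (weak), 0.3 (moderate) and
#' 0.5 (strong); W >= 0.5 is read as non-conformity and the open window
#' 0.3-0.5 as a transition signal.
#'
#' @inheritParams kossovsky_ssd
#' @return Non-negative scalar.
#' @examples
#' cohen_w(load_case("fish_ewh")$tally)  # 0.182
#' @export
cohen_w <- function(obs, ref = benford_probs()) {
  sqrt(sum((digit_probs(obs) - ref)^2 / ref))
}

#' Per-digit Pearson residuals
#'
#' Signed standardized deviations of each digit's observed count from its
#' Benford-expected count,
#' \eqn{PR_d = (O_d - n\,EXP(d)) / \sqrt{n\,EXP(d)}}.  Two or more digits
#' with |PR| >= 1.96 indicate microscopic non-conformity at the 5% level;
#' exactly one is read as a transition signal.  The squared residuals sum
#' to the chi-square goodness-of-fit statistic.
#'
#' @inheritParams morrow_distance
#' @return Named numeric vector of 9 signed residuals.
#' @examples
#' round(pearson_residuals(load_case("fish_ewh")$tally), 2)
#' @export
pearson_residuals <- function(tally, ref = benford_probs()) {
  if (!inherits(tally, "digit_tally")) tally <- digit_tally(tally)
  n <- attr(tally, "n")
  if (n == 0L) stop("Pearson residuals are undefined for an empty tally")
  expected <- n * ref
  (as.numeric(tally) - expected) / sqrt(expected)
}

#' Kullback-Leibler divergence from the Benford reference
#'
#' Relative entropy \eqn{\sum_d OBS(d) \log_b(OBS(d)/EXP(d))} of the
#' observed digit distribution from the reference.  With the default base
#' 10 the result is in Hartley units.  Zero observed cells contribute 0
#' (the \eqn{x \log x \to 0} limit); the reference never vanishes, so no
#' smoothing is needed.  Non-negative by Gibbs' inequality, and zero iff
#' the distributions coincide.
#'
#' @inheritParams kossovsky_ssd
#' @param base Logarithm base; 10 (Hartley units) by default.
#' @return Non-negative scalar.
#' @examples
#' kl_divergence(load_case("fish_ewh")$tally)  # 0.0083
#' @export
kl_divergence <- function(obs, ref = benford_probs(), base = 10) {
  p <- digit_probs(obs)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / ref[pos], base = base))
}

#' Simpson diversity index of a digit distribution
#'
#' \eqn{D = \sum_{d=1}^{9} p_d^2} over the nine first-digit probability
#' categories: 1/9 for a uniform digit distribution (maximum diversity), 1
#' when all mass sits on one digit.  The Benford reference itself gives
#' D = 0.165, a scale-invariant benchmark of digit "evenness" for systems
#' at steady state.
#'
#' @inheritParams kossovsky_ssd
#' @return Scalar in \[1/9, 1\].
#' @examples
#' simpson_index(benford_probs())  # 0.165
#' @export
simpson_index <- function(obs) {
  sum(digit_probs(obs)^2)
}

#' Symmetric percentage difference between two quantities
#'
#' \eqn{PD = |a - b| / ((a + b)/2) \times 100}; used to compare
#' Kullback-Leibler divergences between two sampling occasions or
#' locations, with PD < 10% a nominal level of similarity.
#'
#' @param a,b Non-negative scalars, not both zero.
#' @return Percentage in \[0, 200\].
#' @examples
#' percentage_difference(0.0071, 0.0068)  # 4.32
#' @export
percentage_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("`a` and `b` must be scalars")
  if (is.na(a) || is.na(b) || a < 0 || b < 0)
    stop("`a` and `b` must be non-negative")
  if (a + b == 0) stop("percentage difference is undefined when a = b = 0")
  abs(a - b) / ((a + b) / 2) * 100
}

#' Full conformity report for a digit tally
#'
#' Computes all five conformity statistics plus the digit-probability
#' Simpson index for one dataset: the Morrow distance, Kossovsky SSD,
#' Cohen-W, the nine Pearson residuals, and the Kullback-Leibler
#' divergence in Hartley units.  Values are kept at full precision;
#' rounding to the conventional reporting precision happens only in
#' `print()` / [report_to_json()].
#'
#' @param tally A [digit_tally()], 9 counts, or a numeric vector of raw
#'   measurements (anything longer than 9, or with a `raw = TRUE` hint,
#'   is tallied first).
#' @param raw Set `TRUE` to force `tally` to be treated as raw
#'   measurements even if it has length 9.
#' @inheritParams morrow_distance
#' @return An object of class `conformity_report`: list with elements
#'   `n`, `counts`, `obs_probs`, `morrow_d`, `ssd`, `cohen_w`,
#'   `pearson_residuals`, `max_abs_pr`, `kl_d`, `simpson_d`.
#' @examples
#' conformity_report(load_case("fish_ewh")$tally)
#' @export
conformity_report <- function(tally, ref = benford_probs(), raw = FALSE) {
  if (!inherits(tally, "digit_tally")) {
    tally <- if (raw || length(tally) != 9L) tally_digits(tally)
             else digit_tally(tally)
  }
  pr <- pearson_residuals(tally, ref)
  structure(list(
    n = attr(tally, "n"),
    counts = setNames(as.integer(tally), as.character(1:9)),
    obs_probs = digit_probs(tally),
    morrow_d = morrow_distance(tally, ref),
    ssd = kossovsky_ssd(tally, ref),
    cohen_w = cohen_w(tally, ref),
    pearson_residuals = setNames(pr, as.character(1:9)),
    max_abs_pr = max(abs(pr)),
    kl_d = kl_divergence(tally, ref),
    simpson_d = simpson_index(tally)), class = "conformity_report")
}

# footnote-style display rounding, used by print and the JSON display block
format_report_display <- function(x) {
  list(
    n = x$n,
    morrow_d = sprintf("%.3f", x$morrow_d),
    ssd = sprintf(if (x$ssd < 10) "%.2f" else "%.1f", x$ssd),
    cohen_w = sprintf("%.3f", x$cohen_w),
    max_abs_pr = sprintf("%.2f", x$max_abs_pr),
    kl_d = sprintf("%.4f", x$kl_d),
    simpson_d = sprintf("%.3f", x$simpson_d))
}

#' @export
print.conformity_report <- function(x, ...) {
  disp <- format_report_display(x)
  cat("Benford first-digit conformity report (n =", x$n, ")\n\n")
  tab <- rbind(`OBS count` = x$counts,
               `EXP count` = round(x$n * benford_probs(), 1),
               `Pearson residual` = round(x$pearson_residuals, 2))
  print(tab)
  cat("\n")
  cat("  Morrow distance d*_n :", disp$morrow_d, "\n")
  cat("  Kossovsky SSD        :", disp$ssd, "\n")
  cat("  Cohen-W              :", disp$cohen_w, "\n")
  cat("  max |Pearson resid.| :", disp$max_abs_pr, "\n")
  cat("  KL divergence (Hart.):", disp$kl_d, "\n")
  cat("  Simpson digit index  :", disp$simpson_d, "\n")
  invisible(x)
}

#' Serialize a conformity report to JSON
#'
#' Full-precision fields plus a `display` block rounded to the
#' conventional reporting precision (distance 3 d.p., SSD 1-2 d.p.,
#' Cohen-W 3 d.p., residuals 2 d.p., KL 4 d.p.).
#'
#' @param report A [conformity_report()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "conformity_report"))
  obj <- unclass(report)
  obj$display <- format_report_display(report)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
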