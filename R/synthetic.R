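#' Log-uniform (Benford-exact) sample generator
#'
#' Draws `10^U` with `U` uniform on `[0, decades)`.  For integer
#' `decades` the first-digit law of the draws is exactly Benford in
#' expectation, making this the canonical null generator for positive
#' measurements spanning a given number of orders of magnitude.
#' Reproducible: the RNG state is set from `seed` locally (Mersenne
#' Twister via [withr::with_seed()]) and restored afterwards.
#'
#' @param n Number of values (>= 1).
#' @param decades Orders of magnitude spanned (> 0); six give data like a
#'   well-mixed ecological biomass survey.
#' @param seed Integer seed.
#' @return Numeric vector of n positive values.
#' @examples
#' tally_digits(gen_loguniform(1000, decades = 6, seed = 1))
#' @export
gen_loguniform <- function(n, decades, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  if (!is.numeric(decades) || length(decades) != 1L || is.na(decades) ||
      decades <= 0)
    stop("`decades` must be a positive number, got ", deparse(decades))
  withr::with_seed(seed, 10^runif(n, 0, decades))
}

#' Hill-style mixture generator
#'
#' Emulates the aggregation mechanism behind Hill's theorem: samples are
#' drawn from `n_dists` randomly parameterized lognormal components
#' (log10-scale location uniform on `location`, scale uniform on
#' `scale`), `n_per` values each.  Individual components need not follow
#' the Benford law, but the combined sample tends to be closer to it
#' (lower SSD) than a typical single component.
#'
#' @param n_dists Number of component distributions (>= 1).
#' @param n_per Samples per component (>= 1).
#' @param seed Integer seed.
#' @param location,scale Ranges (length-2) for the component log10
#'   location and scale parameters.
#' @return Data frame with columns `value` and `component`.
#' @examples
#' mix <- gen_hill_mixture(10, 50, seed = 1)
#' kossovsky_ssd(tally_digits(mix$value))
#' @export
gen_hill_mixture <- function(n_dists, n_per, seed = 1L,
                             location = c(-2, 4), scale = c(0.3, 1.5)) {
  if (n_dists < 1 || n_per < 1) stop("`n_dists` and `n_per` must be >= 1")
  withr::with_seed(seed, {
    loc <- runif(n_dists, location[1], location[2])
    sc <- runif(n_dists, scale[1], scale[2])
    values <- unlist(lapply(seq_len(n_dists), function(i)
      10^rnorm(n_per, mean = loc[i], sd = sc[i])))
    data.frame(value = values,
               component = rep(seq_len(n_dists), each = n_per))
  })
}

#' Multinomial digit-tally generator
#'
#' Samples a [digit_tally()] of size n from arbitrary digit
#' probabilities; the null-hypothesis sampler used to calibrate
#' critical values and type-I error of the conformity tests.
#'
#' @param n Total count.
#' @param probs Vector of 9 digit probabilities summing to 1 (tolerance
#'   1e-9); defaults to the Benford reference.
#' @param seed Integer seed.
#' @return A [digit_tally()] with counts summing to n.
#' @examples
#' gen_digit_tally(200, seed = 1)
#' @export
gen_digit_tally <- function(n, probs = benford_probs(), seed = 1L) {
  probs <- as.numeric(probs)
  if (length(probs) != 9L || anyNA(probs) || any(probs < 0))
    stop("`probs` must be 9 non-negative probabilities")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("`probs` must sum to 1 (got ", format(sum(probs)), ")")
  counts <- withr::with_seed(seed, as.vector(rmultinom(1, size = n,
                                                       prob = probs)))
  digit_tally(counts)
}

#' Deplete large first digits from a sample
#'
#' Removes each value whose first significant digit is 6-9 independently
#' with probability `fraction`, mimicking the depletion of large leading
#' digits observed when larger-bodied organisms decline from a
#' community.  `fraction = 0` returns the input unchanged.
#'
#' @param values Numeric vector of positive measurements.
#' @param fraction Thinning probability in \[0, 1).
#' @param seed Integer seed.
#' @return Numeric vector, a subset of `values`.
#' @examples
#' x <- gen_loguniform(1000, 6, seed = 1)
#' length(perturb_large_digits(x, 0.5, seed = 2))
#' @export
perturb_large_digits <- function(values, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1), got ", deparse(fraction))
  if (fraction == 0) return(values)
  big <- first_significant_digit(values) >= 6L
  drop <- withr::with_seed(seed, big & runif(length(values)) < fraction)
  values[!drop]
}
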