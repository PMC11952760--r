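# Independent oracles used across test files.

# Kendall tau-b by exhaustive concordant/discordant pair counting.
brute_kendall <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  tx <- table(x); ty <- table(y)
  n0 <- choose(n, 2)
  s / sqrt((n0 - sum(choose(tx[tx > 1], 2))) *
           (n0 - sum(choose(ty[ty > 1], 2))))
}

# random digit probability vector (normalized exponentials keeps all cells
# strictly positive; zero cells are introduced explicitly where needed)
random_digit_probs <- function() {
  w <- rexp(9)
  w / sum(w)
}

# random non-degenerate digit tally
random_tally <- function(n = NULL) {
  if (is.null(n)) n <- sample(50:500, 1)
  gen_digit_tally(n, probs = random_digit_probs(),
                  seed = sample.int(1e6, 1))
}

printed <- function(case) load_case(case)$expected

# round like the case-report footnotes: SSD gets 2 d.p. below 10, else 1
ssd_digits <- function(x) if (x < 10) 2L else 1L

# The source tables display some cells rounded and some truncated (e.g. an
# SSD of 88.953 shown as 88.9, a KL of 0.012556 shown as 0.0125).  A
# recomputed value matches its record when either display rule explains it.
matches_display <- function(actual, recorded, digits) {
  scale <- 10^digits
  isTRUE(all.equal(round(actual, digits), recorded, tolerance = 1e-9)) ||
    isTRUE(all.equal(trunc(actual * scale) / scale, recorded,
                     tolerance = 1e-9))
}
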