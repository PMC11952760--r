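# minimal report with chosen statistic values, for boundary checks
fake_report <- function(morrow = 0.5, ssd = 10, w = 0.15, pr = rep(0, 9)) {
  structure(list(n = 100L, morrow_d = morrow, ssd = ssd, cohen_w = w,
                 pearson_residuals = pr, max_abs_pr = max(abs(pr)),
                 kl_d = 0.01, simpson_d = 0.17),
            class = "conformity_report")
}

state_of <- function(assessment, method) {
  as.character(assessment$verdicts$state[assessment$verdicts$method == method])
}

test_that("boundary values resolve per the stated inequality directions", {
  # closed non-conformity bounds
  expect_identical(state_of(classify_conformity(fake_report(morrow = 1.33)),
                            "morrow"), "nonconform")
  expect_identical(state_of(classify_conformity(fake_report(ssd = 100)),
                            "ssd"), "nonconform")
  expect_identical(state_of(classify_conformity(fake_report(w = 0.5)),
                            "cohen_w"), "nonconform")
  # open signal windows: the lower edge itself still conforms
  expect_identical(state_of(classify_conformity(fake_report(morrow = 1.22)),
                            "morrow"), "conform")
  expect_identical(state_of(classify_conformity(fake_report(morrow = 1.25)),
                            "morrow"), "transition_signal")
  expect_identical(state_of(classify_conformity(fake_report(ssd = 75)),
                            "ssd"), "conform")
  expect_identical(state_of(classify_conformity(fake_report(ssd = 90)),
                            "ssd"), "transition_signal")
  expect_identical(state_of(classify_conformity(fake_report(w = 0.3)),
                            "cohen_w"), "conform")
  expect_identical(state_of(classify_conformity(fake_report(w = 0.4)),
                            "cohen_w"), "transition_signal")
  # Pearson rule counts absolute residuals at the closed 1.96 bound
  pr1 <- c(1.96, rep(0, 8))
  expect_identical(state_of(classify_conformity(fake_report(pr = pr1)),
                            "pearson"), "transition_signal")
  pr2 <- c(1.96, -2.23, rep(0, 7))
  expect_identical(state_of(classify_conformity(fake_report(pr = pr2)),
                            "pearson"), "nonconform")
})

test_that("the overall verdict is the worst per-method state", {
  a <- classify_conformity(fake_report())
  expect_identical(as.character(a$overall), "conform")
  b <- classify_conformity(fake_report(ssd = 80))
  expect_identical(as.character(b$overall), "transition_signal")
  c_ <- classify_conformity(fake_report(ssd = 80, pr = c(2, 2, rep(0, 7))))
  expect_identical(as.character(c_$overall), "nonconform")
})

test_that("the three recorded case verdict patterns are reproduced", {
  fish <- classify_conformity(conformity_report(load_case("fish_ewh")$tally))
  expect_true(all(fish$verdicts$state == "conform"))
  expect_identical(as.character(fish$overall), "conform")

  large <- classify_conformity(
    conformity_report(load_case("diatoms_large")$tally))
  expect_identical(state_of(large, "ssd"), "transition_signal")
  expect_identical(state_of(large, "cohen_w"), "transition_signal")
  expect_identical(state_of(large, "pearson"), "nonconform")
  expect_identical(state_of(large, "morrow"), "conform")

  post <- classify_conformity(
    conformity_report(load_case("salamanders_post1990")$tally))
  expect_identical(state_of(post, "morrow"), "nonconform")
  expect_identical(state_of(post, "ssd"), "nonconform")
  expect_identical(state_of(post, "pearson"), "nonconform")
})

test_that("incomplete reports and bad threshold configs are rejected", {
  r <- fake_report()
  r$ssd <- NA_real_
  expect_error(classify_conformity(r), "incomplete")
  expect_error(classify_conformity(list(ssd = 5)), "conformity_report")
  expect_error(benford_thresholds(ssd_signal_low = 120), "window")
})

test_that("bootstrap CIs are reproducible, centred, and degenerate-safe", {
  fish <- load_case("fish_ewh")$tally
  a <- bootstrap_ci(fish, "ssd", B = 200, seed = 11)
  b <- bootstrap_ci(fish, "ssd", B = 200, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, bootstrap_ci(fish, "ssd", B = 200, seed = 12)))
  expect_equal(a$point, kossovsky_ssd(fish))
  expect_true(a$lower <= a$point && a$point <= a$upper)

  degenerate <- digit_tally(c(50, rep(0, 8)))
  d <- bootstrap_ci(degenerate, "cohen_w", B = 50, seed = 1)
  expect_equal(d$sd_boot, 0)
  expect_equal(d$lower, d$upper)

  expect_error(bootstrap_ci(fish, "ssd", B = 1), "at least 2")
  expect_error(bootstrap_ci(digit_tally(rep(0, 9)), "ssd"), "empty")
})

test_that("percentile mode gives an interval inside the replicate range", {
  fish <- load_case("fish_ewh")$tally
  p <- bootstrap_ci(fish, "cohen_w", B = 300, seed = 7,
                    method = "percentile")
  expect_true(p$lower < p$upper)
  expect_true(p$lower >= 0)
})

test_that("percentile CI coverage is near nominal for an interior truth", {
  # estimand: population SSD of a perturbed digit distribution; n large
  # enough that the plug-in bias (1 - sum p^2)/n * 1e4 is small against
  # the interval width -- see the vignette for the finite-n caveat
  p0 <- digit_probs(load_case("diatoms_large")$tally)
  truth <- kossovsky_ssd(p0)
  reps <- 150
  covered <- 0
  for (r in seq_len(reps)) {
    tl <- gen_digit_tally(8000, probs = p0, seed = 42 + r)
    ci <- bootstrap_ci(tl, "ssd", B = 300, seed = 42 + r,
                       method = "percentile")
    covered <- covered + (truth >= ci$lower && truth <= ci$upper)
  }
  expect_lt(abs(covered / reps - 0.95), 0.05)
})

test_that("case summaries collect statistics, CIs and verdicts", {
  cases <- load_case(c("fish_ewh", "salamanders_post1990"))
  reports <- lapply(cases, function(cs) conformity_report(cs$tally))
  cis <- list(fish_ewh = list(
    ssd = bootstrap_ci(cases$fish_ewh$tally, "ssd", B = 100, seed = 2)))
  tab <- summarize_cases(reports, om = c(4, 3), cis = cis)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$verdict, c("conform", "nonconform"))
  expect_false(is.na(tab$ssd_lo[1]))
  expect_true(is.na(tab$ssd_lo[2]))  # missing CI left blank
  expect_equal(tab$d_star, c(0.638, 1.437), tolerance = 1e-3)

  single <- summarize_cases(reports[1])
  expect_identical(nrow(single), 1L)
})
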