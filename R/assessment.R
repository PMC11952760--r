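#' Threshold configuration for state assessment
#'
#' Cut-points used by [classify_conformity()].  Defaults follow the
#' published protocol: Morrow critical values 1.22 / 1.33 / 1.57 at alpha
#' 0.10 / 0.05 / 0.01 (non-conformity declared at the alpha-0.05 value,
#' transition signal in the open window 1.22-1.33); Kossovsky SSD <= 25
#' moderate-to-strong conformity, >= 100 non-conformity, open signal
#' window 75-100; Cohen-W 0.1 / 0.3 / 0.5 weak / moderate / strong with
#' non-conformity at >= 0.5 and signal window 0.3-0.5; Pearson rule
#' |PR| >= 1.96 (two-sided 5% z), two or more flagged digits =
#' non-conformity, exactly one = signal; percentage-difference nominal
#' level 10%.
#'
#' @param morrow_alpha10,morrow_alpha05,morrow_alpha01 Morrow critical values.
#' @param ssd_conform,ssd_signal_low,ssd_nonconform SSD cut-points.
#' @param w_weak,w_signal_low,w_nonconform Cohen-W cut-points.
#' @param pr_z Residual flag level.
#' @param pr_nonconform_count,pr_signal_count Flagged-digit counts.
#' @param pd_nominal Nominal percentage-difference level (%).
#' @return A list of class `benford_thresholds`.
#' @export
benford_thresholds <- function(morrow_alpha10 = 1.22,
                               morrow_alpha05 = 1.33,
                               morrow_alpha01 = 1.57,
                               ssd_conform = 25,
                               ssd_signal_low = 75,
                               ssd_nonconform = 100,
                               w_weak = 0.1,
                               w_signal_low = 0.3,
                               w_nonconform = 0.5,
                               pr_z = 1.96,
                               pr_nonconform_count = 2L,
                               pr_signal_count = 1L,
                               pd_nominal = 10) {
  cfg <- list(morrow_alpha10 = morrow_alpha10, morrow_alpha05 = morrow_alpha05,
              morrow_alpha01 = morrow_alpha01, ssd_conform = ssd_conform,
              ssd_signal_low = ssd_signal_low, ssd_nonconform = ssd_nonconform,
              w_weak = w_weak, w_signal_low = w_signal_low,
              w_nonconform = w_nonconform, pr_z = pr_z,
              pr_nonconform_count = pr_nonconform_count,
              pr_signal_count = pr_signal_count, pd_nominal = pd_nominal)
  if (!(cfg$morrow_alpha10 < cfg$morrow_alpha05) ||
      !(cfg$ssd_signal_low < cfg$ssd_nonconform) ||
      !(cfg$w_signal_low < cfg$w_nonconform))
    stop("each transition-signal window must be a non-empty interval ",
         "below its non-conformity bound")
  structure(cfg, class = "benford_thresholds")
}

conformity_states <- c("conform", "transition_signal", "nonconform")

state_factor <- function(x) factor(x, levels = conformity_states, ordered = TRUE)

#' Classify a conformity report against state-transition thresholds
#'
#' Applies the four per-method rules (Morrow distance, Kossovsky SSD,
#' Cohen-W, Pearson residuals) of [benford_thresholds()] and combines them
#' into a weight-of-evidence overall verdict equal to the worst individual
#' state.  Boundary conventions: non-conformity bounds are closed
#' (`>=`), signal windows are open intervals, and the Pearson rule counts
#' absolute residuals.
#'
#' @param report A [conformity_report()].
#' @param config A [benford_thresholds()].
#' @return An object of class `benford_assessment`: list with a
#'   `verdicts` data frame (method, statistic, state, note) and `overall`
#'   (ordered factor: conform < transition_signal < nonconform).
#' @examples
#' classify_conformity(conformity_report(load_case("fish_ewh")$tally))
#' @export
classify_conformity <- function(report, config = benford_thresholds()) {
  if (!inherits(report, "conformity_report"))
    stop("`report` must be a conformity_report; see conformity_report()")
  needed <- c("morrow_d", "ssd", "cohen_w", "pearson_residuals")
  missing <- needed[!vapply(report[needed], function(f) !is.null(f) && !anyNA(f),
                            logical(1))]
  if (length(missing))
    stop("incomplete report; missing or NA fields: ",
         paste(missing, collapse = ", "))

  morrow_state <-
    if (report$morrow_d >= config$morrow_alpha05) "nonconform"
    else if (report$morrow_d > config$morrow_alpha10) "transition_signal"
    else "conform"
  ssd_state <-
    if (report$ssd >= config$ssd_nonconform) "nonconform"
    else if (report$ssd > config$ssd_signal_low) "transition_signal"
    else "conform"
  ssd_note <- if (ssd_state == "conform" && report$ssd <= config$ssd_conform)
    "moderate to strong conformity" else ""
  w_state <-
    if (report$cohen_w >= config$w_nonconform) "nonconform"
    else if (report$cohen_w > config$w_signal_low) "transition_signal"
    else "conform"
  n_flagged <- sum(abs(report$pearson_residuals) >= config$pr_z)
  pr_state <-
    if (n_flagged >= config$pr_nonconform_count) "nonconform"
    else if (n_flagged >= config$pr_signal_count) "transition_signal"
    else "conform"

  verdicts <- data.frame(
    method = c("morrow", "ssd", "cohen_w", "pearson"),
    statistic = c(report$morrow_d, report$ssd, report$cohen_w,
                  report$max_abs_pr),
    state = state_factor(c(morrow_state, ssd_state, w_state, pr_state)),
    note = c("", ssd_note, "",
             if (n_flagged > 0) paste(n_flagged, "digit(s) with |PR| >=",
                                      config$pr_z) else ""),
    stringsAsFactors = FALSE)
  structure(list(verdicts = verdicts,
                 overall = max(verdicts$state),
                 config = config),
            class = "benford_assessment")
}

#' @export
print.benford_assessment <- function(x, ...) {
  cat("Benford conformity assessment (weight of evidence)\n")
  v <- x$verdicts
  v$statistic <- sprintf("%.3f", v$statistic)
  print(v, row.names = FALSE)
  cat("overall:", as.character(x$overall), "\n")
  invisible(x)
}

boot_statistics <- list(
  ssd = function(tally) kossovsky_ssd(tally),
  cohen_w = function(tally) cohen_w(tally))

#' Bootstrap confidence interval for a digit-conformity statistic
#'
#' Resamples the n individual first-digit observations with replacement B
#' times and recomputes the statistic on each replicate tally.  Two
#' interval modes are available.  The default, `"confidence_t"`,
#' replicates the published spreadsheet procedure: the half-width is
#' \eqn{t_{1-\alpha/2, 8} \cdot s_{boot} / \sqrt{9}} where \eqn{s_{boot}}
#' is the standard deviation of the B replicate values and the fixed
#' divisor 9 is the number of digit categories, and the interval is
#' centred on the point estimate.  `"percentile"` is the conventional
#' percentile bootstrap.  Neither is a calibrated frequentist interval for
#' the population statistic (the plug-in statistic is biased upward at
#' finite n); see the package vignette.
#'
#' @param tally A [digit_tally()] or 9 counts.
#' @param statistic `"ssd"` or `"cohen_w"`.
#' @param B Number of bootstrap resamples (>= 2), default 1000.
#' @param alpha Two-sided error level, default 0.05.
#' @param seed Integer seed; required for reproducibility.
#' @param method `"confidence_t"` (default) or `"percentile"`.
#' @return An object of class `bootstrap_ci`: list with `point`, `lower`,
#'   `upper`, `sd_boot`, `B`, `seed`, `statistic`, `method`.
#' @examples
#' bootstrap_ci(load_case("fish_ewh")$tally, "ssd", B = 200, seed = 1)
#' @export
bootstrap_ci <- function(tally, statistic = c("ssd", "cohen_w"), B = 1000L,
                         alpha = 0.05, seed = 1L,
                         method = c("confidence_t", "percentile")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (!inherits(tally, "digit_tally")) tally <- digit_tally(tally)
  if (B < 2L) stop("`B` must be at least 2")
  n <- attr(tally, "n")
  if (n == 0L) stop("cannot bootstrap an empty tally")
  stat_fun <- boot_statistics[[statistic]]
  point <- stat_fun(tally)
  digits <- rep.int(1:9, as.integer(tally))
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ct <- tabulate(digits[sample.int(n, n, replace = TRUE)], nbins = 9L)
      stat_fun(digit_tally(ct))
    }, numeric(1))
  })
  sd_boot <- sd(reps)
  if (method == "confidence_t") {
    hw <- qt(1 - alpha / 2, df = 8L) * sd_boot / sqrt(9)
    lower <- point - hw
    upper <- point + hw
  } else {
    qs <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lower <- qs[1]
    upper <- qs[2]
  }
  structure(list(point = point, lower = lower, upper = upper,
                 sd_boot = sd_boot, B = as.integer(B), seed = seed,
                 alpha = alpha, statistic = statistic, method = method),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%s = %.4g, %d%% CI [%.4g, %.4g]  (%s, B = %d, seed = %d)\n",
              x$statistic, x$point, round(100 * (1 - x$alpha)), x$lower,
              x$upper, x$method, x$B, x$seed))
  invisible(x)
}

#' Summarize several conformity reports as one table
#'
#' One row per case: sample size, orders of magnitude (if supplied),
#' maximum absolute Pearson residual, Morrow distance, Cohen-W, SSD,
#' KL divergence, and the overall weight-of-evidence verdict.  Optional
#' bootstrap CIs for Cohen-W and SSD are appended when supplied; missing
#' CIs leave the columns `NA`.
#'
#' @param reports Named list of [conformity_report()] objects.
#' @param om Optional named/positional integer vector of orders of
#'   magnitude per case.
#' @param cis Optional named list per case, each a list with elements
#'   `cohen_w` and/or `ssd` holding [bootstrap_ci()] objects.
#' @param config Thresholds for the verdict column.
#' @return A data frame, one row per report.
#' @examples
#' reps <- lapply(load_case(c("fish_ewh", "combined_steady_state")),
#'                function(cs) conformity_report(cs$tally))
#' summarize_cases(reps)
#' @export
summarize_cases <- function(reports, om = NULL, cis = NULL,
                            config = benford_thresholds()) {
  if (inherits(reports, "conformity_report")) reports <- list(reports)
  if (length(reports) < 1L) stop("need at least one report")
  nm <- names(reports)
  if (is.null(nm)) nm <- paste0("case_", seq_along(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    cls <- classify_conformity(r, config)
    ci_w <- cis[[nm[i]]]$cohen_w
    ci_s <- cis[[nm[i]]]$ssd
    data.frame(
      case = nm[i],
      n = r$n,
      om = if (is.null(om)) NA_integer_ else as.integer(om[[i]]),
      max_pr = r$max_abs_pr,
      d_star = r$morrow_d,
      cohen_w = r$cohen_w,
      cohen_w_lo = if (is.null(ci_w)) NA_real_ else ci_w$lower,
      cohen_w_hi = if (is.null(ci_w)) NA_real_ else ci_w$upper,
      ssd = r$ssd,
      ssd_lo = if (is.null(ci_s)) NA_real_ else ci_s$lower,
      ssd_hi = if (is.null(ci_s)) NA_real_ else ci_s$upper,
      kl_d = r$kl_d,
      verdict = as.character(cls$overall),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
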