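#' Packaged ecological case datasets
#'
#' Eight first-digit case datasets drawn from published ecological
#' studies of systems at, or departing from, steady-state dynamic
#' equilibrium:
#'
#' * `succession_early`, `succession_late` -- mean annual biomass of
#'   below-ground food-web functional groups during early (stages 1-2)
#'   and late (stages 3-4) ecological succession at two Dutch natural
#'   areas (n = 159, 208).
#' * `diatoms_small`, `diatoms_large` -- cells per diatom species
#'   colonizing small (12 mm2) and large (25 mm2) glass-slide "islands"
#'   in a spring-fed stream (n = 105, 148).
#' * `salamanders_pre1990`, `salamanders_post1990` -- mean woodland
#'   salamander encounters per collector per site visit across eastern
#'   US forests, before and after the onset of widespread declines
#'   (n = 96, 173).
#' * `fish_ewh` -- relative weight (kg/km) of 141 fish species
#'   encounters from five Ohio stream segments of exceptional biotic
#'   integrity; this case also ships the 141 raw biomass values.
#' * `combined_steady_state` -- the pooled digit counts of the four
#'   steady-state cases (succession early/late, pre-1990 salamanders,
#'   fish; n = 604), used to probe the aggregation behaviour predicted
#'   by Hill's theorem.
#'
#' Each fixture carries the published summary statistics as `expected`
#' for regression testing.  Files are checksummed; [load_case()] fails
#' loudly if a fixture was edited.
#'
#' @param name Case name(s); see [case_names()].  With more than one
#'   name a named list of fixtures is returned.
#' @return A list of class `case_fixture`: `name`, `description`,
#'   `tally` (a [digit_tally()]), `raw_values` (fish case only, else
#'   `NULL`), and `expected` (published statistics: `n`, `om`, `d_star`,
#'   `cohen_w`, `cohen_w_ci`, `ssd`, `ssd_ci`, `kl_d`, `max_pr`).
#' @examples
#' fish <- load_case("fish_ewh")
#' fish$tally
#' @export
load_case <- function(name) {
  if (length(name) > 1L)
    return(setNames(lapply(name, load_case), name))
  available <- case_names()
  if (!is.character(name) || length(name) != 1L || !name %in% available)
    stop("unknown case '", paste(name, collapse = ", "), "'; available: ",
         paste(available, collapse = ", "))
  verify_fixture_checksums()
  tally <- read_digit_tally(case_file(file.path("tallies",
                                                paste0(name, ".csv"))))
  expected <- case_manifest()[[name]]
  raw <- NULL
  if (identical(name, "fish_ewh")) {
    raw_df <- read.csv(case_file("fish_ewh_biomass.csv"))
    raw <- raw_df$value
    attr(raw, "printed_digit") <- raw_df$printed_digit
  }
  structure(list(name = name,
                 description = expected$description,
                 tally = tally,
                 raw_values = raw,
                 expected = expected[setdiff(names(expected), "description")]),
            class = "case_fixture")
}

#' @rdname load_case
#' @export
case_names <- function() {
  sort(sub("\\.csv$", "",
           dir(case_file("tallies"), pattern = "\\.csv$")))
}

case_file <- function(...) {
  path <- system.file("extdata", ..., package = "benfordeco")
  if (path == "") stop("fixture file not found: ",
                       file.path(...), call. = FALSE)
  path
}

case_manifest_env <- new.env(parent = emptyenv())

case_manifest <- function() {
  if (is.null(case_manifest_env$expected))
    case_manifest_env$expected <-
      jsonlite::read_json(case_file("expected_stats.json"),
                          simplifyVector = TRUE)
  case_manifest_env$expected
}

verify_fixture_checksums <- function() {
  if (isTRUE(case_manifest_env$checked)) return(invisible(TRUE))
  manifest <- jsonlite::read_json(case_file("checksums.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest)) {
    sum <- unname(tools::md5sum(case_file(f)))
    if (!identical(sum, manifest[[f]]))
      stop("fixture checksum mismatch for '", f, "': expected ",
           manifest[[f]], ", found ", sum,
           " -- the packaged case data appear to have been edited")
  }
  case_manifest_env$checked <- TRUE
  invisible(TRUE)
}

#' @export
print.case_fixture <- function(x, ...) {
  cat("Case fixture:", x$name, "\n")
  cat(" ", x$description, "\n")
  print(x$tally)
  if (!is.null(x$raw_values))
    cat("  raw values:", length(x$raw_values), "measurements\n")
  invisible(x)
}

#' Check that part tallies sum to a whole
#'
#' Returns `TRUE` iff the element-wise sum of the part fixtures' digit
#' counts equals the whole fixture's counts; used to confirm that the
#' pooled steady-state tally really is the sum of its four constituent
#' cases.
#'
#' @param parts Character vector of case names.
#' @param whole A single case name.
#' @return Logical flag.
#' @examples
#' verify_combination(c("succession_early", "succession_late",
#'                      "salamanders_pre1990", "fish_ewh"),
#'                    "combined_steady_state")
#' @export
verify_combination <- function(parts, whole) {
  part_counts <- vapply(parts, function(p) as.integer(load_case(p)$tally),
                        integer(9))
  whole_counts <- as.integer(load_case(whole)$tally)
  all(rowSums(part_counts) == whole_counts)
}
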