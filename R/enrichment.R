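#' Build a restricted universe from query region sets
#'
#' The universe is the merged union of all query sets (LOLA's
#' `buildRestrictedUniverse` logic): every query interval is contained in
#' exactly one universe element.
#'
#' @param query_sets list of `GRanges` (at least one).
#' @return A sorted, non-overlapping `GRanges`.
#' @export
build_restricted_universe <- function(query_sets) {
  if (!is.list(query_sets)) query_sets <- list(query_sets)
  stopifnot(length(query_sets) >= 1)
  merge_intervals(suppressWarnings(do.call(c, unname(query_sets))),
                  max_gap = 0)
}

#' Region-set enrichment of a query against a feature database
#'
#' Contingency over universe elements: `a` query elements overlapping the
#' database (>= `min_overlap` bp), `b` query elements not overlapping,
#' `c`/`d` the same for the non-query remainder of the universe.  The odds
#' ratio is `(a*d)/(b*c)` (infinite when `b*c = 0` with `a*d > 0`) and the
#' p-value is the exact one-sided (enrichment) hypergeometric tail, LOLA
#' style; `alternative = "two.sided"` uses Fisher's exact test.
#'
#' @param query `GRanges`; every element must fall inside the universe.
#' @param universe `GRanges`, e.g. from [build_restricted_universe()].
#' @param db `GRanges` feature database (merged internally).
#' @param min_overlap minimum bp overlap counting as support.
#' @param alternative `"greater"` or `"two.sided"`.
#' @param query_name,db_name labels carried into the result.
#' @return data.frame (one row) with counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `p_value`, `query`, `db`.
#' @export
region_set_enrichment <- function(query, universe, db, min_overlap = 1L,
                                  alternative = c("greater", "two.sided"),
                                  query_name = "query", db_name = "db") {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe")
  .check_shared_chroms(query, universe, "query vs universe")
  if (!all(overlaps_any(query, universe))) {
    stop("query contains elements outside the universe")
  }
  db <- merge_intervals(db, 0)
  rest <- universe[!overlaps_any(universe, query)]
  a <- overlap_count(query, db, min_overlap)
  b <- length(query) - a
  cc <- overlap_count(rest, db, min_overlap)
  d <- length(rest) - cc
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
  }
  data.frame(query = query_name, db = db_name, a = a, b = b, c = cc, d = d,
             odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
}

#' Ratio of odds ratios between triplex-containing and triplex-less peaks
#'
#' Splits a peak set by a per-peak triplex flag, computes
#' [region_set_enrichment()] for both strata against the same universe
#' (default: the merged peaks themselves) and database, and returns the
#' ratio of the two odds ratios.  A ratio above 1 means the feature is
#' preferentially enriched where the lncRNA is predicted to form a triplex.
#'
#' @param peaks `GRanges`.
#' @param triplex_flags logical vector along `peaks` (both strata must be
#'   non-empty).
#' @param db feature database `GRanges`.
#' @param universe optional universe; defaults to
#'   `build_restricted_universe(list(peaks))`.
#' @param min_overlap minimum bp overlap counting as support.
#' @param db_name label.
#' @param haldane apply the Haldane-Anscombe correction (add 0.5 to every
#'   cell) when computing the two odds ratios, keeping the ratio finite
#'   for small strata with empty cells.  The uncorrected ratio (default)
#'   is flagged `undefined_or` in those cases.
#' @return list with `ratio` (NA with `flag = "undefined_or"` when either
#'   stratum's odds ratio is 0, infinite or undefined), `or_triplex`,
#'   `or_triplexless`, and the two `results` rows.
#' @export
stratified_or_ratio <- function(peaks, triplex_flags, db, universe = NULL,
                                min_overlap = 1L, db_name = "db",
                                haldane = FALSE) {
  stopifnot(length(triplex_flags) == length(peaks))
  if (all(triplex_flags) || !any(triplex_flags)) {
    stop("both triplex strata must be non-empty")
  }
  if (is.null(universe)) universe <- build_restricted_universe(list(peaks))
  e1 <- region_set_enrichment(peaks[triplex_flags], universe, db,
                              min_overlap, query_name = "triplex",
                              db_name = db_name)
  e0 <- region_set_enrichment(peaks[!triplex_flags], universe, db,
                              min_overlap, query_name = "triplexless",
                              db_name = db_name)
  or_of <- function(e) {
    if (haldane) {
      ((e$a + 0.5) * (e$d + 0.5)) / ((e$b + 0.5) * (e$c + 0.5))
    } else e$odds_ratio
  }
  or1 <- or_of(e1); or0 <- or_of(e0)
  undef <- !is.finite(or1) || !is.finite(or0) || or0 == 0 || is.nan(or1)
  list(ratio = if (undef) NA_real_ else or1 / or0,
       flag = if (undef) "undefined_or" else "ok",
       or_triplex = or1, or_triplexless = or0,
       results = rbind(e1, e0))
}
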