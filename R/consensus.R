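#' Parameters for consensus peak derivation
#'
#' @param min_support minimum number of distinct replicate experiments that
#'   must contribute a peak to a consensus region.
#' @param n_replicates expected number of replicate peak sets.
#' @param extend_size bp added on both sides of each peak center before
#'   overlap chaining.
#' @param shrink_to_fit shrink each consensus interval to the span of its
#'   member narrow regions whenever all of them fit inside the extended
#'   span.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(min_support = 2L, n_replicates = 3L,
                             extend_size = 500L, shrink_to_fit = TRUE) {
  stopifnot(min_support >= 1, min_support <= n_replicates, extend_size > 0)
  structure(list(min_support = as.integer(min_support),
                 n_replicates = as.integer(n_replicates),
                 extend_size = as.integer(extend_size),
                 shrink_to_fit = isTRUE(shrink_to_fit)),
            class = "consensus_params")
}

# Peak center: summit when a non-negative summit offset is recorded,
# otherwise the interval midpoint.
.peak_centers <- function(gr) {
  mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
  so <- S4Vectors::mcols(gr)$summit_offset
  if (is.null(so)) return(mid)
  so <- ifelse(is.na(so), -1L, so)
  ifelse(so >= 0L, GenomicRanges::start(gr) + so, mid)
}

#' Derive consensus peaks shared by replicate experiments
#'
#' Each replicate peak is extended `extend_size` bp on both sides of its
#' center (summit if available, midpoint otherwise).  Connected components
#' of overlapping extended regions, pooled across replicates, become
#' candidate consensus regions; a component is kept when it draws peaks
#' from at least `min_support` distinct replicates.  The consensus interval
#' is the span of the component's extended regions, shrunk to the minimal
#' interval covering the members' narrow regions whenever all of those lie
#' inside the extended span.
#'
#' @param replicate_peaks list of `GRanges` (one per replicate, narrowPeak
#'   metadata optional); must have at least `n_replicates` elements (empty
#'   sets allowed).
#' @param params a [consensus_params()] object.
#' @return A sorted, non-overlapping `GRanges` with metadata `support`
#'   (distinct replicates), `n_members`, `members` (collapsed
#'   `replicate:peak` labels), and `name`.
#' @export
find_consensus_peaks <- function(replicate_peaks,
                                 params = consensus_params()) {
  if (length(replicate_peaks) < params$n_replicates) {
    stop("expected at least ", params$n_replicates,
         " replicate peak sets, got ", length(replicate_peaks))
  }
  if (is.null(names(replicate_peaks))) {
    names(replicate_peaks) <- sprintf("rep%d", seq_along(replicate_peaks))
  }
  pooled <- list()
  for (r in names(replicate_peaks)) {
    gr <- replicate_peaks[[r]]
    if (length(gr) == 0L) next
    centers <- .peak_centers(gr)
    ext <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr),
      IRanges::IRanges(pmax(1L, centers - params$extend_size),
                       centers + params$extend_size))
    ext$replicate <- r
    ext$peak_idx <- seq_along(gr)
    ext$narrow_start <- GenomicRanges::start(gr)
    ext$narrow_end <- GenomicRanges::end(gr)
    pooled[[r]] <- ext
  }
  if (length(pooled) == 0L) return(.empty_consensus())
  all_ext <- suppressWarnings(do.call(c, unname(pooled)))
  comp <- GenomicRanges::reduce(all_ext, with.revmap = TRUE,
                                ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(comp)$revmap
  idx <- unlist(revmap)
  grp <- rep(seq_along(comp), lengths(revmap))
  reps_v <- all_ext$replicate[idx]
  label_v <- sprintf("%s:%d", reps_v, all_ext$peak_idx[idx])
  ns_v <- all_ext$narrow_start[idx]
  ne_v <- all_ext$narrow_end[idx]
  gf <- factor(grp, levels = seq_along(comp))
  support <- vapply(split(reps_v, gf), function(r) length(unique(r)),
                    integer(1))
  keep <- which(support >= params$min_support)
  if (length(keep) == 0L) return(.empty_consensus())
  ns <- vapply(split(ns_v, gf), min, numeric(1))
  ne <- vapply(split(ne_v, gf), max, numeric(1))
  members <- vapply(split(label_v, gf), paste, character(1), collapse = ",")
  span_s <- GenomicRanges::start(comp)
  span_e <- GenomicRanges::end(comp)
  shrink <- params$shrink_to_fit & ns >= span_s & ne <= span_e
  s <- ifelse(shrink, ns, span_s)[keep]
  e <- ifelse(shrink, ne, span_e)[keep]
  gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(comp))[keep],
    IRanges::IRanges(s, e))
  gr$support <- unname(support[keep])
  gr$n_members <- unname(lengths(revmap)[keep])
  gr$members <- unname(members[keep])
  gr <- GenomicRanges::sort(gr)
  gr$name <- sprintf("consensus_%d", seq_along(gr))
  gr$score <- gr$support
  gr
}

.empty_consensus <- function() {
  gr <- GenomicRanges::GRanges()
  gr$support <- integer(0)
  gr$n_members <- integer(0)
  gr$members <- character(0)
  gr$name <- character(0)
  gr$score <- integer(0)
  gr
}
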