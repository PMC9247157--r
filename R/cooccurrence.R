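#' Distance from each peak's DBS to its nearest Alu element
#'
#' For every peak carrying at least one DNA binding site, reports the
#' edge-to-edge distance between the (first) DBS and the nearest Alu
#' interval within the peak span extended by `window` bp on both sides
#' (0 when they overlap).  Peaks with no Alu in the search window are
#' flagged `no_alu` and excluded from the summary denominator.
#'
#' @param peaks `GRanges` of peaks.
#' @param dbs `GRanges` of DNA binding sites with a `peak` metadata column
#'   (index into `peaks`), e.g. built from [find_triplex_hits()] output.
#' @param alu `GRanges` Alu annotation.
#' @param window bp added around the peak when searching for Alu.
#' @param near_cutoff distance (bp) defining "near" in the summary.
#' @return list with `records` (peak, dbs/alu coordinates, `gap`,
#'   `no_alu`) and `summary` (`n`, `n_with_alu`, `fraction_near`,
#'   `median_gap`).
#' @export
dbs_alu_distance <- function(peaks, dbs, alu, window = 1000L,
                             near_cutoff = 300L) {
  if (length(dbs) == 0) stop("no DBS supplied")
  if (is.null(dbs$peak)) stop("dbs must carry a 'peak' column")
  peak_ids <- unique(dbs$peak)
  rec <- lapply(peak_ids, function(pi) {
    d <- dbs[dbs$peak == pi][1]
    search <- GenomicRanges::resize(peaks[pi],
                                    GenomicRanges::width(peaks[pi]) +
                                      2L * window, fix = "center")
    cand <- alu[overlaps_any(alu, search)]
    if (length(cand) == 0) {
      return(data.frame(peak = pi,
                        dbs_start = GenomicRanges::start(d),
                        dbs_end = GenomicRanges::end(d),
                        alu_start = NA_integer_, alu_end = NA_integer_,
                        gap = NA_real_, no_alu = TRUE))
    }
    gaps <- GenomicRanges::distance(d, cand, ignore.strand = TRUE)
    k <- which.min(gaps)
    data.frame(peak = pi,
               dbs_start = GenomicRanges::start(d),
               dbs_end = GenomicRanges::end(d),
               alu_start = GenomicRanges::start(cand)[k],
               alu_end = GenomicRanges::end(cand)[k],
               gap = as.numeric(gaps[k]), no_alu = FALSE)
  })
  records <- do.call(rbind, rec)
  with_alu <- records[!records$no_alu, , drop = FALSE]
  list(records = records,
       summary = list(
         n = nrow(records),
         n_with_alu = nrow(with_alu),
         fraction_near = if (nrow(with_alu) > 0) {
           mean(with_alu$gap < near_cutoff)
         } else NA_real_,
         median_gap = if (nrow(with_alu) > 0) {
           stats::median(with_alu$gap)
         } else NA_real_,
         near_cutoff = near_cutoff))
}

#' Per-bin triplex/Alu class percentages over fold-change-ranked genes
#'
#' Genes are ranked by decreasing absolute fold change (ties broken by gene
#' id), cut into consecutive bins of `bin_size` (the first bin holding the
#' most strongly modulated genes), and each bin is decomposed into the four
#' classes triplex+Alu / triplex only / Alu only / neither.
#'
#' @param gene_ids character vector.
#' @param has_dbs,has_alu logical vectors along `gene_ids`.
#' @param fold_change numeric vector along `gene_ids`.
#' @param bin_size genes per bin (>= 1).
#' @return data.frame with one row per bin: `bin`, `n`, and the four
#'   percentages (summing to 100 per bin) plus the `triplex_alu` indicator
#'   list-column used by the trend test.
#' @export
triplex_alu_table <- function(gene_ids, has_dbs, has_alu, fold_change,
                              bin_size = 20L) {
  stopifnot(bin_size >= 1,
            length(has_dbs) == length(gene_ids),
            length(has_alu) == length(gene_ids),
            length(fold_change) == length(gene_ids))
  if (any(is.na(fold_change))) stop("every gene needs a fold change")
  ord <- order(-abs(fold_change), gene_ids)
  n <- length(gene_ids)
  bin <- ceiling(seq_len(n) / bin_size)
  hd <- has_dbs[ord]; ha <- has_alu[ord]
  out <- lapply(unique(bin), function(b) {
    i <- bin == b
    cls <- c(triplex_alu = sum(hd[i] & ha[i]),
             triplex_only = sum(hd[i] & !ha[i]),
             alu_only = sum(!hd[i] & ha[i]),
             neither = sum(!hd[i] & !ha[i]))
    data.frame(bin = b, n = sum(i),
               pct_triplex_alu = 100 * cls[1] / sum(i),
               pct_triplex_only = 100 * cls[2] / sum(i),
               pct_alu_only = 100 * cls[3] / sum(i),
               pct_neither = 100 * cls[4] / sum(i))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "indicator_by_bin") <-
    split(as.numeric(hd & ha), bin)
  res
}

#' Jonckheere-Terpstra test for a monotone trend across ordered groups
#'
#' The statistic sums, over ordered group pairs i < j, the number of
#' cross-group value pairs with `x < y`, counting ties as 1/2.  The normal
#' approximation uses the tie-corrected null variance; a seeded permutation
#' p-value is available for small samples.  With no between-group
#' variability at all (every value identical) the p-value is 1.
#'
#' @param groups ordered list of numeric vectors (>= 3 non-empty groups).
#' @param alternative `"decreasing"` (values fall along the group order) or
#'   `"increasing"`.
#' @param method `"normal"` or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed seed for the permutation null.
#' @return list with `statistic`, `p_value`, `z`, `method`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("decreasing", "increasing"),
                                method = c("normal", "permutation"),
                                n_perm = 2000L, seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(groups) < 3) stop("need at least 3 ordered groups")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  jt_stat <- function(gr) {
    s <- 0
    for (i in seq_len(length(gr) - 1)) {
      for (j in (i + 1):length(gr)) {
        s <- s + sum(outer(gr[[i]], gr[[j]], "<")) +
          0.5 * sum(outer(gr[[i]], gr[[j]], "=="))
      }
    }
    s
  }
  obs <- jt_stat(groups)
  ni <- lengths(groups)
  N <- sum(ni)
  if (method == "permutation") {
    pooled <- unlist(groups)
    gidx <- rep(seq_along(groups), ni)
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        jt_stat(split(sample(pooled), gidx))
      }, numeric(1))
    })
    extreme <- if (alternative == "increasing") sum(perm >= obs)
               else sum(perm <= obs)
    return(list(statistic = obs, p_value = (1 + extreme) / (n_perm + 1),
                z = NA_real_, method = "permutation"))
  }
  mu <- (N^2 - sum(ni^2)) / 4
  tj <- as.numeric(table(unlist(groups)))
  v1 <- (N * (N - 1) * (2 * N + 5) -
           sum(ni * (ni - 1) * (2 * ni + 5)) -
           sum(tj * (tj - 1) * (2 * tj + 5))) / 72
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (36 * N * (N - 1) * (N - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (8 * N * (N - 1))
  v <- v1 + v2 + v3
  if (!is.finite(v) || v <= 1e-8) {
    return(list(statistic = obs, p_value = 1, z = NA_real_,
                method = "normal"))
  }
  z <- (obs - mu) / sqrt(v)
  p <- if (alternative == "increasing") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  list(statistic = obs, p_value = p, z = z, method = "normal")
}
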