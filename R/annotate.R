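#' TSS-relative region scheme
#'
#' Windows are expressed half-open in transcript-relative coordinates,
#' offset 0 being the TSS, and are projected strand-aware onto the genome.
#' The proximal window is the union of region 1 (upstream,
#' `[-1500, -500)`) and region 2 (TSS-spanning, `[-500, +500)`).
#'
#' @param upstream bp upstream of the TSS included in the proximal window.
#' @param downstream bp downstream of the TSS included in the proximal
#'   window.
#' @param boundary offset splitting region 1 from region 2.
#' @param downstream_limit bp past the gene end counted as "Downstream".
#' @return list of class `region_scheme` with half-open relative windows.
#' @export
region_scheme <- function(upstream = 1500L, downstream = 500L,
                          boundary = -500L, downstream_limit = 3000L) {
  stopifnot(upstream > 0, downstream > 0,
            -upstream < boundary, boundary < downstream)
  structure(list(proximal = c(-upstream, downstream),
                 region1 = c(-upstream, boundary),
                 region2 = c(boundary, downstream),
                 downstream_limit = as.integer(downstream_limit)),
            class = "region_scheme")
}

# Project a half-open relative window [a, b) onto the genome for each gene
# (1-based closed GRanges), strand-aware.
.project_window <- function(genes, rel) {
  a <- rel[1]; b <- rel[2]
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + a, genes$tss - b + 1)
  end <- ifelse(plus, genes$tss + b - 1, genes$tss - a)
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start, end),
                         strand = genes$strand, gene_id = genes$gene_id)
}

#' Strand-aware proximal windows of all genes
#' @param genes gene table.
#' @param scheme a [region_scheme()].
#' @return `GRanges` parallel to `genes` with a `gene_id` column.
#' @export
proximal_windows <- function(genes, scheme = region_scheme()) {
  .project_window(genes, scheme$proximal)
}

#' Strand-aware region-1 or region-2 windows of all genes
#' @inheritParams proximal_windows
#' @param region `"region1"` or `"region2"`.
#' @export
region_windows <- function(genes, region = c("region1", "region2"),
                           scheme = region_scheme()) {
  region <- match.arg(region)
  .project_window(genes, scheme[[region]])
}

# Transcript-relative closed interval of peaks w.r.t. a gene's TSS.
.relative_span <- function(peaks, tss, strand) {
  s <- GenomicRanges::start(peaks); e <- GenomicRanges::end(peaks)
  rs <- ifelse(strand == "+", s - tss, tss - e)
  re <- ifelse(strand == "+", e - tss, tss - s)
  cbind(rs, re)
}

#' Assign a genomic feature category to each peak
#'
#' The peak is anchored at its midpoint and classified by the first
#' category, in priority order Proximal Region > 5'UTR > 3'UTR > Exon >
#' Intron > Downstream > Distal Intergenic, whose (strand-aware) window
#' contains the anchor.  Ties between genes within a category are broken by
#' TSS proximity.  UTR windows require `utr5_len`/`utr3_len` columns in the
#' gene table; Exon requires an `exons` GRanges — absent annotations simply
#' leave those categories empty.
#'
#' @param peaks `GRanges`.
#' @param genes gene table.
#' @param scheme a [region_scheme()].
#' @param exons optional `GRanges` of exons with a `gene_id` column.
#' @return data.frame with `category` (factor over all levels), `gene_id`,
#'   `tss_dist` (anchor minus TSS, strand-projected; NA for intergenic).
#' @export
assign_feature <- function(peaks, genes, scheme = region_scheme(),
                           exons = NULL) {
  n <- length(peaks)
  out <- data.frame(category = factor(rep("Distal Intergenic", n),
                                      levels = FEATURE_LEVELS),
                    gene_id = rep(NA_character_, n),
                    tss_dist = rep(NA_real_, n))
  if (n == 0L || nrow(genes) == 0L) return(out)
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  anchors <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                    IRanges::IRanges(mid, mid))
  glen <- abs(genes$gene_end - genes$tss) + 1L

  windows <- list(
    "Proximal Region" = proximal_windows(genes, scheme),
    "5'UTR" = if (!is.null(genes$utr5_len) && any(genes$utr5_len > 0)) {
      g <- genes[genes$utr5_len > 0, , drop = FALSE]
      gr <- .project_window(g, c(0L, 1L))  # placeholder, fixed below
      GenomicRanges::resize(gr, g$utr5_len, fix = "start")
    },
    "3'UTR" = if (!is.null(genes$utr3_len) && any(genes$utr3_len > 0)) {
      g <- genes[genes$utr3_len > 0, , drop = FALSE]
      gl <- abs(g$gene_end - g$tss) + 1L
      # relative [gene_len - utr3_len, gene_len)
      starts <- ifelse(g$strand == "+", g$tss + gl - g$utr3_len,
                       g$tss - gl + 1)
      ends <- ifelse(g$strand == "+", g$tss + gl - 1,
                     g$tss - gl + g$utr3_len)
      GenomicRanges::GRanges(g$chrom, IRanges::IRanges(starts, ends),
                             strand = g$strand, gene_id = g$gene_id)
    },
    "Exon" = exons,
    "Intron" = {
      starts <- pmin(genes$tss, genes$gene_end)
      ends <- pmax(genes$tss, genes$gene_end)
      GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(starts, ends),
                             strand = genes$strand, gene_id = genes$gene_id)
    },
    "Downstream" = {
      plus <- genes$strand == "+"
      starts <- ifelse(plus, genes$gene_end + 1,
                       genes$gene_end - scheme$downstream_limit)
      ends <- ifelse(plus, genes$gene_end + scheme$downstream_limit,
                     genes$gene_end - 1)
      GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(starts, ends),
                             strand = genes$strand, gene_id = genes$gene_id)
    }
  )
  tss_by_id <- setNames(genes$tss, genes$gene_id)
  strand_by_id <- setNames(genes$strand, genes$gene_id)
  unassigned <- rep(TRUE, n)
  for (cat in names(windows)) {
    w <- windows[[cat]]
    if (is.null(w) || length(w) == 0L) next
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(anchors, w, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- unassigned[qh]
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh) == 0L) next
    gid <- w$gene_id[sh]
    dist <- abs(mid[qh] - tss_by_id[gid])
    ord <- order(qh, dist, gid)
    qh <- qh[ord]; gid <- gid[ord]
    first <- !duplicated(qh)
    sel <- qh[first]
    out$category[sel] <- cat
    out$gene_id[sel] <- gid[first]
    unassigned[sel] <- FALSE
  }
  has_gene <- !is.na(out$gene_id)
  if (any(has_gene)) {
    g <- out$gene_id[has_gene]
    sgn <- ifelse(strand_by_id[g] == "+", 1, -1)
    out$tss_dist[has_gene] <- sgn * (mid[has_gene] - tss_by_id[g])
  }
  out
}

#' Feature category distribution of a peak set
#'
#' @inheritParams assign_feature
#' @return data.frame with `category`, `count`, `percent` (summing to 100;
#'   all zero for an empty peak set).
#' @export
feature_distribution <- function(peaks, genes, scheme = region_scheme(),
                                 exons = NULL) {
  af <- assign_feature(peaks, genes, scheme, exons)
  counts <- table(af$category)
  total <- sum(counts)
  data.frame(category = factor(names(counts), levels = FEATURE_LEVELS),
             count = as.integer(counts),
             percent = if (total > 0) 100 * as.integer(counts) / total
                       else rep(0, length(counts)))
}

#' Sample lists of random fixed-length regions
#'
#' Regions are placed uniformly over chromosome coordinates with full
#' containment in the chromosome.  With `proximal_only` each region is
#' placed fully inside the proximal window of a uniformly chosen gene
#' (the 500-random-proximal-peak control of the enrichment analysis).
#'
#' @param n_lists number of independent lists.
#' @param list_size regions per list.
#' @param peak_length fixed region length (bp).
#' @param genome named `DNAStringSet` or named numeric vector of chromosome
#'   lengths.
#' @param genes gene table; required when `proximal_only`.
#' @param proximal_only constrain regions to proximal windows.
#' @param scheme a [region_scheme()].
#' @param seed integer seed.
#' @return list of `GRanges` of length `n_lists`.
#' @export
sample_random_regions <- function(n_lists = 1000L, list_size = 5000L,
                                  peak_length = 775L, genome = NULL,
                                  genes = NULL, proximal_only = FALSE,
                                  scheme = region_scheme(), seed = 1L) {
  stopifnot(n_lists >= 1, list_size >= 1, peak_length >= 1)
  if (proximal_only && (is.null(genes) || nrow(genes) == 0)) {
    stop("proximal_only sampling requires a gene table")
  }
  lens <- if (is.numeric(genome)) genome else {
    setNames(Biostrings::width(genome), names(genome))
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_lists), function(i) {
      if (proximal_only) {
        prom <- proximal_windows(genes, scheme)
        slack <- GenomicRanges::width(prom) - peak_length
        if (all(slack < 0)) stop("peak_length exceeds the proximal window")
        ok <- which(slack >= 0)
        gi <- ok[sample.int(length(ok), list_size, replace = TRUE)]
        off <- vapply(gi, function(g) sample.int(slack[g] + 1L, 1L) - 1L,
                      integer(1))
        GenomicRanges::GRanges(
          as.character(GenomicRanges::seqnames(prom))[gi],
          IRanges::IRanges(GenomicRanges::start(prom)[gi] + off,
                           width = peak_length))
      } else {
        usable <- lens - peak_length + 1
        if (all(usable < 1)) stop("peak_length exceeds every chromosome")
        keep <- usable >= 1
        chroms <- names(lens)[keep]
        ci <- sample.int(length(chroms), list_size, replace = TRUE,
                         prob = usable[keep])
        start <- vapply(ci, function(k) sample.int(usable[keep][k], 1L),
                        integer(1))
        GenomicRanges::GRanges(chroms[ci],
                               IRanges::IRanges(start, width = peak_length))
      }
    })
  })
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction; upper-tail p on 1 degree of freedom.
#'
#' @param a,b first row (e.g. observed proximal / non-proximal counts).
#' @param c,d second row (e.g. expected counts from random regions).
#' @return list with `statistic`, `p_value`, `table`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square test undefined: a table margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Empirical p-value against random-region lists
#'
#' Two variants.  `"standard"` is the add-one permutation p-value
#' `(1 + #(list fraction >= observed)) / (n_lists + 1)` (enrichment;
#' `<=` for depletion).  `"per_list_chisq"` follows the published rule:
#' each random list is chi-square-tested against the observed table, the
#' p-values are multiple-testing corrected, and the empirical p is one over
#' the number of significantly different lists (1 when none is).
#'
#' @param observed_fraction observed feature fraction of the peak list.
#' @param random_fractions per-list feature fractions.
#' @param variant `"standard"` or `"per_list_chisq"`.
#' @param alternative `"greater"` (enrichment) or `"less"`.
#' @param n_observed,list_size counts behind the fractions, required for
#'   `per_list_chisq`.
#' @param alpha per-list significance threshold after adjustment.
#' @param adjust multiple-testing method (see [stats::p.adjust()]).
#' @return Numeric p-value.
#' @export
empirical_pvalue <- function(observed_fraction, random_fractions,
                             variant = c("standard", "per_list_chisq"),
                             alternative = c("greater", "less"),
                             n_observed = NULL, list_size = NULL,
                             alpha = 0.05, adjust = "BH") {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  N <- length(random_fractions)
  stopifnot(N >= 1)
  if (variant == "standard") {
    extreme <- if (alternative == "greater") {
      sum(random_fractions >= observed_fraction)
    } else {
      sum(random_fractions <= observed_fraction)
    }
    return((1 + extreme) / (N + 1))
  }
  if (is.null(n_observed) || is.null(list_size)) {
    stop("per_list_chisq needs n_observed and list_size")
  }
  a <- round(observed_fraction * n_observed)
  ps <- vapply(random_fractions, function(f) {
    cc <- round(f * list_size)
    tab <- matrix(c(a, n_observed - a, cc, list_size - cc), 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  k <- sum(stats::p.adjust(ps, method = adjust) < alpha)
  if (k == 0) 1 else 1 / k
}

#' TSS-relative binned peak profile
#'
#' Each peak contributes a count to every bin its transcript-relative span
#' overlaps, relative to the TSS of its nearest gene; the bin axis runs
#' 5'->3' of the gene.
#'
#' @param peaks `GRanges`.
#' @param genes gene table.
#' @param window half-width of the profiled window (bp).
#' @param binsize bin width; must divide `2 * window`.
#' @return data.frame with `bin_start`, `bin_end` (relative, half-open) and
#'   `count`.
#' @export
tss_profile <- function(peaks, genes, window = 3000L, binsize = 100L) {
  if ((2 * window) %% binsize != 0) stop("binsize must divide 2*window")
  edges <- seq(-window, window, by = binsize)
  counts <- integer(length(edges) - 1L)
  if (length(peaks) > 0 && nrow(genes) > 0) {
    mid <- floor((GenomicRanges::start(peaks) +
                  GenomicRanges::end(peaks)) / 2)
    for (i in seq_along(peaks)) {
      chrom <- as.character(GenomicRanges::seqnames(peaks))[i]
      cand <- which(genes$chrom == chrom)
      if (length(cand) == 0L) next
      g <- cand[which.min(abs(genes$tss[cand] - mid[i]))]
      rel <- .relative_span(peaks[i], genes$tss[g], genes$strand[g])
      lo <- rel[1]; hi <- rel[2]   # closed relative span
      hit <- which(edges[-length(edges)] <= hi & edges[-1] - 1 >= lo)
      counts[hit] <- counts[hit] + 1L
    }
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             count = counts)
}

#' Intersect proximal peaks with region-1 or region-2 windows
#'
#' Produces "cutpeaks": the non-empty genomic intersections between
#' proximal peaks and the strand-projected region window of their assigned
#' gene.  Peaks with an empty intersection are dropped.
#'
#' @param peaks `GRanges`.
#' @param genes gene table.
#' @param region `"region1"` or `"region2"`.
#' @param scheme a [region_scheme()].
#' @param assignment optional precomputed [assign_feature()] result for
#'   `peaks`.
#' @return `GRanges` with metadata `parent` (index into `peaks`),
#'   `gene_id`, `region`.
#' @export
cut_peaks <- function(peaks, genes, region = c("region1", "region2"),
                      scheme = region_scheme(), assignment = NULL) {
  region <- match.arg(region)
  if (is.null(assignment)) assignment <- assign_feature(peaks, genes, scheme)
  sel <- which(assignment$category == "Proximal Region")
  if (length(sel) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$parent <- integer(0); gr$gene_id <- character(0)
    gr$region <- character(0)
    return(gr)
  }
  gid <- assignment$gene_id[sel]
  g <- genes[match(gid, genes$gene_id), , drop = FALSE]
  win <- region_windows(g, region, scheme)
  ps <- GenomicRanges::start(peaks)[sel]; pe <- GenomicRanges::end(peaks)[sel]
  ws <- GenomicRanges::start(win); we <- GenomicRanges::end(win)
  is <- pmax(ps, ws); ie <- pmin(pe, we)
  keep <- is <= ie
  gr <- GenomicRanges::GRanges(g$chrom[keep],
                               IRanges::IRanges(is[keep], ie[keep]))
  gr$parent <- sel[keep]
  gr$gene_id <- gid[keep]
  gr$region <- rep(region, sum(keep))
  gr$name <- sprintf("%s_%s", region, gr$parent)
  gr
}

#' Classify how proximal peaks overlap region 2
#'
#' With F the strand-projected region-2 window of the peak's gene:
#' a peak covering F entirely while starting upstream of it (in region 1)
#' is `includeFeature`; starting upstream and ending inside F is
#' `overlapStart`; contained in F is `inside`; starting inside F and
#' extending past its end is `overlapEnd`.  Proximal peaks that never touch
#' F are reported as `region1_only`.  Percentages are computed over all
#' proximal peaks.
#'
#' @inheritParams cut_peaks
#' @return list with `classes` (per-proximal-peak data.frame) and
#'   `distribution` (percent per class).
#' @export
classify_overlap <- function(peaks, genes, scheme = region_scheme(),
                             assignment = NULL) {
  if (is.null(assignment)) assignment <- assign_feature(peaks, genes, scheme)
  sel <- which(assignment$category == "Proximal Region")
  lv <- c("includeFeature", "overlapStart", "inside", "overlapEnd",
          "region1_only")
  if (length(sel) == 0L) {
    return(list(classes = data.frame(peak = integer(0), gene_id = character(0),
                                     class = factor(character(0), lv)),
                distribution = data.frame(class = factor(lv, lv),
                                          count = 0L, percent = 0)))
  }
  gid <- assignment$gene_id[sel]
  g <- genes[match(gid, genes$gene_id), , drop = FALSE]
  rel <- .relative_span(peaks[sel], g$tss, g$strand)
  f_lo <- scheme$region2[1]; f_hi <- scheme$region2[2] - 1L  # closed
  rs <- rel[, 1]; re <- rel[, 2]
  cls <- ifelse(re < f_lo, "region1_only",
         ifelse(rs < f_lo & re >= f_hi, "includeFeature",
         ifelse(rs < f_lo, "overlapStart",
         ifelse(re <= f_hi, "inside", "overlapEnd"))))
  cls <- factor(cls, levels = lv)
  counts <- table(cls)
  list(classes = data.frame(peak = sel, gene_id = gid, class = cls),
       distribution = data.frame(class = factor(names(counts), lv),
                                 count = as.integer(counts),
                                 percent = 100 * as.integer(counts) /
                                   length(sel)))
}
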