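#' Parameters for Hoogsteen triplex search
#'
#' @param min_length minimum hit length (nt); the underlying study screens
#'   triplexes of 15-20 bp, so 15 and 20 are the two settings of interest.
#' @param max_length maximum hit length (nt).  A finite cap keeps reported
#'   windows in the biophysically plausible 15-25 nt range and bounds the
#'   purine-content prefilter of the scanner.
#' @param max_error_rate maximum fraction of mismatching triplets in the
#'   aligned window (mismatch-only error model, no indels).
#' @param min_guanine_rate minimum guanine fraction of the triplex target
#'   site (the purine strand window of the duplex), Triplexator-style.
#'   Set to 0 to disable.
#' @param motifs subset of
#'   `c("pyrimidine_parallel","purine_antiparallel","GT_parallel","GT_antiparallel")`.
#' @param merge_gap maximum gap (nt) between RNA-side hit intervals merged
#'   into one DNA-binding domain (DBD).
#' @param ss_prob_threshold accessibility masking threshold: RNA bases with
#'   single-strandedness probability below this are masked.
#' @return A list of class `triplex_params`.
#' @export
triplex_params <- function(min_length = 15L, max_length = 25L,
                           max_error_rate = 0.20, min_guanine_rate = 0.10,
                           motifs = TRIPLEX_MOTIFS, merge_gap = 10L,
                           ss_prob_threshold = 0.10) {
  stopifnot(min_length >= 10, max_length >= min_length,
            max_error_rate >= 0, max_error_rate <= 1,
            min_guanine_rate >= 0, min_guanine_rate <= 1,
            merge_gap >= 0)
  motifs <- match.arg(motifs, TRIPLEX_MOTIFS, several.ok = TRUE)
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 max_error_rate = max_error_rate,
                 min_guanine_rate = min_guanine_rate,
                 motifs = motifs,
                 merge_gap = as.integer(merge_gap),
                 ss_prob_threshold = ss_prob_threshold),
            class = "triplex_params")
}

# Nucleotide character -> integer code (A0 C1 G2 T/U3, anything else 4).
.encode_seq <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T", "U")) - 1L
  code[code == 4L] <- 3L
  code[is.na(code)] <- 4L
  code
}

.decode_rna <- function(code) {
  paste(c("A", "C", "G", "U", "N")[code + 1L], collapse = "")
}

#' Mask RNA bases folded into secondary structure
#'
#' Bases whose probability of being single-stranded falls below `threshold`
#' are replaced by `N` and can never take part in a triplex hit.
#'
#' @param rna RNA sequence (character scalar, `ACGU`/`ACGT` alphabet).
#' @param profile numeric vector of per-base single-strandedness
#'   probabilities, same length as `rna`.
#' @param threshold masking threshold (probability).
#' @return The masked sequence (character scalar, `T` normalised to `U`).
#' @export
mask_rna <- function(rna, profile, threshold = 0.10) {
  chars <- strsplit(toupper(chartr("T", "U", rna)), "", fixed = TRUE)[[1]]
  if (length(chars) != length(profile)) {
    stop("profile length (", length(profile),
         ") does not match RNA length (", length(chars), ")")
  }
  chars[profile < threshold] <- "N"
  paste(chars, collapse = "")
}

#' Find triplex target sites (purine tracts) in duplex DNA
#'
#' Reports containment-maximal tracts, on both strands, of length at least
#' `min_length` whose purine fraction on the reported strand is at least
#' `1 - max_error_rate`.  Tracts begin and end on a purine.
#'
#' @param dna_seq DNA sequence (character scalar, `ACGT`).
#' @param params a [triplex_params()] object.
#' @return data.frame with columns `start`, `end` (1-based on the forward
#'   sequence), `strand` (strand carrying the purine tract), `length`,
#'   `purity`, `purine_seq` (5'->3' purine-strand sequence).
#' @export
find_tts <- function(dna_seq, params = triplex_params()) {
  code <- .encode_seq(dna_seq)
  m <- length(code)
  res <- list()
  for (strand in c("+", "-")) {
    d <- if (strand == "+") code else rev(3L - ifelse(code <= 3L, code, -1L))
    pur <- d == 0L | d == 2L
    tr <- .maximal_rate_tracts(pur, params$min_length, params$max_error_rate)
    if (nrow(tr) > 0) {
      # map back to forward coordinates
      if (strand == "-") {
        s <- m - tr$end + 1L
        e <- m - tr$start + 1L
        tr$start <- s
        tr$end <- e
      }
      tr$strand <- strand
      res[[strand]] <- tr
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length = integer(0),
                      purity = numeric(0), purine_seq = character(0)))
  }
  out$length <- out$end - out$start + 1L
  fwd <- strsplit(toupper(dna_seq), "", fixed = TRUE)[[1]]
  out$purine_seq <- vapply(seq_len(nrow(out)), function(i) {
    s <- fwd[out$start[i]:out$end[i]]
    if (out$strand[i] == "-") {
      s <- rev(chartr("ACGT", "TGCA", s))
    }
    paste(s, collapse = "")
  }, character(1))
  rownames(out) <- NULL
  out[order(out$start, out$end, out$strand),
      c("start", "end", "strand", "length", "purity", "purine_seq")]
}

# Containment-maximal runs with hit fraction >= 1 - rate, edges TRUE,
# length >= min_len.  `ok` is a logical vector.
.maximal_rate_tracts <- function(ok, min_len, rate) {
  n <- length(ok)
  bad_pref <- c(0L, cumsum(!ok))
  starts <- integer(0); ends <- integer(0); purity <- numeric(0)
  best_e <- 0L
  for (s in which(ok)) {
    if (s + min_len - 1L > n) break
    emax <- -1L
    for (e in n:(s + min_len - 1L)) {
      if (!ok[e]) next
      bad <- bad_pref[e + 1L] - bad_pref[s]
      if (bad <= rate * (e - s + 1L) + 1e-9) { emax <- e; break }
    }
    if (emax < 0L || emax <= best_e) next
    best_e <- emax
    starts <- c(starts, s); ends <- c(ends, emax)
    purity <- c(purity,
                1 - (bad_pref[emax + 1L] - bad_pref[s]) / (emax - s + 1L))
  }
  data.frame(start = starts, end = ends, purity = purity)
}

#' Count mismatches of an aligned RNA/purine-strand window under a motif
#'
#' Per-position Hoogsteen triplet rules: `pyrimidine_parallel` matches U.A
#' and C.G; `purine_antiparallel` matches A.A and G.G; the GT motifs match
#' G.G and U.A.  For antiparallel motifs the RNA (given 5'->3') is compared
#' 3'->5' against the purine strand.  Masked bases (`N`) always mismatch.
#'
#' @param rna_window RNA window, 5'->3' (character scalar).
#' @param tts_purine_seq purine-strand window, 5'->3', same length.
#' @param motif one of [TRIPLEX_MOTIFS].
#' @return Integer mismatch count.
#' @export
score_window <- function(rna_window, tts_purine_seq,
                         motif = TRIPLEX_MOTIFS) {
  motif <- match.arg(motif)
  r <- .encode_seq(chartr("T", "U", rna_window))
  d <- .encode_seq(tts_purine_seq)
  if (length(r) != length(d)) stop("windows must have equal length")
  if (motif %in% c("purine_antiparallel", "GT_antiparallel")) r <- rev(r)
  pairs <- .motif_pairs(motif)
  match <- vapply(seq_along(r), function(i) {
    any(pairs[, 1] == r[i] & pairs[, 2] == d[i])
  }, logical(1))
  sum(!match)
}

# motif -> matrix of matching (rna_code, purine_code) pairs
.motif_pairs <- function(motif) {
  switch(motif,
    pyrimidine_parallel = rbind(c(3L, 0L), c(1L, 2L)),
    purine_antiparallel = rbind(c(0L, 0L), c(2L, 2L)),
    GT_parallel = ,
    GT_antiparallel = rbind(c(2L, 2L), c(3L, 0L))
  )
}

#' Find triplex hits between an RNA and DNA sequences
#'
#' Core Hoogsteen scanner.  For every motif, both duplex strands and every
#' alignment register, reports the containment-maximal windows that begin
#' and end with a matching triplet, have length within
#' `[min_length, max_length]`, mismatch rate at most `max_error_rate`, and
#' triplex-target-site guanine rate at least `min_guanine_rate`.
#'
#' @param rna RNA sequence (character scalar; may contain `N` masks, see
#'   [mask_rna()]).
#' @param dna_seqs character vector of DNA sequences (one per region).
#' @param params a [triplex_params()] object.
#' @return data.frame with one row per hit: `region` (index into
#'   `dna_seqs`), `strand` (purine strand of the target), `motif`,
#'   `rna_start`, `rna_end` (1-based transcript coordinates of the TFO),
#'   `dna_start`, `dna_end` (1-based forward coordinates within the
#'   region of the DBS), `length`, `mismatches`, `guanine_rate`.
#' @export
find_triplex_hits_seq <- function(rna, dna_seqs, params = triplex_params()) {
  rna_code <- .encode_seq(chartr("T", "U", rna))
  if (length(rna_code) < params$min_length) {
    warning("RNA shorter than min_length; no hits possible")
    return(.empty_hits())
  }
  dna_codes <- lapply(dna_seqs, .encode_seq)
  motif_codes <- match(params$motifs, TRIPLEX_MOTIFS) - 1L
  df <- .triplex_scan_cpp(rna_code, dna_codes, params$min_length,
                          params$max_length, params$max_error_rate,
                          params$min_guanine_rate, motif_codes)
  df <- as.data.frame(df)
  df$motif <- TRIPLEX_MOTIFS[df$motif_code + 1L]
  df$guanine_rate <- df$guanines / df$length
  df$motif_code <- NULL
  df$guanines <- NULL
  df <- df[order(df$region, df$dna_start, df$dna_end, df$strand, df$motif),
           , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_hits <- function() {
  data.frame(region = integer(0), strand = character(0),
             rna_start = integer(0), rna_end = integer(0),
             dna_start = integer(0), dna_end = integer(0),
             length = integer(0), mismatches = integer(0),
             motif = character(0), guanine_rate = numeric(0))
}

#' Find triplex hits in genomic regions
#'
#' Extracts each region's sequence from the genome and runs
#' [find_triplex_hits_seq()]; DNA-side coordinates are reported in genomic
#' space.
#'
#' @param rna RNA sequence (character scalar, possibly masked).
#' @param regions `GRanges` of target regions.
#' @param genome named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param params a [triplex_params()] object.
#' @return As [find_triplex_hits_seq()], with additional columns `chrom`,
#'   and `dna_start`/`dna_end` in 1-based genomic coordinates; `region`
#'   indexes into `regions`.
#' @export
find_triplex_hits <- function(rna, regions, genome,
                              params = triplex_params()) {
  seqs <- .region_seqs(regions, genome)
  df <- find_triplex_hits_seq(rna, seqs, params)
  if (nrow(df) > 0) {
    off <- GenomicRanges::start(regions)[df$region] - 1L
    df$chrom <- as.character(GenomicRanges::seqnames(regions))[df$region]
    df$dna_start <- df$dna_start + off
    df$dna_end <- df$dna_end + off
  } else {
    df$chrom <- character(0)
  }
  df
}

# Extract forward-strand sequences of regions from a DNAStringSet/character.
.region_seqs <- function(regions, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chroms <- as.character(GenomicRanges::seqnames(regions))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing) > 0) {
    stop("regions reference chromosomes absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(GenomicRanges::end(regions) > lens[chroms] |
          GenomicRanges::start(regions) < 1)) {
    stop("region exceeds chromosome bounds")
  }
  out <- character(length(regions))
  for (cn in unique(chroms)) {
    i <- which(chroms == cn)
    v <- Biostrings::Views(genome[[cn]],
                           start = GenomicRanges::start(regions)[i],
                           end = GenomicRanges::end(regions)[i])
    out[i] <- as.character(v)
  }
  out
}

#' Merge RNA-side hit intervals into DNA-binding domains (DBDs)
#'
#' TFO intervals separated by at most `merge_gap` nt are merged; each DBD
#' records how many distinct target regions support it.
#'
#' @param hits hit table from [find_triplex_hits()].
#' @param merge_gap maximum gap (nt) bridged when merging.
#' @return data.frame with `dbd_id`, `rna_start`, `rna_end`, `width`,
#'   `n_hits`, `n_regions`, sorted by decreasing region support.
#' @export
merge_dbds <- function(hits, merge_gap = 10L) {
  if (nrow(hits) == 0) {
    return(data.frame(dbd_id = character(0), rna_start = integer(0),
                      rna_end = integer(0), width = integer(0),
                      n_hits = integer(0), n_regions = integer(0)))
  }
  ir <- IRanges::IRanges(hits$rna_start, hits$rna_end)
  merged <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
  ov <- IRanges::findOverlaps(ir, merged)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  df <- data.frame(
    rna_start = IRanges::start(merged),
    rna_end = IRanges::end(merged),
    width = IRanges::width(merged),
    n_hits = as.integer(table(factor(grp, seq_along(merged)))),
    n_regions = vapply(seq_along(merged), function(i) {
      length(unique(hits$region[grp == i]))
    }, integer(1))
  )
  df <- df[order(-df$n_regions, df$rna_start), , drop = FALSE]
  df$dbd_id <- sprintf("DBD_%d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("dbd_id", "rna_start", "rna_end", "width", "n_hits", "n_regions")]
}

#' Genomic region test for triplex enrichment
#'
#' Counts how many target regions carry at least one DNA binding site (DBS)
#' overall and per DBD, and compares against a null distribution built by
#' repeatedly sampling length-matched random regions from the genome (or
#' from a supplied background pool).  The empirical p-value is
#' `(1 + #(null >= observed)) / (n_randomizations + 1)`.
#'
#' @param rna RNA sequence (possibly masked).
#' @param target_regions `GRanges` of tested regions.
#' @param genome named `DNAStringSet`.
#' @param params a [triplex_params()] object.
#' @param n_randomizations number of null samples (>= 19).
#' @param seed integer seed for the null sampling.
#' @param background optional `GRanges` pool; each randomization samples
#'   `length(target_regions)` of its elements without replacement.
#' @return list with elements `summary` (data.frame: one row per DBD plus
#'   an `any` row, with `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_value`), `dbds`, `hits`, `n_randomizations`.
#' @export
region_test <- function(rna, target_regions, genome,
                        params = triplex_params(),
                        n_randomizations = 100L, seed = 1L,
                        background = NULL) {
  stopifnot(n_randomizations >= 19)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  nT <- length(target_regions)
  hits <- find_triplex_hits(rna, target_regions, genome, params)
  dbds <- merge_dbds(hits, params$merge_gap)
  count_regions <- function(h) {
    counts <- c(any = length(unique(h$region)))
    if (nrow(dbds) > 0) {
      per_dbd <- vapply(seq_len(nrow(dbds)), function(i) {
        sel <- h$rna_start <= dbds$rna_end[i] & h$rna_end >= dbds$rna_start[i]
        length(unique(h$region[sel]))
      }, numeric(1))
      counts <- c(counts, setNames(per_dbd, dbds$dbd_id))
    }
    counts
  }
  observed <- count_regions(hits)
  null_counts <- matrix(0, nrow = n_randomizations, ncol = length(observed),
                        dimnames = list(NULL, names(observed)))
  widths <- GenomicRanges::width(target_regions)
  # all randomizations drawn and scanned in one batch
  withr::with_seed(seed, {
    rand_all <- if (is.null(background)) {
      .sample_length_matched(rep(widths, n_randomizations), genome)
    } else {
      idx <- vapply(seq_len(n_randomizations), function(b) {
        sample.int(length(background), nT,
                   replace = length(background) < nT)
      }, integer(nT))
      background[as.vector(idx)]
    }
  })
  h_all <- find_triplex_hits(rna, rand_all, genome, params)
  block <- ceiling(h_all$region / nT)
  for (b in unique(block)) {
    h <- h_all[block == b, , drop = FALSE]
    null_counts[b, ] <- count_regions(h)
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2, stats::sd)
  p <- vapply(seq_along(observed), function(i) {
    (1 + sum(null_counts[, i] >= observed[i])) / (n_randomizations + 1)
  }, numeric(1))
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  list(summary = data.frame(set = names(observed),
                            observed = as.numeric(observed),
                            n_targets = nT,
                            null_mean = null_mean, null_sd = null_sd,
                            z = z, p_value = p, row.names = NULL),
       dbds = dbds, hits = hits, n_randomizations = n_randomizations)
}

# Sample one region of each requested width uniformly over the genome.
.sample_length_matched <- function(widths, genome) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  chrom_p <- lens / sum(lens)
  chroms <- names(lens)[sample.int(length(lens), length(widths),
                                   replace = TRUE, prob = chrom_p)]
  start <- vapply(seq_along(widths), function(i) {
    hi <- lens[[chroms[i]]] - widths[i] + 1L
    if (hi < 1L) stop("region longer than chromosome")
    sample.int(hi, 1L)
  }, integer(1))
  GenomicRanges::GRanges(chroms,
                         IRanges::IRanges(start, width = widths))
}

#' Promoter test for triplex enrichment in a gene list
#'
#' Compares the fraction of genes with at least one DBS in their promoter
#' (strand-aware window around the TSS) between a target gene list and all
#' remaining genes, with a Pearson chi-square p-value.
#'
#' @param rna RNA sequence (possibly masked).
#' @param gene_list character vector of target gene ids (non-empty, subset
#'   of `genes$gene_id`).
#' @param genes gene table (see [read_gene_table()]).
#' @param genome named `DNAStringSet`.
#' @param params a [triplex_params()] object.
#' @param scheme a [region_scheme()]; its proximal window defines the
#'   promoter.
#' @return list with `table` (2x2 counts), `percent_target`,
#'   `percent_nontarget`, `p_value`, `gene_hits` (per-gene logical).
#' @export
promoter_test <- function(rna, gene_list, genes, genome,
                          params = triplex_params(),
                          scheme = region_scheme()) {
  if (length(gene_list) == 0) stop("gene_list is empty")
  if (!all(gene_list %in% genes$gene_id)) {
    stop("gene_list contains ids absent from the gene table")
  }
  prom <- proximal_windows(genes, scheme)
  hits <- find_triplex_hits(rna, prom, genome, params)
  has_dbs <- seq_along(prom) %in% hits$region
  is_target <- genes$gene_id %in% gene_list
  a <- sum(has_dbs & is_target); b <- sum(!has_dbs & is_target)
  cc <- sum(has_dbs & !is_target); d <- sum(!has_dbs & !is_target)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("target", "non_target"),
                                c("with_dbs", "without_dbs")))
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    chisq_2x2(a, b, cc, d)$p_value
  } else NA_real_
  list(table = tab,
       percent_target = 100 * a / max(1, a + b),
       percent_nontarget = 100 * cc / max(1, cc + d),
       p_value = p,
       gene_hits = setNames(has_dbs, genes$gene_id))
}
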