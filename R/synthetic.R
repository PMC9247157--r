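# Fixed 300-bp synthetic Alu-like consensus.  Deliberately NOT a RepBase
# sequence: the co-occurrence statistics only need a recognisable, reusable
# element.  Constructed so every 15-bp window holds between 5 and 10
# purines on either strand, hence insertions can never create a triplex
# target site (which needs >= 12/15 purines on one strand).
ALU_CONSENSUS <- paste0(
  "CTGACAGTCGTTAGGATAATCATGTGTCACTCGCAATCTTATATAGCTGCAGTAGCCCAT",
  "CACCATATAAGTCATAGGATAGCGACGCTTCTGGTGCGCGGAGACACAATGTATACTAAC",
  "GAGCGATTTTATGGCGCCGTGCCGGGTAAGAGCCGTTGTGCGCTCAATTCAGGTAGCTGT",
  "CCAACGGTACCAATTAAACTGGTACGGGCGACTGAATCCATAATATGCACGCGCAGTCTG",
  "TTGGTGCCAATGAAACGACACCAATGTTAGGCGTGTAGGGCCACGGGCCGAGTGATCAAT")

#' Configuration for the synthetic fixture generator
#'
#' The defaults mirror the study conditions: three replicate ChIRP peak
#' sets averaging 775-bp peaks with a 10.23% proximal share over an 8%
#' proximal background, a 2,000-nt lncRNA carrying pyrimidine
#' triplex-forming domains at transcript positions 119-196 (DBD-A) and
#' 47-70 (DBD-B), purine-tract triplex target sites planted in half of the
#' gene promoters, Alu-like insertions near planted sites, and histone-mark
#' tracks whose presence is enriched (or depleted) at triplex-carrying
#' peaks.
#'
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   byte-identical.
#' @param n_chroms,chrom_length genome geometry.
#' @param n_genes number of genes (promoter density together with the
#'   genome size sets the background proximal rate).
#' @param gene_length_range uniform range of transcription-unit lengths.
#' @param utr5_len,utr3_len UTR annotation lengths (bp) carried by every
#'   gene.
#' @param alu_promoter_fraction probability that a promoter WITHOUT a
#'   planted triplex target site receives an Alu insertion.
#' @param alu_at_target_prob probability that a promoter WITH a planted
#'   site receives an Alu at `alu_distance` bp from it.
#' @param n_intergenic_alus extra Alu insertions outside promoters.
#' @param alu_consensus_length length (<= 300) of the planted element.
#' @param alu_distance edge-to-edge distance (bp) between a planted triplex
#'   target site and its companion Alu.
#' @param lncrna_length lncRNA length (nt).
#' @param planted_dbd_intervals named list of 1-based inclusive RNA
#'   intervals acting as DNA-binding domains; the first is the primary
#'   domain planted in every target promoter.
#' @param tile_lengths per-domain length of each planted target site; a
#'   tile shorter than 20 nt makes that domain disappear when the search
#'   minimum is raised from 15 to 20 nt.
#' @param secondary_dbd_fraction fraction of target promoters additionally
#'   receiving a secondary-domain site.
#' @param tts_errors mismatches planted inside each target site.
#' @param tts_flank pyrimidine buffer (bp) written on both sides of each
#'   planted purine tract so hits cannot creep into flanking sequence.
#' @param tts_target_fraction fraction of genes whose promoter receives a
#'   planted target site.
#' @param n_replicates,peaks_per_replicate replicate structure: every
#'   replicate carries the same `peaks_per_replicate` true peaks (minus
#'   drop-outs, see `share_all_fraction`).
#' @param proximal_fraction share of true peaks whose center is placed in a
#'   proximal window; `NULL` places all peaks uniformly (null mode).
#' @param background_proximal_fraction the intended proximal rate of
#'   uniformly placed regions; realised through gene density, recorded for
#'   reference.
#' @param replicate_jitter per-replicate coordinate jitter (bp).
#' @param share_all_fraction fraction of true peaks present in all
#'   replicates (the remainder appears in a random pair).
#' @param noise_peaks_per_replicate replicate-private noise peaks.
#' @param peak_width_mean,peak_width_sd,min_peak_width peak width model.
#' @param mark_tracks named list of odds of mark presence at
#'   triplex-carrying versus triplex-less true peaks.
#' @param mark_base_prob mark presence probability at triplex-less peaks.
#' @param decoy_interval optional RNA interval planted like a domain but
#'   assigned <0.1 single-strandedness, so masking must remove its hits.
#' @param min_center_sep minimum distance between true/noise peak centers,
#'   keeping consensus components unambiguous.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 5e5,
    n_genes = 40L, gene_length_range = c(3000L, 8000L),
    utr5_len = 200L, utr3_len = 300L,
    alu_promoter_fraction = 0.2, alu_at_target_prob = 0.9,
    n_intergenic_alus = 20L, alu_consensus_length = 300L,
    alu_distance = 150L, lncrna_length = 2000L,
    planted_dbd_intervals = list(DBD_A = c(119L, 196L),
                                 DBD_B = c(47L, 70L)),
    tile_lengths = c(DBD_A = 30L, DBD_B = 18L),
    secondary_dbd_fraction = 0.25, tts_errors = 0L, tts_flank = 7L,
    tts_target_fraction = 0.5,
    n_replicates = 3L, peaks_per_replicate = 390L,
    proximal_fraction = 0.1023, background_proximal_fraction = 0.0802,
    replicate_jitter = 25L, share_all_fraction = 0.8,
    noise_peaks_per_replicate = 50L,
    peak_width_mean = 775, peak_width_sd = 80, min_peak_width = 300L,
    mark_tracks = list(H3K4me1 = 6, H3K36me3 = 6, H3K27me3 = 1 / 6),
    mark_base_prob = 0.3, decoy_interval = NULL, min_center_sep = 1200L) {
  cfg <- as.list(environment())
  fr <- c(alu_promoter_fraction, alu_at_target_prob, tts_target_fraction,
          share_all_fraction, secondary_dbd_fraction, mark_base_prob)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (!is.null(proximal_fraction) &&
      (proximal_fraction < 0 || proximal_fraction > 1)) {
    stop("proximal_fraction must lie in [0,1] (or be NULL)")
  }
  for (nm in names(planted_dbd_intervals)) {
    iv <- planted_dbd_intervals[[nm]]
    if (iv[1] < 1 || iv[2] > lncrna_length || iv[1] >= iv[2]) {
      stop("planted DBD interval ", nm, " outside the lncRNA")
    }
  }
  if (!is.null(decoy_interval) &&
      (decoy_interval[1] < 1 || decoy_interval[2] > lncrna_length)) {
    stop("decoy interval outside the lncRNA")
  }
  n_targets <- round(tts_target_fraction * n_genes)
  if (n_targets > n_genes) {
    stop("infeasible config: more planted target sites than promoters")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Rebalance a DNA character vector so that no 15-base window carries 12 or
# more purines on either strand (i.e. purine counts stay in [4, 11]).
# Since any triplex hit window must be >= 80% purine on one strand and
# therefore contains a >= 12/15-purine sub-window, a genome passed through
# this filter carries no triplex target sites outside the planted ones.
.suppress_purine_windows <- function(chars, win = 15L, hi = 11L) {
  n <- length(chars)
  if (n < win) return(chars)
  lo <- win - hi
  for (iter in 1:50) {
    pur <- as.integer(chars %in% c("A", "G"))
    cs <- cumsum(pur)
    w <- cs[win:n] - c(0L, cs)[1:(n - win + 1L)]
    bad <- which(w > hi | w < lo)
    if (length(bad) == 0L) break
    # flip one base near the center of each offending window, skipping
    # neighbours already handled in this pass
    bad <- bad[c(TRUE, diff(bad) >= win)]
    at <- bad + sample(4:(win - 5L), length(bad), replace = TRUE)
    too_many <- w[bad] > hi
    chars[at] <- ifelse(too_many,
                        sample(c("C", "T"), length(at), replace = TRUE),
                        sample(c("A", "G"), length(at), replace = TRUE))
  }
  chars
}

# Break purine and pyrimidine runs of length >= threshold, only at
# positions outside `protect` (logical vector).
.suppress_runs <- function(chars, threshold = 12L, protect = NULL,
                           alphabet = c("A", "C", "G", "T")) {
  if (is.null(protect)) protect <- rep(FALSE, length(chars))
  purine_sym <- intersect(alphabet, c("A", "G"))
  pyr_sym <- setdiff(alphabet, purine_sym)
  for (iter in 1:25) {
    pur <- chars %in% c("A", "G")
    r <- rle(pur)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$lengths >= threshold)
    changed <- FALSE
    for (i in long) {
      pos <- seq(starts[i] + threshold - 2L, ends[i], by = threshold - 1L)
      pos <- pos[!protect[pos]]
      if (length(pos) == 0L) next
      repl <- if (r$values[i]) pyr_sym else purine_sym
      chars[pos] <- sample(repl, length(pos), replace = TRUE)
      changed <- TRUE
    }
    if (!changed) break
  }
  chars
}

# Purine-strand complement of an RNA window under a Hoogsteen motif:
# the purine base that MATCHES each RNA base, NA when none exists.
.motif_partner <- function(rna_chars, motif) {
  map <- switch(motif,
    pyrimidine_parallel = c(U = "A", C = "G"),
    purine_antiparallel = c(A = "A", G = "G"),
    GT_parallel = ,
    GT_antiparallel = c(G = "G", U = "A"))
  unname(map[rna_chars])
}

#' Plant a triplex target site into a promoter sequence
#'
#' Writes into `promoter_seq` the duplex window that the given RNA window
#' recognises under `motif`, with exactly `errors` mismatches (purine
#' swaps at interior positions, so the tract stays purine-pure).  For
#' antiparallel motifs the purine strand is laid down 3'->5' relative to
#' the RNA.  With `strand = "-"` the reverse complement of the purine
#' strand is written, i.e. the purine tract sits on the minus strand.
#'
#' @param promoter_seq promoter sequence (character scalar, forward
#'   strand).
#' @param dbd_rna_seq RNA window (5'->3', `ACGU`), length >= the intended
#'   triplex length; first and last base must be motif-compatible.
#' @param motif one of [TRIPLEX_MOTIFS].
#' @param errors exact number of mismatching positions to plant.
#' @param insert_at 1-based position of the target site in the promoter;
#'   `NULL` picks a uniform feasible position.  Uses the current RNG state.
#' @param strand which genomic strand carries the purine tract.
#' @param flank number of pyrimidine buffer bases written on each side of
#'   the tract (0 disables; buffers stop hits from extending into flanking
#'   sequence).
#' @return list with `seq` (mutated promoter), `start`, `end` (1-based
#'   tract coordinates in the promoter), `strand`, `purine_seq`, `motif`,
#'   `errors`.
#' @export
plant_tts <- function(promoter_seq, dbd_rna_seq, motif = TRIPLEX_MOTIFS,
                      errors = 0L, insert_at = NULL,
                      strand = c("+", "-"), flank = 0L) {
  motif <- match.arg(motif)
  strand <- match.arg(strand)
  rna <- strsplit(toupper(chartr("T", "U", dbd_rna_seq)), "")[[1]]
  len <- length(rna)
  partner <- .motif_partner(rna, motif)
  if (is.na(partner[1]) || is.na(partner[len])) {
    stop("dbd_rna_seq must start and end with a motif-compatible base")
  }
  forced <- which(is.na(partner))
  if (length(forced) > errors) {
    stop("dbd_rna_seq has ", length(forced),
         " motif-incompatible bases but only ", errors,
         " errors were requested")
  }
  purine <- partner
  if (length(forced) > 0) {
    purine[forced] <- sample(c("A", "G"), length(forced), replace = TRUE)
    # a random purine might accidentally match; force the swap
    bad <- forced[purine[forced] == partner[forced] & !is.na(partner[forced])]
    purine[bad] <- ifelse(purine[bad] == "A", "G", "A")
  }
  extra <- errors - length(forced)
  if (extra > 0) {
    interior <- setdiff(2:(len - 1L), forced)
    if (length(interior) < extra) stop("window too short for ", errors,
                                       " errors")
    at <- if (length(interior) == 1L) interior else
      sample(interior, extra)
    purine[at] <- ifelse(purine[at] == "A", "G", "A")
  }
  # antiparallel motifs: purine strand runs 3'->5' of the RNA
  if (motif %in% c("purine_antiparallel", "GT_antiparallel")) {
    purine <- rev(purine)
  }
  purine_str <- paste(purine, collapse = "")
  prom <- strsplit(toupper(promoter_seq), "")[[1]]
  total <- len + 2L * flank
  if (is.null(insert_at)) {
    hi <- length(prom) - total + 1L
    if (hi < 1L) stop("promoter too short for the target site")
    insert_at <- sample.int(hi, 1L) + flank
  }
  s <- insert_at; e <- insert_at + len - 1L
  if (s - flank < 1L || e + flank > length(prom)) {
    stop("target site does not fit in the promoter")
  }
  frag <- purine
  buf5 <- sample(c("C", "T"), flank, replace = TRUE)
  buf3 <- sample(c("C", "T"), flank, replace = TRUE)
  fwd <- c(buf5, frag, buf3)
  if (strand == "-") {
    fwd <- rev(chartr("ACGT", "TGCA", fwd))
  }
  prom[(s - flank):(e + flank)] <- fwd
  list(seq = paste(prom, collapse = ""), start = s, end = e,
       strand = strand, purine_seq = purine_str, motif = motif,
       errors = as.integer(errors))
}

# Rejection-sample `n` centers uniformly over the genome, at least
# `min_sep` from `existing` centers on the same chromosome and (optionally)
# outside the windows in `avoid`.
.sample_centers <- function(n, chrom_lens, min_sep, existing, avoid = NULL,
                            margin = 500L) {
  if (n == 0L) return(data.frame(chrom = character(0), pos = numeric(0)))
  # per-chromosome position pools, thinned in batches
  taken <- split(existing$pos, factor(existing$chrom,
                                      levels = names(chrom_lens)))
  out_chrom <- character(0); out_pos <- numeric(0)
  rounds <- 0L
  while (length(out_pos) < n) {
    rounds <- rounds + 1L
    if (rounds > 200L) {
      stop("could not place peaks: genome too crowded for min_center_sep")
    }
    todo <- n - length(out_pos)
    batch <- max(2L * todo, 32L)
    ci <- sample.int(length(chrom_lens), batch, replace = TRUE,
                     prob = chrom_lens / sum(chrom_lens))
    pos <- vapply(ci, function(k) {
      sample.int(chrom_lens[[k]] - 2L * margin, 1L) + margin
    }, integer(1))
    chrom <- names(chrom_lens)[ci]
    for (b in seq_len(batch)) {
      if (!is.null(avoid)) {
        hit <- avoid$chrom == chrom[b] & pos[b] >= avoid$start &
          pos[b] <= avoid$end
        if (any(hit)) next
      }
      near <- taken[[chrom[b]]]
      if (length(near) > 0 && min(abs(near - pos[b])) < min_sep) next
      taken[[chrom[b]]] <- c(near, pos[b])
      out_chrom <- c(out_chrom, chrom[b]); out_pos <- c(out_pos, pos[b])
      if (length(out_pos) == n) break
    }
  }
  data.frame(chrom = out_chrom, pos = out_pos)
}

#' Generate replicate narrowPeak sets from a true-peak table
#'
#' Realises each true peak in all replicates (or a random pair, for the
#' non-`in_all` fraction) with independent start/end jitter, then adds
#' replicate-private noise peaks at pre-sampled positions.  Uses the
#' current RNG state; [generate_bundle()] seeds it.
#'
#' @param config a [synthetic_config()].
#' @param true_peaks data.frame with `chrom`, `center`, `width`, `name`,
#'   `in_all` (logical), `pair` (replicate pair index for drop-out peaks).
#' @param noise data.frame per replicate-private peak: `chrom`, `center`,
#'   `width`, `replicate`.
#' @return named list of `GRanges` with narrowPeak metadata.
#' @export
generate_replicate_peaks <- function(config, true_peaks, noise) {
  j <- config$replicate_jitter
  pairs <- utils::combn(config$n_replicates, 2)
  reps <- lapply(seq_len(config$n_replicates), function(r) {
    present <- true_peaks$in_all |
      vapply(true_peaks$pair, function(p) !is.na(p) && r %in% pairs[, p],
             logical(1))
    tp <- true_peaks[present, , drop = FALSE]
    n <- nrow(tp)
    jit <- function(k) if (j > 0) sample(-j:j, k, replace = TRUE) else
      integer(k)
    s <- tp$center - floor(tp$width / 2) + jit(n)
    e <- s + tp$width - 1L + jit(n)
    df <- data.frame(chrom = tp$chrom, start = pmax(1L, s), end = e,
                     name = sprintf("rep%d_%s", r, tp$name),
                     summit = tp$center)
    if (config$noise_peaks_per_replicate > 0) {
      nz <- noise[noise$replicate == r, , drop = FALSE]
      s2 <- nz$center - floor(nz$width / 2)
      df <- rbind(df, data.frame(
        chrom = nz$chrom, start = pmax(1L, s2), end = s2 + nz$width - 1L,
        name = sprintf("rep%d_noise%d", r, seq_len(nrow(nz))),
        summit = nz$center))
    }
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    gr$name <- df$name
    gr$signal <- round(stats::rlnorm(length(gr), log(10), 0.4), 3)
    gr$score <- round(10 * gr$signal)
    gr$neglog10_p <- round(runif(length(gr), 5, 50), 3)
    gr$neglog10_q <- round(gr$neglog10_p * 0.8, 3)
    gr$summit_offset <- pmin(pmax(as.integer(df$summit -
                                               GenomicRanges::start(gr)), 0L),
                             GenomicRanges::width(gr) - 1L)
    GenomicRanges::sort(gr)
  })
  names(reps) <- sprintf("rep%d", seq_len(config$n_replicates))
  reps
}

.pair_members <- function(pair_idx, n) {
  if (is.na(pair_idx)) return(integer(0))
  pairs <- utils::combn(n, 2)
  pairs[, pair_idx]
}

#' Generate a complete synthetic fixture bundle
#'
#' Builds, deterministically under `config$seed`: a random genome purged of
#' long purine/pyrimidine runs; a gene table with strand, UTR lengths and
#' exons; a lncRNA with planted pyrimidine DNA-binding domains and an
#' accessibility profile that keeps them single-stranded; promoters of the
#' target genes carrying planted purine-tract triplex target sites
#' (pyrimidine-buffered, with the configured mismatch count) and Alu-like
#' insertions at the configured distance; replicate narrowPeak sets with a
#' fixed proximal excess, shared true peaks and replicate-private noise;
#' histone-mark tracks correlated with triplex-carrying peaks; and a
#' ground-truth manifest sufficient to score every downstream stage.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle` with elements `genome`
#'   (`DNAStringSet`), `genes`, `exons`, `alu`, `replicate_peaks`,
#'   `lncrna`, `profile`, `marks`, `manifest`, `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(as.integer(config$seed), .generate_bundle_impl(config))
}

.generate_bundle_impl <- function(cfg) {
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_lens <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                         chrom_names)
  genome_chars <- lapply(chrom_names, function(cn) {
    .suppress_purine_windows(sample(c("A", "C", "G", "T"),
                                    cfg$chrom_length, replace = TRUE))
  })
  names(genome_chars) <- chrom_names

  ## ---- genes ------------------------------------------------------------
  genes <- .place_genes(cfg, chrom_lens)
  scheme <- region_scheme()
  prom <- if (nrow(genes) > 0) proximal_windows(genes, scheme) else NULL

  ## ---- lncRNA + profile --------------------------------------------------
  lnc <- .build_lncrna(cfg)

  ## ---- plant target sites and Alus ---------------------------------------
  planted <- .plant_promoters(cfg, genes, prom, genome_chars, lnc)
  genome_chars <- planted$genome_chars

  ## ---- peaks -------------------------------------------------------------
  pk <- .plan_peaks(cfg, genes, prom, planted$tts, chrom_lens)
  replicate_peaks <- generate_replicate_peaks(cfg, pk$true_peaks, pk$noise)

  ## ---- marks -------------------------------------------------------------
  marks <- .build_marks(cfg, pk$true_peaks, chrom_lens)

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            character(1), collapse = ""))
  names(genome) <- chrom_names
  manifest <- list(
    seed = as.integer(cfg$seed),
    chrom_lengths = as.list(chrom_lens),
    target_genes = planted$target_genes,
    tts = planted$tts,
    dbd_intervals = cfg$planted_dbd_intervals,
    decoy_interval = cfg$decoy_interval,
    alu = planted$alu_df,
    true_peaks = pk$true_peaks,
    noise = pk$noise,
    mark_flags = marks$flags
  )
  structure(list(genome = genome, genes = genes, exons = .build_exons(genes),
                 alu = planted$alu_granges,
                 replicate_peaks = replicate_peaks,
                 lncrna = lnc$seq, profile = lnc$profile,
                 marks = marks$tracks, manifest = manifest, config = cfg),
            class = "synthetic_bundle")
}

.place_genes <- function(cfg, chrom_lens) {
  if (cfg$n_genes == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = integer(0),
                      gene_end = integer(0), utr5_len = integer(0),
                      utr3_len = integer(0)))
  }
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot_w <- floor(cfg$chrom_length / per_chrom)
  need <- max(cfg$gene_length_range) + 4000L + cfg$region_margin %||% 0L
  if (slot_w < need + 5000L) {
    stop("infeasible config: too many genes for the genome size")
  }
  rows <- lapply(seq_len(cfg$n_genes), function(i) {
    ci <- ((i - 1L) %% cfg$n_chroms) + 1L
    slot <- ((i - 1L) %/% cfg$n_chroms)
    base <- slot * slot_w
    strand <- sample(c("+", "-"), 1L)
    len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1L)
    if (strand == "+") {
      tss <- base + sample(4000:(slot_w - len - 3500L), 1L)
      gene_end <- tss + len - 1L
    } else {
      tss <- base + sample((len + 3500L):(slot_w - 4000L), 1L)
      gene_end <- tss - len + 1L
    }
    data.frame(gene_id = sprintf("gene%03d", i),
               chrom = names(chrom_lens)[ci], strand = strand,
               tss = tss, gene_end = gene_end,
               utr5_len = cfg$utr5_len, utr3_len = cfg$utr3_len)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.build_exons <- function(genes) {
  if (nrow(genes) == 0) return(GenomicRanges::GRanges())
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gl <- abs(g$gene_end - g$tss) + 1L
    rels <- rbind(c(0L, 300L), c(gl - 400L, gl))  # first and last exon
    sgn <- if (g$strand == "+") 1L else -1L
    starts <- ifelse(g$strand == "+", g$tss + rels[, 1],
                     g$tss - rels[, 2] + 1L)
    ends <- ifelse(g$strand == "+", g$tss + rels[, 2] - 1L,
                   g$tss - rels[, 1])
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(starts, ends),
                           strand = g$strand, gene_id = g$gene_id)
  })
  suppressWarnings(do.call(c, res))
}

.build_lncrna <- function(cfg) {
  n <- cfg$lncrna_length
  chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  protect <- rep(FALSE, n)
  planted <- cfg$planted_dbd_intervals
  if (!is.null(cfg$decoy_interval)) {
    planted <- c(planted, list(decoy = cfg$decoy_interval))
  }
  for (iv in planted) {
    idx <- iv[1]:iv[2]
    chars[idx] <- sample(c("U", "C"), length(idx), replace = TRUE,
                         prob = c(0.55, 0.45))
    protect[idx] <- TRUE
  }
  chars <- .suppress_runs(chars, protect = protect,
                          alphabet = c("A", "C", "G", "U"))
  chars <- .scrub_lncrna(chars, .dbd_tile_table(cfg), protect)
  profile <- round(runif(n, 0.12, 0.95), 4)
  for (nm in names(cfg$planted_dbd_intervals)) {
    iv <- cfg$planted_dbd_intervals[[nm]]
    profile[iv[1]:iv[2]] <- round(runif(iv[2] - iv[1] + 1, 0.90, 1.0), 4)
  }
  if (!is.null(cfg$decoy_interval)) {
    iv <- cfg$decoy_interval
    profile[iv[1]:iv[2]] <- round(runif(iv[2] - iv[1] + 1, 0.01, 0.09), 4)
  }
  list(seq = paste(chars, collapse = ""), profile = profile)
}

# Tile a planted DBD interval into target-site windows.
.dbd_tiles <- function(iv, tile) {
  width <- iv[2] - iv[1] + 1L
  if (width <= tile) return(matrix(iv, nrow = 1))
  n_tiles <- if (width >= 2L * tile - 8L) 3L else 2L
  starts <- round(seq(iv[1], iv[2] - tile + 1L, length.out = n_tiles))
  cbind(starts, starts + tile - 1L)
}

# All planted target-site tiles (DBDs plus the optional decoy).
.dbd_tile_table <- function(cfg) {
  rows <- list()
  for (nm in names(cfg$planted_dbd_intervals)) {
    tile_len <- if (!is.null(cfg$tile_lengths) &&
                    nm %in% names(cfg$tile_lengths)) {
      cfg$tile_lengths[[nm]]
    } else 20L
    iv <- cfg$planted_dbd_intervals[[nm]]
    t <- .dbd_tiles(iv, tile_len)
    rows[[nm]] <- data.frame(dbd = nm, start = t[, 1], end = t[, 2],
                             parent_start = iv[1], parent_end = iv[2])
  }
  if (!is.null(cfg$decoy_interval)) {
    iv <- cfg$decoy_interval
    t <- .dbd_tiles(iv, min(18L, iv[2] - iv[1] + 1L))
    rows[["decoy"]] <- data.frame(dbd = "decoy", start = t[, 1],
                                  end = t[, 2], parent_start = iv[1],
                                  parent_end = iv[2])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

# Flip lncRNA bases until the scanner finds no off-target hit between the
# RNA and the perfect target sequences of the planted tiles (or the Alu
# consensus).  Scanned at slightly looser thresholds than the runtime
# search so that per-promoter planted mismatches cannot re-enable an
# off-target window.  Keeps planted tracts pyrimidine (U<->C flips).
.scrub_lncrna <- function(chars, tiles, in_tract) {
  pars <- triplex_params(min_length = 14L, max_length = 25L,
                         max_error_rate = 0.28, min_guanine_rate = 0,
                         merge_gap = 10L)
  # emulate the runtime context of a planted site: 5-bp pyrimidine buffer,
  # then purine-balanced filler (balanced on both strands, so the pad can
  # not act as a target site itself)
  pad5 <- "CTCTCTC"; fill <- strrep("CATG", 5)
  parents <- unique(tiles[, c("parent_start", "parent_end")])
  # longest tile per parent: hits inside a parent are acceptable only up
  # to that length, so a domain planted with sub-20-nt tiles really does
  # vanish when the search minimum is raised to 20
  parents$max_len <- vapply(seq_len(nrow(parents)), function(pi) {
    sel <- tiles$parent_start == parents$parent_start[pi]
    as.integer(max(tiles$end[sel] - tiles$start[sel] + 1L))
  }, integer(1))
  for (iter in 1:1500) {
    rna <- paste(chars, collapse = "")
    regions <- c(vapply(seq_len(nrow(tiles)), function(i) {
      w <- chars[tiles$start[i]:tiles$end[i]]
      paste0(fill, pad5, paste(.motif_partner(w, "pyrimidine_parallel"),
                               collapse = ""), pad5, fill)
    }, character(1)), ALU_CONSENSUS)
    hits <- find_triplex_hits_seq(rna, regions, pars)
    if (nrow(hits) > 0) {
      # a hit is acceptable when its TFO stays inside SOME planted domain
      # and is no longer than that domain's planted tiles: such hits can
      # neither widen a merged domain nor outlive a raised length minimum;
      # spills outside all domains, over-long within-domain matches and
      # Alu matches get scrubbed
      ok_parent <- rep(FALSE, nrow(hits))
      for (pi in seq_len(nrow(parents))) {
        ok_parent <- ok_parent |
          (hits$rna_start >= parents$parent_start[pi] &
             hits$rna_end <= parents$parent_end[pi] &
             hits$length <= max(parents$max_len[pi], 18L) +
               (parents$max_len[pi] >= 20L) * 100L)
      }
      ok <- hits$region <= nrow(tiles) & ok_parent
      spur <- hits[!ok, , drop = FALSE]
    } else spur <- hits
    if (nrow(spur) == 0L) return(chars)
    h <- spur[1, ]
    span <- h$rna_start:h$rna_end
    free <- span[!in_tract[span]]
    pool <- if (length(free) > 0) free else span
    pos <- if (length(pool) == 1L) pool else sample(pool, 1L)
    if (in_tract[pos]) {
      chars[pos] <- if (chars[pos] == "U") "C" else "U"
    } else {
      chars[pos] <- sample(setdiff(c("A", "C", "G", "U"), chars[pos]), 1L)
    }
  }
  warning("lncRNA off-target scrub did not fully converge")
  chars
}

.plant_promoters <- function(cfg, genes, prom, genome_chars, lnc) {
  empty_tts <- data.frame(gene_id = character(0), dbd = character(0),
                          rna_start = integer(0), rna_end = integer(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          motif = character(0), errors = integer(0))
  alu_rows <- list()
  tts_rows <- list()
  target_genes <- character(0)
  if (nrow(genes) > 0) {
    n_targets <- round(cfg$tts_target_fraction * cfg$n_genes)
    target_idx <- sort(sample.int(cfg$n_genes, n_targets))
    target_genes <- genes$gene_id[target_idx]
    dbd_names <- names(cfg$planted_dbd_intervals)
    primary <- dbd_names[1]
    secondary <- if (length(dbd_names) > 1) dbd_names[-1] else character(0)
    n_secondary <- if (length(secondary) > 0 && n_targets > 0) {
      max(2L, round(cfg$secondary_dbd_fraction * n_targets))
    } else 0L
    rna_chars <- strsplit(lnc$seq, "")[[1]]
    tile_tab <- .dbd_tile_table(cfg)
    tile_sets <- lapply(split(tile_tab, tile_tab$dbd), function(d) {
      cbind(d$start, d$end)
    })
    sec_targets <- if (n_secondary > 0) {
      target_idx[seq_len(min(n_secondary, n_targets))]
    } else integer(0)

    for (k in seq_along(target_idx)) {
      gi <- target_idx[k]
      g <- genes[gi, ]
      ps <- GenomicRanges::start(prom)[gi]
      pe <- GenomicRanges::end(prom)[gi]
      local_seq <- paste(genome_chars[[g$chrom]][ps:pe], collapse = "")
      region1_local <- if (g$strand == "+") c(1L, 1000L) else c(1001L, 2000L)
      occupied <- list()
      primary_at <- NULL
      plant_one <- function(dbd_name, seq_now) {
        tiles <- tile_sets[[dbd_name]]
        ti <- ((k - 1L) %% nrow(tiles)) + 1L
        iv <- tiles[ti, ]
        window_rna <- paste(rna_chars[iv[1]:iv[2]], collapse = "")
        motif <- "pyrimidine_parallel"
        len_tot <- (iv[2] - iv[1] + 1L) + 2L * cfg$tts_flank
        # secondary sites co-locate with the primary so one peak covers all
        win <- if (is.null(primary_at)) region1_local else {
          c(max(region1_local[1], primary_at[1] - 120L - len_tot),
            min(region1_local[2], primary_at[2] + 120L + len_tot))
        }
        pos <- .free_position(win, len_tot, occupied, margin = 10L)
        res <- plant_tts(seq_now, window_rna, motif,
                         errors = cfg$tts_errors,
                         insert_at = pos + cfg$tts_flank,
                         strand = sample(c("+", "-"), 1L),
                         flank = cfg$tts_flank)
        occupied[[length(occupied) + 1L]] <<-
          c(res$start - cfg$tts_flank, res$end + cfg$tts_flank)
        if (is.null(primary_at)) primary_at <<- c(res$start, res$end)
        tts_rows[[length(tts_rows) + 1L]] <<- data.frame(
          gene_id = g$gene_id, dbd = dbd_name,
          rna_start = iv[1], rna_end = iv[2], chrom = g$chrom,
          start = ps + res$start - 1L, end = ps + res$end - 1L,
          strand = res$strand, motif = motif,
          errors = cfg$tts_errors)
        res$seq
      }
      local_seq <- plant_one(primary, local_seq)
      if (gi %in% sec_targets) {
        for (nm in secondary) local_seq <- plant_one(nm, local_seq)
      }
      if (!is.null(cfg$decoy_interval)) {
        iv <- tile_sets[["decoy"]][1, ]
        window_rna <- paste(rna_chars[iv[1]:iv[2]], collapse = "")
        len_tot <- (iv[2] - iv[1] + 1L) + 2L * cfg$tts_flank
        win <- if (is.null(primary_at)) region1_local else {
          c(max(region1_local[1], primary_at[1] - 120L - len_tot),
            min(region1_local[2], primary_at[2] + 120L + len_tot))
        }
        pos <- .free_position(win, len_tot, occupied, margin = 10L)
        res <- plant_tts(local_seq, window_rna, "pyrimidine_parallel",
                         errors = 0L, insert_at = pos + cfg$tts_flank,
                         strand = "+", flank = cfg$tts_flank)
        occupied[[length(occupied) + 1L]] <-
          c(res$start - cfg$tts_flank, res$end + cfg$tts_flank)
        local_seq <- res$seq
        tts_rows[[length(tts_rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, dbd = "decoy",
          rna_start = iv[1], rna_end = iv[2], chrom = g$chrom,
          start = ps + res$start - 1L, end = ps + res$end - 1L,
          strand = "+", motif = "pyrimidine_parallel", errors = 0L)
      }
      # companion Alu at the configured distance from the primary site
      if (runif(1) < cfg$alu_at_target_prob) {
        primary_row <- tts_rows[[which(vapply(tts_rows, function(x)
          x$gene_id == g$gene_id && x$dbd == primary, logical(1)))[1]]]
        local_tts <- c(primary_row$start - ps + 1L,
                       primary_row$end - ps + 1L)
        alu_len <- cfg$alu_consensus_length
        cand <- c(local_tts[2] + cfg$alu_distance + 1L,
                  local_tts[1] - cfg$alu_distance - alu_len)
        placed <- FALSE
        for (astart in cand) {
          if (astart < 1L || astart + alu_len - 1L > nchar(local_seq)) next
          if (.overlaps_occupied(astart, astart + alu_len - 1L, occupied)) next
          local_seq <- .write_alu(local_seq, astart, alu_len)
          occupied[[length(occupied) + 1L]] <- c(astart, astart + alu_len - 1L)
          alu_rows[[length(alu_rows) + 1L]] <- data.frame(
            chrom = g$chrom, start = ps + astart - 1L,
            end = ps + astart + alu_len - 2L, gene_id = g$gene_id,
            at_target = TRUE)
          placed <- TRUE
          break
        }
      }
      genome_chars[[g$chrom]][ps:pe] <- strsplit(local_seq, "")[[1]]
    }

    # Alus in non-target promoters
    for (gi in setdiff(seq_len(nrow(genes)), target_idx)) {
      if (runif(1) >= cfg$alu_promoter_fraction) next
      g <- genes[gi, ]
      ps <- GenomicRanges::start(prom)[gi]
      alu_len <- cfg$alu_consensus_length
      width <- GenomicRanges::width(prom)[gi]
      astart <- sample.int(width - alu_len + 1L, 1L)
      local_seq <- paste(genome_chars[[g$chrom]][ps:(ps + width - 1L)],
                         collapse = "")
      local_seq <- .write_alu(local_seq, astart, alu_len)
      genome_chars[[g$chrom]][ps:(ps + width - 1L)] <-
        strsplit(local_seq, "")[[1]]
      alu_rows[[length(alu_rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ps + astart - 1L,
        end = ps + astart + alu_len - 2L, gene_id = g$gene_id,
        at_target = FALSE)
    }
  }
  # intergenic Alus
  if (cfg$n_intergenic_alus > 0) {
    chrom_lens <- setNames(vapply(genome_chars, length, integer(1)),
                           names(genome_chars))
    avoid <- if (nrow(genes) > 0) {
      data.frame(chrom = as.character(GenomicRanges::seqnames(prom)),
                 start = GenomicRanges::start(prom) - 500L,
                 end = GenomicRanges::end(prom) + 500L)
    } else NULL
    centers <- .sample_centers(cfg$n_intergenic_alus, chrom_lens,
                               min_sep = 500L,
                               existing = data.frame(chrom = character(0),
                                                     pos = numeric(0)),
                               avoid = avoid)
    for (i in seq_len(nrow(centers))) {
      alu_len <- cfg$alu_consensus_length
      astart <- as.integer(centers$pos[i])
      chrom <- centers$chrom[i]
      seq_len_c <- length(genome_chars[[chrom]])
      if (astart + alu_len - 1L > seq_len_c) astart <- seq_len_c - alu_len
      frag <- .write_alu(paste(genome_chars[[chrom]][astart:(astart +
                                                               alu_len - 1L)],
                               collapse = ""), 1L, alu_len)
      genome_chars[[chrom]][astart:(astart + alu_len - 1L)] <-
        strsplit(frag, "")[[1]]
      alu_rows[[length(alu_rows) + 1L]] <- data.frame(
        chrom = chrom, start = astart, end = astart + alu_len - 1L,
        gene_id = NA_character_, at_target = FALSE)
    }
  }
  alu_df <- if (length(alu_rows) > 0) do.call(rbind, alu_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               gene_id = character(0), at_target = logical(0))
  alu_granges <- if (nrow(alu_df) > 0) {
    gr <- GenomicRanges::GRanges(alu_df$chrom,
                                 IRanges::IRanges(alu_df$start, alu_df$end))
    gr$name <- sprintf("Alu_%d", seq_along(gr))
    gr
  } else GenomicRanges::GRanges()
  tts_df <- if (length(tts_rows) > 0) do.call(rbind, tts_rows) else empty_tts
  list(genome_chars = genome_chars, tts = tts_df, alu_df = alu_df,
       alu_granges = alu_granges, target_genes = target_genes)
}

# First free position for a span of `len` inside `range` (local coords),
# sampled uniformly among non-overlapping placements.
.free_position <- function(range, len, occupied, margin = 10L,
                           tries = 200L) {
  lo <- range[1] + margin
  hi <- range[2] - margin - len + 1L
  if (hi < lo) stop("planted site does not fit in the target window")
  for (t in seq_len(tries)) {
    pos <- sample(lo:hi, 1L)
    if (!.overlaps_occupied(pos, pos + len - 1L, occupied)) return(pos)
  }
  stop("could not find a free position for a planted site")
}

.overlaps_occupied <- function(s, e, occupied) {
  for (iv in occupied) if (s <= iv[2] && e >= iv[1]) return(TRUE)
  FALSE
}

# Overwrite a stretch of `seq` with the Alu consensus (~2% divergence).
.write_alu <- function(seq, at, len) {
  alu <- strsplit(substr(ALU_CONSENSUS, 1L, len), "")[[1]]
  nmut <- max(0L, stats::rbinom(1, len, 0.02))
  if (nmut > 0) {
    at_mut <- sample.int(len, nmut)
    alu[at_mut] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
  }
  chars <- strsplit(seq, "")[[1]]
  chars[at:(at + len - 1L)] <- alu
  paste(chars, collapse = "")
}

.plan_peaks <- function(cfg, genes, prom, tts, chrom_lens) {
  widths <- function(n) {
    pmax(cfg$min_peak_width,
         round(stats::rnorm(n, cfg$peak_width_mean, cfg$peak_width_sd)))
  }
  n_peaks <- cfg$peaks_per_replicate
  rows <- list()
  uniform_mode <- is.null(cfg$proximal_fraction) || nrow(genes) == 0L
  # noise peaks are placed outside proximal windows, so the proximal count
  # is budgeted over everything a replicate file will contain
  n_prox <- if (uniform_mode) 0L else
    round(cfg$proximal_fraction *
            (n_peaks + cfg$noise_peaks_per_replicate))
  target_ids <- unique(tts$gene_id[tts$dbd != "decoy"])
  primary_dbd <- names(cfg$planted_dbd_intervals)[1]

  if (n_prox > 0) {
    # triplex peaks: one per target promoter, covering its primary site
    tri_ids <- head(target_ids, n_prox)
    for (gid in tri_ids) {
      g <- genes[genes$gene_id == gid, ]
      rows_g <- tts[tts$gene_id == gid, , drop = FALSE]
      w <- widths(1)
      tts_mid <- floor((min(rows_g$start) + max(rows_g$end)) / 2)
      # clamp so the peak covers every planted site of this promoter
      lo <- max(rows_g$end) + 6L - w + floor(w / 2)
      hi <- min(rows_g$start) - 6L + floor(w / 2)
      if (lo > hi) { lo <- tts_mid; hi <- tts_mid }
      center <- min(max(tts_mid + sample(-50:50, 1L), lo), hi)
      gi <- which(genes$gene_id == gid)
      pw <- c(GenomicRanges::start(prom)[gi], GenomicRanges::end(prom)[gi])
      center <- min(max(center, pw[1] + 10L), pw[2] - 10L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, center = center, width = w,
        kind = "triplex_proximal", gene_id = gid)
    }
    # plain proximal peaks in non-target promoters (two slots per promoter)
    n_plain <- n_prox - length(tri_ids)
    plain_pool <- setdiff(genes$gene_id, target_ids)
    if (n_plain > 2L * length(plain_pool)) {
      stop("infeasible config: not enough non-target promoters for the ",
           "requested proximal fraction")
    }
    for (i in seq_len(n_plain)) {
      gid <- plain_pool[((i - 1L) %% length(plain_pool)) + 1L]
      slot <- (i - 1L) %/% length(plain_pool)
      g <- genes[genes$gene_id == gid, ]
      rel <- if (slot == 0L) -1150L + sample(-80:80, 1L) else
        100L + sample(-80:80, 1L)
      center <- if (g$strand == "+") g$tss + rel else g$tss - rel
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, center = center, width = widths(1),
        kind = "proximal", gene_id = gid)
    }
  }
  # background peaks
  n_bg <- n_peaks - length(rows)
  existing <- if (length(rows) > 0) {
    df <- do.call(rbind, rows)
    data.frame(chrom = df$chrom, pos = df$center)
  } else data.frame(chrom = character(0), pos = numeric(0))
  avoid <- if (!uniform_mode && nrow(genes) > 0) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(prom)),
               start = GenomicRanges::start(prom),
               end = GenomicRanges::end(prom))
  } else NULL
  bg <- .sample_centers(n_bg, chrom_lens, cfg$min_center_sep, existing,
                        avoid = avoid)
  if (nrow(bg) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = bg$chrom, center = bg$pos, width = widths(nrow(bg)),
      kind = "background", gene_id = NA_character_)
  }
  true_peaks <- do.call(rbind, rows)
  true_peaks$name <- sprintf("true%03d", seq_len(nrow(true_peaks)))
  true_peaks$center <- as.integer(true_peaks$center)
  true_peaks$start <- true_peaks$center - floor(true_peaks$width / 2)
  true_peaks$end <- true_peaks$start + true_peaks$width - 1L
  true_peaks$is_triplex <- true_peaks$kind == "triplex_proximal"
  true_peaks$is_proximal <- true_peaks$kind != "background"
  n_pairs <- choose(cfg$n_replicates, 2)
  true_peaks$in_all <- runif(nrow(true_peaks)) < cfg$share_all_fraction
  true_peaks$pair <- ifelse(true_peaks$in_all, NA_integer_,
                            sample.int(n_pairs, nrow(true_peaks),
                                       replace = TRUE))
  # replicate-private noise, kept clear of everything else
  noise <- NULL
  if (cfg$noise_peaks_per_replicate > 0) {
    all_existing <- data.frame(chrom = true_peaks$chrom,
                               pos = true_peaks$center)
    nz <- .sample_centers(cfg$n_replicates * cfg$noise_peaks_per_replicate,
                          chrom_lens,
                          cfg$min_center_sep + 2L * cfg$replicate_jitter,
                          all_existing, avoid = avoid)
    noise <- data.frame(chrom = nz$chrom, center = as.integer(nz$pos),
                        width = widths(nrow(nz)),
                        replicate = rep(seq_len(cfg$n_replicates),
                                        each = cfg$noise_peaks_per_replicate))
  } else {
    noise <- data.frame(chrom = character(0), center = integer(0),
                        width = integer(0), replicate = integer(0))
  }
  list(true_peaks = true_peaks, noise = noise)
}

.build_marks <- function(cfg, true_peaks, chrom_lens) {
  tracks <- list()
  flags <- list()
  p0 <- cfg$mark_base_prob
  for (nm in names(cfg$mark_tracks)) {
    odds <- cfg$mark_tracks[[nm]]
    o1 <- odds * p0 / (1 - p0)
    p1 <- o1 / (1 + o1)
    pr <- ifelse(true_peaks$is_triplex, p1, p0)
    present <- runif(nrow(true_peaks)) < pr
    gr <- GenomicRanges::GRanges(
      true_peaks$chrom[present],
      IRanges::IRanges(true_peaks$start[present], true_peaks$end[present]))
    if (length(gr) > 0) gr$name <- sprintf("%s_%d", nm, seq_along(gr))
    tracks[[nm]] <- gr
    flags[[nm]] <- setNames(present, true_peaks$name)
  }
  list(tracks = tracks, flags = flags)
}
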