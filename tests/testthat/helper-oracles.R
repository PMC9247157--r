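# Independent brute-force oracles.  These deliberately re-derive every
# result from first principles (per-base unions, quadratic scans, full
# window enumeration) and never call the code paths they check.

# Covered-base set of a region set, as "chrom:pos" strings.
oracle_covered_bases <- function(gr) {
  if (length(gr) == 0) return(character(0))
  unlist(lapply(seq_along(gr), function(i) {
    paste0(as.character(GenomicRanges::seqnames(gr))[i], ":",
           seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }))
}

# Quadratic overlap count: query intervals with >= min_bp overlap with at
# least one subject interval.
oracle_overlap_count <- function(query, subject, min_bp = 1) {
  qc <- as.character(GenomicRanges::seqnames(query))
  sc <- as.character(GenomicRanges::seqnames(subject))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  n <- 0L
  for (i in seq_along(query)) {
    hit <- FALSE
    for (j in seq_along(subject)) {
      if (qc[i] != sc[j]) next
      ov <- min(qe[i], se[j]) - max(qs[i], ss[j]) + 1
      if (ov >= min_bp) { hit <- TRUE; break }
    }
    n <- n + hit
  }
  n
}

# ---- triplex oracles ------------------------------------------------------

.orc_code <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T", "U")) - 1L
  code[code == 4L] <- 3L
  code[is.na(code)] <- 4L
  code
}

.orc_match_fun <- function(motif) {
  pairs <- switch(motif,
    pyrimidine_parallel = list(c(3L, 0L), c(1L, 2L)),
    purine_antiparallel = list(c(0L, 0L), c(2L, 2L)),
    GT_parallel = ,
    GT_antiparallel = list(c(2L, 2L), c(3L, 0L)))
  function(r, d) {
    out <- rep(FALSE, length(r))
    for (p in pairs) out <- out | (r == p[1] & d == p[2])
    out
  }
}

# Exhaustive triplex hit enumeration for one RNA vs one DNA sequence.
# Same hit definition as the scanner, independently realised:
# every motif, both duplex strands, every diagonal, every (start, length),
# edge positions must match, mismatch rate <= max_error_rate, length in
# [min_length, max_length]; containment-maximal per diagonal; then filter
# on TTS purine-strand guanine rate.
oracle_triplex_hits <- function(rna, dna, params) {
  rna_code <- .orc_code(chartr("T", "U", rna))
  dna_code <- .orc_code(dna)
  n <- length(rna_code); m <- length(dna_code)
  out <- list()
  for (motif in params$motifs) {
    anti <- motif %in% c("purine_antiparallel", "GT_antiparallel")
    R <- if (anti) rev(rna_code) else rna_code
    mf <- .orc_match_fun(motif)
    for (strand in c("+", "-")) {
      D <- if (strand == "+") dna_code else {
        rev(ifelse(dna_code <= 3L, 3L - dna_code, 4L))
      }
      gua <- as.integer(D == 2L)
      for (d in (-(n - 1)):(m - 1)) {
        i0 <- if (d < 0) 1 - d else 1
        j0 <- if (d < 0) 1 else 1 + d
        L <- min(n - i0 + 1, m - j0 + 1)
        if (L < params$min_length) next
        mt <- mf(R[i0:(i0 + L - 1)], D[j0:(j0 + L - 1)])
        mm_pref <- c(0L, cumsum(!mt))
        cand <- NULL
        for (s in which(mt)) {
          max_here <- min(params$max_length, L - s + 1)
          if (max_here < params$min_length) next
          lens <- params$min_length:max_here
          e <- s + lens - 1
          oke <- mt[e]
          mm <- mm_pref[e + 1L] - mm_pref[s]
          feas <- oke & (mm <= params$max_error_rate * lens + 1e-9)
          if (any(feas)) {
            cand <- rbind(cand, cbind(s, e[feas], mm[feas]))
          }
        }
        if (is.null(cand)) next
        # containment-maximal on this diagonal
        ord <- order(cand[, 1], -cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        best_e <- 0
        keep <- logical(nrow(cand))
        last_s <- -1
        for (k in seq_len(nrow(cand))) {
          if (cand[k, 1] == last_s) next  # only longest per start
          last_s <- cand[k, 1]
          if (cand[k, 2] > best_e) { keep[k] <- TRUE; best_e <- cand[k, 2] }
        }
        cand <- cand[keep, , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          s <- cand[k, 1]; e <- cand[k, 2]; mm <- cand[k, 3]
          len <- e - s + 1
          js <- j0 + s - 1; je <- j0 + e - 1
          g <- sum(gua[js:je])
          if (g + 1e-9 < params$min_guanine_rate * len) next
          is_ <- i0 + s - 1; ie_ <- i0 + e - 1
          rs <- if (anti) n - ie_ + 1 else is_
          re <- if (anti) n - is_ + 1 else ie_
          ds <- if (strand == "+") js else m - je + 1
          de <- if (strand == "+") je else m - js + 1
          out[[length(out) + 1L]] <- data.frame(
            region = 1L, strand = strand, rna_start = rs, rna_end = re,
            dna_start = ds, dna_end = de, length = len,
            mismatches = mm, motif = motif)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(region = integer(0), strand = character(0),
                      rna_start = integer(0), rna_end = integer(0),
                      dna_start = integer(0), dna_end = integer(0),
                      length = integer(0), mismatches = integer(0),
                      motif = character(0)))
  }
  do.call(rbind, out)
}

# Canonical key set for hit-table comparison.
hit_keys <- function(df) {
  sort(sprintf("%s|%s|%d|%d|%d|%d|%d", df$motif, df$strand, df$rna_start,
               df$rna_end, df$dna_start, df$dna_end, df$mismatches))
}

# Exhaustive TTS enumeration: all purine-edged windows with purity >=
# 1 - max_error_rate and length >= min_length, containment-maximal per
# strand.
oracle_tts <- function(dna, params) {
  code <- .orc_code(dna)
  m <- length(code)
  res <- list()
  for (strand in c("+", "-")) {
    D <- if (strand == "+") code else rev(ifelse(code <= 3L, 3L - code, 4L))
    pur <- D == 0L | D == 2L
    cand <- NULL
    for (s in seq_len(m)) {
      if (!pur[s]) next
      for (e in s:m) {
        if (!pur[e]) next
        len <- e - s + 1
        if (len < params$min_length) next
        if (sum(!pur[s:e]) <= params$max_error_rate * len + 1e-9) {
          cand <- rbind(cand, c(s, e))
        }
      }
    }
    if (is.null(cand)) next
    keep <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      contained <- cand[, 1] <= cand[k, 1] & cand[, 2] >= cand[k, 2] &
        (cand[, 1] != cand[k, 1] | cand[, 2] != cand[k, 2])
      if (any(contained)) keep[k] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
    if (strand == "-") {
      cand <- cbind(m - cand[, 2] + 1, m - cand[, 1] + 1)
    }
    res[[strand]] <- data.frame(start = cand[, 1], end = cand[, 2],
                                strand = strand)
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, res)
}

# Brute-force Jonckheere-Terpstra statistic (explicit loops, ties 1/2).
oracle_jt <- function(groups) {
  s <- 0
  for (i in seq_len(length(groups) - 1)) {
    for (j in (i + 1):length(groups)) {
      for (x in groups[[i]]) {
        for (y in groups[[j]]) {
          s <- s + (x < y) + 0.5 * (x == y)
        }
      }
    }
  }
  s
}

# One-sided hypergeometric enrichment p-value by direct enumeration.
oracle_hyper_p <- function(a, b, c, d) {
  k <- a + b          # draws (query size)
  K <- a + c          # db-positive universe elements
  N <- a + b + c + d
  xs <- max(0, k + K - N):min(k, K)
  probs <- vapply(xs, function(x) {
    choose(K, x) * choose(N - K, k - x) / choose(N, k)
  }, numeric(1))
  sum(probs[xs >= a])
}
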