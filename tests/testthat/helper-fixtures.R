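# Small builders shared across the suite.

# GRanges from 0-based half-open (BED-style) coordinates.
gr_bed <- function(chrom, start0, end0, strand = "*", ...) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  extra <- list(...)
  for (nm in names(extra)) S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

# Random region set on a toy genome, BED coordinates.
random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                           max_len = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  start0 <- sample.int(max_pos - max_len, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gr_bed(chrom, start0, start0 + len,
         strand = sample(c("+", "-", "*"), n, replace = TRUE),
         name = sprintf("r%d", seq_len(n)),
         score = round(runif(n), 3))
}

# Minimal gene table in internal (1-based) coordinates.
gene_table <- function(gene_id, chrom, strand, tss, gene_end,
                       utr5_len = 0L, utr3_len = 0L) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tss = tss, gene_end = gene_end,
             utr5_len = utr5_len, utr3_len = utr3_len,
             stringsAsFactors = FALSE)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A reduced synthetic configuration for quick pipeline-level tests.
quick_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, n_chroms = 1L, chrom_length = 4e5,
                   n_genes = 16L, peaks_per_replicate = 120L,
                   noise_peaks_per_replicate = 15L,
                   n_intergenic_alus = 8L, ...)
}
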