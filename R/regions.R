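#' Read a BED6 or ENCODE narrowPeak file into a GRanges
#'
#' Coordinates on disk are 0-based half-open (UCSC BED); the returned
#' [GenomicRanges::GRanges] uses the 1-based closed convention native to
#' Bioconductor.  Chromosome names are taken verbatim: no "chr" prefix
#' normalisation is ever applied, so a naming mismatch between files surfaces
#' as an empty overlap that the higher-level functions treat as an error
#' rather than a silent empty join.
#'
#' Lines starting with `#` (provenance headers written by this package) and
#' `track` lines are skipped.
#'
#' @param path file to read.
#' @param dialect `"bed6"` (6 columns) or `"narrowPeak"` (ENCODE 10-column).
#' @return A `GRanges` with metadata columns `name` and `score`; for
#'   narrowPeak additionally `signal`, `neglog10_p`, `neglog10_q` and
#'   `summit_offset` (0-based offset of the summit from the region start,
#'   `-1` when unknown).
#' @export
read_region_file <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  ncol_needed <- if (dialect == "bed6") 6L else 10L
  if (length(lines) == 0L) return(.empty_regions(dialect))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad) > 0L) {
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": expected at least ", ncol_needed, " fields, got ", nf[bad[1]])
  }
  mat <- t(vapply(fields, function(f) f[seq_len(ncol_needed)],
                  character(ncol_needed)))
  chrom <- mat[, 1]
  start0 <- suppressWarnings(as.numeric(mat[, 2]))
  end0 <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad) > 0L) {
    stop("malformed ", dialect, " line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad) > 0L) {
    stop("invalid interval at line ", lineno[bad[1]], " in ", path,
         ": start must be < end and >= 0 (got [",
         start0[bad[1]], ",", end0[bad[1]], "))")
  }
  strand <- mat[, 6]
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = mat[, 4],
    score = suppressWarnings(as.numeric(mat[, 5]))
  )
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.integer(mat[, 10]))
    width <- end0 - start0
    bad <- which(!is.na(summit) & (summit < -1 | summit >= width))
    if (length(bad) > 0L) {
      stop("invalid summit offset at line ", lineno[bad[1]], " in ", path,
           ": must satisfy -1 <= offset < region width")
    }
    gr$signal <- suppressWarnings(as.numeric(mat[, 7]))
    gr$neglog10_p <- suppressWarnings(as.numeric(mat[, 8]))
    gr$neglog10_q <- suppressWarnings(as.numeric(mat[, 9]))
    gr$summit_offset <- summit
  }
  S4Vectors::metadata(gr)$dialect <- dialect
  gr
}

.empty_regions <- function(dialect = "bed6") {
  gr <- GenomicRanges::GRanges()
  gr$name <- character(0)
  gr$score <- numeric(0)
  if (dialect == "narrowPeak") {
    gr$signal <- numeric(0)
    gr$neglog10_p <- numeric(0)
    gr$neglog10_q <- numeric(0)
    gr$summit_offset <- integer(0)
  }
  gr
}

#' Write a GRanges as BED6 or narrowPeak
#'
#' Inverse of [read_region_file()]: internal 1-based closed coordinates are
#' written as 0-based half-open.  Reading the written file back reproduces
#' the input field for field.
#'
#' @param regions a `GRanges`; missing `name`/`score`/narrowPeak columns are
#'   filled with `"."`/`0`/`-1` defaults.
#' @param path output file.
#' @param dialect output format.
#' @param header optional character vector of provenance lines written as
#'   `#`-prefixed comments before the records.
#' @return `path`, invisibly.
#' @export
write_region_file <- function(regions, path,
                              dialect = c("bed6", "narrowPeak"),
                              header = NULL) {
  dialect <- match.arg(dialect)
  n <- length(regions)
  getcol <- function(col, default) {
    if (col %in% names(S4Vectors::mcols(regions))) {
      v <- S4Vectors::mcols(regions)[[col]]
      v[is.na(v)] <- default
      v
    } else rep(default, n)
  }
  strand <- as.character(GenomicRanges::strand(regions))
  strand[strand == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1,
    end = GenomicRanges::end(regions),
    name = getcol("name", "."),
    score = getcol("score", 0),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (dialect == "narrowPeak") {
    df$signal <- getcol("signal", 0)
    df$neglog10_p <- getcol("neglog10_p", -1)
    df$neglog10_q <- getcol("neglog10_q", -1)
    df$summit_offset <- getcol("summit_offset", -1L)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (n > 0L) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Strand-blind union of intervals: any two intervals whose half-open gap is
#' at most `max_gap` are merged.  With `max_gap = 0` overlapping and
#' book-ended intervals are merged and the set of covered bases is preserved.
#'
#' @param regions a `GRanges`.
#' @param max_gap maximum half-open gap (bp) bridged by a merge.
#' @return A sorted, pairwise non-overlapping `GRanges`.
#' @export
merge_intervals <- function(regions, max_gap = 0) {
  stopifnot(max_gap >= 0)
  GenomicRanges::reduce(GenomicRanges::sort(regions),
                        min.gapwidth = max_gap + 1L,
                        ignore.strand = TRUE)
}

#' Count query intervals overlapping a subject set
#'
#' Number of query intervals having at least `min_bp` bases of overlap with
#' at least one subject interval (strand-blind).
#'
#' @param query,subject `GRanges`.
#' @param min_bp minimum overlap width in bp.
#' @return Integer count in `[0, length(query)]`.
#' @export
overlap_count <- function(query, subject, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  sum(GenomicRanges::countOverlaps(query, subject, minoverlap = min_bp,
                                   ignore.strand = TRUE) > 0L)
}

#' Logical per-query overlap indicator
#' @inheritParams overlap_count
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject, min_bp = 1L) {
  GenomicRanges::countOverlaps(query, subject, minoverlap = min_bp,
                               ignore.strand = TRUE) > 0L
}

#' Read a per-base single-strandedness probability profile
#'
#' Two-column TSV: 1-based transcript position, probability of the base
#' being single-stranded (in `[0,1]`).  Positions must be a complete
#' 1..n run.
#'
#' @param path TSV file.
#' @return Numeric vector of probabilities, one per base.
#' @export
read_accessibility_profile <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("accessibility profile needs 2 columns")
  pos <- as.integer(df[[1]])
  p <- as.numeric(df[[2]])
  if (!identical(pos, seq_along(pos))) {
    stop("profile positions must be 1..n without gaps")
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0,1]")
  }
  p
}

#' Write an accessibility profile
#' @param profile numeric vector in `[0,1]`.
#' @param path output TSV.
#' @param header optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_accessibility_profile <- function(profile, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(data.frame(pos = seq_along(profile), prob = profile),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' BED6 file whose intervals span the transcription unit; the TSS is the
#' 5' end of the interval on the annotated strand.  Strand must be `+` or
#' `-`.  Optional columns 7..10 carry 5'UTR and 3'UTR lengths (bp) and are
#' used by feature annotation when present.
#'
#' @param path BED-like TSV.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   (1-based), `gene_end` (1-based 3'-most position), `utr5_len`,
#'   `utr3_len`.
#' @export
read_gene_table <- function(path) {
  gr <- read_region_file(path, "bed6")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stop("gene records must be stranded (+/-)")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track\\b)", lines) & nzchar(lines)]
  extra <- strsplit(lines, "\t", fixed = TRUE)
  utr5 <- vapply(extra, function(f)
    if (length(f) >= 7) suppressWarnings(as.integer(f[7])) else 0L, integer(1))
  utr3 <- vapply(extra, function(f)
    if (length(f) >= 8) suppressWarnings(as.integer(f[8])) else 0L, integer(1))
  utr5[is.na(utr5)] <- 0L
  utr3[is.na(utr3)] <- 0L
  data.frame(
    gene_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    tss = ifelse(strand == "+", GenomicRanges::start(gr),
                 GenomicRanges::end(gr)),
    gene_end = ifelse(strand == "+", GenomicRanges::end(gr),
                      GenomicRanges::start(gr)),
    utr5_len = utr5,
    utr3_len = utr3,
    stringsAsFactors = FALSE
  )
}

#' Write a gene table as BED6 (+ UTR length columns)
#' @param genes gene table as from [read_gene_table()].
#' @param path output file.
#' @param header optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, header = NULL) {
  start1 <- ifelse(genes$strand == "+", genes$tss, genes$gene_end)
  end1 <- ifelse(genes$strand == "+", genes$gene_end, genes$tss)
  df <- data.frame(genes$chrom, start1 - 1, end1, genes$gene_id, 0,
                   genes$strand,
                   if (!is.null(genes$utr5_len)) genes$utr5_len else 0L,
                   if (!is.null(genes$utr3_len)) genes$utr3_len else 0L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared sanity check: two region sets that are supposed to be joined must
# live on a common chromosome namespace.
.check_shared_chroms <- function(a, b, what = "inputs") {
  ca <- unique(as.character(GenomicRanges::seqnames(a)))
  cb <- unique(as.character(GenomicRanges::seqnames(b)))
  if (length(ca) > 0 && length(cb) > 0 && length(intersect(ca, cb)) == 0) {
    stop("chromosome names of ", what, " do not intersect (",
         paste(head(ca, 3), collapse = ","), " vs ",
         paste(head(cb, 3), collapse = ","),
         "); names are compared verbatim")
  }
  invisible(TRUE)
}
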