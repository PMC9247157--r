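#' Write a synthetic bundle to a directory of standard-format files
#'
#' Emits `genome.fa`, `genes.bed`, `exons.bed`, `alu.bed`,
#' `repN.narrowPeak`, `lncrna.fa`, `accessibility.tsv`, `mark_<name>.bed`
#' and `manifest.json`.  All files are plain text and byte-stable for a
#' fixed generator seed.
#'
#' @param bundle a `synthetic_bundle` from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("triplexChIRP synthetic bundle seed=%d",
                 bundle$manifest$seed)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"),
                              width = 80L)
  write_gene_table(bundle$genes, file.path(dir, "genes.bed"), header = hdr)
  ex <- bundle$exons
  if (length(ex) > 0) ex$name <- ex$gene_id
  write_region_file(ex, file.path(dir, "exons.bed"), "bed6", header = hdr)
  write_region_file(bundle$alu, file.path(dir, "alu.bed"), "bed6",
                    header = hdr)
  for (r in names(bundle$replicate_peaks)) {
    write_region_file(bundle$replicate_peaks[[r]],
                      file.path(dir, paste0(r, ".narrowPeak")),
                      "narrowPeak", header = hdr)
  }
  rna <- Biostrings::RNAStringSet(chartr("T", "U", bundle$lncrna))
  names(rna) <- "lncRNA"
  Biostrings::writeXStringSet(rna, file.path(dir, "lncrna.fa"), width = 80L)
  write_accessibility_profile(bundle$profile,
                              file.path(dir, "accessibility.tsv"),
                              header = hdr)
  for (nm in names(bundle$marks)) {
    write_region_file(bundle$marks[[nm]],
                      file.path(dir, paste0("mark_", nm, ".bed")), "bed6",
                      header = hdr)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' Inverse of [write_bundle()] for the artifacts the pipeline consumes
#' (the JSON manifest is reloaded as plain lists/data.frames).
#'
#' @param dir directory written by [write_bundle()].
#' @return list with `genome`, `genes`, `exons`, `alu`,
#'   `replicate_peaks`, `lncrna`, `profile`, `marks`, `manifest`.
#' @export
read_bundle <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  rep_files <- sort(list.files(dir, pattern = "^rep[0-9]+\\.narrowPeak$",
                               full.names = TRUE))
  reps <- lapply(rep_files, read_region_file, dialect = "narrowPeak")
  names(reps) <- sub("\\.narrowPeak$", "", basename(rep_files))
  mark_files <- sort(list.files(dir, pattern = "^mark_.*\\.bed$",
                                full.names = TRUE))
  marks <- lapply(mark_files, read_region_file, dialect = "bed6")
  names(marks) <- sub("^mark_(.*)\\.bed$", "\\1", basename(mark_files))
  lnc <- Biostrings::readBStringSet(file.path(dir, "lncrna.fa"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(genome = genome,
       genes = read_gene_table(file.path(dir, "genes.bed")),
       exons = read_region_file(file.path(dir, "exons.bed"), "bed6"),
       alu = read_region_file(file.path(dir, "alu.bed"), "bed6"),
       replicate_peaks = reps,
       lncrna = as.character(lnc[[1]]),
       profile = read_accessibility_profile(
         file.path(dir, "accessibility.tsv")),
       marks = marks,
       manifest = manifest)
}
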