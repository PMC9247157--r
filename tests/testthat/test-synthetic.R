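test_that("plant_tts writes the motif complement with exact error counts", {
  prom <- strrep("C", 60)
  res <- plant_tts(prom, strrep("U", 15), "pyrimidine_parallel",
                   errors = 0, insert_at = 20, strand = "+")
  expect_equal(res$purine_seq, strrep("A", 15))
  expect_equal(substr(res$seq, 20, 34), strrep("A", 15))
  expect_equal(c(res$start, res$end), c(20L, 34L))
  res2 <- plant_tts(prom, strrep("G", 15), "purine_antiparallel",
                    errors = 0, insert_at = 10, strand = "+")
  expect_equal(res2$purine_seq, strrep("G", 15))
  # minus strand: reverse complement is written
  res3 <- plant_tts(prom, strrep("U", 15), "pyrimidine_parallel",
                    errors = 0, insert_at = 20, strand = "-")
  expect_equal(substr(res3$seq, 20, 34), strrep("T", 15))
})

test_that("planted windows score exactly `errors` mismatches (scorer oracle)", {
  withr::local_seed(19)
  for (i in 1:30) {
    motif <- sample(c("pyrimidine_parallel", "GT_parallel"), 1)
    alphabet <- if (motif == "pyrimidine_parallel") c("U", "C") else
      c("G", "U")
    rna <- paste(sample(alphabet, 20, replace = TRUE), collapse = "")
    errors <- sample(0:3, 1)
    res <- plant_tts(strrep("T", 80), rna, motif, errors = errors,
                     strand = "+")
    planted <- substr(res$seq, res$start, res$end)
    expect_equal(score_window(rna, planted, motif), errors)
  }
})

test_that("infeasible plantings are rejected", {
  expect_error(plant_tts(strrep("C", 10), strrep("U", 15),
                         "pyrimidine_parallel"), "too short")
  expect_error(plant_tts(strrep("C", 60), "AUUUUUUUUUUUUUU",
                         "pyrimidine_parallel", errors = 0),
               "motif-compatible")
  expect_error(synthetic_config(tts_target_fraction = 1.5), "\\[0,1\\]")
  expect_error(synthetic_config(planted_dbd_intervals =
                                  list(DBD_A = c(100L, 3000L))), "outside")
})

test_that("bundles are byte-identical under a fixed seed", {
  cfg <- quick_config(seed = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(generate_bundle(cfg), d1)
  write_bundle(generate_bundle(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the genome
  b3 <- generate_bundle(quick_config(seed = 6))
  expect_false(identical(as.character(b3$genome[[1]]),
                         as.character(generate_bundle(cfg)$genome[[1]])))
})

test_that("an empty gene table yields background-only peaks", {
  cfg <- synthetic_config(seed = 2, n_chroms = 1L, chrom_length = 3e5,
                          n_genes = 0L, peaks_per_replicate = 40L,
                          noise_peaks_per_replicate = 5L,
                          n_intergenic_alus = 3L)
  b <- generate_bundle(cfg)
  expect_equal(nrow(b$genes), 0)
  expect_true(all(b$manifest$true_peaks$kind == "background"))
  expect_equal(nrow(b$manifest$tts), 0)
})

test_that("planted target sites sit inside their promoters (manifest audit)", {
  b <- generate_bundle(quick_config(seed = 9))
  tts <- b$manifest$tts
  expect_equal(nrow(tts) >= round(0.5 * 16), TRUE)
  prom <- proximal_windows(b$genes)
  gi <- match(tts$gene_id, b$genes$gene_id)
  expect_true(all(tts$start >= GenomicRanges::start(prom)[gi] &
                    tts$end <= GenomicRanges::end(prom)[gi]))
  # and inside region 1 specifically
  r1 <- region_windows(b$genes, "region1")
  expect_true(all(tts$start >= GenomicRanges::start(r1)[gi] &
                    tts$end <= GenomicRanges::end(r1)[gi]))
  # genomic sequence at each site carries a detectable planted window
  rna <- b$lncrna
  for (k in head(seq_len(nrow(tts)), 5)) {
    reg <- GenomicRanges::GRanges(tts$chrom[k],
                                  IRanges::IRanges(tts$start[k] - 10,
                                                   tts$end[k] + 10))
    h <- find_triplex_hits(rna, reg, b$genome,
                           triplex_params(min_length = 15))
    expect_gt(nrow(h), 0)
    expect_true(any(h$rna_start >= tts$rna_start[k] - 1 &
                      h$rna_end <= tts$rna_end[k] + 1))
  }
})

test_that("realized proximal share of replicate peaks matches the target", {
  for (s in 1:3) {
    b <- generate_bundle(synthetic_config(seed = s))
    genes <- b$genes
    for (r in names(b$replicate_peaks)) {
      af <- assign_feature(b$replicate_peaks[[r]], genes)
      realized <- mean(af$category == "Proximal Region")
      expect_lt(abs(realized - 0.1023), 0.01)
    }
  }
})

test_that("replicate structure honours jitter and membership settings", {
  cfg <- synthetic_config(seed = 4, n_chroms = 1L, chrom_length = 4e5,
                          n_genes = 0L, proximal_fraction = NULL,
                          peaks_per_replicate = 30L,
                          noise_peaks_per_replicate = 0L,
                          replicate_jitter = 0L, share_all_fraction = 1,
                          n_intergenic_alus = 0L)
  b <- generate_bundle(cfg)
  coords <- lapply(b$replicate_peaks, function(gr) {
    cbind(GenomicRanges::start(gr), GenomicRanges::end(gr))
  })
  expect_identical(coords[[1]], coords[[2]])
  expect_identical(coords[[1]], coords[[3]])
  # drop-out peaks appear in exactly two replicates
  cfg2 <- synthetic_config(seed = 4, n_chroms = 1L, chrom_length = 4e5,
                           n_genes = 0L, proximal_fraction = NULL,
                           peaks_per_replicate = 40L,
                           noise_peaks_per_replicate = 0L,
                           share_all_fraction = 0,
                           n_intergenic_alus = 0L)
  b2 <- generate_bundle(cfg2)
  counts <- table(unlist(lapply(b2$replicate_peaks, function(gr) {
    sub("^rep[0-9]+_", "", gr$name)
  })))
  expect_true(all(counts == 2))
})

test_that("accessibility keeps planted domains exposed and the decoy buried", {
  cfg <- quick_config(seed = 12, decoy_interval = c(320L, 345L))
  b <- generate_bundle(cfg)
  for (iv in cfg$planted_dbd_intervals) {
    expect_true(all(b$profile[iv[1]:iv[2]] >= 0.9))
  }
  expect_true(all(b$profile[320:345] < 0.1))
  expect_true(all(b$profile >= 0 & b$profile <= 1))
  expect_equal(length(b$profile), nchar(b$lncrna))
  # masking removes decoy hits but keeps domain hits
  prom <- proximal_windows(b$genes)
  tg <- prom[b$genes$gene_id %in% b$manifest$target_genes]
  h_un <- find_triplex_hits(b$lncrna, tg, b$genome)
  h_m <- find_triplex_hits(mask_rna(b$lncrna, b$profile), tg, b$genome)
  in_decoy <- function(h) sum(h$rna_start <= 345 & h$rna_end >= 320)
  in_a <- function(h) sum(h$rna_start >= 119 & h$rna_end <= 196)
  expect_gt(in_decoy(h_un), 0)
  expect_equal(in_decoy(h_m), 0)
  expect_gt(in_a(h_m), 0)
})

test_that("bundle files round-trip through the standard readers", {
  b <- generate_bundle(quick_config(seed = 14))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  back <- read_bundle(d)
  expect_equal(as.character(back$genome[[1]]), as.character(b$genome[[1]]))
  expect_equal(chartr("T", "U", back$lncrna), chartr("T", "U", b$lncrna))
  expect_equal(back$profile, b$profile)
  expect_equal(back$genes$tss, b$genes$tss)
  expect_equal(length(back$replicate_peaks), 3)
  expect_equal(GenomicRanges::start(back$replicate_peaks$rep1),
               GenomicRanges::start(b$replicate_peaks$rep1))
  expect_equal(back$replicate_peaks$rep2$summit_offset,
               b$replicate_peaks$rep2$summit_offset)
  expect_setequal(names(back$marks), names(b$marks))
})

test_that("region-1 planting shows up as 5'-shifted TSS profile mass", {
  b <- generate_bundle(quick_config(seed = 31))
  cons <- find_consensus_peaks(b$replicate_peaks)
  af <- assign_feature(cons, b$genes)
  prox <- cons[af$category == "Proximal Region"]
  prof <- tss_profile(prox, b$genes, window = 1500, binsize = 100)
  mass_r1 <- sum(prof$count[prof$bin_start >= -1500 & prof$bin_start <= -600])
  mass_r2 <- sum(prof$count[prof$bin_start >= -500 & prof$bin_start <= 400])
  expect_gte(mass_r1, 10 * max(1, mass_r2))
})
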