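test_that("masking replaces low-accessibility bases and nothing else", {
  expect_equal(mask_rna("ACG", c(0.05, 0.50, 0.95), 0.10), "NCG")
  expect_equal(mask_rna("ACGT", rep(0.5, 4), 0), "ACGU")
  expect_error(mask_rna("ACG", c(0.5, 0.5), 0.1), "length")
})

test_that("score_window applies the per-motif triplet tables", {
  expect_equal(score_window("UUUUU", "AAAAA", "pyrimidine_parallel"), 0)
  expect_equal(score_window("GGGGG", "AAAAA", "purine_antiparallel"), 5)
  expect_equal(score_window("GGGGG", "GGGGG", "purine_antiparallel"), 0)
  expect_equal(score_window("GUGUG", "GAGAG", "GT_parallel"), 0)
  expect_equal(score_window("NUUUU", "AAAAA", "pyrimidine_parallel"), 1)
  # antiparallel motifs read the RNA 3'->5'
  expect_equal(score_window("AAGGG", "GGGAA", "purine_antiparallel"), 0)
})

test_that("score_window agrees with a direct table lookup on random pairs", {
  tab <- list(pyrimidine_parallel = c(U = "A", C = "G"),
              purine_antiparallel = c(A = "A", G = "G"),
              GT_parallel = c(G = "G", U = "A"),
              GT_antiparallel = c(G = "G", U = "A"))
  withr::local_seed(17)
  for (i in 1:200) {
    motif <- sample(names(tab), 1)
    r <- sample(c("A", "C", "G", "U"), 30, replace = TRUE)
    d <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
    rr <- if (motif %in% c("purine_antiparallel", "GT_antiparallel")) {
      rev(r)
    } else r
    want <- sum(is.na(tab[[motif]][rr]) | tab[[motif]][rr] != d)
    expect_equal(score_window(paste(r, collapse = ""),
                              paste(d, collapse = ""), motif), want)
  }
})

test_that("find_tts reports maximal purine tracts on both strands", {
  p <- triplex_params(min_length = 15)
  t1 <- find_tts("GGGGAGGGGAGGGGG", p)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$strand, "+")
  expect_equal(t1$length, 15L)
  t2 <- find_tts("CCCCTCCCCTCCCCC", p)
  expect_equal(t2$strand, "-")
  expect_equal(t2$purine_seq, "GGGGGAGGGGAGGGG")
  expect_equal(nrow(find_tts(rand_seq(0) , p)), 0)
})

test_that("find_tts equals the exhaustive all-substring oracle", {
  withr::local_seed(23)
  for (i in 1:60) {
    p <- triplex_params(min_length = sample(c(10L, 12L, 15L), 1),
                        max_error_rate = sample(c(0.1, 0.2), 1))
    dna <- paste(sample(c("A", "G", "C", "T"), sample(80:200, 1), TRUE,
                        prob = c(0.35, 0.3, 0.2, 0.15)), collapse = "")
    impl <- find_tts(dna, p)
    orc <- oracle_tts(dna, p)
    expect_identical(
      sort(sprintf("%s:%d-%d", impl$strand, impl$start, impl$end)),
      sort(sprintf("%s:%d-%d", orc$strand, orc$start, orc$end)))
  }
})

test_that("poly-U RNA against an A-tract yields the textbook hit", {
  p <- triplex_params(min_length = 15, min_guanine_rate = 0,
                      motifs = "pyrimidine_parallel")
  rna <- strrep("U", 15)
  dna <- paste0("CCTCC", strrep("A", 15), "CCTCC")
  h <- find_triplex_hits_seq(rna, dna, p)
  expect_equal(nrow(h), 1)
  expect_equal(h$motif, "pyrimidine_parallel")
  expect_equal(h$length, 15L)
  expect_equal(h$mismatches, 0L)
  expect_equal(c(h$dna_start, h$dna_end), c(6L, 20L))
  # no pyrimidine/purine content at all: no hits
  h0 <- find_triplex_hits_seq(strrep("A", 20), strrep("C", 40),
                              triplex_params(min_guanine_rate = 0))
  expect_equal(nrow(h0), 0)
  expect_warning(find_triplex_hits_seq("ACGU", dna, p), "min_length")
})

test_that("triplex search equals the exhaustive scan oracle", {
  withr::local_seed(29)
  for (i in 1:25) {
    p <- triplex_params(
      min_length = sample(c(12L, 15L), 1),
      max_length = sample(c(20L, 25L), 1),
      max_error_rate = sample(c(0.1, 0.2), 1),
      min_guanine_rate = sample(c(0, 0.1), 1))
    rna <- rand_seq(sample(40:90, 1), c("A", "C", "G", "U"))
    dna <- paste(sample(c("A", "G", "C", "T"), sample(100:250, 1), TRUE,
                        prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
    impl <- find_triplex_hits_seq(rna, dna, p)
    expect_identical(hit_keys(impl), hit_keys(oracle_triplex_hits(rna, dna, p)))
  }
})

test_that("raising min_length never adds hits; masking never adds hits", {
  withr::local_seed(37)
  for (i in 1:10) {
    rna <- rand_seq(120, c("A", "C", "G", "U"))
    dna <- paste(sample(c("A", "G", "C", "T"), 400, TRUE,
                        prob = c(0.33, 0.33, 0.17, 0.17)), collapse = "")
    h15 <- find_triplex_hits_seq(rna, dna, triplex_params(min_length = 15))
    h20 <- find_triplex_hits_seq(rna, dna, triplex_params(min_length = 20))
    expect_lte(nrow(h20), nrow(h15))
    expect_true(all(h20$length >= 20))
    # mask a stretch: the masked run can only lose hits
    prof <- rep(1, 120); prof[30:60] <- 0.01
    hm <- find_triplex_hits_seq(mask_rna(rna, prof), dna,
                                triplex_params(min_length = 15))
    expect_lte(nrow(hm), nrow(h15))
    expect_true(all(!(hm$rna_start >= 30 & hm$rna_end <= 60)))
  }
})

test_that("reverse-complementing the DNA swaps strands but keeps hits", {
  withr::local_seed(41)
  for (i in 1:8) {
    rna <- rand_seq(80, c("A", "C", "G", "U"))
    dna <- paste(sample(c("A", "G", "C", "T"), 200, TRUE,
                        prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]),
                collapse = "")
    h1 <- find_triplex_hits_seq(rna, dna, triplex_params())
    h2 <- find_triplex_hits_seq(rna, rc, triplex_params())
    m <- nchar(dna)
    h2$strand <- ifelse(h2$strand == "+", "-", "+")
    tmp <- m - h2$dna_end + 1
    h2$dna_end <- m - h2$dna_start + 1
    h2$dna_start <- tmp
    expect_identical(hit_keys(h1), hit_keys(h2))
  }
})

test_that("merge_dbds merges TFO intervals across the configured gap", {
  hits <- data.frame(region = c(1, 2, 3),
                     rna_start = c(119, 140, 47), rna_end = c(150, 196, 70))
  d <- merge_dbds(hits, merge_gap = 10)
  expect_equal(nrow(d), 2)
  expect_equal(d$rna_start, c(119, 47))
  expect_equal(d$rna_end, c(196, 70))
  expect_equal(d$n_regions, c(2L, 1L))
  # distant TFOs stay apart
  hits2 <- data.frame(region = 1:2, rna_start = c(47, 119),
                      rna_end = c(70, 196))
  expect_equal(nrow(merge_dbds(hits2, 10)), 2)
  expect_equal(nrow(merge_dbds(hits2, 60)), 1)
})

test_that("region test is exact at the no-TFO and full-separation limits", {
  withr::local_seed(43)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_seq(20000)))
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, 10000, by = 1000), width = 150))
  # all-masked RNA has no TFO: observed 0 everywhere, p = 1
  rt <- region_test(strrep("N", 100), regions, genome,
                    n_randomizations = 19, seed = 1)
  expect_equal(rt$summary$observed[rt$summary$set == "any"], 0)
  expect_equal(rt$summary$p_value[rt$summary$set == "any"], 1)
  expect_equal(nrow(rt$dbds), 0)
})

test_that("promoter test separates planted targets from the rest", {
  b <- generate_bundle(quick_config(seed = 3))
  rna <- mask_rna(b$lncrna, b$profile)
  pt <- promoter_test(rna, b$manifest$target_genes, b$genes, b$genome)
  expect_gt(pt$percent_target, pt$percent_nontarget)
  expect_lt(pt$p_value, 0.05)
  expect_error(promoter_test(rna, character(0), b$genes, b$genome), "empty")
  expect_error(promoter_test(rna, "no_such_gene", b$genes, b$genome),
               "absent")
})
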