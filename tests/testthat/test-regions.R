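test_that("BED6 and narrowPeak parsing follows the half-open convention", {
  f <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tp1\t0\t+", f)
  gr <- read_region_file(f, "bed6")
  expect_equal(GenomicRanges::start(gr), 101)
  expect_equal(GenomicRanges::end(gr), 200)
  expect_equal(GenomicRanges::width(gr), 100)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  expect_equal(gr$name, "p1")

  np <- withr::local_tempfile()
  writeLines("chr1\t100\t200\tpk\t10\t.\t5.5\t12\t8\t50", np)
  gr <- read_region_file(np, "narrowPeak")
  expect_equal(gr$summit_offset, 50L)
  # summit at genomic (0-based) 150 = internal 151
  expect_equal(GenomicRanges::start(gr) + gr$summit_offset, 151)
  expect_equal(gr$signal, 5.5)
})

test_that("malformed region lines raise errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\ta\t0\t+", "chr1\t200\t100\tb\t0\t+"), f)
  expect_error(read_region_file(f, "bed6"), "line 2")
  writeLines(c("chr1\t100\t200\ta\t0"), f)
  expect_error(read_region_file(f, "bed6"), "at least 6")
  expect_error(read_region_file(withr::local_tempfile(fileext = "missing"),
                                "bed6"), "exist")
})

test_that("write/read round-trip is the identity for both dialects", {
  withr::local_seed(11)
  for (dialect in c("bed6", "narrowPeak")) {
    gr <- random_regions(100)
    if (dialect == "narrowPeak") {
      gr$signal <- round(runif(100), 3)
      gr$neglog10_p <- round(runif(100, 1, 40), 3)
      gr$neglog10_q <- round(runif(100, 1, 40), 3)
      gr$summit_offset <- as.integer(
        floor(runif(100) * GenomicRanges::width(gr)))
    }
    f <- withr::local_tempfile()
    write_region_file(gr, f, dialect, header = "round-trip fixture")
    back <- read_region_file(f, dialect)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
    expect_equal(as.character(GenomicRanges::seqnames(back)),
                 as.character(GenomicRanges::seqnames(gr)))
    expect_equal(back$name, gr$name)
    expect_equal(back$score, gr$score)
    if (dialect == "narrowPeak") {
      expect_equal(back$summit_offset, gr$summit_offset)
      expect_equal(back$signal, gr$signal)
    }
  }
})

test_that("empty region sets survive writing and reading", {
  f <- withr::local_tempfile()
  write_region_file(GenomicRanges::GRanges(), f, "bed6")
  expect_length(read_region_file(f, "bed6"), 0)
})

test_that("merge_intervals merges overlap and book-ends, keeps gaps", {
  a <- gr_bed(c("chr1", "chr1"), c(100, 150), c(200, 250))
  m <- merge_intervals(a, 0)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 101)
  expect_equal(GenomicRanges::end(m), 250)
  b <- gr_bed(c("chr1", "chr1"), c(100, 210), c(200, 300))
  expect_length(merge_intervals(b, 0), 2)
  expect_length(merge_intervals(b, 10), 1)
})

test_that("merge_intervals preserves covered bases (per-base oracle)", {
  withr::local_seed(7)
  for (rep in 1:5) {
    gr <- random_regions(200, max_pos = 5000, max_len = 60)
    m <- merge_intervals(gr, 0)
    expect_setequal(unique(oracle_covered_bases(m)),
                    unique(oracle_covered_bases(gr)))
    # pairwise disjoint with gap > 0
    expect_true(all(GenomicRanges::countOverlaps(m, m) == 1))
  }
})

test_that("overlap_count honours half-open boundaries and the quadratic oracle", {
  q <- gr_bed("chr1", 100, 200)
  expect_equal(overlap_count(q, gr_bed("chr1", 199, 300)), 1)
  expect_equal(overlap_count(q, gr_bed("chr1", 200, 300)), 0)
  withr::local_seed(3)
  for (rep in 1:4) {
    q <- random_regions(120, max_pos = 4000, max_len = 80)
    s <- random_regions(120, max_pos = 4000, max_len = 80)
    min_bp <- sample(c(1, 5, 25), 1)
    expect_equal(overlap_count(q, s, min_bp),
                 oracle_overlap_count(q, s, min_bp))
  }
})

test_that("accessibility profiles round-trip and are validated", {
  p <- round(runif(50), 4)
  f <- withr::local_tempfile()
  write_accessibility_profile(p, f, header = "fixture")
  expect_equal(read_accessibility_profile(f), p)
  writeLines(c("1\t0.5", "3\t0.2"), f)
  expect_error(read_accessibility_profile(f), "1..n")
  writeLines(c("1\t0.5", "2\t1.2"), f)
  expect_error(read_accessibility_profile(f), "\\[0,1\\]")
})

test_that("gene tables round-trip with strand-aware TSS", {
  genes <- gene_table(c("gA", "gB"), "chr1", c("+", "-"),
                      tss = c(1001, 9000), gene_end = c(4000, 6001),
                      utr5_len = 200L, utr3_len = 300L)
  f <- withr::local_tempfile()
  write_gene_table(genes, f, header = "fixture")
  back <- read_gene_table(f)
  expect_equal(back$tss, genes$tss)
  expect_equal(back$gene_end, genes$gene_end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$utr5_len, genes$utr5_len)
})
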