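test_that("proximal windows are strand-aware and peaks annotate by priority", {
  genes <- gene_table(c("gP", "gM"), "chr1", c("+", "-"),
                      tss = c(10001, 50000), gene_end = c(14000, 46001))
  # + strand gene at BED TSS 10,000: window [8,500, 10,500)
  w <- proximal_windows(genes)
  expect_equal(GenomicRanges::start(w)[1], 10001 - 1500)
  expect_equal(GenomicRanges::end(w)[1], 10001 + 499)
  # - strand gene: genomic [tss-500+1, tss+1500]
  expect_equal(GenomicRanges::start(w)[2], 50000 - 499)
  expect_equal(GenomicRanges::end(w)[2], 50000 + 1500)

  peaks <- c(gr_bed("chr1", 9000, 9200),    # in + proximal window
             gr_bed("chr1", 50500, 51200),  # in - proximal window
             gr_bed("chr1", 12000, 12200),  # + gene body -> Intron
             gr_bed("chr1", 30000, 30200))  # intergenic
  af <- assign_feature(peaks, genes)
  expect_equal(as.character(af$category),
               c("Proximal Region", "Proximal Region", "Intron",
                 "Distal Intergenic"))
  expect_equal(af$gene_id[1:2], c("gP", "gM"))
})

test_that("proximal beats intron when a peak sits in both", {
  genes <- gene_table(c("gA", "gB"), "chr1", c("+", "+"),
                      tss = c(10001, 8000), gene_end = c(14000, 9600))
  # peak center 9100: proximal window of gA [8501,10500], intron of gB
  af <- assign_feature(gr_bed("chr1", 9000, 9200), genes)
  expect_equal(as.character(af$category), "Proximal Region")
  expect_equal(af$gene_id, "gA")
})

test_that("UTR, exon and downstream categories engage when annotated", {
  genes <- gene_table("g1", "chr1", "+", tss = 10001, gene_end = 20000,
                      utr5_len = 800L, utr3_len = 500L)
  exons <- gr_bed("chr1", 12000, 12500, gene_id = "g1")
  peaks <- c(gr_bed("chr1", 10550, 10650),  # past proximal, inside 5'UTR
             gr_bed("chr1", 19600, 19800),  # 3'UTR
             gr_bed("chr1", 12100, 12300),  # exon
             gr_bed("chr1", 15000, 15100),  # intron
             gr_bed("chr1", 21000, 21200))  # downstream (< 3 kb past end)
  af <- assign_feature(peaks, genes, exons = exons)
  expect_equal(as.character(af$category),
               c("5'UTR", "3'UTR", "Exon", "Intron", "Downstream"))
})

test_that("feature distribution handles degenerate inputs", {
  genes <- gene_table("g1", "chr1", "+", 10001, 14000)
  fd <- feature_distribution(GenomicRanges::GRanges(), genes)
  expect_true(all(fd$count == 0))
  peaks <- gr_bed(rep("chr2", 10), seq(1000, 91000, by = 10000),
                  seq(1200, 91200, by = 10000))
  fd <- feature_distribution(peaks, genes)
  expect_equal(fd$percent[fd$category == "Distal Intergenic"], 100)
  expect_equal(sum(fd$percent), 100)
})

test_that("random region lists are seeded, contained and length-fixed", {
  lens <- c(chr1 = 50000, chr2 = 30000)
  l1 <- sample_random_regions(3, 50, 775, lens, seed = 4)
  l2 <- sample_random_regions(3, 50, 775, lens, seed = 4)
  expect_length(l1, 3)
  expect_identical(l1, l2)
  for (gr in l1) {
    expect_true(all(GenomicRanges::width(gr) == 775))
    expect_true(all(GenomicRanges::end(gr) <=
                      lens[as.character(GenomicRanges::seqnames(gr))]))
  }
})

test_that("proximal-only random regions all annotate as proximal", {
  genes <- gene_table(sprintf("g%d", 1:6), "chr1",
                      rep(c("+", "-"), 3),
                      tss = seq(20000, 120000, by = 20000),
                      gene_end = seq(24000, 124000, by = 20000))
  gr <- sample_random_regions(1, 200, 775, c(chr1 = 2e5), genes,
                              proximal_only = TRUE, seed = 2)[[1]]
  af <- assign_feature(gr, genes)
  expect_true(all(af$category == "Proximal Region"))
  expect_error(sample_random_regions(1, 10, 775, c(chr1 = 2e5),
                                     proximal_only = TRUE, seed = 1),
               "gene table")
})

test_that("chisq_2x2 matches the closed form and flags zero margins", {
  expect_equal(chisq_2x2(10, 90, 10, 90)$statistic, 0)
  expect_equal(chisq_2x2(10, 90, 10, 90)$p_value, 1)
  # closed form N(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(chisq_2x2(30, 70, 10, 90)$statistic, 12.5)
  expect_error(chisq_2x2(0, 0, 5, 5), "margin")
  withr::local_seed(21)
  for (i in 1:200) {
    x <- sample(1:80, 4, replace = TRUE)
    got <- chisq_2x2(x[1], x[2], x[3], x[4])$statistic
    N <- sum(x)
    want <- N * (x[1] * x[4] - x[2] * x[3])^2 /
      ((x[1] + x[2]) * (x[3] + x[4]) * (x[1] + x[3]) * (x[2] + x[4]))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("standard empirical p-value has the add-one form", {
  rf <- (1:1000) / 1000
  expect_equal(empirical_pvalue(2, rf), 1 / 1001)           # above all lists
  expect_equal(empirical_pvalue(stats::median(rf), rf), 501 / 1001)
  expect_equal(empirical_pvalue(0, rf, alternative = "less"), 1 / 1001)
})

test_that("per-list chi-square empirical p follows the 1/k rule", {
  # all 1000 lists wildly different from the observed fraction
  p <- empirical_pvalue(0.5, rep(0.05, 1000), variant = "per_list_chisq",
                        n_observed = 5000, list_size = 5000)
  expect_equal(p, 1 / 1000)
  # no list significantly different
  p <- empirical_pvalue(0.10, rep(0.10, 1000), variant = "per_list_chisq",
                        n_observed = 5000, list_size = 5000)
  expect_equal(p, 1)
})

test_that("tss_profile bins strand-projected peak spans", {
  genes <- gene_table("g1", "chr1", "+", tss = 10001, gene_end = 20000)
  # 100-bp peak centered on the TSS: internal [9951,10050]
  pk <- gr_bed("chr1", 9950, 10050)
  prof <- tss_profile(pk, genes, window = 1000, binsize = 100)
  hit_bins <- prof$bin_start[prof$count > 0]
  expect_setequal(hit_bins, c(-100, 0))
  expect_equal(sum(prof$count), 2)
  empty <- tss_profile(GenomicRanges::GRanges(), genes, 1000, 100)
  expect_true(all(empty$count == 0))
  # minus-strand gene: downstream peak appears on the negative axis
  gm <- gene_table("gm", "chr1", "-", tss = 10000, gene_end = 5001)
  pk2 <- gr_bed("chr1", 10100, 10200)  # internal [10101,10200], rel [-200,-101]
  prof2 <- tss_profile(pk2, gm, window = 1000, binsize = 100)
  expect_setequal(prof2$bin_start[prof2$count > 0], -200)
})

test_that("cutpeaks split exactly at the region boundary", {
  genes <- gene_table("g1", "chr1", "+", tss = 10001, gene_end = 20000)
  # BED peak [9300, 9700): straddles the region1/region2 boundary (9500)
  pk <- gr_bed("chr1", 9300, 9700)
  c1 <- cut_peaks(pk, genes, "region1")
  c2 <- cut_peaks(pk, genes, "region2")
  expect_equal(GenomicRanges::start(c1), 9301)
  expect_equal(GenomicRanges::end(c1), 9500)
  expect_equal(GenomicRanges::start(c2), 9501)
  expect_equal(GenomicRanges::end(c2), 9700)
  # fully region1 peak is dropped from region2
  pk2 <- gr_bed("chr1", 8700, 9300)
  expect_equal(GenomicRanges::start(cut_peaks(pk2, genes, "region1")), 8701)
  expect_length(cut_peaks(pk2, genes, "region2"), 0)
})

test_that("region1 and region2 cutpeaks tile the proximal intersection", {
  withr::local_seed(31)
  genes <- gene_table(sprintf("g%d", 1:8), "chr1",
                      sample(c("+", "-"), 8, TRUE),
                      tss = seq(20000, 160000, by = 20000),
                      gene_end = seq(26000, 166000, by = 20000))
  centers <- genes$tss + sample(-1300:300, 8)
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(centers - 400,
                                                   centers + 400))
  asn <- assign_feature(peaks, genes)
  prox_idx <- which(asn$category == "Proximal Region")
  c1 <- cut_peaks(peaks, genes, "region1", assignment = asn)
  c2 <- cut_peaks(peaks, genes, "region2", assignment = asn)
  both <- c(c1, c2)
  # no double-covered base and full coverage of peak-window intersections
  expect_true(all(GenomicRanges::countOverlaps(both, both) == 1))
  prox_cover <- GenomicRanges::intersect(
    merge_intervals(peaks[prox_idx]),
    merge_intervals(proximal_windows(genes)))
  expect_setequal(oracle_covered_bases(both), oracle_covered_bases(prox_cover))
})

test_that("overlap classes follow the region-2 geometry", {
  genes <- gene_table("g1", "chr1", "+", tss = 10001, gene_end = 20000)
  peaks <- c(gr_bed("chr1", 9200, 10600),  # covers region2 -> includeFeature
             gr_bed("chr1", 9200, 9900),   # ends inside -> overlapStart
             gr_bed("chr1", 9600, 10300),  # inside
             gr_bed("chr1", 10200, 10700), # overlapEnd
             gr_bed("chr1", 8600, 9400))   # region1 only
  cls <- classify_overlap(peaks, genes)
  expect_equal(as.character(cls$classes$class),
               c("includeFeature", "overlapStart", "inside", "overlapEnd",
                 "region1_only"))
  expect_equal(sum(cls$distribution$percent), 100)
})
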