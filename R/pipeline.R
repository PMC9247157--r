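#' Configuration for the end-to-end pipeline
#'
#' A single seeded configuration drives simulate -> consensus -> annotate
#' -> triplex -> enrich -> co-occurrence.  Per-stage seeds are derived from
#' the global seed by fixed offsets so any stage can be rerun in isolation.
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param synthetic a [synthetic_config()]; its seed is overridden by
#'   `seed`.
#' @param consensus a [consensus_params()].
#' @param scheme a [region_scheme()].
#' @param triplex a [triplex_params()].
#' @param n_random_lists,random_list_size random-region lists for the
#'   annotation null (desk-scaled defaults; the study used 1,000 lists of
#'   5,000).
#' @param n_randomizations randomizations of the triplex region test.
#' @param bin_size gene bin size of the co-occurrence table.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("triplexchirp_"),
                            synthetic = synthetic_config(),
                            consensus = consensus_params(),
                            scheme = region_scheme(),
                            triplex = triplex_params(),
                            n_random_lists = 50L,
                            random_list_size = 1000L,
                            n_randomizations = 50L,
                            bin_size = 5L) {
  synthetic$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 synthetic = synthetic, consensus = consensus,
                 scheme = scheme, triplex = triplex,
                 n_random_lists = as.integer(n_random_lists),
                 random_list_size = as.integer(random_list_size),
                 n_randomizations = as.integer(n_randomizations),
                 bin_size = as.integer(bin_size)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `seed`, `out_dir`, `n_random_lists`, `random_list_size`,
#' `n_randomizations`, `bin_size` and nested `synthetic`, `consensus`,
#' `triplex` blocks override the corresponding [pipeline_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  cns <- do.call(consensus_params, y$consensus %||% list())
  trx <- do.call(triplex_params, y$triplex %||% list())
  args <- y[setdiff(names(y), c("synthetic", "consensus", "triplex"))]
  do.call(pipeline_config,
          c(args, list(synthetic = syn, consensus = cns, triplex = trx)))
}

.stage_seed <- function(config, offset) {
  (config$seed + offset * 10007L) %% .Machine$integer.max
}

.provenance <- function(config) {
  sprintf("triplexChIRP %s seed=%d",
          as.character(utils::packageVersion("triplexChIRP")), config$seed)
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Generates the bundle, writes it to disk, reads it back through the
#' standard-format readers, and runs every analysis stage in order,
#' writing per-stage outputs plus a `report.json` aggregating the headline
#' numbers (feature distribution, chi-square and empirical p-values,
#' region-test summary, enrichment odds ratios, co-occurrence trend).
#' Byte-identical outputs for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return The report, invisibly (a list).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(config)
  report <- list(seed = config$seed,
                 version = as.character(
                   utils::packageVersion("triplexChIRP")))

  ## stage 1: simulate ------------------------------------------------------
  bundle <- generate_bundle(config$synthetic)
  bdir <- file.path(out, "bundle")
  write_bundle(bundle, bdir)
  data <- read_bundle(bdir)

  ## stage 2: consensus -----------------------------------------------------
  cons <- find_consensus_peaks(data$replicate_peaks, config$consensus)
  write_region_file(cons, file.path(out, "consensus.bed"), "bed6",
                    header = hdr)
  report$consensus <- list(n_peaks = length(cons),
                           mean_width = round(mean(
                             GenomicRanges::width(cons)), 1))

  ## stage 3: annotate ------------------------------------------------------
  genes <- data$genes
  assignment <- assign_feature(cons, genes, config$scheme, data$exons)
  dist <- feature_distribution(cons, genes, config$scheme, data$exons)
  write.table(dist, file.path(out, "feature_distribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rand <- sample_random_regions(config$n_random_lists,
                                config$random_list_size,
                                peak_length = round(mean(
                                  GenomicRanges::width(cons))),
                                genome = data$genome,
                                seed = .stage_seed(config, 3L))
  prox_frac <- function(gr) {
    mean(assign_feature(gr, genes, config$scheme)$category ==
           "Proximal Region")
  }
  obs_frac <- dist$percent[dist$category == "Proximal Region"] / 100
  rand_fracs <- vapply(rand, prox_frac, numeric(1))
  avg_rand <- mean(rand_fracs)
  n_obs <- length(cons)
  chi <- chisq_2x2(round(obs_frac * n_obs), n_obs - round(obs_frac * n_obs),
                   round(avg_rand * config$random_list_size),
                   config$random_list_size -
                     round(avg_rand * config$random_list_size))
  emp <- empirical_pvalue(obs_frac, rand_fracs, "standard", "greater")
  profile_df <- tss_profile(cons, genes)
  write.table(profile_df, file.path(out, "tss_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cp1 <- cut_peaks(cons, genes, "region1", config$scheme, assignment)
  cp2 <- cut_peaks(cons, genes, "region2", config$scheme, assignment)
  write_region_file(cp1, file.path(out, "cutpeaks_region1.bed"), "bed6",
                    header = hdr)
  write_region_file(cp2, file.path(out, "cutpeaks_region2.bed"), "bed6",
                    header = hdr)
  ovl <- classify_overlap(cons, genes, config$scheme, assignment)
  write.table(ovl$distribution, file.path(out, "overlap_classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$annotate <- list(
    proximal_percent = 100 * obs_frac,
    random_proximal_percent = 100 * avg_rand,
    fold_enrichment = obs_frac / avg_rand,
    chisq_p = chi$p_value,
    empirical_p = emp,
    overlap_percent = setNames(ovl$distribution$percent,
                               as.character(ovl$distribution$class)))

  ## stage 4: triplex -------------------------------------------------------
  rna_masked <- mask_rna(data$lncrna, data$profile,
                         config$triplex$ss_prob_threshold)
  prox_peaks <- cons[assignment$category == "Proximal Region"]
  rt <- region_test(rna_masked, prox_peaks, data$genome, config$triplex,
                    n_randomizations = config$n_randomizations,
                    seed = .stage_seed(config, 4L))
  write.table(rt$summary, file.path(out, "region_test.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rt$dbds, file.path(out, "dbd_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dbs <- if (nrow(rt$hits) > 0) {
    gr <- GenomicRanges::GRanges(rt$hits$chrom,
                                 IRanges::IRanges(rt$hits$dna_start,
                                                  rt$hits$dna_end),
                                 strand = rt$hits$strand)
    gr$name <- sprintf("DBS_%d", seq_along(gr))
    gr$peak <- rt$hits$region
    gr
  } else GenomicRanges::GRanges()
  write_region_file(dbs, file.path(out, "dbs.bed"), "bed6", header = hdr)
  report$triplex <- list(
    n_hits = nrow(rt$hits),
    n_dbds = nrow(rt$dbds),
    dbd_table = rt$dbds,
    region_test = rt$summary)

  ## stage 5: enrichment ----------------------------------------------------
  triplex_flags <- seq_along(prox_peaks) %in% rt$hits$region
  dbs_tab <- data.frame(peak = seq_along(prox_peaks),
                        name = prox_peaks$name, triplex = triplex_flags)
  write.table(dbs_tab, file.path(out, "triplex_flags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  enr <- list()
  dbl <- c(list(Alu = data$alu), data$marks)
  if (any(triplex_flags) && !all(triplex_flags)) {
    for (nm in names(dbl)) {
      s <- stratified_or_ratio(prox_peaks, triplex_flags, dbl[[nm]],
                               db_name = nm, haldane = TRUE)
      enr[[nm]] <- data.frame(db = nm, ratio = s$ratio,
                              or_triplex = s$or_triplex,
                              or_triplexless = s$or_triplexless)
    }
  }
  enr_df <- if (length(enr) > 0) do.call(rbind, enr) else
    data.frame(db = character(0), ratio = numeric(0),
               or_triplex = numeric(0), or_triplexless = numeric(0))
  write.table(enr_df, file.path(out, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$enrichment <- enr_df

  ## stage 6: co-occurrence -------------------------------------------------
  cooc <- NULL
  if (length(dbs) > 0) {
    dd <- dbs_alu_distance(prox_peaks, dbs, data$alu)
    write.table(dd$records, file.path(out, "dbs_alu_distance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gene_flags <- .gene_level_flags(genes, dbs, data$alu, config$scheme)
    fc <- .synthetic_fold_changes(genes, gene_flags,
                                  seed = .stage_seed(config, 6L))
    tab <- triplex_alu_table(genes$gene_id, gene_flags$has_dbs,
                             gene_flags$has_alu, fc, config$bin_size)
    write.table(tab, file.path(out, "triplex_alu_bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jt <- jonckheere_terpstra(attr(tab, "indicator_by_bin"), "decreasing")
    cooc <- list(fraction_dbs_near_alu = dd$summary$fraction_near,
                 median_gap = dd$summary$median_gap,
                 jt_statistic = jt$statistic, jt_p = jt$p_value)
  }
  report$cooccurrence <- cooc

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(report)
}

# Promoter-level DBS / Alu indicators per gene.
.gene_level_flags <- function(genes, dbs, alu, scheme) {
  prom <- proximal_windows(genes, scheme)
  data.frame(gene_id = genes$gene_id,
             has_dbs = overlaps_any(prom, dbs),
             has_alu = overlaps_any(prom, alu))
}

# Fold changes coupled to the triplex+Alu indicator, emulating expression
# modulation that is strongest for directly bound (triplex+Alu) genes.
.synthetic_fold_changes <- function(genes, flags, seed = 1L) {
  withr::with_seed(seed, {
    both <- flags$has_dbs & flags$has_alu
    abs_fc <- ifelse(both, stats::rexp(nrow(genes), 1 / 3) + 1,
                     stats::rexp(nrow(genes), 1) + 0.2)
    sign <- sample(c(-1, 1), nrow(genes), replace = TRUE)
    sign * abs_fc
  })
}
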