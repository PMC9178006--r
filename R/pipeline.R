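#' Pipeline configuration with study defaults
#'
#' Bundles every tunable parameter of the synthetic end-to-end run.
#' Defaults follow the analysis conventions baked into the individual
#' modules: 1 kb bins advanced by 200 bp, TSS +/- 2 kb promoters, peak
#' quality filters RPKM >= 1 and width >= 800 bp at q <= 0.05,
#' differential thresholds q < 0.05 and |log2FC| > 1, fold-change 3 for
#' ZGA and transcript calls, and k in {4, 5} for co-occupancy clustering.
#'
#' @param ... Named overrides of any default listed in the function body.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # genome / truth
    n_chrom = 3, chrom_length = 5e6, n_genes = 300, gene_length = 2000,
    n_marked_gv = 150, mii_loss = 0.9, cko_mii_loss = 0,
    twocell_off_frac = 0.2, n_zga = 60, sensitive_frac = 0.5,
    n_k4 = 150, k27_given_ub = 0.7, k27_base = 0.1,
    # reads
    depth = 5e5, background_fraction = NULL, enrichment = 20,
    domain_width = 4000, read_length = 50, dup_rate = 0.1, n_reps = 3,
    # signal
    binsize = 1000, stepsize = 200, flank = 2000,
    random_n = 10000, random_length = 5000,
    # peaks
    peak_q = 0.05, merge_gap = 1000, min_rpkm = 1, min_width = 800,
    # differential
    diff_q = 0.05, diff_lfc = 1, min_count = 1,
    # expression
    noise_sd = 0.2, zga_fc = 3, transcript_fc = 3,
    # clustering / metaplot / qpcr
    k_marks = 4, k_with_ub = 5, restarts = 10, window = 5000,
    qpcr_true_ratio = 5, qpcr_efficiencies = c(1, 1), qpcr_noise_sd = 0,
    # reproducibility
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges without throwing; violations are returned as a
#' tibble so callers can report them all at once.
#'
#' @param config A `pipeline_config`.
#' @return A tibble (`field`, `message`); zero rows when valid.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, message) {
    v[[length(v) + 1]] <<- tibble(field = field, message = message)
  }
  if (config$stepsize > config$binsize) {
    bad("stepsize", "stepsize must not exceed binsize")
  }
  if (config$flank <= 0) bad("flank", "flank must be positive")
  if (!is.null(config$background_fraction) &&
      (config$background_fraction < 0 || config$background_fraction > 1)) {
    bad("background_fraction", "must lie in [0, 1]")
  }
  if (config$mii_loss < 0 || config$mii_loss > 1) {
    bad("mii_loss", "must lie in [0, 1]")
  }
  if (config$cko_mii_loss > config$mii_loss) {
    bad("cko_mii_loss", "cKO cannot lose more genes than WT (retention model)")
  }
  if (config$depth <= 0) bad("depth", "depth must be positive")
  if (config$n_reps < 2) bad("n_reps", "need >= 2 replicates per condition")
  if (config$peak_q <= 0 || config$peak_q > 1) bad("peak_q", "q in (0, 1]")
  if (config$min_width < 0) bad("min_width", "must be non-negative")
  if (config$zga_fc <= 0) bad("zga_fc", "must be positive")
  for (k in c("k_marks", "k_with_ub")) {
    if (config[[k]] < 2) bad(k, "k must be at least 2")
  }
  if (length(v) == 0) {
    tibble(field = character(0), message = character(0))
  } else {
    bind_rows(v)
  }
}

# deterministic per-stage seeds derived from the root seed
stage_seed_ <- function(seed, stage_index) {
  (as.integer(seed) * 1000L + stage_index * 97L) %% .Machine$integer.max
}

#' Simulate the full synthetic study
#'
#' Generates a genome, planted truth, one read set per ChIP condition and
#' replicate (H2AK119ub1 in GV/MII/two-cell wild type and MII cKO;
#' H3K4me3 and H3K27me3 in GV), an FPKM table, and a qPCR Ct table.
#'
#' @param config A `pipeline_config`.
#' @return A list: `ann`, `truth`, `read_sets` (named list), `expression`,
#'   `qpcr`, `config`.
#' @export
simulate_study <- function(config = pipeline_config()) {
  ann <- simulate_genome(config$n_chrom, config$chrom_length,
                         config$n_genes, config$gene_length, config$flank,
                         seed = stage_seed_(config$seed, 1L))
  truth <- simulate_truth(ann,
                          n_marked_gv = config$n_marked_gv,
                          mii_loss = config$mii_loss,
                          cko_mii_loss = config$cko_mii_loss,
                          twocell_off_frac = config$twocell_off_frac,
                          n_zga = config$n_zga,
                          sensitive_frac = config$sensitive_frac,
                          n_k4 = config$n_k4,
                          k27_given_ub = config$k27_given_ub,
                          k27_base = config$k27_base,
                          seed = stage_seed_(config$seed, 2L))
  conditions <- list(
    list(mark = "H2AK119ub1", stage = "GV", genotype = "WT",
         reps = config$n_reps),
    list(mark = "H2AK119ub1", stage = "MII", genotype = "WT",
         reps = config$n_reps),
    list(mark = "H2AK119ub1", stage = "twocell", genotype = "WT",
         reps = config$n_reps),
    list(mark = "H2AK119ub1", stage = "MII", genotype = "cKO",
         reps = config$n_reps),
    list(mark = "H3K4me3", stage = "GV", genotype = "WT", reps = 1L),
    list(mark = "H3K27me3", stage = "GV", genotype = "WT", reps = 1L)
  )
  read_sets <- list()
  idx <- 10L
  for (cond in conditions) {
    marked <- marked_genes(truth, cond$mark, cond$stage, cond$genotype)
    width <- switch(cond$mark, H3K4me3 = config$domain_width / 4,
                    H3K27me3 = config$domain_width * 1.5,
                    config$domain_width)
    for (r in seq_len(cond$reps)) {
      idx <- idx + 1L
      id <- sprintf("%s_%s_%s_r%d", cond$mark, cond$stage, cond$genotype, r)
      read_sets[[id]] <- simulate_reads(
        ann, marked, depth = config$depth,
        background_fraction = config$background_fraction,
        enrichment = config$enrichment, domain_width = width,
        read_length = config$read_length, dup_rate = config$dup_rate,
        seed = stage_seed_(config$seed, idx),
        stage = cond$stage, genotype = cond$genotype, mark = cond$mark,
        replicate = r)
    }
  }
  expression <- simulate_expression(ann, truth, noise_sd = config$noise_sd,
                                    n_reps = config$n_reps,
                                    seed = stage_seed_(config$seed, 3L))
  qpcr <- simulate_qpcr(true_ratio = config$qpcr_true_ratio,
                        efficiencies = config$qpcr_efficiencies,
                        noise_sd = config$qpcr_noise_sd,
                        seed = stage_seed_(config$seed, 4L))
  list(ann = ann, truth = truth, read_sets = read_sets,
       expression = expression, qpcr = qpcr, config = config)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> signal -> peaks -> promoter differential ->
#' co-occupancy clustering -> expression gene sets -> metaplots -> qPCR,
#' optionally writing every table (TSV/BED/bedGraph/JSON) plus a run
#' manifest to `out_dir`. With the same config (including its seed) the
#' tabular outputs are byte-identical across runs.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created); `NULL` skips file output.
#' @return A list of in-memory results: `study`, `tracks` (normalized),
#'   `peaks`, `peak_annotation`, `diff` (three contrasts), `catalog`,
#'   `clusters4`, `clusters5`, `cluster_expression`, `zga`,
#'   `transcripts`, `zga_overlap`, `sensitivity`, `profiles`, `qpcr`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  viol <- validate_config(config)
  if (nrow(viol) > 0) {
    abort(paste0("invalid config: ",
                 paste(viol$field, viol$message, sep = ": ",
                       collapse = "; ")))
  }
  study <- simulate_study(config)
  ann <- study$ann
  truth <- study$truth

  # --- signal stage -------------------------------------------------------
  grid <- bin_grid(ann, config$binsize, config$stepsize)
  regions <- sample_random_regions(ann, n = config$random_n,
                                   length = config$random_length,
                                   seed = stage_seed_(config$seed, 5L))
  dedup <- purrr::map(study$read_sets, deduplicate_reads)
  tracks <- purrr::map(dedup, build_track, grid = grid, dedup = FALSE)
  is_ub <- purrr::map_lgl(tracks, function(t) {
    identical(attr(t, "meta")$mark, "H2AK119ub1")
  })
  tracks[is_ub] <- background_normalize(tracks[is_ub], regions)

  # --- peaks --------------------------------------------------------------
  rep1 <- names(tracks)[grepl("_r1$", names(tracks)) & is_ub]
  peaks <- purrr::map(tracks[rep1], function(t) {
    filter_peaks(call_broad_peaks(t, regions = regions,
                                  q_threshold = config$peak_q,
                                  merge_gap = config$merge_gap),
                 min_rpkm = config$min_rpkm, min_width = config$min_width)
  })
  peak_annotation <- purrr::imap(peaks, function(p, id) {
    mutate(annotate_peaks(p, ann, zone = config$flank), sample_id = id)
  }) |> bind_rows()

  # --- promoter differential ---------------------------------------------
  promoters <- promoters_of(ann, flank = config$flank)
  ub_ids <- names(dedup)[is_ub]
  mat <- promoter_counts(dedup[ub_ids], promoters)
  scales <- purrr::map_dbl(tracks[ub_ids],
                           function(t) attr(t, "background_scale"))
  mat <- set_background_scales(mat, scales)
  sf <- background_size_factors(mat)
  grp <- function(stage, genotype) {
    s <- promoter_samples(mat)
    s$sample_id[s$stage == stage & s$genotype == genotype]
  }
  diff <- list(
    gv_vs_mii = nb_wald_test(mat, grp("GV", "WT"), grp("MII", "WT"),
                             size_factors = sf, min_count = config$min_count,
                             q_cutoff = config$diff_q,
                             lfc_cutoff = config$diff_lfc),
    gv_vs_twocell = nb_wald_test(mat, grp("GV", "WT"), grp("twocell", "WT"),
                                 size_factors = sf,
                                 min_count = config$min_count,
                                 q_cutoff = config$diff_q,
                                 lfc_cutoff = config$diff_lfc),
    wt_vs_cko_mii = nb_wald_test(mat, grp("MII", "WT"), grp("MII", "cKO"),
                                 size_factors = sf,
                                 min_count = config$min_count,
                                 q_cutoff = config$diff_q,
                                 lfc_cutoff = config$diff_lfc)
  )
  catalog <- derive_ub_gene_sets(diff$gv_vs_mii, diff$gv_vs_twocell,
                                 diff$wt_vs_cko_mii,
                                 q_cutoff = config$diff_q,
                                 lfc_cutoff = config$diff_lfc)

  # --- co-occupancy clustering -------------------------------------------
  rpkm <- promoter_rpkm(mat)
  mark_track_rpkm <- function(id) {
    pm <- promoter_counts(dedup[id], promoters)
    promoter_rpkm(pm)[, c("gene_id", id)]
  }
  k4 <- mark_track_rpkm("H3K4me3_GV_WT_r1")
  k27 <- mark_track_rpkm("H3K27me3_GV_WT_r1")
  ub_gv <- rpkm[, c("gene_id", "H2AK119ub1_GV_WT_r1")]
  feats2 <- build_feature_matrix(list(H3K4me3 = k4, H3K27me3 = k27))
  feats3 <- build_feature_matrix(list(H3K4me3 = k4, H3K27me3 = k27,
                                      H2AK119ub1 = ub_gv))
  clusters4 <- kmeans_promoters(feats2, k = config$k_marks,
                                seed = stage_seed_(config$seed, 6L),
                                restarts = config$restarts)
  clusters5 <- kmeans_promoters(feats3, k = config$k_with_ub,
                                seed = stage_seed_(config$seed, 7L),
                                restarts = config$restarts)

  # --- expression gene sets ----------------------------------------------
  floored <- floor_fpkm(study$expression)
  zga <- define_zga(floored, fc_threshold = config$zga_fc)
  transcripts <- differential_transcripts(floored,
                                          fc_threshold = config$transcript_fc)
  zga_overlap <- overlap_with_zga(transcripts$down, zga)
  sensitivity <- classify_zga_sensitivity(zga, transcripts$down)
  cluster_expression <- cluster_expression_summary(clusters5, floored,
                                                   stage = "GV",
                                                   genotype = "WT")
  down_enrichment <- geneset_cluster_enrichment(clusters5, transcripts$down)

  # --- metaplots ----------------------------------------------------------
  rand_genes <- sample_random_genes(ann, length(zga),
                                    seed = stage_seed_(config$seed, 8L))
  profile_tracks <- c("H2AK119ub1_GV_WT_r1", "H2AK119ub1_MII_WT_r1",
                      "H2AK119ub1_twocell_WT_r1")
  profiles <- purrr::map(setNames(profile_tracks, profile_tracks),
                         function(id) {
    list(zga = tss_profile(tracks[[id]], zga, ann, window = config$window),
         random = tss_profile(tracks[[id]], rand_genes, ann,
                              window = config$window))
  })

  # --- qPCR ---------------------------------------------------------------
  qpcr <- qpcr_ratios(study$qpcr)

  result <- list(study = study, tracks = tracks, peaks = peaks,
                 peak_annotation = peak_annotation, diff = diff,
                 catalog = catalog, clusters4 = clusters4,
                 clusters5 = clusters5,
                 cluster_expression = cluster_expression,
                 down_enrichment = down_enrichment,
                 zga = zga, transcripts = transcripts,
                 zga_overlap = zga_overlap, sensitivity = sensitivity,
                 profiles = profiles, qpcr = qpcr)
  if (!is.null(out_dir)) {
    write_pipeline_outputs_(result, config, out_dir)
  }
  result
}

write_pipeline_outputs_ <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_annotation(result$study$ann, p("annotation.tsv"))
  write_expression(result$study$expression, p("expression_fpkm.tsv"))
  mat <- NULL
  samples <- purrr::imap(result$tracks, function(t, id) {
    m <- attr(t, "meta")
    tibble(sample_id = id, stage = m$stage, genotype = m$genotype,
           mark = m$mark, replicate = m$replicate,
           total_reads = attr(t, "total_reads"),
           background_scale = attr(t, "background_scale"))
  }) |> bind_rows()
  readr::write_tsv(samples, p("sample_sheet.tsv"))
  for (id in names(result$tracks)) {
    if (grepl("_r1$", id)) {
      write_bedgraph(result$tracks[[id]], p(sprintf("track_%s.bedGraph", id)))
    }
  }
  for (id in names(result$peaks)) {
    pk <- result$peaks[[id]]
    write_bed(tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                     name = pk$name, score = round(pk$mean_rpkm, 4),
                     strand = "."),
              p(sprintf("peaks_%s.bed", id)))
  }
  readr::write_tsv(result$peak_annotation, p("peak_categories.tsv"))
  for (nm in names(result$diff)) {
    readr::write_tsv(as_tibble(result$diff[[nm]]),
                     p(sprintf("diff_%s.tsv", nm)))
  }
  readr::write_tsv(as_tibble(result$catalog), p("gene_sets.tsv"))
  readr::write_tsv(set_venn(result$catalog), p("gene_set_venn.tsv"))
  readr::write_tsv(result$clusters4$assignment, p("clusters_k4.tsv"))
  readr::write_tsv(result$clusters5$assignment, p("clusters_k5.tsv"))
  readr::write_tsv(result$cluster_expression, p("cluster_expression.tsv"))
  readr::write_tsv(result$down_enrichment, p("cluster_down_enrichment.tsv"))
  readr::write_tsv(tibble(gene_id = result$zga), p("zga_genes.tsv"))
  readr::write_tsv(tibble(gene_id = result$transcripts$up),
                   p("cko_up_transcripts.tsv"))
  readr::write_tsv(tibble(gene_id = result$transcripts$down),
                   p("cko_down_transcripts.tsv"))
  readr::write_tsv(tibble(gene_id = result$sensitivity$sensitive),
                   p("zga_usp16_sensitive.tsv"))
  readr::write_tsv(tibble(gene_id = result$sensitivity$insensitive),
                   p("zga_usp16_insensitive.tsv"))
  jsonlite::write_json(result$zga_overlap$venn, p("zga_overlap.json"),
                       auto_unbox = TRUE)
  for (id in names(result$profiles)) {
    readr::write_tsv(as_tibble(result$profiles[[id]]$zga),
                     p(sprintf("metaprofile_zga_%s.tsv", id)))
    readr::write_tsv(as_tibble(result$profiles[[id]]$random),
                     p(sprintf("metaprofile_random_%s.tsv", id)))
  }
  readr::write_tsv(result$qpcr, p("qpcr_ratios.tsv"))
  manifest <- list(
    package = "catchub",
    version = as.character(utils::packageVersion("catchub")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    files = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
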