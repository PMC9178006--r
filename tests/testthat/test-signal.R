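test_that("deduplication keeps one read per coordinate tuple,
           order-independently", {
  r <- tibble::tibble(chrom = "chr1",
                      start = c(100, 100, 100, 300),
                      end = c(150, 150, 150, 350),
                      strand = "+")
  expect_equal(nrow(deduplicate_reads(r)), 2)
  shuffled <- r[c(3, 1, 4, 2), ]
  expect_identical(tibble::as_tibble(deduplicate_reads(r)),
                   tibble::as_tibble(deduplicate_reads(shuffled)))
  # no duplicates: identity (up to sort order)
  clean <- tibble::tibble(chrom = "chr1", start = 1:10 * 100,
                          end = 1:10 * 100 + 50, strand = "+")
  expect_equal(nrow(deduplicate_reads(clean)), 10)

  # simulated duplicate rate: recount matches the distinct-site oracle
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 1)
  rs <- simulate_reads(ann, character(0), depth = 1e5,
                       background_fraction = 1, dup_rate = 0.1, seed = 2)
  oracle <- nrow(unique(as.data.frame(rs)[c("chrom", "start", "end",
                                            "strand")]))
  expect_equal(nrow(deduplicate_reads(rs)), oracle)
})

test_that("sliding tiles count read midpoints with overlap sharing", {
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 0, end = 100),
    tibble::tibble(chrom = "chr1", length = 10000))
  grid <- bin_grid(ann, binsize = 1000, stepsize = 200)
  tr <- bin_counts(reads_at(1100), grid)
  # brute-force oracle: all tiles whose [start, start+1000) contains 1100
  expected <- as.integer(tr$start <= 1100 & 1100 < tr$start + 1000)
  expect_equal(tr$count, expected)
  expect_equal(tr$start[tr$count == 1], seq(200, 1000, 200))

  # empty read set
  empty <- bin_counts(reads_at(numeric(0)), grid)
  expect_true(all(empty$count == 0))

  # non-overlapping grid: one tile holds everything
  grid1 <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  tr1 <- bin_counts(reads_at(c(2100, 2200, 2900)), grid1)
  expect_equal(tr1$count[tr1$start == 2000], 3)
  expect_equal(sum(tr1$count), 3)

  # decimated tile sums conserve the total read count
  r <- reads_at(sort(sample.int(9000, 500)) + 100)
  tr2 <- bin_counts(r, grid)
  decimated <- tr2[tr2$start %% 1000 == 0, ]
  expect_equal(sum(decimated$count), 500)
})

test_that("RPKM follows its definition and is scale invariant", {
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 0, end = 100),
    tibble::tibble(chrom = "chr1", length = 5000))
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  tr <- bin_counts(reads_at(rep(500, 10)), grid)
  expect_equal(rpkm_track(tr, total_reads = 1e6)$value[1], 10)
  expect_equal(rpkm_track(tr, total_reads = 5e5)$value[1], 20)
  # doubling counts and depth together leaves RPKM unchanged
  tr2 <- bin_counts(reads_at(c(rep(500, 20))), grid)
  expect_equal(rpkm_track(tr2, total_reads = 2e6)$value,
               rpkm_track(tr, total_reads = 1e6)$value)
  expect_error(rpkm_track(tr, total_reads = 0), "positive")
})

test_that("background normalization equalizes backgrounds and is
           idempotent", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 1e6, n_genes = 10,
                         seed = 1)
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  rs <- simulate_reads(ann, character(0), depth = 5e4,
                       background_fraction = 1, dup_rate = 0, seed = 2)
  t1 <- build_track(rs, grid)
  t2 <- t1
  t2$value <- t2$value * 2   # global 2x efficiency factor
  regions <- sample_random_regions(ann, n = 200, length = 5000, seed = 3)
  norm <- background_normalize(list(a = t1, b = t2), regions)
  expect_equal(attr(norm$b, "background_scale"), 0.5)
  expect_equal(norm$b$value, norm$a$value, tolerance = 1e-9)
  # already-equal tracks: scales 1
  norm2 <- background_normalize(norm, regions)
  expect_equal(attr(norm2$a, "background_scale"),
               attr(norm$a, "background_scale"))
  expect_equal(norm2$b$value, norm$b$value)
  # error paths
  zero <- t1
  zero$value <- 0
  expect_error(background_normalize(list(a = t1, b = zero), regions),
               "zero background")
  expect_error(background_normalize(list(a = t1), regions), "at least 2")
})

test_that("normalization preserves cross-stage promoter-signal ratios", {
  ann <- simulate_genome(seed = 1)
  truth <- simulate_truth(ann, seed = 1)
  gv_marked <- marked_genes(truth, stage = "GV")
  grid <- bin_grid(ann)
  # same background level, GV-only promoter signal, MII sampled deeper;
  # duplicate-free reads, no dedup, so counts follow the generator exactly
  gv <- build_track(simulate_reads(ann, gv_marked, depth = 3e5,
                                   background_fraction = 0.7, dup_rate = 0,
                                   seed = 4), grid, dedup = FALSE)
  mii <- build_track(simulate_reads(ann, character(0), depth = 6e5,
                                    background_fraction = 1, dup_rate = 0,
                                    seed = 5), grid, dedup = FALSE)
  regions <- sample_random_regions(ann, n = 2000, length = 5000, seed = 6)
  norm <- background_normalize(list(gv = gv, mii = mii), regions)
  # interior promoter tiles only, so every counted tile lies fully inside
  # the planted 4 kb domain
  proms <- promoters_of(ann, flank = 1400)
  proms <- proms[proms$gene_id %in% gv_marked, ]
  in_prom <- catchub:::points_in_regions_(norm$gv$chrom,
                                          norm$gv$start + 500, proms)
  ratio <- mean(norm$gv$value[in_prom]) / mean(norm$mii$value[in_prom])
  # truth: GV promoter rate = background + signal, MII = background only
  bg_per_bp <- 0.7 * 3e5 / sum(chromosomes(ann)$length)
  sig_per_bp <- 0.3 * 3e5 / (length(gv_marked) * 4000)
  expected <- (bg_per_bp + sig_per_bp) / bg_per_bp
  expect_lt(abs(ratio - expected) / expected, 0.05)
})

test_that("replicate tracks correlate and correlation identities hold", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 1)
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  # i.i.d. replicate redraws of the same marked-gene model
  r1 <- build_track(simulate_reads(ann, ann$gene_id[1:10], depth = 5e5,
                                   seed = 21), grid)
  r2 <- build_track(simulate_reads(ann, ann$gene_id[1:10], depth = 5e5,
                                   seed = 22), grid)
  expect_equal(track_correlation(r1, r1), 1.0)
  neg <- r1
  neg$value <- -neg$value
  expect_equal(track_correlation(r1, neg), -1.0)
  expect_gt(track_correlation(r1, r2), 0.8)
  flat <- r1
  flat$value <- 1
  expect_error(track_correlation(r1, flat), "zero-variance")
})

test_that("RPKM is depth invariant in expectation under subsampling", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 1)
  truth <- simulate_truth(ann, n_marked_gv = 10, n_zga = 5, n_k4 = 10,
                          seed = 1)
  rs <- deduplicate_reads(simulate_reads(ann, marked_genes(truth),
                                         depth = 4e5, dup_rate = 0,
                                         seed = 8))
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  full <- build_track(rs, grid, dedup = FALSE)
  set.seed(99)
  half <- rs[sample.int(nrow(rs), nrow(rs) / 2), ]
  half_tr <- rpkm_track(bin_counts(half, grid))
  sel <- full$count >= 10
  rel <- abs(half_tr$value[sel] - full$value[sel]) / full$value[sel]
  expect_lt(mean(rel), 0.10)
})

test_that("bedGraph round-trips non-overlapping tracks to 6 significant
           digits", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 1e6, n_genes = 10,
                         seed = 1)
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  tr <- build_track(simulate_reads(ann, ann$gene_id[1:5], depth = 5e4,
                                   seed = 31), grid)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$value, signif(tr$value, 6), tolerance = 1e-6)
})
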