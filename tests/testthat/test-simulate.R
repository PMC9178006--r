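test_that("simulated genomes pack genes with non-overlapping promoters", {
  ann <- simulate_genome(n_chrom = 3, chrom_length = 5e6, n_genes = 300,
                         seed = 1)
  expect_equal(nrow(ann), 300)
  expect_identical(tibble::as_tibble(ann),
                   tibble::as_tibble(simulate_genome(seed = 1)))
  p <- promoters_of(ann) |> dplyr::arrange(chrom, start)
  by_chr <- split(p, p$chrom)
  for (d in by_chr) {
    expect_true(all(d$start[-1] >= head(d$end, -1)))
  }
  # ~50% minus strand (binomial 99.9% CI)
  n_minus <- sum(ann$strand == "-")
  expect_true(n_minus > qbinom(0.0005, 300, 0.5) &&
                n_minus < qbinom(0.9995, 300, 0.5))
  expect_error(simulate_genome(n_chrom = 1, chrom_length = 1e5,
                               n_genes = 100), "infeasible")
})

test_that("planted truth respects the retention and nesting invariants", {
  ann <- simulate_genome(seed = 2)
  truth <- simulate_truth(ann, seed = 3)
  gv <- marked_genes(truth, stage = "GV")
  mii_wt <- marked_genes(truth, stage = "MII")
  mii_cko <- marked_genes(truth, stage = "MII", genotype = "cKO")
  expect_length(gv, 150)
  expect_length(mii_wt, 15)
  expect_true(all(mii_wt %in% mii_cko))   # cKO retains at least WT's marks
  expect_true(all(mii_cko %in% gv))
  expect_true(all(truth$usp16_sensitive %in% truth$zga_genes))
  # two-cell loss set nests inside the MII loss set
  lost_mii <- setdiff(gv, mii_wt)
  lost_2c <- setdiff(gv, marked_genes(truth, stage = "twocell"))
  expect_true(all(lost_2c %in% lost_mii))
  # ZGA genes are unmarked at the two-cell stage by construction
  expect_length(intersect(truth$zga_genes,
                          marked_genes(truth, stage = "twocell")), 0)
})

test_that("pure-background reads are uniform over 1 kb bins", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 4)
  rs <- simulate_reads(ann, marked = character(0), depth = 1e5,
                       background_fraction = 1, dup_rate = 0, seed = 5)
  expect_equal(nrow(rs), 1e5)
  grid <- bin_grid(ann, binsize = 1000, stepsize = 1000)
  tr <- bin_counts(rs, grid)
  counts <- tr$count[tr$end <= 2e6]
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  p <- pchisq(chisq, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("signal reads concentrate in marked promoter domains", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 4)
  marked <- ann$gene_id[1:10]
  rs <- simulate_reads(ann, marked, depth = 2e4, background_fraction = 0,
                       domain_width = 4000, dup_rate = 0, seed = 6)
  domains <- tibble::tibble(
    chrom = ann$chrom[match(marked, ann$gene_id)],
    start = ann$tss[match(marked, ann$gene_id)] - 2000,
    end = ann$tss[match(marked, ann$gene_id)] + 2000)
  mid <- floor((rs$start + rs$end) / 2)
  inside <- mapply(function(ch, m) {
    any(domains$chrom == ch & domains$start <= m & m < domains$end)
  }, rs$chrom, mid)
  expect_true(all(inside))
})

test_that("GV-marked promoters carry more signal at GV than at MII", {
  ann <- simulate_genome(seed = 1)
  truth <- simulate_truth(ann, seed = 1)
  gv_reads <- simulate_reads(ann, marked_genes(truth, stage = "GV"),
                             depth = 2e5, seed = 11)
  mii_reads <- simulate_reads(ann, marked_genes(truth, stage = "MII"),
                              depth = 2e5, seed = 12)
  proms <- promoters_of(ann)
  pm <- promoter_counts(list(GV = deduplicate_reads(gv_reads),
                             MII = deduplicate_reads(mii_reads)), proms)
  rp <- promoter_rpkm(pm)
  at_gv <- rp$gene_id %in% marked_genes(truth, stage = "GV")
  expect_gt(mean(rp$GV[at_gv]), 2 * mean(rp$MII[at_gv]))
})

test_that("duplicate injection hits the configured rate", {
  ann <- simulate_genome(n_chrom = 1, chrom_length = 2e6, n_genes = 20,
                         seed = 4)
  rs <- simulate_reads(ann, character(0), depth = 1e5,
                       background_fraction = 1, dup_rate = 0.1, seed = 7)
  expect_equal(nrow(rs), 1e5)
  n_unique <- nrow(dplyr::distinct(tibble::as_tibble(rs)))
  # 90k independent draws minus birthday collisions
  expect_lt(abs(n_unique - 90000) / 90000, 0.02)
})

test_that("noiseless expression tables satisfy the planted definitions", {
  ann <- simulate_genome(seed = 1)
  truth <- simulate_truth(ann, seed = 2)
  tab <- simulate_expression(ann, truth, noise_sd = 0, seed = 3)
  expect_identical(tibble::as_tibble(tab),
                   tibble::as_tibble(simulate_expression(ann, truth,
                                                         noise_sd = 0,
                                                         seed = 3)))
  floored <- floor_fpkm(tab)
  zga <- define_zga(floored)
  expect_setequal(zga, truth$zga_genes)
  tr <- differential_transcripts(floored)
  expect_setequal(tr$down, truth$usp16_sensitive)
})

test_that("noiseless qPCR simulation inverts exactly", {
  ct <- simulate_qpcr(true_ratio = 5, noise_sd = 0, seed = 1)
  out <- qpcr_ratios(ct)
  expect_equal(out$absolute_ratio, 5)
  # equal primer efficiencies: relative equals absolute
  expect_equal(out$relative_ratio, out$absolute_ratio)
  ct2 <- simulate_qpcr(true_ratio = 5, efficiencies = c(2, 1),
                       noise_sd = 0, seed = 1)
  out2 <- qpcr_ratios(ct2)
  expect_equal(out2$efficiency_ratio, 2)
  expect_equal(out2$absolute_ratio, 5)
  expect_equal(out2$relative_ratio, 10)
  expect_identical(simulate_qpcr(seed = 9, noise_sd = 0.1),
                   simulate_qpcr(seed = 9, noise_sd = 0.1))
})
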