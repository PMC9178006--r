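test_that("promoter counting uses half-open midpoint assignment", {
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 10000, end = 12000),
    tibble::tibble(chrom = "chr1", length = 50000))
  proms <- promoters_of(ann)   # [8000, 12000)
  # midpoints: at the promoter center, just inside the left edge, exactly
  # at the (excluded) right edge, far away
  rs <- reads_at(c(10000, 8000, 12000, 30000))
  pm <- promoter_counts(list(s1 = rs), proms)
  expect_equal(pm$s1, 2L)
  # conservation: promoter totals never exceed the read total
  expect_lte(sum(pm$s1), nrow(rs))
})

test_that("median-of-ratios size factors match hand computation", {
  mat <- counts_matrix(matrix(c(2, 8, 4, 16), 2, 2))
  sf <- size_factors(mat)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # sample B = 3x sample A
  mat2 <- counts_matrix(cbind(c(5, 10, 20), c(15, 30, 60)))
  sf2 <- size_factors(mat2)
  expect_equal(unname(sf2[2] / sf2[1]), 3)
  # identical samples: equal factors
  mat3 <- counts_matrix(cbind(c(5, 7), c(5, 7), c(5, 7)))
  expect_true(all(size_factors(mat3) == size_factors(mat3)[1]))
  # all-zero gene rows only -> error
  mat4 <- counts_matrix(cbind(c(0, 3), c(2, 0)))
  expect_error(size_factors(mat4), "pseudo-count")
})

test_that("identical groups give zero fold changes and p ~ 1", {
  set.seed(1)
  a <- matrix(rnbinom(600, mu = 40, size = 20), 200, 3)
  mat <- counts_matrix(cbind(a, a))
  res <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_true(all(res$log2_fold_change == 0))
  expect_true(all(res$p_value[!is.na(res$p_value)] > 0.999))
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  set.seed(2)
  counts <- matrix(rnbinom(1200, mu = 60, size = 10), 200, 6)
  mat <- counts_matrix(counts)
  ab <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  ba <- nb_wald_test(mat, c("s4", "s5", "s6"), c("s1", "s2", "s3"))
  expect_equal(ba$log2_fold_change, -ab$log2_fold_change)
  expect_equal(ba$p_value, ab$p_value)
})

test_that("BH adjustment matches a brute-force oracle", {
  set.seed(3)
  counts <- matrix(rnbinom(900, mu = 50, size = 15), 150, 6)
  mat <- counts_matrix(counts)
  res <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  p <- res$p_value[!is.na(res$p_value)]
  m <- length(p)
  # oracle: q_i = min over j with p_j >= p_i of m * p_j / rank_j
  o <- order(p)
  q_oracle <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_oracle <- pmin(q_oracle, 1)[order(o)]
  expect_equal(res$q_value[!is.na(res$p_value)], q_oracle)
})

test_that("scaling one sample's counts leaves calls unchanged", {
  set.seed(4)
  counts <- matrix(rnbinom(1800, mu = 80, size = 10), 300, 6)
  counts[1:20, 4:6] <- rnbinom(60, mu = 640, size = 10)
  mat <- counts_matrix(counts)
  res1 <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 5L
  res2 <- nb_wald_test(counts_matrix(scaled),
                       c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(res2$call, res1$call)
})

test_that("a planted 8-fold decrease is recovered at q < 0.05", {
  set.seed(5)
  n <- 1000
  mu <- rep(100, n)
  mu_b <- mu
  mu_b[1:100] <- mu[1:100] / 8
  counts <- cbind(
    matrix(rnbinom(3 * n, mu = mu, size = 1 / 0.05), n, 3),
    matrix(rnbinom(3 * n, mu = mu_b, size = 1 / 0.05), n, 3))
  mat <- counts_matrix(counts)
  res <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  hits <- which(res$call == "down")
  expect_gte(length(intersect(hits, 1:100)), 90)
})

test_that("gene-set derivation applies thresholds per contrast and
           reports overlaps", {
  mk <- function(lfc, q) {
    out <- tibble::tibble(gene_id = sprintf("g%02d", seq_along(lfc)),
                          base_mean = 50, log2_fold_change = lfc,
                          stat = 0, p_value = q, q_value = q,
                          call = "unchanged")
    class(out) <- c("ub_diff", class(out))
    out
  }
  mii <- mk(lfc = c(-3, -2, -0.5, 3, 0), q = c(0.001, 0.01, 0.001, 0.001, 0.9))
  two <- mk(lfc = c(-3, 0, 0, 0, 0), q = c(0.001, 0.9, 0.9, 0.9, 0.9))
  cko <- mk(lfc = c(2.5, 2, 0, -2, 0), q = c(0.001, 0.2, 0.9, 0.001, 0.9))
  cat <- derive_ub_gene_sets(mii, two, cko)
  expect_setequal(gene_set(cat, "MII-ub-down"), c("g01", "g02"))
  expect_setequal(gene_set(cat, "two-cell-ub-down"), "g01")
  expect_setequal(gene_set(cat, "cKO-MII-ub-up"), "g01")
  venn <- set_venn(cat)
  ov <- venn$n_overlap[venn$set_a == "MII-ub-down" &
                         venn$set_b == "cKO-MII-ub-up"]
  expect_equal(ov, 1)
  # empty differential input -> empty sets, no error
  empty <- mk(numeric(0), numeric(0))
  cat0 <- derive_ub_gene_sets(empty, empty, empty)
  expect_equal(nrow(cat0), 0)
  expect_length(gene_set(cat0, "MII-ub-down"), 0)
})

test_that("the internal NB test agrees with DESeq2 on a planted contrast", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  n <- 400
  mu <- rep(120, n)
  mu_b <- mu
  mu_b[1:40] <- mu[1:40] / 6
  counts <- cbind(
    matrix(rnbinom(3 * n, mu = mu, size = 1 / 0.05), n, 3),
    matrix(rnbinom(3 * n, mu = mu_b, size = 1 / 0.05), n, 3))
  dimnames(counts) <- list(sprintf("g%03d", seq_len(n)),
                           sprintf("s%d", 1:6))
  mat <- counts_matrix(counts)
  res <- nb_wald_test(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = counts,
      colData = data.frame(group = factor(rep(c("A", "B"), each = 3))),
      design = ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("group", "B", "A"))
  })
  ours <- res$gene_id[res$call == "down"]
  theirs <- rownames(dres)[!is.na(dres$padj) & dres$padj < 0.05 &
                             dres$log2FoldChange < -1]
  # the two tests should call essentially the same planted genes
  jaccard <- length(intersect(ours, theirs)) /
    length(union(ours, theirs))
  expect_gte(jaccard, 0.8)
  expect_gt(cor(res$log2_fold_change, dres$log2FoldChange), 0.98)
})
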