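# Shared in-code fixtures: a tiny deterministic genome and read helpers.

tiny_annotation <- function() {
  genome_annotation(
    genes = tibble::tibble(
      gene_id = c("gA", "gB", "gC"),
      chrom = c("chr1", "chr1", "chr2"),
      strand = c("+", "-", "+"),
      start = c(10000, 40000, 20000),
      end = c(15000, 47000, 26000)
    ),
    chromosomes = tibble::tibble(chrom = c("chr1", "chr2"),
                                 length = c(100000, 60000))
  )
}

# Reads as plain midpoint positions on one chromosome
reads_at <- function(midpoints, chrom = "chr1", len = 50) {
  tibble::tibble(chrom = chrom,
                 start = midpoints - floor(len / 2),
                 end = midpoints - floor(len / 2) + len,
                 strand = "+")
}

# A fully in-memory promoter matrix from a plain count matrix
counts_matrix <- function(counts, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(counts)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(counts)))
  dimnames(counts) <- list(genes, samples)
  promoter_matrix(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adjusted Rand index from the pair-counting contingency form
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
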