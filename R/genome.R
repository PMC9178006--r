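#' Build a genome annotation from a gene table
#'
#' A genome annotation is a tibble of single-TSS gene records plus a
#' chromosome-size table carried as an attribute. All coordinates are
#' 0-based, half-open (BED convention); the TSS of a minus-strand gene is
#' `end - 1`.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open).
#' @param chromosomes A data frame with columns `chrom` and `length` (bp).
#' @return A `genome_annotation` tibble with derived `tss` and `tes` columns.
#' @export
genome_annotation <- function(genes, chromosomes) {
  stopifnot_cols_(genes, c("gene_id", "chrom", "strand", "start", "end"),
                  "`genes`")
  stopifnot_cols_(chromosomes, c("chrom", "length"), "`chromosomes`")
  chromosomes <- as_tibble(chromosomes)
  if (anyDuplicated(chromosomes$chrom)) {
    abort("chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_id)) {
    abort("gene ids must be unique")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  bad <- which(genes$start >= genes$end)
  if (length(bad) > 0L) {
    abort(sprintf("gene '%s': start must be < end", genes$gene_id[bad[1]]))
  }
  len <- chromosomes$length[match(genes$chrom, chromosomes$chrom)]
  if (anyNA(len)) {
    abort(sprintf("gene '%s' on unknown chromosome '%s'",
                  genes$gene_id[which(is.na(len))[1]],
                  genes$chrom[which(is.na(len))[1]]))
  }
  if (any(genes$start < 0) || any(genes$end > len)) {
    abort("gene coordinates must lie within [0, chromosome length]")
  }
  genes <- genes |>
    mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1),
      tes = ifelse(.data$strand == "+", .data$end - 1, .data$start)
    ) |>
    select("gene_id", "chrom", "strand", "start", "end", "tss", "tes")
  attr(genes, "chromosomes") <- chromosomes
  class(genes) <- c("genome_annotation", class(genes))
  genes
}

#' Chromosome-size table of an annotation
#' @param ann A `genome_annotation`.
#' @return A tibble with columns `chrom` and `length`.
#' @export
chromosomes <- function(ann) {
  chrom <- attr(ann, "chromosomes")
  if (is.null(chrom)) abort("not a genome_annotation: no chromosome table")
  chrom
}

#' Read a gene annotation from a TSV gene table or BED file
#'
#' The TSV format has five columns (`gene_id`, `chrom`, `strand`, `start`,
#' `end`), 0-based half-open, with a header line. BED input (6 or 12
#' columns, no header) uses `name` as the gene id. Chromosome lengths are
#' taken from `chromosomes` when supplied, otherwise set to the largest end
#' coordinate per chromosome.
#'
#' @param path Path to the gene table.
#' @param format `"tsv"` or `"bed"`.
#' @param chromosomes Optional chromosome-size data frame (`chrom`, `length`).
#' @return A `genome_annotation`.
#' @export
load_annotation <- function(path, format = c("tsv", "bed"),
                            chromosomes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (format == "tsv") {
    genes <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(
                               gene_id = "c", chrom = "c", strand = "c",
                               start = "d", end = "d"))
    prob <- readr::problems(genes)
    if (nrow(prob) > 0L) {
      abort(sprintf("parse error in %s at line %d: %s", path,
                    prob$row[1] + 1L, prob$expected[1]))
    }
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    if (ncol(raw) < 6L) abort("BED gene input needs at least 6 columns")
    genes <- tibble(gene_id = as.character(raw[[4]]),
                    chrom = as.character(raw[[1]]),
                    strand = as.character(raw[[6]]),
                    start = as.numeric(raw[[2]]),
                    end = as.numeric(raw[[3]]))
  }
  if (is.null(chromosomes)) {
    chromosomes <- genes |>
      group_by(chrom = .data$chrom) |>
      summarise(length = max(.data$end), .groups = "drop")
  }
  genome_annotation(genes, chromosomes)
}

#' Write an annotation back to the five-column TSV gene table
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ann |>
    as_tibble() |>
    select("gene_id", "chrom", "strand", "start", "end") |>
    readr::write_tsv(path)
  invisible(path)
}

#' Promoter regions of all genes
#'
#' Promoters are `[tss - flank, tss + flank)` clipped to chromosome bounds;
#' the default 2 kb flank gives the conventional TSS +/- 2 kb promoter.
#'
#' @param ann A `genome_annotation`.
#' @param flank Flank size in bp (> 0).
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
promoters_of <- function(ann, flank = 2000) {
  if (flank <= 0) abort("`flank` must be positive")
  len <- chromosomes(ann)$length[match(ann$chrom, chromosomes(ann)$chrom)]
  ann |>
    as_tibble() |>
    mutate(start = pmax(0, .data$tss - flank),
           end = pmin(len, .data$tss + flank)) |>
    select("gene_id", "chrom", "start", "end", "strand", "tss")
}

#' Classify intervals by their midpoint relative to gene features
#'
#' Each interval is assigned exactly one of `TSS`, `TES`, `gene body`, or
#' `intergenic` from the location of its midpoint, with precedence
#' TSS > TES > gene body. TSS/TES zones extend `zone` bp on each side of the
#' annotated site.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`.
#' @param ann A `genome_annotation`.
#' @param zone Half-width of the TSS/TES zones in bp.
#' @return The input tibble with an added `category` factor column.
#' @export
classify_intervals <- function(intervals, ann, zone = 2000) {
  stopifnot_cols_(intervals, c("chrom", "start", "end"), "`intervals`")
  intervals <- as_tibble(intervals)
  if (nrow(intervals) > 0 &&
      !all(intervals$chrom %in% chromosomes(ann)$chrom)) {
    abort("interval chromosome absent from annotation")
  }
  mid <- floor((intervals$start + intervals$end) / 2)
  tss_zones <- tibble(chrom = ann$chrom, start = ann$tss - zone,
                      end = ann$tss + zone)
  tes_zones <- tibble(chrom = ann$chrom, start = ann$tes - zone,
                      end = ann$tes + zone)
  bodies <- tibble(chrom = ann$chrom, start = ann$start, end = ann$end)
  cat <- rep("intergenic", nrow(intervals))
  cat[points_in_regions_(intervals$chrom, mid, bodies)] <- "gene body"
  cat[points_in_regions_(intervals$chrom, mid, tes_zones)] <- "TES"
  cat[points_in_regions_(intervals$chrom, mid, tss_zones)] <- "TSS"
  intervals$category <- factor(cat, levels = c("TSS", "TES", "gene body",
                                               "intergenic"))
  intervals
}

#' Sample random fixed-length regions from a genome
#'
#' Regions are drawn uniformly over the genome, proportionally to
#' chromosome length, and may overlap genes: they are intended as a
#' genome-as-is background sample for cross-sample normalization.
#'
#' @param ann A `genome_annotation`.
#' @param n Number of regions.
#' @param length Region length in bp; must not exceed the shortest
#'   chromosome.
#' @param seed RNG seed (reproducible draws).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
sample_random_regions <- function(ann, n = 10000, length = 5000, seed = 1) {
  if (n <= 0) abort("`n` must be positive")
  chrom <- chromosomes(ann)
  if (length > min(chrom$length)) {
    abort("`length` exceeds the shortest chromosome")
  }
  with_seed_(seed, {
    # weight by the number of valid start positions so coverage is uniform
    w <- chrom$length - length + 1
    idx <- sample.int(nrow(chrom), n, replace = TRUE, prob = w)
    start <- floor(runif(n, 0, w[idx]))
    tibble(chrom = chrom$chrom[idx], start = start, end = start + length) |>
      arrange(.data$chrom, .data$start)
  })
}

#' Sample random genes without replacement
#'
#' Used to build size-matched random control sets for metaplots and
#' expression comparisons.
#'
#' @param ann A `genome_annotation`.
#' @param n Number of genes (at most the number of genes annotated).
#' @param seed RNG seed.
#' @return A character vector of gene ids.
#' @export
sample_random_genes <- function(ann, n, seed = 1) {
  if (n > nrow(ann)) abort("`n` exceeds the number of genes")
  with_seed_(seed, sample(ann$gene_id, n))
}
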