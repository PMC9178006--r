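#' Strand-aware average TSS signal profile
#'
#' For each gene the track is sampled at `TSS + offset` for plus-strand
#' genes and `TSS - offset` for minus-strand genes, so positive offsets
#' always point downstream of transcription. The value at a genomic
#' position is the mean over all sliding tiles covering that position — a
#' window symmetric around the position, so TSS-centered signal peaks at
#' offset 0. Offsets that leave the chromosome are dropped for that gene,
#' and the per-offset denominator is tracked.
#'
#' @param track A `signal_track`.
#' @param genes Character vector of gene ids (non-empty).
#' @param ann A `genome_annotation`.
#' @param window Half-window around the TSS (bp), a multiple of `step`.
#' @param step Offset increment; defaults to the track's stepsize.
#' @return A `meta_profile` tibble: `offset`, `mean`, `n`, with the gene
#'   set size in the `n_genes` attribute.
#' @export
tss_profile <- function(track, genes, ann, window = 5000, step = NULL) {
  if (length(genes) == 0) abort("`genes` must be non-empty")
  grid <- track_grid(track)
  step <- step %||% grid$stepsize
  if (window %% step != 0) abort("`window` must be a multiple of `step`")
  g <- ann[ann$gene_id %in% genes, ]
  if (nrow(g) == 0) abort("none of `genes` found in the annotation")
  offsets <- seq(-window, window, by = step)
  chrom <- grid$chromosomes
  chrom_index <- match(g$chrom, chrom$chrom)
  chrom_offset <- c(0, cumsum(grid$n_tiles))[chrom_index]
  len <- chrom$length[chrom_index]
  sgn <- ifelse(g$strand == "+", 1, -1)
  acc <- matrix(0, nrow = length(offsets), ncol = 2,
                dimnames = list(NULL, c("sum", "n")))
  vals <- track$value
  tile_step <- grid$stepsize
  bin <- grid$binsize
  max_cover <- ceiling(bin / tile_step)
  for (i in seq_along(offsets)) {
    pos <- g$tss + sgn * offsets[i]
    ok <- pos >= 0 & pos < len
    if (!any(ok)) next
    nt <- grid$n_tiles[chrom_index[ok]]
    kmax <- floor(pos[ok] / tile_step)
    kmin <- floor((pos[ok] - bin) / tile_step) + 1
    vsum <- numeric(sum(ok))
    vcnt <- numeric(sum(ok))
    for (j in 0:(max_cover - 1)) {
      k <- kmax - j
      valid <- k >= kmin & k >= 0 & k < nt
      if (!any(valid)) next
      idx <- chrom_offset[ok][valid] + k[valid] + 1
      vsum[valid] <- vsum[valid] + vals[idx]
      vcnt[valid] <- vcnt[valid] + 1
    }
    use <- vcnt > 0
    acc[i, "sum"] <- sum(vsum[use] / vcnt[use])
    acc[i, "n"] <- sum(use)
  }
  out <- tibble(offset = offsets,
                mean = ifelse(acc[, "n"] > 0, acc[, "sum"] / acc[, "n"],
                              NA_real_),
                n = as.integer(acc[, "n"]))
  attr(out, "n_genes") <- nrow(g)
  attr(out, "set_name") <- NULL
  class(out) <- unique(c("meta_profile", class(out)))
  out
}

#' Compare a gene-set profile against a size-matched random control
#'
#' @param profile_set `meta_profile` of the gene set of interest.
#' @param profile_random `meta_profile` of a random control set of equal
#'   cardinality (see [sample_random_genes()]).
#' @return A list: `difference` tibble (`offset`, `difference`), and
#'   `ratio_at_tss` (set mean over control mean at offset 0).
#' @export
compare_profiles <- function(profile_set, profile_random) {
  if (!identical(profile_set$offset, profile_random$offset)) {
    abort("profiles have mismatched offsets")
  }
  diff_tbl <- tibble(offset = profile_set$offset,
                     difference = profile_set$mean - profile_random$mean)
  at0 <- profile_set$offset == 0
  r <- profile_set$mean[at0] / profile_random$mean[at0]
  list(difference = diff_tbl, ratio_at_tss = unname(r))
}
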