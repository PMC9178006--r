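#' Count reads per promoter per sample
#'
#' A read contributes to a promoter when its midpoint lies inside the
#' promoter interval (half-open), matching the tile-assignment rule of the
#' signal module. Works for overlapping promoters (a read can then count
#' toward several genes).
#'
#' @param read_sets A named list of deduplicated `read_set`s (names become
#'   sample ids).
#' @param promoters Promoter table from [promoters_of()].
#' @return A `promoter_matrix`: tibble with `gene_id` and one integer count
#'   column per sample; sample metadata (stage, genotype, mark, replicate,
#'   total_reads, background_scale) and promoter widths carried as
#'   attributes.
#' @export
promoter_counts <- function(read_sets, promoters) {
  if (is.null(names(read_sets)) || any(names(read_sets) == "")) {
    abort("`read_sets` must be a named list")
  }
  mat <- tibble(gene_id = promoters$gene_id)
  samples <- purrr::imap(read_sets, function(rs, id) {
    meta <- read_meta(rs)
    cnt <- numeric(nrow(promoters))
    for (ch in unique(promoters$chrom)) {
      m <- with(rs[rs$chrom == ch, ], floor((start + end) / 2))
      if (length(m) == 0) next
      m <- sort(m)
      psel <- which(promoters$chrom == ch)
      # reads with midpoint in [start, end): rank of end-1 minus rank of
      # start-1 in the sorted midpoints
      hi <- findInterval(promoters$end[psel] - 0.5, m)
      lo <- findInterval(promoters$start[psel] - 0.5, m)
      cnt[psel] <- hi - lo
    }
    mat[[id]] <<- as.integer(cnt)
    tibble(sample_id = id,
           stage = meta$stage %||% NA_character_,
           genotype = meta$genotype %||% NA_character_,
           mark = meta$mark %||% NA_character_,
           replicate = meta$replicate %||% NA_integer_,
           total_reads = nrow(rs),
           background_scale = attr(rs, "background_scale") %||% 1)
  }) |> bind_rows()
  new_promoter_matrix(mat, samples = samples,
                      widths = promoters$end - promoters$start)
}

#' Build a promoter matrix from a count matrix
#'
#' Convenience constructor for simulation studies and tests: wraps a
#' genes-by-samples integer count matrix as a `promoter_matrix`.
#'
#' @param counts Matrix (genes x samples) with row and column names, or a
#'   tibble with a `gene_id` column.
#' @param samples Optional sample-sheet tibble; defaults to minimal
#'   metadata with library size equal to the column sum.
#' @param widths Promoter widths in bp (recycled).
#' @return A `promoter_matrix`.
#' @export
promoter_matrix <- function(counts, samples = NULL, widths = 4000) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts)) || is.null(colnames(counts))) {
      abort("`counts` matrix needs row and column names")
    }
    mat <- as_tibble(counts)
    mat <- dplyr::bind_cols(tibble(gene_id = rownames(counts)), mat)
  } else {
    stopifnot_cols_(counts, "gene_id", "`counts`")
    mat <- as_tibble(counts)
  }
  ids <- setdiff(names(mat), "gene_id")
  samples <- samples %||% tibble(
    sample_id = ids, stage = NA_character_, genotype = NA_character_,
    mark = NA_character_, replicate = NA_integer_,
    total_reads = purrr::map_dbl(ids, function(id) sum(mat[[id]])),
    background_scale = 1
  )
  new_promoter_matrix(mat, samples = samples,
                      widths = rep_len(widths, nrow(mat)))
}

new_promoter_matrix <- function(mat, samples, widths) {
  attr(mat, "samples") <- samples
  attr(mat, "widths") <- widths
  class(mat) <- unique(c("promoter_matrix", class(mat)))
  mat
}

#' Sample sheet of a promoter matrix
#' @param mat A `promoter_matrix`.
#' @return The sample metadata tibble.
#' @export
promoter_samples <- function(mat) {
  s <- attr(mat, "samples")
  if (is.null(s)) abort("not a promoter_matrix: no sample metadata")
  s
}

#' Attach background scales to a promoter matrix
#'
#' Records per-sample background scales (e.g. from the tracks returned by
#' [background_normalize()]) so that background-anchored size factors can
#' be used in the differential test.
#'
#' @param mat A `promoter_matrix`.
#' @param scales Named numeric vector of background scales per sample id.
#' @return The updated `promoter_matrix`.
#' @export
set_background_scales <- function(mat, scales) {
  s <- promoter_samples(mat)
  idx <- match(s$sample_id, names(scales))
  if (anyNA(idx)) abort("`scales` must name every sample")
  s$background_scale <- unname(scales[idx])
  new_promoter_matrix(as_tibble(mat), samples = s, widths = attr(mat, "widths"))
}

#' Promoter intensities in normalized RPKM
#' @param mat A `promoter_matrix`.
#' @return A tibble of `gene_id` plus one RPKM column per sample, scaled by
#'   each sample's background scale.
#' @export
promoter_rpkm <- function(mat) {
  s <- promoter_samples(mat)
  w_kb <- attr(mat, "widths") / 1000
  out <- tibble(gene_id = mat$gene_id)
  for (i in seq_len(nrow(s))) {
    id <- s$sample_id[i]
    out[[id]] <- mat[[id]] / w_kb / (s$total_reads[i] / 1e6) *
      s$background_scale[i]
  }
  out
}

#' Median-of-ratios size factors
#'
#' The classical count-normalization estimator: per sample, the median over
#' genes of the ratio of that sample's count to the gene's geometric mean,
#' restricted to genes with positive counts in every sample.
#'
#' @param mat A `promoter_matrix`.
#' @return A named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(mat) {
  s <- promoter_samples(mat)
  counts <- as.matrix(as_tibble(mat)[, s$sample_id, drop = FALSE])
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider adding a pseudo-count"))
  }
  logc <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(logc)
  apply(exp(logc - geo), 2, median)
}

#' Background-anchored size factors
#'
#' Size factors proportional to library size divided by the background
#' scale, so that normalized promoter counts are on the cross-stage
#' background-equalized scale. Appropriate when a large fraction of
#' promoters genuinely changes between conditions, which breaks the
#' median-of-ratios assumption.
#'
#' @param mat A `promoter_matrix` with background scales set.
#' @return A named numeric vector of size factors (geometric mean 1).
#' @export
background_size_factors <- function(mat) {
  s <- promoter_samples(mat)
  f <- s$total_reads / 1e6 / s$background_scale
  f <- f / exp(mean(log(f)))
  setNames(f, s$sample_id)
}

#' Negative-binomial Wald test for differential promoter enrichment
#'
#' For each promoter, counts are normalized by size factors and an NB
#' dispersion is estimated by pooled within-group method of moments,
#' moderated toward the across-gene median dispersion (per-gene moment
#' estimates are very noisy at 2-3 replicates) and floored at 1e-8. The
#' log2 fold change of group means (B over A, each floored at `pseudo` so
#' ratios of well-measured genes are untouched) is tested with a
#' Wald-type statistic whose standard error comes from the NB
#' mean-variance relation; the reference distribution is t with
#' `nA + nB - 2 + prior_df` degrees of freedom (residual df augmented by
#' the moderation prior, which keeps the test calibrated at few
#' replicates). P-values are BH-adjusted across tested genes; genes
#' whose normalized counts are all below `min_count` are excluded from
#' testing.
#'
#' @param mat A `promoter_matrix`.
#' @param group_a,group_b Character vectors of sample ids (at least 2
#'   replicates each).
#' @param size_factors Optional named size factors; default
#'   [size_factors()] (median of ratios).
#' @param min_count Minimum-signal prefilter on normalized counts.
#' @param pseudo Floor applied to group means before the log ratio.
#' @param prior_df Weight (in pseudo-degrees of freedom) of the
#'   across-gene median dispersion in the moderated estimate.
#' @param q_cutoff,lfc_cutoff Thresholds for the `call` column.
#' @return A `ub_diff` tibble: `gene_id`, `base_mean`, `log2_fold_change`,
#'   `stat`, `p_value`, `q_value`, `call` (up/down/unchanged; NA for genes
#'   failing the prefilter).
#' @export
nb_wald_test <- function(mat, group_a, group_b, size_factors = NULL,
                         min_count = 1, pseudo = 0.5, prior_df = 10,
                         q_cutoff = 0.05, lfc_cutoff = 1) {
  s <- promoter_samples(mat)
  if (!all(c(group_a, group_b) %in% s$sample_id)) {
    abort("group sample ids must exist in the matrix")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 replicates")
  }
  sf <- size_factors %||% size_factors(mat)
  if (is.null(names(sf))) names(sf) <- s$sample_id
  counts <- as.matrix(as_tibble(mat)[, c(group_a, group_b), drop = FALSE])
  norm <- sweep(counts, 2, sf[colnames(counts)], "/")
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var)
  vb <- apply(xb, 1, stats::var)
  # pooled within-group method-of-moments dispersion: var = mu + a * mu^2
  aa <- (va - ma) / pmax(ma, 1e-12)^2
  ab <- (vb - mb) / pmax(mb, 1e-12)^2
  alpha_raw <- ((na - 1) * aa + (nb - 1) * ab) / (na + nb - 2)
  df <- na + nb - 2
  alpha_prior <- median(alpha_raw[is.finite(alpha_raw)])
  if (!is.finite(alpha_prior)) alpha_prior <- 0
  alpha <- pmax((prior_df * alpha_prior + df * alpha_raw) /
                  (prior_df + df), 1e-8)
  tested <- rowSums(norm >= min_count) > 0
  ma_f <- pmax(ma, pseudo)
  mb_f <- pmax(mb, pseudo)
  lfc <- log2(mb_f / ma_f)
  inv_sa <- mean(1 / sf[group_a])
  inv_sb <- mean(1 / sf[group_b])
  var_ma <- (ma * inv_sa + alpha * ma^2) / na
  var_mb <- (mb * inv_sb + alpha * mb^2) / nb
  se_lfc <- sqrt(var_ma / ma_f^2 + var_mb / mb_f^2) / log(2)
  stat <- ifelse(se_lfc > 0, lfc / se_lfc, 0)
  # moderated-variance reference: residual df augmented by the prior df,
  # as in moderated-t practice
  p <- 2 * pt(-abs(stat), df = df + prior_df)
  p[!tested] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[tested] <- p.adjust(p[tested], method = "BH")
  call <- rep(NA_character_, length(p))
  call[tested] <- "unchanged"
  call[tested & !is.na(q) & q < q_cutoff & lfc > lfc_cutoff] <- "up"
  call[tested & !is.na(q) & q < q_cutoff & lfc < -lfc_cutoff] <- "down"
  out <- tibble(gene_id = mat$gene_id,
                base_mean = rowMeans(norm),
                log2_fold_change = lfc,
                stat = stat, p_value = p, q_value = q,
                call = call)
  attr(out, "groups") <- list(A = group_a, B = group_b)
  attr(out, "cutoffs") <- list(q = q_cutoff, lfc = lfc_cutoff)
  class(out) <- unique(c("ub_diff", class(out)))
  out
}

#' Derive the stage-wise promoter-mark gene sets
#'
#' From three differential contrasts — GV vs MII (WT), GV vs two-cell
#' (WT), and WT-MII vs cKO-MII — builds the named gene sets: genes whose
#' promoter mark drops significantly from GV to MII ("MII-ub-down"), from
#' GV to the two-cell stage ("two-cell-ub-down"), and genes up-regulated
#' in knockout MII oocytes ("cKO-MII-ub-up"). A gene qualifies when
#' `q < q_cutoff` and `|log2FC| > lfc_cutoff` in the relevant direction
#' (B over A; "down" means lower in the later/right-hand condition).
#'
#' @param gv_vs_mii,gv_vs_twocell,wt_vs_cko_mii `ub_diff` results with the
#'   earlier/reference condition as group A.
#' @param q_cutoff,lfc_cutoff Significance and fold-change thresholds.
#' @return A `gene_set_catalog` tibble (`set_name`, `gene_id`) with Venn
#'   overlap counts in the `venn` attribute.
#' @export
derive_ub_gene_sets <- function(gv_vs_mii, gv_vs_twocell, wt_vs_cko_mii,
                                q_cutoff = 0.05, lfc_cutoff = 1) {
  for (x in list(gv_vs_mii, gv_vs_twocell, wt_vs_cko_mii)) {
    if (is.null(x)) abort("all three contrasts are required")
  }
  pick <- function(res, dir) {
    sel <- !is.na(res$q_value) & res$q_value < q_cutoff &
      (if (dir == "down") res$log2_fold_change < -lfc_cutoff
       else res$log2_fold_change > lfc_cutoff)
    res$gene_id[sel]
  }
  sets <- list(
    `MII-ub-down` = pick(gv_vs_mii, "down"),
    `two-cell-ub-down` = pick(gv_vs_twocell, "down"),
    `cKO-MII-ub-up` = pick(wt_vs_cko_mii, "up")
  )
  gene_set_catalog(sets,
                   provenance = list(q_cutoff = q_cutoff,
                                     lfc_cutoff = lfc_cutoff))
}

#' Build a gene-set catalog
#' @param sets A named list of character vectors of gene ids.
#' @param provenance Optional list recording how the sets were derived.
#' @return A `gene_set_catalog` tibble (`set_name`, `gene_id`); pairwise
#'   overlap counts available via [set_venn()].
#' @export
gene_set_catalog <- function(sets, provenance = list()) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("sets must have unique names")
  }
  out <- purrr::imap(sets, function(g, nm) {
    tibble(set_name = nm, gene_id = unique(g))
  }) |> bind_rows()
  attr(out, "set_names") <- names(sets)
  attr(out, "provenance") <- provenance
  class(out) <- unique(c("gene_set_catalog", class(out)))
  out
}

#' Extract one gene set from a catalog
#' @param catalog A `gene_set_catalog`.
#' @param name Set name.
#' @return Character vector of gene ids (empty if the set is empty).
#' @export
gene_set <- function(catalog, name) {
  if (!name %in% (attr(catalog, "set_names") %||% catalog$set_name)) {
    abort(sprintf("unknown gene set '%s'", name))
  }
  catalog$gene_id[catalog$set_name == name]
}

#' Pairwise Venn counts of the sets in a catalog
#' @param catalog A `gene_set_catalog`.
#' @return A tibble with columns `set_a`, `set_b`, `n_a`, `n_b`,
#'   `n_overlap`.
#' @export
set_venn <- function(catalog) {
  nms <- attr(catalog, "set_names") %||% unique(catalog$set_name)
  if (length(nms) < 2) return(tibble(set_a = character(0),
                                     set_b = character(0), n_a = integer(0),
                                     n_b = integer(0), n_overlap = integer(0)))
  pairs <- utils::combn(nms, 2)
  purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- gene_set(catalog, pairs[1, i])
    b <- gene_set(catalog, pairs[2, i])
    tibble(set_a = pairs[1, i], set_b = pairs[2, i],
           n_a = length(a), n_b = length(b),
           n_overlap = length(intersect(a, b)))
  }) |> bind_rows()
}
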