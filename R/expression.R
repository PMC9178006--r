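#' Floor an FPKM table
#'
#' Drops genes whose FPKM is below 1 in every sample (to avoid dramatic
#' fold changes driven by near-zero values) and clamps the remaining
#' sub-1 values up to 1. Flooring is recorded and may only be applied
#' once.
#'
#' @param table An unfloored `expression_table` (long: `gene_id`, `stage`,
#'   `genotype`, `replicate`, `fpkm`).
#' @return The floored `expression_table`.
#' @export
floor_fpkm <- function(table) {
  stopifnot_cols_(table, c("gene_id", "fpkm"), "`table`")
  if (isTRUE(attr(table, "floored"))) {
    abort("table is already floored; flooring twice is not allowed")
  }
  keep <- table |>
    group_by(.data$gene_id) |>
    summarise(keep = max(.data$fpkm) >= 1, .groups = "drop")
  out <- table |>
    as_tibble() |>
    dplyr::semi_join(filter(keep, .data$keep), by = "gene_id") |>
    mutate(fpkm = pmax(.data$fpkm, 1))
  new_expression_table(out, floored = TRUE)
}

# mean FPKM per gene for one condition, with aggregation over replicates
condition_means_ <- function(table, stage, genotype,
                             aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  sel <- table$stage == stage & table$genotype == genotype
  if (!any(sel)) {
    abort(sprintf("no samples for condition %s/%s", stage, genotype))
  }
  agg <- if (aggregate == "mean") mean else median
  table[sel, ] |>
    group_by(.data$gene_id) |>
    summarise(fpkm = agg(.data$fpkm), .groups = "drop")
}

#' Define ZGA genes from a floored expression table
#'
#' ZGA (zygotic genome activation) genes are those whose two-cell
#' expression exceeds `fc_threshold` times their zygote expression
#' (strictly), computed on replicate-aggregated floored FPKM.
#'
#' @param table A floored `expression_table`.
#' @param genotype Genotype whose zygote/two-cell samples define the fold
#'   change.
#' @param zygote_stage,twocell_stage Stage labels.
#' @param fc_threshold Fold-change threshold (strict).
#' @param aggregate Replicate aggregation (`"mean"` or `"median"`).
#' @return Character vector of ZGA gene ids.
#' @export
define_zga <- function(table, genotype = "WT", zygote_stage = "zygote",
                       twocell_stage = "twocell", fc_threshold = 3,
                       aggregate = "mean") {
  if (!isTRUE(attr(table, "floored"))) {
    abort("ZGA definition requires a floored table; call floor_fpkm() first")
  }
  zy <- condition_means_(table, zygote_stage, genotype, aggregate)
  tc <- condition_means_(table, twocell_stage, genotype, aggregate)
  j <- dplyr::inner_join(zy, tc, by = "gene_id", suffix = c("_zy", "_tc"))
  j$gene_id[j$fpkm_tc / j$fpkm_zy > fc_threshold]
}

#' Up/down-regulated transcripts between genotypes
#'
#' At a given stage, up-regulated transcripts satisfy cKO/WT >
#' `fc_threshold` and down-regulated ones WT/cKO > `fc_threshold`
#' (strict); the two sets are disjoint by construction.
#'
#' @param table A floored `expression_table`.
#' @param stage Stage at which to compare.
#' @param wt_genotype,cko_genotype Genotype labels.
#' @param fc_threshold Fold-change threshold.
#' @param aggregate Replicate aggregation.
#' @return A list with character vectors `up` and `down`.
#' @export
differential_transcripts <- function(table, stage = "twocell",
                                     wt_genotype = "WT",
                                     cko_genotype = "cKO",
                                     fc_threshold = 3, aggregate = "mean") {
  if (!isTRUE(attr(table, "floored"))) {
    abort("differential transcripts require a floored table")
  }
  wt <- condition_means_(table, stage, wt_genotype, aggregate)
  ko <- condition_means_(table, stage, cko_genotype, aggregate)
  j <- dplyr::inner_join(wt, ko, by = "gene_id", suffix = c("_wt", "_ko"))
  list(up = j$gene_id[j$fpkm_ko / j$fpkm_wt > fc_threshold],
       down = j$gene_id[j$fpkm_wt / j$fpkm_ko > fc_threshold])
}

#' Overlap of a down-regulated set with the ZGA genes
#'
#' @param down Character vector of down-regulated gene ids.
#' @param zga Character vector of ZGA gene ids.
#' @return A list: `overlap` (intersection), `fraction`
#'   (|overlap| / |down|; NA when `down` is empty), and `venn` counts.
#' @export
overlap_with_zga <- function(down, zga) {
  ov <- intersect(down, zga)
  list(overlap = ov,
       fraction = if (length(down) > 0) length(ov) / length(down)
       else NA_real_,
       venn = list(n_down = length(down), n_zga = length(zga),
                   n_overlap = length(ov)))
}

#' Split ZGA genes into USP16-sensitive and -insensitive classes
#'
#' Sensitive ZGA genes are those also down-regulated in the maternal
#' knockout at the two-cell stage; the two classes partition the ZGA set.
#'
#' @param zga Character vector of ZGA gene ids.
#' @param cko_down Character vector of knockout-down-regulated gene ids.
#' @return A list with character vectors `sensitive` and `insensitive`.
#' @export
classify_zga_sensitivity <- function(zga, cko_down) {
  list(sensitive = intersect(zga, cko_down),
       insensitive = setdiff(zga, cko_down))
}

#' Read/write expression tables
#'
#' Long-format TSV with columns `gene_id`, `stage`, `genotype`,
#' `replicate`, `fpkm`.
#'
#' @param path File path.
#' @param floored Whether the stored table was floored.
#' @return An `expression_table`.
#' @export
read_expression <- function(path, floored = FALSE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", stage = "c", genotype = "c",
                           replicate = "i", fpkm = "d"))
  new_expression_table(as_tibble(tab), floored = floored)
}

#' @rdname read_expression
#' @param table An `expression_table`.
#' @export
write_expression <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}
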