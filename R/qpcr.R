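#' Primer-efficiency ratio from plasmid standards
#'
#' Two plasmids each carry one gene fragment plus a shared Gfp reference.
#' With Ct1/Ct2 the gene-primer Cts on plasmid 1/2 and Ct3/Ct4 the Gfp
#' Cts on the same plasmids, the relative efficiency of the two gene
#' primer pairs is `2^-(Ct1-Ct3) / 2^-(Ct2-Ct4)` (one Ct unit = one
#' template doubling).
#'
#' @param ct1,ct2 Gene-1/gene-2 primer Cts on their plasmid standards.
#' @param ct3,ct4 Reference (Gfp) primer Cts on plasmid 1/2.
#' @return The primer-efficiency ratio (positive scalar). Vector inputs
#'   (replicates) are averaged on the Ct scale first.
#' @export
primer_efficiency_ratio <- function(ct1, ct2, ct3, ct4) {
  cts <- c(ct1, ct2, ct3, ct4)
  if (!all(is.finite(cts))) abort("all Cts must be finite")
  2^-(mean(ct1) - mean(ct3)) / 2^-(mean(ct2) - mean(ct4))
}

#' Gapdh-referenced relative ratio of two transcripts
#'
#' Each gene's level relative to Gapdh is `2^-(Ct_gene - Ct_ref)`; their
#' ratio reduces to `2^(Ct_g2 - Ct_g1)` and is independent of the
#' reference Ct.
#'
#' @param ct_g1,ct_g2 Sample Cts of the two genes.
#' @param ct_ref Sample Ct of the reference (Gapdh); cancels
#'   algebraically but is accepted for clarity.
#' @return The relative ratio (gene 1 over gene 2).
#' @export
relative_ratio <- function(ct_g1, ct_g2, ct_ref = 0) {
  cts <- c(ct_g1, ct_g2, ct_ref)
  if (!all(is.finite(cts))) abort("all Cts must be finite")
  2^-(mean(ct_g1) - mean(ct_ref)) / 2^-(mean(ct_g2) - mean(ct_ref))
}

#' Efficiency-corrected absolute ratio
#'
#' The absolute molar ratio is the Gapdh-referenced relative ratio divided
#' by the primer-efficiency ratio.
#'
#' @param relative Relative ratio from [relative_ratio()].
#' @param efficiency Primer-efficiency ratio from
#'   [primer_efficiency_ratio()].
#' @return The absolute ratio.
#' @export
absolute_ratio <- function(relative, efficiency) {
  if (!is.finite(efficiency) || efficiency <= 0) {
    abort("`efficiency` must be a positive finite number")
  }
  relative / efficiency
}

#' Full ratio computation from a labeled Ct table
#'
#' Replicate Cts are averaged on the measurement (Ct) scale before the
#' exponentiation, which is equivalent to taking geometric means of the
#' derived quantities.
#'
#' @param ct_table A `ct_table` (long tibble `quantity`, `replicate`,
#'   `ct`) as written by [simulate_qpcr()] or read from TSV.
#' @return A tibble with one row: `efficiency_ratio`, `relative_ratio`,
#'   `absolute_ratio`.
#' @export
qpcr_ratios <- function(ct_table) {
  stopifnot_cols_(ct_table, c("quantity", "ct"), "`ct_table`")
  need <- c("ct1", "ct2", "ct3", "ct4", "ct_g1", "ct_g2", "ct_ref")
  missing <- setdiff(need, unique(ct_table$quantity))
  if (length(missing) > 0) {
    abort(sprintf("ct table is missing quantities: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- ct_table |>
    group_by(.data$quantity) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  ct <- setNames(m$ct, m$quantity)
  eff <- primer_efficiency_ratio(ct["ct1"], ct["ct2"], ct["ct3"], ct["ct4"])
  rel <- relative_ratio(ct["ct_g1"], ct["ct_g2"], ct["ct_ref"])
  tibble(efficiency_ratio = unname(eff), relative_ratio = unname(rel),
         absolute_ratio = unname(absolute_ratio(rel, eff)))
}
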