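#' Call broad enrichment domains on a signal track
#'
#' A global-background broad caller: each tile's read count is tested
#' against a single Poisson background rate (upper tail), estimated as the
#' mean tile count over `regions` when supplied (random background
#' regions) and over the whole genome otherwise. P-values are BH-adjusted
#' across all tiles; significant tiles (`q <= q_threshold`) are merged
#' into one peak whenever the gap between their tile intervals is at most
#' `merge_gap` bp. Each peak reports the mean RPKM `value` of its
#' constituent tiles and their minimum q.
#'
#' @param track A normalized `signal_track` with `count` and `value`.
#' @param regions Optional background regions used to estimate the
#'   Poisson rate.
#' @param q_threshold BH-adjusted significance cutoff per tile.
#' @param merge_gap Maximum gap (bp) bridged when merging tiles.
#' @return A `peak_set` tibble: `chrom`, `start`, `end`, `name`,
#'   `mean_rpkm`, `width`, `q_value`, sorted and disjoint per chromosome.
#' @export
call_broad_peaks <- function(track, regions = NULL, q_threshold = 0.05,
                             merge_gap = 1000) {
  stopifnot_cols_(track, c("chrom", "start", "end", "count", "value"),
                  "`track`")
  lambda <- if (is.null(regions)) {
    mean(track$count)
  } else {
    sel <- tiles_in_regions_(track, regions)
    if (!any(sel)) abort("no tiles fall inside the background regions")
    mean(track$count[sel])
  }
  if (lambda == 0) abort("background rate is zero; cannot call peaks")
  p <- ppois(track$count - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- which(q <= q_threshold)
  chrom_len <- track_grid(track)$chromosomes
  peaks <- tibble(chrom = character(0), start = numeric(0),
                  end = numeric(0), mean_rpkm = numeric(0),
                  q_value = numeric(0))
  if (length(sig) > 0) {
    d <- tibble(chrom = track$chrom[sig], start = track$start[sig],
                end = track$end[sig], value = track$value[sig], q = q[sig])
    peaks <- d |>
      arrange(.data$chrom, .data$start) |>
      group_by(.data$chrom) |>
      mutate(new_run = cumsum(
        c(1, as.numeric(.data$start[-1] - cummax_prev_end(.data$end) >
                          merge_gap)))) |>
      group_by(.data$chrom, .data$new_run) |>
      summarise(start = min(.data$start), end = max(.data$end),
                mean_rpkm = mean(.data$value), q_value = min(.data$q),
                .groups = "drop") |>
      select(-"new_run")
    len <- chrom_len$length[match(peaks$chrom, chrom_len$chrom)]
    peaks$end <- pmin(peaks$end, len)
  }
  peaks <- peaks |>
    arrange(.data$chrom, .data$start) |>
    mutate(width = .data$end - .data$start,
           name = sprintf("peak_%d", row_number())) |>
    select("chrom", "start", "end", "name", "mean_rpkm", "width", "q_value")
  class(peaks) <- unique(c("peak_set", class(peaks)))
  peaks
}

# running maximum of previous ends, aligned so element i compares start[i]
# against the furthest end among tiles 1..(i-1)
cummax_prev_end <- function(end) {
  if (length(end) <= 1) return(numeric(0))
  cummax(end)[-length(end)]
}

#' Apply broad-peak quality filters
#'
#' Retains peaks with mean RPKM at least `min_rpkm` and width at least
#' `min_width`; the defaults drop low-quality peaks (RPKM < 1 or width
#' < 800 bp).
#'
#' @param peaks A `peak_set`.
#' @param min_rpkm Minimum mean RPKM.
#' @param min_width Minimum width (bp).
#' @return The filtered `peak_set`.
#' @export
filter_peaks <- function(peaks, min_rpkm = 1, min_width = 800) {
  out <- filter(as_tibble(peaks), .data$mean_rpkm >= min_rpkm,
                .data$width >= min_width)
  class(out) <- unique(c("peak_set", class(out)))
  out
}

#' Tally peaks by genomic category
#'
#' Classifies every peak by its midpoint (TSS > TES > gene body >
#' intergenic precedence) and counts peaks per category; counts always sum
#' to the number of peaks.
#'
#' @param peaks A `peak_set`.
#' @param ann A `genome_annotation`.
#' @param zone Half-width of the TSS/TES zones (bp).
#' @return A tibble with columns `category` and `n`.
#' @export
annotate_peaks <- function(peaks, ann, zone = 2000) {
  cls <- classify_intervals(as_tibble(peaks), ann, zone = zone)
  cls |>
    dplyr::count(.data$category, .drop = FALSE, name = "n") |>
    as_tibble()
}
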