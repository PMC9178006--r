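#' Read a BED6 file of aligned-read intervals
#'
#' @param path Path to a BED file (3-6 tab-separated columns, no header).
#' @return A tibble with columns `chrom`, `start`, `end`, and when present
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  if (ncol(raw) < 3L) abort("BED input needs at least 3 columns")
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]))
  if (ncol(raw) >= 4L) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5L) out$score <- raw[[5]]
  if (ncol(raw) >= 6L) out$strand <- as.character(raw[[6]])
  if (any(out$start >= out$end)) abort("BED intervals must satisfy start < end")
  out
}

#' Write intervals as BED6
#'
#' @param x A data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot_cols_(x, c("chrom", "start", "end"), "`x`")
  out <- tibble(chrom = x$chrom,
                start = format(x$start, scientific = FALSE, trim = TRUE),
                end = format(x$end, scientific = FALSE, trim = TRUE),
                name = x$name %||% ".",
                score = x$score %||% 0,
                strand = x$strand %||% ".")
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write a signal track as bedGraph
#'
#' bedGraph forbids overlapping intervals, so overlapping sliding tiles are
#' decimated to non-overlapping stepsize windows, each carrying the mean
#' value of the tiles that cover it.
#'
#' @param track A `signal_track` (see [build_track()]).
#' @param path Output path.
#' @param column Which track column to export: `"value"` (normalized RPKM)
#'   or `"count"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, column = c("value", "count")) {
  column <- match.arg(column)
  grid <- track_grid(track)
  step <- grid$stepsize
  bin <- grid$binsize
  r <- ceiling(bin / step)
  per_chr <- track |>
    as_tibble() |>
    group_by(.data$chrom) |>
    group_modify_(function(d) {
      # window k = [k*step, (k+1)*step) is covered by tiles k-r+1 .. k
      # (clipped); its value is the mean over those tiles
      d <- arrange(d, .data$start)
      nt <- nrow(d)
      v <- d[[column]]
      cs <- c(0, cumsum(v))
      k <- seq_len(nt) - 1
      lo <- pmax(0, k - r + 1)
      val <- (cs[k + 2] - cs[lo + 1]) / (k - lo + 1)
      tibble(start = k * step, end = (k + 1) * step, value = val)
    }) |>
    ungroup()
  out <- tibble(chrom = per_chr$chrom,
                start = format(per_chr$start, scientific = FALSE, trim = TRUE),
                end = format(per_chr$end, scientific = FALSE, trim = TRUE),
                value = formatC(per_chr$value, digits = 6, format = "g"))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path Path to a 4-column bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         show_col_types = FALSE, comment = "#")
  as_tibble(raw)
}

# dplyr::group_modify without exporting the lambda syntax everywhere
group_modify_ <- function(.tbl, .f) {
  dplyr::group_modify(.tbl, function(.x, .y) .f(.x))
}
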