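#' Sliding-bin grid over a genome
#'
#' Tile k on each chromosome starts at `k * stepsize` and spans `binsize`
#' bp, so consecutive tiles overlap when `stepsize < binsize`. The default
#' 1 kb bins advanced in 200 bp steps follow standard practice for broad
#' histone marks.
#'
#' @param ann A `genome_annotation` (supplies chromosome sizes).
#' @param binsize Tile width (bp).
#' @param stepsize Tile spacing (bp); must not exceed `binsize`.
#' @return A `bin_grid` list.
#' @export
bin_grid <- function(ann, binsize = 1000, stepsize = 200) {
  if (stepsize > binsize) abort("`stepsize` must not exceed `binsize`")
  if (stepsize <= 0) abort("`stepsize` must be positive")
  chrom <- chromosomes(ann)
  structure(list(binsize = binsize, stepsize = stepsize,
                 chromosomes = chrom,
                 n_tiles = ceiling(chrom$length / stepsize)),
            class = "bin_grid")
}

#' Remove PCR duplicates from a read set
#'
#' Keeps at most one read per identical (chrom, start, end, strand)
#' coordinate tuple; the result does not depend on input order.
#'
#' @param reads A `read_set` or read tibble.
#' @return The deduplicated `read_set`.
#' @export
deduplicate_reads <- function(reads) {
  stopifnot_cols_(reads, c("chrom", "start", "end"), "`reads`")
  keys <- c("chrom", "start", "end", intersect("strand", names(reads)))
  out <- reads |>
    as_tibble() |>
    dplyr::distinct(across(all_of(keys)), .keep_all = TRUE) |>
    arrange(across(all_of(keys)))
  meta <- attr(reads, "meta")
  new_read_set(out, stage = meta$stage %||% NA, genotype = meta$genotype %||% NA,
               mark = meta$mark %||% NA, replicate = meta$replicate %||% NA,
               read_length = attr(reads, "read_length") %||% NA)
}

#' Count read midpoints per sliding tile
#'
#' A read is assigned to every tile whose interval
#' `[tile_start, tile_start + binsize)` contains the read midpoint
#' (`floor((start + end)/2)`), so overlapping tiles share reads.
#'
#' @param reads A deduplicated read set.
#' @param grid A `bin_grid`.
#' @return A `signal_track` tibble (`chrom`, `start`, `end`, `count`) with
#'   `value` unset (use [rpkm_track()]).
#' @export
bin_counts <- function(reads, grid) {
  stopifnot_cols_(reads, c("chrom", "start", "end"), "`reads`")
  step <- grid$stepsize
  bin <- grid$binsize
  max_cover <- ceiling(bin / step)
  out <- purrr::map2(grid$chromosomes$chrom, grid$n_tiles, function(ch, nt) {
    m <- with(reads[reads$chrom == ch, ], floor((start + end) / 2))
    counts <- integer(nt)
    if (length(m) > 0) {
      kmax <- floor(m / step)
      kmin <- floor((m - bin) / step) + 1
      for (j in 0:(max_cover - 1)) {
        k <- kmax - j
        k <- k[k >= kmin & k >= 0 & k < nt]
        if (length(k) > 0) counts <- counts + tabulate(k + 1L, nbins = nt)
      }
    }
    starts <- (seq_len(nt) - 1) * step
    tibble(chrom = ch, start = starts, end = starts + bin, count = counts)
  }) |> bind_rows()
  new_signal_track(out, grid = grid, meta = attr(reads, "meta"),
                   total_reads = nrow(reads), background_scale = 1)
}

new_signal_track <- function(tab, grid, meta, total_reads,
                             background_scale = 1) {
  attr(tab, "grid") <- grid
  attr(tab, "meta") <- meta
  attr(tab, "total_reads") <- total_reads
  attr(tab, "background_scale") <- background_scale
  class(tab) <- unique(c("signal_track", class(tab)))
  tab
}

#' Bin grid of a signal track
#' @param track A `signal_track`.
#' @return The `bin_grid` the track was computed on.
#' @export
track_grid <- function(track) {
  g <- attr(track, "grid")
  if (is.null(g)) abort("not a signal_track: no grid attribute")
  g
}

#' Scale tile counts to RPKM
#'
#' RPKM = count / (binsize in kb) / (total reads in millions); the working
#' unit for all downstream signal comparisons.
#'
#' @param track A `signal_track` from [bin_counts()].
#' @param total_reads Library size used for scaling; defaults to the read
#'   count recorded on the track.
#' @return The track with a `value` column in RPKM.
#' @export
rpkm_track <- function(track, total_reads = NULL) {
  total_reads <- total_reads %||% attr(track, "total_reads")
  if (is.null(total_reads) || total_reads <= 0) {
    abort("`total_reads` must be positive")
  }
  bin_kb <- track_grid(track)$binsize / 1000
  out <- mutate(as_tibble(track),
                value = .data$count / bin_kb / (total_reads / 1e6))
  new_signal_track(out, grid = track_grid(track), meta = attr(track, "meta"),
                   total_reads = total_reads,
                   background_scale = attr(track, "background_scale") %||% 1)
}

#' Deduplicate, bin and scale a read set in one step
#' @param reads A `read_set`.
#' @param grid A `bin_grid`.
#' @param dedup Remove PCR duplicates first (default TRUE).
#' @return A `signal_track` with `count` and RPKM `value` columns.
#' @export
build_track <- function(reads, grid, dedup = TRUE) {
  if (dedup) reads <- deduplicate_reads(reads)
  rpkm_track(bin_counts(reads, grid))
}

# Logical selector of tiles whose midpoints fall inside `regions`.
tiles_in_regions_ <- function(track, regions) {
  bin <- track_grid(track)$binsize
  points_in_regions_(track$chrom, track$start + bin / 2, regions)
}

#' Background-anchor normalization across samples
#'
#' Carrier-assisted ChIP yields a high, even background; assuming that
#' background reflects equal input material across samples, tracks are
#' rescaled so their trimmed-mean RPKM over a common set of random
#' background regions matches the reference track's. This equalizes
#' samples without spike-ins while preserving relative promoter signal.
#'
#' @param tracks A (named) list of `signal_track`s on identical grids.
#' @param regions Background regions (tibble `chrom`, `start`, `end`),
#'   typically from [sample_random_regions()].
#' @param trim Trim fraction for the trimmed mean (each tail).
#' @param reference Index or name of the reference track.
#' @return The list of tracks with rescaled `value` columns and updated
#'   `background_scale` attributes.
#' @export
background_normalize <- function(tracks, regions, trim = 0.2,
                                 reference = 1) {
  if (length(tracks) < 2) abort("need at least 2 tracks to normalize")
  if (nrow(regions) == 0) abort("`regions` must be non-empty")
  g1 <- track_grid(tracks[[1]])
  for (t in tracks[-1]) {
    g <- track_grid(t)
    if (g$binsize != g1$binsize || g$stepsize != g1$stepsize ||
        nrow(t) != nrow(tracks[[1]])) {
      abort("all tracks must share an identical grid")
    }
  }
  sel <- tiles_in_regions_(tracks[[1]], regions)
  if (!any(sel)) abort("no tiles fall inside the background regions")
  bg <- purrr::map_dbl(tracks, function(t) mean(t$value[sel], trim = trim))
  if (any(bg == 0)) abort("a track has zero background signal; cannot scale")
  ref_bg <- bg[[if (is.character(reference)) reference else reference]]
  purrr::imap(tracks, function(t, i) {
    s <- ref_bg / bg[[i]]
    out <- mutate(as_tibble(t), value = .data$value * s)
    new_signal_track(out, grid = track_grid(t), meta = attr(t, "meta"),
                     total_reads = attr(t, "total_reads"),
                     background_scale =
                       (attr(t, "background_scale") %||% 1) * s)
  })
}

#' Pearson correlation between two tracks
#'
#' @param a,b `signal_track`s on identical grids.
#' @param scope `"genome"` (all tiles) or `"promoters"` (tiles whose
#'   midpoints fall in `promoters`).
#' @param promoters Promoter regions, required when `scope = "promoters"`.
#' @return The Pearson correlation coefficient of tile values.
#' @export
track_correlation <- function(a, b, scope = c("genome", "promoters"),
                              promoters = NULL) {
  scope <- match.arg(scope)
  if (nrow(a) != nrow(b)) abort("tracks must share an identical grid")
  x <- a$value
  y <- b$value
  if (scope == "promoters") {
    if (is.null(promoters)) abort("`promoters` required for promoter scope")
    sel <- tiles_in_regions_(a, promoters)
    x <- x[sel]
    y <- y[sel]
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance track: correlation undefined")
  }
  cor(x, y)
}
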