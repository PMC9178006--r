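#' @importFrom rlang abort warn `%||%` .data `:=`
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats ppois p.adjust pnorm pt median cor kmeans rnorm runif
#'   rbinom rnbinom quantile phyper sd setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Merge possibly-overlapping half-open intervals on one chromosome into a
# disjoint sorted set. `starts`/`ends` are numeric vectors.
merge_intervals_ <- function(starts, ends) {
  if (length(starts) == 0L) {
    return(list(starts = numeric(0), ends = numeric(0)))
  }
  o <- order(starts, ends)
  s <- starts[o]
  e <- ends[o]
  ms <- s[1]
  me <- e[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] <= me) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms)
        out_e <- c(out_e, me)
        ms <- s[i]
        me <- e[i]
      }
    }
  }
  list(starts = c(out_s, ms), ends = c(out_e, me))
}

# TRUE for each point that lies inside any of the half-open intervals
# described by `regions` (tibble: chrom, start, end). Points given as
# parallel vectors `chrom`, `pos`.
points_in_regions_ <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  if (nrow(regions) == 0L || length(pos) == 0L) {
    return(hit)
  }
  for (ch in unique(regions$chrom)) {
    sel <- regions$chrom == ch
    m <- merge_intervals_(regions$start[sel], regions$end[sel])
    idx <- which(chrom == ch)
    if (length(idx) == 0L) next
    j <- findInterval(pos[idx], m$starts)
    ok <- j > 0L
    ok[ok] <- pos[idx][ok] < m$ends[j[ok]]
    hit[idx] <- ok
  }
  hit
}

stopifnot_cols_ <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
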