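# Brute-force reference caller: enumerate threshold-passing tiles, merge by
# definition, filter by definition. Kept deliberately naive and independent
# of the package implementation.
oracle_caller <- function(track, lambda, q_threshold, merge_gap,
                          min_rpkm, min_width) {
  p <- ppois(track$count - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, "BH")
  sig <- track[q <= q_threshold, ]
  sig$q <- q[q <= q_threshold]
  peaks <- list()
  for (ch in unique(sig$chrom)) {
    d <- sig[sig$chrom == ch, ]
    d <- d[order(d$start), ]
    i <- 1
    while (i <= nrow(d)) {
      j <- i
      while (j < nrow(d) && d$start[j + 1] - max(d$end[i:j]) <= merge_gap) {
        j <- j + 1
      }
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = ch, start = d$start[i], end = max(d$end[i:j]),
        mean_rpkm = mean(d$value[i:j]), q_value = min(d$q[i:j]))
      i <- j + 1
    }
  }
  out <- do.call(rbind, peaks)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_rpkm = numeric(0),
                      q_value = numeric(0)))
  }
  out <- out[out$mean_rpkm >= min_rpkm & out$end - out$start >= min_width, ]
  out[order(out$chrom, out$start), ]
}

random_track <- function(n_tiles, seed) {
  set.seed(seed)
  ann <- genome_annotation(
    tibble::tibble(gene_id = "g", chrom = "chr1", strand = "+",
                   start = 0, end = 100),
    tibble::tibble(chrom = "chr1", length = n_tiles * 500 + 500))
  grid <- bin_grid(ann, binsize = 1000, stepsize = 500)
  counts <- rpois(n_tiles, 5) +
    rbinom(n_tiles, 1, 0.1) * rpois(n_tiles, 40)
  starts <- (seq_len(n_tiles) - 1) * 500
  tr <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 1000,
                       count = counts,
                       value = counts / (sum(counts) / 1e6))
  catchub:::new_signal_track(tr, grid = grid, meta = NULL,
                             total_reads = sum(counts))
}

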