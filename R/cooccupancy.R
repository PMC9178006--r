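#' Build a standardized promoter feature matrix from mark signals
#'
#' Joins per-mark promoter intensity tables on their shared gene universe,
#' applies a `log2(x + 1)` transform (RPKM is heavy-tailed) and
#' standardizes each feature to mean 0, sd 1.
#'
#' @param signals A named list of tibbles (`gene_id` + one value column),
#'   e.g. promoter RPKM per mark; names become feature names. A tibble
#'   with `gene_id` plus several value columns is also accepted.
#' @param transform Transform applied before standardization.
#' @param standardize Standardize features to z-scores.
#' @return A numeric matrix (genes x features) with gene ids as rownames.
#' @export
build_feature_matrix <- function(signals, transform = function(x) log2(x + 1),
                                 standardize = TRUE) {
  if (is.data.frame(signals)) {
    df <- as_tibble(signals)
  } else {
    if (is.null(names(signals))) abort("`signals` must be named")
    df <- purrr::reduce(purrr::imap(signals, function(s, nm) {
      stopifnot_cols_(s, "gene_id", nm)
      val <- s[[setdiff(names(s), "gene_id")[1]]]
      tibble(gene_id = s$gene_id, !!nm := val)
    }), function(a, b) dplyr::inner_join(a, b, by = "gene_id"))
  }
  if (nrow(df) == 0) abort("feature tables share no genes")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  m <- transform(m)
  if (!all(is.finite(m))) abort("non-finite feature values after transform")
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("constant feature: %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    }
    m <- scale(m)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

# k-means++ seeding: spread initial centers by sampling points with
# probability proportional to squared distance from the nearest chosen
# center.
kmeanspp_centers_ <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        i <- sample.int(n, 1)
      } else {
        i <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[i, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' K-means clustering of promoters by mark co-occupancy
#'
#' Lloyd's algorithm from k-means++ initializations, best of `restarts`
#' runs by total within-cluster sum of squares, deterministic for a given
#' seed. Clusters are relabeled in order of decreasing mean of the first
#' feature so labels are reproducible across runs.
#'
#' @param features Matrix from [build_feature_matrix()].
#' @param k Number of clusters (2..distinct rows).
#' @param seed RNG seed.
#' @param restarts Number of independent initializations.
#' @param max_iter Lloyd iteration cap.
#' @return A `promoter_clusters` object: list with `assignment` tibble
#'   (`gene_id`, `cluster`), `centroids` matrix, `k`, `inertia`,
#'   `inertias` (all restarts), `seed`.
#' @export
kmeans_promoters <- function(features, k, seed = 1, restarts = 10,
                             max_iter = 300) {
  if (k < 2) abort("`k` must be at least 2")
  n_distinct <- nrow(unique(features))
  if (k > n_distinct) abort("`k` exceeds the number of distinct rows")
  with_seed_(seed, {
    fits <- purrr::map(seq_len(restarts), function(r) {
      centers <- kmeanspp_centers_(features, k)
      centers <- unique(centers)
      while (nrow(centers) < k) {
        extra <- features[sample.int(nrow(features), k - nrow(centers)), ,
                          drop = FALSE]
        centers <- unique(rbind(centers, extra))
      }
      kmeans(features, centers = centers, iter.max = max_iter,
             algorithm = "Lloyd")
    })
    inertias <- purrr::map_dbl(fits, "tot.withinss")
    best <- fits[[which.min(inertias)]]
    # relabel by descending centroid mean of the first feature
    ord <- order(best$centers[, 1], decreasing = TRUE)
    relabel <- match(seq_len(k), ord)
    labels <- relabel[best$cluster]
    centroids <- best$centers[ord, , drop = FALSE]
    rownames(centroids) <- seq_len(k)
    structure(list(
      assignment = tibble(gene_id = rownames(features), cluster = labels),
      centroids = centroids, k = k,
      inertia = min(inertias), inertias = inertias, seed = seed
    ), class = "promoter_clusters")
  })
}

#' Per-cluster expression summary
#'
#' Summarizes log2 of replicate-aggregated floored FPKM per cluster —
#' the substrate for claims like "the H3K4me3-dominated cluster is the
#' most transcriptionally active".
#'
#' @param clusters A `promoter_clusters`.
#' @param table A floored `expression_table`.
#' @param stage,genotype Condition whose expression is summarized.
#' @return A tibble: `cluster`, `n`, `median`, `q1`, `q3` of log2 FPKM.
#' @export
cluster_expression_summary <- function(clusters, table, stage = "GV",
                                       genotype = "WT") {
  expr <- condition_means_(table, stage, genotype)
  j <- dplyr::inner_join(clusters$assignment, expr, by = "gene_id")
  if (nrow(j) == 0) abort("cluster and expression gene universes are disjoint")
  full <- tibble(cluster = seq_len(clusters$k))
  j |>
    group_by(.data$cluster) |>
    summarise(n = n(),
              median = median(log2(.data$fpkm)),
              q1 = quantile(log2(.data$fpkm), 0.25),
              q3 = quantile(log2(.data$fpkm), 0.75),
              .groups = "drop") |>
    dplyr::right_join(full, by = "cluster") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    arrange(.data$cluster)
}

#' Gene-set enrichment across clusters
#'
#' For each cluster: the fraction of the gene set falling in it, the fold
#' enrichment over the cluster's share of the universe, and a
#' hypergeometric upper-tail p-value, BH-adjusted across clusters.
#'
#' @param clusters A `promoter_clusters`.
#' @param gene_set Character vector of gene ids (non-empty, within the
#'   clustered universe).
#' @param universe Optional universe; defaults to all clustered genes.
#' @return A tibble: `cluster`, `n_cluster`, `n_set_in_cluster`,
#'   `fraction`, `fold_enrichment`, `p_value`, `q_value`.
#' @export
geneset_cluster_enrichment <- function(clusters, gene_set,
                                       universe = NULL) {
  if (length(gene_set) == 0) abort("`gene_set` must be non-empty")
  assign <- clusters$assignment
  universe <- universe %||% assign$gene_id
  assign <- assign[assign$gene_id %in% universe, ]
  gs <- intersect(unique(gene_set), universe)
  if (length(gs) == 0) abort("`gene_set` shares no genes with the universe")
  n_u <- nrow(assign)
  n_s <- length(gs)
  out <- purrr::map(seq_len(clusters$k), function(cl) {
    in_cl <- assign$gene_id[assign$cluster == cl]
    n_c <- length(in_cl)
    x <- length(intersect(gs, in_cl))
    frac <- x / n_s
    share <- n_c / n_u
    tibble(cluster = cl, n_cluster = n_c, n_set_in_cluster = x,
           fraction = frac,
           fold_enrichment = if (share > 0) frac / share else NA_real_,
           p_value = phyper(x - 1, n_c, n_u - n_c, n_s,
                            lower.tail = FALSE))
  }) |> bind_rows()
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}
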