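#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs theme_minimal scale_color_manual
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a differential promoter-enrichment result
#' @param x A `ub_diff`.
#' @param ... Unused.
#' @return A plain tibble with one row per gene.
#' @method tidy ub_diff
#' @export
tidy.ub_diff <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ub_diff")
  out
}

#' One-row summary of a differential result
#' @param x A `ub_diff`.
#' @param ... Unused.
#' @return A tibble: `n_genes`, `n_tested`, `n_up`, `n_down`.
#' @method glance ub_diff
#' @export
glance.ub_diff <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_tested = sum(!is.na(x$p_value)),
         n_up = sum(x$call == "up", na.rm = TRUE),
         n_down = sum(x$call == "down", na.rm = TRUE))
}

#' Tidy a promoter clustering
#' @param x A `promoter_clusters`.
#' @param ... Unused.
#' @return The assignment tibble (`gene_id`, `cluster`).
#' @method tidy promoter_clusters
#' @export
tidy.promoter_clusters <- function(x, ...) x$assignment

#' One-row summary of a promoter clustering
#' @param x A `promoter_clusters`.
#' @param ... Unused.
#' @return A tibble: `k`, `inertia`, `restarts`.
#' @method glance promoter_clusters
#' @export
glance.promoter_clusters <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, restarts = length(x$inertias))
}

#' MA-style plot of a differential result
#' @param object A `ub_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ub_diff
#' @export
autoplot.ub_diff <- function(object, ...) {
  d <- tidy(object) |> filter(!is.na(.data$p_value))
  ggplot(d, aes(x = log2(.data$base_mean + 0.5),
                y = .data$log2_fold_change,
                color = .data$call)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    scale_color_manual(values = c(up = "#d95f02", down = "#1b9e77",
                                  unchanged = "grey60")) +
    labs(x = "log2 mean normalized promoter count",
         y = "log2 fold change", color = NULL) +
    theme_minimal()
}

#' Plot a TSS metaprofile
#' @param object A `meta_profile`.
#' @param ... Optional further `meta_profile`s to overlay, named.
#' @return A ggplot.
#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  extra <- list(...)
  extra <- extra[purrr::map_lgl(extra, inherits, "meta_profile")]
  all <- c(list(profile = object), extra)
  d <- purrr::imap(all, function(p, nm) {
    mutate(as_tibble(p), set = nm)
  }) |> bind_rows()
  ggplot(d, aes(x = .data$offset, y = .data$mean, color = .data$set)) +
    geom_line() +
    labs(x = "distance from TSS (bp)", y = "mean normalized signal",
         color = NULL) +
    theme_minimal()
}

#' Bar plot of gene-set enrichment across clusters
#' @param enrichment Result of [geneset_cluster_enrichment()].
#' @return A ggplot.
#' @export
plot_cluster_enrichment <- function(enrichment) {
  ggplot(enrichment, aes(x = factor(.data$cluster),
                         y = .data$fold_enrichment)) +
    geom_col(fill = "#7570b3") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "cluster", y = "fold enrichment") +
    theme_minimal()
}

#' @export
print.promoter_clusters <- function(x, ...) {
  cat(sprintf("promoter k-means clustering: k = %d, %d genes, inertia %.2f\n",
              x$k, nrow(x$assignment), x$inertia))
  print(table(x$assignment$cluster))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("synthetic ground truth\n")
  for (mk in names(x$marked)) {
    for (gt in names(x$marked[[mk]])) {
      for (st in names(x$marked[[mk]][[gt]])) {
        cat(sprintf("  %s %s/%s: %d genes\n", mk, gt, st,
                    length(x$marked[[mk]][[gt]][[st]])))
      }
    }
  }
  cat(sprintf("  ZGA genes: %d (USP16-sensitive: %d)\n",
              length(x$zga_genes), length(x$usp16_sensitive)))
  invisible(x)
}
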