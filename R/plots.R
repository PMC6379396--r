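# ggplot2 autoplot methods for result objects

#' @export
autoplot.lnc_perm <- function(object, ...) {
  ggplot(tibble(null = object$null), aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$observed, colour = "firebrick") +
    labs(x = "null overlap fraction", y = "permutations",
         title = sprintf("observed %.3f, p = %.3g", object$observed,
                         object$p)) +
    theme_minimal()
}

#' @export
autoplot.lnc_se <- function(object, ...) {
  ggplot(object$regions, aes(x = .data$rank, y = .data$total_signal,
                             colour = .data$is_se)) +
    geom_point() +
    geom_hline(yintercept = object$cutoff, linetype = 2) +
    labs(x = "region rank (ascending signal)", y = "aggregate H3K27ac signal",
         colour = "super-enhancer") +
    theme_minimal()
}

#' @export
autoplot.lnc_folded <- function(object, ...) {
  ggplot(object$curves, aes(x = .data$x, y = .data$folded,
                            colour = .data$group)) +
    geom_step() +
    labs(x = "value", y = "folded ECDF min(F, 1-F)",
         title = sprintf("rank-sum p = %.3g", object$p)) +
    theme_minimal()
}

#' @export
autoplot.lnc_distance_profile <- function(object, ...) {
  ggplot(filter(object, .data$n > 0),
         aes(x = .data$bin_mid / 1000, y = .data$mean_lfc,
             colour = .data$direction)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "distance from DE coding gene TSS (kb)",
         y = "mean lncRNA log2FC", colour = "anchor direction") +
    theme_minimal()
}

#' @export
autoplot.lnc_pca <- function(object, ...) {
  aes_pt <- if ("cell_type" %in% names(object$scores)) {
    aes(x = .data$PC1, y = .data$PC2, colour = .data$cell_type)
  } else {
    aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot(object$scores, aes_pt) +
    geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    theme_minimal()
}

#' @export
autoplot.lnc_tau <- function(object, ...) {
  ggplot(tidyr::drop_na(object, "tau"), aes(x = .data$tau)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    labs(x = expression(tau), y = "genes") +
    theme_minimal()
}

#' @export
autoplot.lnc_traj <- function(object, ...) {
  centers <- as_tibble(object$centers) |>
    mutate(cluster = factor(dplyr::row_number())) |>
    pivot_longer(-"cluster", names_to = "cell_type",
                 values_to = "normalized")
  centers$cell_type <- factor(centers$cell_type,
                              levels = colnames(object$centers))
  ggplot(centers, aes(x = .data$cell_type, y = .data$normalized,
                      group = .data$cluster)) +
    geom_line() +
    facet_wrap(~cluster) +
    labs(x = NULL, y = "max-normalized median TPM") +
    theme_minimal()
}

#' @export
autoplot.lnc_chromatin_clusters <- function(object, ...) {
  ggplot(object$embedding, aes(x = .data$dim1, y = .data$dim2,
                               colour = factor(.data$cluster))) +
    geom_point(size = 1) +
    labs(colour = "cluster", x = "embedding 1", y = "embedding 2") +
    theme_minimal()
}

#' Heatmap of per-cluster chromatin feature medians
#'
#' @param x A [functional_clusters()] result.
#' @param scale_features Clip-scale medians per feature for display.
#' @return A ggplot object.
#' @export
plot_cluster_medians <- function(x, scale_features = TRUE) {
  med <- x$medians
  mat <- select(med, -"cluster", -"n")
  if (scale_features) mat <- as_tibble(clip_scale(as.matrix(mat)))
  long <- bind_cols(med["cluster"], mat) |>
    pivot_longer(-"cluster", names_to = "feature", values_to = "value")
  ggplot(long, aes(x = .data$feature, y = factor(.data$cluster),
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = "cluster", fill = "median") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the cell-type phylogeny with bootstrap supports
#'
#' @param x A [group_phylogeny()] result.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.lnc_phylo <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(x$tree$node.label, frame = "none", adj = c(1.2, -0.3),
                  cex = 0.8)
  invisible(x)
}
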