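#' Plot sample PCA
#'
#' @param object A `uv_pca` from [pca_samples()].
#' @param type `"scores"` (PC1 vs PC2, coloured by fraction and labelled
#'   by timepoint when the design was attached) or `"scree"` (variance
#'   explained per component).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot uv_pca
#' @export
autoplot.uv_pca <- function(object, type = c("scores", "scree"), ...) {
  type <- match.arg(type)
  if (type == "scree") {
    df <- glance(object)
    df$component <- factor(df$component, levels = df$component)
    return(
      ggplot2::ggplot(df, ggplot2::aes(
        x = .data$component,
        y = .data$var_explained
      )) +
        ggplot2::geom_col(fill = "grey35") +
        ggplot2::geom_line(ggplot2::aes(group = 1)) +
        ggplot2::labs(x = NULL, y = "fraction of variance") +
        ggplot2::theme_minimal()
    )
  }
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("fraction" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$fraction), size = 2.5)
  } else {
    p + ggplot2::geom_point(size = 2.5)
  }
  if ("timepoint" %in% names(sc)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = paste0(.data$timepoint, "h")),
      vjust = -0.8, size = 3
    )
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot cluster centroid profiles
#'
#' @param object A `uv_clusters` from [cluster_profiles()].
#' @param ... Ignored.
#' @return A ggplot object: one panel per cluster, centroid z-score
#'   against timepoint.
#' @method autoplot uv_clusters
#' @export
autoplot.uv_clusters <- function(object, ...) {
  df <- tidy(object)
  df$timepoint <- as.numeric(sub("^t", "", df$timepoint))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$centroid)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster,
      labeller = ggplot2::labeller(
        cluster = function(x) paste0("cluster ", x)
      )
    ) +
    ggplot2::labs(x = "time (h)", y = "centroid (z-scored log2 expression)") +
    ggplot2::theme_minimal()
}

#' Chromatin-enrichment boxplot by biotype
#'
#' @param enrichment Output of [chromatin_enrichment()] with a `biotype`
#'   column.
#' @return A ggplot object (log2 chromatin/cytoplasm fold per biotype).
#' @export
plot_enrichment <- function(enrichment) {
  if (!"biotype" %in% names(enrichment)) {
    abort("`enrichment` needs a biotype column", class = "uvtx_input_error")
  }
  ggplot2::ggplot(enrichment, ggplot2::aes(
    x = .data$biotype,
    y = .data$log2_fold
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "log2 (chromatin FPKM / cytoplasm FPKM)") +
    ggplot2::theme_minimal()
}

#' Plot a binned feature histogram
#'
#' @param histogram Output of [feature_histogram()], optionally row-bound
#'   across groups with a `group` column.
#' @return A ggplot object (size-class counts as step lines).
#' @export
plot_feature_histogram <- function(histogram) {
  p <- ggplot2::ggplot(histogram, ggplot2::aes(
    x = .data$bin_start,
    y = .data$count
  ))
  p <- if ("group" %in% names(histogram)) {
    p + ggplot2::geom_step(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_step()
  }
  p + ggplot2::labs(x = "size class", y = "count") + ggplot2::theme_minimal()
}
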