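#' Plot a Silhouette scan
#'
#' Score-versus-cluster-count curve with the selected k (if supplied)
#' marked by a vertical line.
#'
#' @param x A `silhouette_scan`.
#' @param selected Optional k to highlight.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.silhouette_scan <- function(x, selected = NULL, ...) {
  graphics::plot(x$grid, x$scores, type = "b", pch = 16,
                 xlab = "number of clusters", ylab = "mean Silhouette",
                 main = paste("Silhouette scan,", x$method), ...)
  if (!is.null(selected)) {
    graphics::abline(v = selected, lty = 2, col = "red3")
    graphics::mtext(paste("selected k =", selected), side = 3, line = 0,
                    col = "red3", cex = 0.8)
  }
  invisible(x)
}

#' Cluster-size distribution barplot
#'
#' @param assignment A `cluster_assignment`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_cluster_sizes <- function(assignment, ...) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  sizes <- table(factor(assignment$labels, levels = 0:(assignment$k - 1L)))
  graphics::barplot(sizes, xlab = "cluster", ylab = "molecules",
                    main = "Cluster size distribution", ...)
  invisible(assignment)
}

#' Scatter plot of 2D coordinates colored by cluster
#'
#' Points are colored by label and each cluster is annotated with its id at
#' the cluster median position.
#'
#' @param coords n x 2 matrix (e.g. from [tsne_2d()]).
#' @param labels Integer cluster labels.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_tsne_clusters <- function(coords, labels, ...) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L,
            nrow(coords) == length(labels))
  lev <- sort(unique(labels))
  cols <- grDevices::hcl.colors(max(length(lev), 3L), "Dark 3")
  graphics::plot(coords, col = cols[match(labels, lev)], pch = 16,
                 cex = 0.6, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  for (i in seq_along(lev)) {
    sel <- labels == lev[i]
    graphics::text(stats::median(coords[sel, 1L]),
                   stats::median(coords[sel, 2L]),
                   labels = lev[i], font = 2)
  }
  invisible(coords)
}

#' Tanimoto similarity heatmap with cluster-block outlines
#'
#' @param mat Symmetric similarity matrix from [tanimoto_matrix()].
#' @param groups Optional vector of group (cluster) ids, one per row of
#'   `mat`, assumed contiguous; block boundaries are outlined.
#' @param ... Passed to [graphics::image()].
#' @export
plot_tanimoto_heatmap <- function(mat, groups = NULL, ...) {
  n <- nrow(mat)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_len(n), seq_len(n), t(mat[n:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "", main = "Tanimoto similarity", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(mat), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(mat)), las = 2,
                 cex.axis = 0.6)
  if (!is.null(groups)) {
    bounds <- which(diff(as.integer(factor(groups, levels = unique(groups)))) != 0)
    starts <- c(1L, bounds + 1L)
    ends <- c(bounds, n)
    for (g in seq_along(starts)) {
      graphics::rect(starts[g] - 0.5, n - ends[g] + 0.5,
                     ends[g] + 0.5, n - starts[g] + 1.5,
                     border = "orange", lwd = 2)
    }
  }
  invisible(mat)
}
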