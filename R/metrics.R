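#' @name validation_metrics
#' @title Internal clustering validation indices
#'
#' @description
#' Three ground-truth-free indices quantify clustering quality under the
#' Euclidean metric:
#'
#' * **Silhouette** `s = (b - a) / max(a, b)` averaged over points, where `a`
#'   is the mean distance to the other members of the point's own cluster and
#'   `b` the mean distance to the members of the nearest other cluster;
#'   bounded in \[-1, 1\], higher is better. Points in singleton clusters
#'   contribute 0.
#' * **Calinski-Harabasz** `(tr(B_k) / tr(W_k)) * ((n - k) / (k - 1))`, the
#'   variance-ratio of between-cluster to within-cluster dispersion; higher
#'   is better.
#' * **Davies-Bouldin** `(1/k) * sum_u max_{v != u} (s_u + s_v) / d_uv`,
#'   where `s_w` is the mean distance of cluster-`w` points to their centroid
#'   and `d_uv` the centroid distance; lower is better.
#'
#' All three are invariant to cluster relabeling and to rigid translation of
#' the data.
NULL

.check_labels <- function(X, labels) {
  stopifnot(is.matrix(X), nrow(X) == length(labels))
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (k < 2L) stop("at least 2 clusters are required", call. = FALSE)
  labels
}

#' Mean Silhouette coefficient
#'
#' @param X Numeric matrix (points x dimensions).
#' @param labels Integer cluster labels, one per row of `X`.
#' @return Mean Silhouette over all points, in \[-1, 1\].
#' @export
silhouette_index <- function(X, labels) {
  labels <- .check_labels(X, labels)
  # centering is a no-op for the index but curbs cancellation error in the
  # expanded squared-distance form
  X <- sweep(X, 2L, colMeans(X), "-")
  lev <- sort(unique(labels))
  k <- length(lev)
  n <- nrow(X)
  Z <- matrix(0, n, k)
  Z[cbind(seq_len(n), match(labels, lev))] <- 1
  sizes <- colSums(Z)
  sq <- rowSums(X^2)
  s <- numeric(n)
  own <- match(labels, lev)
  # chunked n x k matrix of summed distances to each cluster
  chunk <- max(1L, floor(2^22 / n))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    d2[cbind(seq_along(idx), idx)] <- 0  # exact self-distance
    d <- sqrt(pmax(d2, 0))
    S <- d %*% Z  # summed distance from each point in chunk to each cluster
    for (j in seq_along(idx)) {
      i <- idx[j]
      q <- own[i]
      if (sizes[q] <= 1L) { s[i] <- 0; next }
      a <- S[j, q] / (sizes[q] - 1L)
      b <- min(S[j, -q] / sizes[-q])
      s[i] <- (b - a) / max(a, b)
    }
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' @inheritParams silhouette_index
#' @return Non-negative score; `Inf` (with a warning) when the
#'   within-cluster dispersion is exactly zero.
#' @export
calinski_harabasz <- function(X, labels) {
  labels <- .check_labels(X, labels)
  lev <- sort(unique(labels))
  k <- length(lev)
  n <- nrow(X)
  if (n <= k) stop("need more points than clusters", call. = FALSE)
  grand <- colMeans(X)
  tr_b <- 0
  tr_w <- 0
  for (q in lev) {
    Xq <- X[labels == q, , drop = FALSE]
    cq <- colMeans(Xq)
    tr_b <- tr_b + nrow(Xq) * sum((cq - grand)^2)
    tr_w <- tr_w + sum(sweep(Xq, 2L, cq, "-")^2)
  }
  if (tr_w == 0) {
    warning("within-cluster dispersion is zero; index is infinite",
            call. = FALSE)
    return(Inf)
  }
  (tr_b / tr_w) * ((n - k) / (k - 1))
}

#' Davies-Bouldin index
#'
#' @inheritParams silhouette_index
#' @return Non-negative score, lower is better.
#' @export
davies_bouldin <- function(X, labels) {
  labels <- .check_labels(X, labels)
  lev <- sort(unique(labels))
  k <- length(lev)
  centroids <- t(vapply(lev, function(q) colMeans(X[labels == q, , drop = FALSE]),
                        numeric(ncol(X))))
  spread <- vapply(seq_along(lev), function(qi) {
    Xq <- X[labels == lev[qi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xq, 2L, centroids[qi, ], "-")^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(centroids))
  if (any(d[upper.tri(d)] < 1e-12)) {
    co <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("coincident centroids for clusters ", lev[co[1]], " and ", lev[co[2]],
         call. = FALSE)
  }
  r <- vapply(seq_len(k), function(u) {
    max(vapply(setdiff(seq_len(k), u), function(v) {
      (spread[u] + spread[v]) / d[u, v]
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' All three internal indices at once
#'
#' @inheritParams silhouette_index
#' @return An object of class `internal_indices`: named list with
#'   `silhouette`, `calinski_harabasz`, `davies_bouldin`.
#' @export
evaluate_all <- function(X, labels) {
  structure(list(
    silhouette = silhouette_index(X, labels),
    calinski_harabasz = calinski_harabasz(X, labels),
    davies_bouldin = davies_bouldin(X, labels)),
    class = "internal_indices")
}

#' @export
print.internal_indices <- function(x, ...) {
  cat(sprintf("Silhouette: %.4f  Calinski-Harabasz: %.3f  Davies-Bouldin: %.3f\n",
              x$silhouette, x$calinski_harabasz, x$davies_bouldin))
  invisible(x)
}

#' Format clustering evaluations as a comparison table
#'
#' One row per clustering run: method, number of clusters, and the three
#' internal indices.
#'
#' @param results Named list; each element a list with `k` and an
#'   `internal_indices` object under `indices`.
#' @return A data frame with columns `method`, `n_clusters`,
#'   `calinski_harabasz`, `silhouette`, `davies_bouldin`.
#' @export
index_report <- function(results) {
  data.frame(
    method = names(results),
    n_clusters = vapply(results, function(r) as.integer(r$k), integer(1)),
    calinski_harabasz = vapply(results, function(r)
      r$indices$calinski_harabasz, numeric(1)),
    silhouette = vapply(results, function(r) r$indices$silhouette, numeric(1)),
    davies_bouldin = vapply(results, function(r)
      r$indices$davies_bouldin, numeric(1)),
    row.names = NULL)
}
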