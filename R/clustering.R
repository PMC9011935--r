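#' @name clustering
#' @title K-means and BIRCH clustering with Silhouette-based model selection
#'
#' @description
#' Molecules (raw feature tables or embeddings) are grouped under the
#' Euclidean metric. K-means runs Lloyd iterations from k-means++ seeding,
#' keeping the best of `n_init` restarts by inertia. BIRCH summarizes the
#' data into a clustering-feature (CF) tree and clusters the leaf entries in
#' a global step. The number of clusters is chosen by scanning a grid of
#' candidate counts and selecting the plateau onset of the mean Silhouette
#' score.
#'
#' Cluster labels follow the `0 .. k-1` convention throughout.
NULL

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.sq_dist <- function(A, B) {
  # squared Euclidean distances, rows of A x rows of B
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  mind2 <- .sq_dist(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(mind2) > 0) mind2 / sum(mind2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- X[idx, ]
    mind2 <- pmin(mind2, .sq_dist(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

.lloyd <- function(X, centers, max_iter, tol, weights = NULL) {
  n <- nrow(X)
  k <- nrow(centers)
  w <- if (is.null(weights)) rep(1, n) else weights
  inertia_history <- numeric(0)
  labels <- integer(n)
  for (iter in seq_len(max_iter)) {
    d2 <- .sq_dist(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    # empty clusters: re-seed at the point farthest from its centroid
    for (q in which(tabulate(labels, k) == 0L)) {
      far <- which.max(d2[cbind(seq_len(n), labels)])
      centers[q, ] <- X[far, ]
      d2[, q] <- .sq_dist(X, centers[q, , drop = FALSE])[, 1L]
      labels <- max.col(-d2, ties.method = "first")
    }
    inertia_history <- c(inertia_history,
                         sum(w * d2[cbind(seq_len(n), labels)]))
    new_centers <- centers
    for (q in seq_len(k)) {
      sel <- labels == q
      if (any(sel)) {
        new_centers[q, ] <- colSums(X[sel, , drop = FALSE] * w[sel]) /
          sum(w[sel])
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- .sq_dist(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(w * d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       n_iter = iter, inertia_history = inertia_history)
}

#' K-means clustering (k-means++ seeding, Lloyd iterations)
#'
#' Runs `n_init` independent restarts from k-means++ seedings and keeps the
#' solution with the lowest within-cluster sum of squared distances
#' (inertia). Iterations stop when the largest centroid shift drops below
#' `tol` or after `max_iter` rounds. Clusters that empty out during a round
#' are re-seeded at the point farthest from its current centroid.
#'
#' @param X Numeric matrix (points x dimensions).
#' @param k Number of clusters, `2 <= k <= nrow(X)`.
#' @param seed Integer seed controlling all restarts.
#' @param n_init Number of restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Centroid-shift convergence threshold (default 1e-4).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integers in `0 .. k-1`, row-aligned with `X`), `centroids` (k x dim),
#'   `k`, `inertia`, `inertia_history` (per iteration of the winning
#'   restart), `n_iter` and `method = "kmeans"`.
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_init = 10L, max_iter = 300L,
                           tol = 1e-4) {
  stopifnot(is.matrix(X))
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of points (",
                        nrow(X), ")", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(n_init)) {
      fit <- .lloyd(X, .kmeanspp_init(X, k), max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(list(
    labels = best$labels - 1L,
    centroids = best$centers,
    k = as.integer(k),
    inertia = best$inertia,
    inertia_history = best$inertia_history,
    n_iter = best$n_iter,
    method = "kmeans"), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %s>  k = %d, n = %d, inertia = %.4g\n",
              x$method, x$k, length(x$labels), x$inertia))
  print(utils::head(table(x$labels), 20))
  invisible(x)
}

# --- BIRCH ------------------------------------------------------------------

.cf_new_node <- function(leaf) {
  e <- new.env(parent = emptyenv())
  e$leaf <- leaf
  e$entries <- list()   # leaf: list(n, ls, ss); internal: child nodes
  e
}

.cf_stats <- function(entry) {
  if (is.environment(entry)) {
    # internal child node: aggregate its entries
    agg <- list(n = 0, ls = NULL, ss = 0)
    for (sub in entry$entries) {
      s <- .cf_stats(sub)
      agg$n <- agg$n + s$n
      agg$ls <- if (is.null(agg$ls)) s$ls else agg$ls + s$ls
      agg$ss <- agg$ss + s$ss
    }
    agg
  } else entry
}

.cf_centroid <- function(entry) {
  s <- .cf_stats(entry)
  s$ls / s$n
}

.cf_radius <- function(n, ls, ss) {
  sqrt(max(ss / n - sum((ls / n)^2), 0))
}

.cf_split <- function(node) {
  cents <- t(vapply(node$entries, .cf_centroid,
                    numeric(length(.cf_centroid(node$entries[[1]])))))
  d <- as.matrix(stats::dist(cents))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  s1 <- far[1]; s2 <- far[2]
  left <- .cf_new_node(node$leaf)
  right <- .cf_new_node(node$leaf)
  for (i in seq_along(node$entries)) {
    if (d[i, s1] <= d[i, s2]) left$entries <- c(left$entries, node$entries[i])
    else right$entries <- c(right$entries, node$entries[i])
  }
  list(left, right)
}

.cf_insert <- function(node, x, threshold, branching) {
  if (node$leaf) {
    if (length(node$entries) > 0L) {
      cents <- t(vapply(node$entries, .cf_centroid, numeric(length(x))))
      d2 <- colSums((t(cents) - x)^2)
      j <- which.min(d2)
      e <- node$entries[[j]]
      n2 <- e$n + 1; ls2 <- e$ls + x; ss2 <- e$ss + sum(x^2)
      if (.cf_radius(n2, ls2, ss2) <= threshold) {
        node$entries[[j]] <- list(n = n2, ls = ls2, ss = ss2)
        return(NULL)
      }
    }
    node$entries <- c(node$entries, list(list(n = 1, ls = x, ss = sum(x^2))))
    if (length(node$entries) > branching) return(.cf_split(node))
    return(NULL)
  }
  # internal node: descend into the child with the closest centroid
  cents <- t(vapply(node$entries, .cf_centroid, numeric(length(x))))
  j <- which.min(colSums((t(cents) - x)^2))
  split <- .cf_insert(node$entries[[j]], x, threshold, branching)
  if (!is.null(split)) {
    node$entries <- c(node$entries[-j], split)
    if (length(node$entries) > branching) return(.cf_split(node))
  }
  NULL
}

.cf_leaf_entries <- function(node) {
  if (node$leaf) return(node$entries)
  do.call(c, lapply(node$entries, .cf_leaf_entries))
}

# deterministic farthest-first initialization (weighted start at heaviest)
.farthest_first <- function(X, k, weights = NULL) {
  n <- nrow(X)
  w <- if (is.null(weights)) rep(1, n) else weights
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[which.max(w), ]
  mind2 <- .sq_dist(X, centers[1L, , drop = FALSE])[, 1L]
  for (j in seq_len(k - 1L) + 1L) {
    centers[j, ] <- X[which.max(mind2), ]
    mind2 <- pmin(mind2, .sq_dist(X, centers[j, , drop = FALSE])[, 1L])
  }
  centers
}

#' BIRCH clustering
#'
#' Builds a CF tree (clustering features: count, linear sum, squared sum) by
#' inserting points in input order; a point is absorbed into the closest leaf
#' entry when the merged entry's radius stays below `threshold`, otherwise it
#' opens a new entry, and nodes exceeding `branching_factor` are split on
#' their farthest entry pair. The leaf-entry centroids (weighted by entry
#' size) are then clustered into `k` groups by Lloyd iterations from a
#' deterministic farthest-first seeding, and each point inherits the cluster
#' of its leaf entry. The whole procedure is deterministic given the input
#' order.
#'
#' When the tree summarizes the data into fewer than `k` entries (for
#' example when `threshold` exceeds the data diameter), the global step falls
#' back to clustering the raw points so `k` clusters are still returned.
#'
#' @inheritParams kmeans_cluster
#' @param threshold Maximum radius of a leaf entry (default 0.5).
#' @param branching_factor Maximum entries per node (default 50).
#' @return A `cluster_assignment` (see [kmeans_cluster()]); `centroids` are
#'   the global-step cluster centroids and `method = "birch"`.
#' @export
birch_cluster <- function(X, k, threshold = 0.5, branching_factor = 50L) {
  stopifnot(is.matrix(X))
  if (k > nrow(X)) stop("k (", k, ") exceeds the number of points (",
                        nrow(X), ")", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  root <- .cf_new_node(TRUE)
  for (i in seq_len(nrow(X))) {
    split <- .cf_insert(root, X[i, ], threshold, branching_factor)
    if (!is.null(split)) {
      new_root <- .cf_new_node(FALSE)
      new_root$entries <- split
      root <- new_root
    }
  }
  entries <- .cf_leaf_entries(root)
  cents <- t(vapply(entries, function(e) e$ls / e$n, numeric(ncol(X))))
  sizes <- vapply(entries, `[[`, numeric(1), "n")

  if (nrow(cents) < k) {
    fit <- .lloyd(X, .farthest_first(X, k), max_iter = 100L, tol = 1e-6)
    labels <- fit$labels
    centers <- fit$centers
  } else {
    fit <- .lloyd(cents, .farthest_first(cents, k, sizes),
                  max_iter = 100L, tol = 1e-6, weights = sizes)
    centers <- fit$centers
    # route each point through its nearest leaf entry
    entry_of <- max.col(-.sq_dist(X, cents), ties.method = "first")
    labels <- fit$labels[entry_of]
    # guard: global step on summaries can still leave a cluster unused
    for (q in which(tabulate(labels, k) == 0L)) {
      d2q <- .sq_dist(X, centers[q, , drop = FALSE])[, 1L]
      labels[which.min(d2q)] <- q
    }
  }
  d2 <- .sq_dist(X, centers)
  inertia <- sum(d2[cbind(seq_len(nrow(X)), labels)])
  structure(list(
    labels = labels - 1L,
    centroids = centers,
    k = as.integer(k),
    inertia = inertia,
    inertia_history = numeric(0),
    n_iter = fit$n_iter,
    method = "birch",
    n_leaf_entries = nrow(cents)), class = "cluster_assignment")
}

# --- cluster-count selection ------------------------------------------------

#' Silhouette scan over candidate cluster counts
#'
#' Clusters `X` at every `k` in `k_grid` and records the mean Silhouette
#' score. For large datasets the Silhouette is computed on a seeded
#' subsample of up to `subsample` points (the clustering itself always uses
#' all points). Scores can be cached to a CSV file so interrupted scans
#' resume where they stopped.
#'
#' @param X Numeric matrix (points x dimensions).
#' @param k_grid Increasing integer vector of candidate cluster counts
#'   (default `seq(5, 200, by = 5)`).
#' @param method `"kmeans"` or `"birch"`.
#' @param seed Seed for clustering restarts and the Silhouette subsample.
#' @param subsample Maximum points used for the Silhouette (default 10000).
#' @param cache_file Optional CSV path for resumable scans.
#' @param ... Further arguments passed to the clustering function.
#' @return An object of class `silhouette_scan`: list with `grid`, `scores`,
#'   `method`, `subsample_size`, `seed`.
#' @export
scan_k <- function(X, k_grid = seq(5L, 200L, by = 5L),
                   method = c("kmeans", "birch"), seed = 1L,
                   subsample = 10000L, cache_file = NULL, ...) {
  method <- match.arg(method)
  stopifnot(is.matrix(X))
  k_grid <- as.integer(k_grid)
  if (any(diff(k_grid) <= 0L)) stop("k_grid must be strictly increasing",
                                    call. = FALSE)
  if (max(k_grid) >= nrow(X)) stop("max(k_grid) must be below the number of points",
                                   call. = FALSE)
  sub_idx <- if (nrow(X) > subsample) {
    .with_seed(seed, sort(sample.int(nrow(X), subsample)))
  } else seq_len(nrow(X))

  cached <- data.frame(k = integer(0), silhouette = numeric(0))
  if (!is.null(cache_file) && file.exists(cache_file)) {
    cached <- utils::read.csv(cache_file)
  }
  scores <- rep(NA_real_, length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    hit <- match(k, cached$k)
    if (!is.na(hit)) {
      scores[i] <- cached$silhouette[hit]
      next
    }
    fit <- if (method == "kmeans") kmeans_cluster(X, k, seed = seed + k, ...)
           else birch_cluster(X, k, ...)
    lab_sub <- fit$labels[sub_idx]
    scores[i] <- if (length(unique(lab_sub)) < 2L) NA_real_
                 else silhouette_index(X[sub_idx, , drop = FALSE], lab_sub)
    if (!is.null(cache_file)) {
      done <- seq_len(i)[!is.na(scores[seq_len(i)])]
      # full-precision scores so resumed scans are bit-identical
      utils::write.csv(data.frame(k = k_grid[done],
                                  silhouette = sprintf("%.17g", scores[done])),
                       cache_file, row.names = FALSE, quote = FALSE)
    }
  }
  structure(list(grid = k_grid, scores = scores, method = method,
                 subsample_size = length(sub_idx), seed = seed),
            class = "silhouette_scan")
}

#' @export
print.silhouette_scan <- function(x, ...) {
  cat(sprintf("<silhouette_scan: %s>  k in [%d, %d], %d points scored\n",
              x$method, min(x$grid), max(x$grid), x$subsample_size))
  print(data.frame(k = x$grid, silhouette = round(x$scores, 4)))
  invisible(x)
}

#' Select the cluster count at the Silhouette plateau onset
#'
#' Returns the smallest grid value whose score differs by at most `epsilon`
#' from every score in the next `window` grid points (the point where the
#' curve becomes "relatively stable"). When no such plateau exists the
#' argmax of the score is returned instead; the rule actually applied is
#' recorded in the `"rule"` attribute and reported via `message()`.
#'
#' @param scan A `silhouette_scan`.
#' @param window Number of forward grid points that must stay within
#'   `epsilon` (default 2).
#' @param epsilon Stability tolerance on the score (default 0.01).
#' @return The selected `k` (integer) with attribute `"rule"` =
#'   `"plateau"` or `"argmax"`.
#' @export
select_k <- function(scan, window = 2L, epsilon = 0.01) {
  stopifnot(inherits(scan, "silhouette_scan"), length(scan$grid) >= 1L)
  g <- scan$grid
  s <- scan$scores
  n <- length(g)
  for (i in seq_len(n)) {
    ahead <- seq(i + 1L, length.out = window)
    ahead <- ahead[ahead <= n]
    if (length(ahead) < window) break
    if (all(abs(s[ahead] - s[i]) <= epsilon, na.rm = TRUE) && !is.na(s[i])) {
      message("select_k: plateau onset at k = ", g[i],
              " (window ", window, ", epsilon ", epsilon, ")")
      return(structure(g[i], rule = "plateau"))
    }
  }
  k <- g[which.max(s)]
  message("select_k: no plateau; falling back to argmax k = ", k)
  structure(k, rule = "argmax")
}
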