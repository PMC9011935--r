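#' t-SNE projection of an embedding to two dimensions
#'
#' Exact (non-tree-accelerated) t-distributed stochastic neighbour
#' embedding: input similarities are Gaussian with per-point bandwidths
#' calibrated to the target perplexity by bisection; the low-dimensional
#' map minimizes the Kullback-Leibler divergence to Student-t similarities
#' by gradient descent with momentum, adaptive gains and early
#' exaggeration. Complexity is O(n^2) per iteration, adequate for the
#' visualization sizes this package targets.
#'
#' @param E Numeric matrix (points x dimensions), e.g. an
#'   `embedding_matrix`.
#' @param perplexity Target perplexity (default 30); requires
#'   `nrow(E) > 3 * perplexity`.
#' @param seed Integer seed for the initial map.
#' @param max_iter Gradient iterations (default 500).
#' @param learning_rate Step size (default `max(nrow(E) / 12, 50)`).
#' @return n x 2 coordinate matrix (row-aligned with `E`).
#' @export
tsne_2d <- function(E, perplexity = 30, seed = 1L, max_iter = 500L,
                    learning_rate = NULL) {
  E <- unclass(E)
  stopifnot(is.matrix(E))
  n <- nrow(E)
  if (n <= 3 * perplexity) {
    stop("perplexity ", perplexity, " is too large for ", n,
         " points; choose perplexity < n/3", call. = FALSE)
  }
  if (is.null(learning_rate)) learning_rate <- max(n / 12, 50)

  D2 <- .sq_dist(E, E)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- 0; hi <- Inf
    for (iter in seq_len(50L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  .with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration <- 12
    momentum <- 0.5
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= 100L) P * exaggeration else P
      if (iter == 21L) momentum <- 0.8
      num <- 1 / (1 + .sq_dist(Y, Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - learning_rate * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y), "-")
    }
    colnames(Y) <- c("tsne1", "tsne2")
    rownames(Y) <- rownames(E)
    Y
  })
}
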