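# Independent brute-force oracles, written from the index and PCA
# definitions directly. They deliberately share no code with the package
# implementations they check.

oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(q) {
      mean(D[i, labels == q])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_calinski_harabasz <- function(X, labels) {
  # explicit outer-product dispersion matrices
  lev <- unique(labels)
  k <- length(lev)
  n <- nrow(X)
  cE <- colMeans(X)
  Bk <- matrix(0, ncol(X), ncol(X))
  Wk <- matrix(0, ncol(X), ncol(X))
  for (q in lev) {
    Xq <- X[labels == q, , drop = FALSE]
    cq <- colMeans(Xq)
    Bk <- Bk + nrow(Xq) * tcrossprod(cq - cE)
    for (r in seq_len(nrow(Xq))) {
      Wk <- Wk + tcrossprod(Xq[r, ] - cq)
    }
  }
  (sum(diag(Bk)) / sum(diag(Wk))) * ((n - k) / (k - 1))
}

oracle_davies_bouldin <- function(X, labels) {
  lev <- sort(unique(labels))
  k <- length(lev)
  cents <- lapply(lev, function(q) colMeans(X[labels == q, , drop = FALSE]))
  s <- vapply(seq_along(lev), function(qi) {
    Xq <- X[labels == lev[qi], , drop = FALSE]
    mean(apply(Xq, 1, function(x) sqrt(sum((x - cents[[qi]])^2))))
  }, numeric(1))
  total <- 0
  for (u in seq_len(k)) {
    best <- -Inf
    for (v in seq_len(k)) {
      if (v == u) next
      duv <- sqrt(sum((cents[[u]] - cents[[v]])^2))
      best <- max(best, (s[u] + s[v]) / duv)
    }
    total <- total + best
  }
  total / k
}

# PC1 scores by direct eigendecomposition of the column covariance
oracle_pc1_scores <- function(m) {
  centered <- sweep(m, 2L, colMeans(m), "-")
  cv <- stats::cov(centered)
  v1 <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  drop(centered %*% v1)
}

# agreement up to a global sign flip
expect_equal_up_to_sign <- function(x, y, tol) {
  expect_true(max(abs(x - y)) <= tol || max(abs(x + y)) <= tol)
}

# neighbourhood-preservation score of a map Y against reference space X
trustworthiness <- function(X, Y, k = 10L) {
  n <- nrow(X)
  DX <- as.matrix(stats::dist(X))
  DY <- as.matrix(stats::dist(Y))
  diag(DX) <- diag(DY) <- Inf
  rank_x <- t(apply(DX, 1, rank, ties.method = "first"))
  total <- 0
  for (i in seq_len(n)) {
    nn_y <- order(DY[i, ])[seq_len(k)]
    for (j in nn_y) {
      r <- rank_x[i, j]
      if (r > k) total <- total + (r - k)
    }
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

random_instance <- function(seed, n_max = 50L, dim_max = 5L, k_max = 4L) {
  set.seed(seed)
  n <- sample(10:n_max, 1)
  d <- sample(2:dim_max, 1)
  k <- sample(2:k_max, 1)
  X <- matrix(rnorm(n * d), n)
  labels <- sample(0:(k - 1L), n, replace = TRUE)
  # ensure every cluster is populated
  labels[seq_len(k)] <- 0:(k - 1L)
  list(X = X, labels = labels)
}
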