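test_that("silhouette matches a hand-worked two-cluster instance", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(0, 0, 1, 1)
  # point 0: a = 1, b = mean(10, 11) = 10.5; symmetric for the rest
  expected <- mean(c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                     (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(silhouette_index(X, labels), expected, tolerance = 1e-12)
  expect_equal(silhouette_index(X, labels), oracle_silhouette(X, labels),
               tolerance = 1e-12)
})

test_that("all three indices match their brute-force oracles", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    expect_equal(silhouette_index(inst$X, inst$labels),
                 oracle_silhouette(inst$X, inst$labels), tolerance = 1e-9)
    expect_equal(calinski_harabasz(inst$X, inst$labels),
                 oracle_calinski_harabasz(inst$X, inst$labels),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(inst$X, inst$labels),
                 oracle_davies_bouldin(inst$X, inst$labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette separation limit and random-label baseline", {
  # widely separated tight clusters approach s = 1
  for (sep in c(10, 100, 1000)) {
    X <- rbind(matrix(rnorm(20, sd = 0.1), 10),
               matrix(rnorm(20, sd = 0.1) + sep, 10))
    s <- silhouette_index(X, rep(0:1, each = 10))
    expect_gt(s, 1 - 5 / sep)
  }
  # random labels on a single blob stay near zero
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(200 * 3), 200)
    s <- silhouette_index(X, sample(0:2, 200, replace = TRUE))
    expect_lt(abs(s), 0.1)
  }
})

test_that("silhouette stays within [-1, 1] on fuzzed instances", {
  for (seed in 1:200) {
    inst <- random_instance(seed, n_max = 30)
    s <- silhouette_index(inst$X, inst$labels)
    expect_gte(s, -1)
    expect_lte(s, 1)
  }
})

test_that("Calinski-Harabasz invariances and monotonicity", {
  inst <- random_instance(101)
  base <- calinski_harabasz(inst$X, inst$labels)
  shifted <- sweep(inst$X, 2, rep(7.3, ncol(inst$X)), "+")
  expect_equal(calinski_harabasz(shifted, inst$labels), base,
               tolerance = 1e-9)
  # increasing separation of two fixed-shape blobs strictly increases S
  set.seed(5)
  blob <- matrix(rnorm(60), 30)
  labels <- rep(0:1, each = 15)
  scores <- vapply(c(1, 2, 4, 8, 16), function(sep) {
    X <- blob
    X[16:30, 1] <- X[16:30, 1] + sep
    calinski_harabasz(X, labels)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  # zero within-cluster dispersion is an infinite-score sentinel
  X0 <- matrix(rep(c(0, 1), each = 3), ncol = 1)
  expect_warning(s0 <- calinski_harabasz(X0, rep(0:1, each = 3)), "infinite")
  expect_identical(s0, Inf)
})

test_that("Davies-Bouldin scaling law and directionality", {
  # identical-shape blobs: doubling centroid separation halves the index
  set.seed(6)
  cloud <- matrix(rnorm(40), 20)
  mk <- function(sep) rbind(cloud, sweep(cloud, 2, c(sep, 0), "+"))
  labels <- rep(0:1, each = 20)
  db1 <- davies_bouldin(mk(10), labels)
  db2 <- davies_bouldin(mk(20), labels)
  expect_equal(db2, db1 / 2, tolerance = 1e-9)
  # far tight blobs score lower than overlapping blobs
  expect_lt(davies_bouldin(mk(50), labels), davies_bouldin(mk(1), labels))
  expect_error(davies_bouldin(rbind(cloud, cloud), labels), "coincident")
})

test_that("directionality sweep: silhouette and CH rise, DB falls", {
  set.seed(7)
  seps <- c(1, 2, 4, 8)
  sil <- ch <- db <- numeric(length(seps))
  for (i in seq_along(seps)) {
    gm <- gaussian_mixture(mixture_spec(300, 5, 3, seps[i], seed = 42))
    sil[i] <- silhouette_index(gm$X, gm$labels)
    ch[i] <- calinski_harabasz(gm$X, gm$labels)
    db[i] <- davies_bouldin(gm$X, gm$labels)
  }
  expect_true(all(diff(sil) > 0))
  expect_true(all(diff(ch) > 0))
  expect_true(all(diff(db) < 0))
})

test_that("indices are invariant to label permutation; degenerate errors", {
  inst <- random_instance(77)
  e1 <- evaluate_all(inst$X, inst$labels)
  relabeled <- (inst$labels + 1) %% length(unique(inst$labels))
  e2 <- evaluate_all(inst$X, relabeled)
  expect_equal(unclass(e1), unclass(e2), tolerance = 1e-12,
               ignore_attr = TRUE)
  e3 <- evaluate_all(inst$X, inst$labels)
  expect_identical(unclass(e1), unclass(e3))
  expect_error(silhouette_index(inst$X, rep(0, nrow(inst$X))), "2 clusters")
  expect_error(calinski_harabasz(inst$X, rep(0, nrow(inst$X))), "2 clusters")
})

test_that("index_report emits the method/#clusters/three-indices layout", {
  inst <- random_instance(55)
  rep1 <- index_report(list(
    "K-means" = list(k = 3, indices = evaluate_all(inst$X, inst$labels))))
  expect_identical(names(rep1), c("method", "n_clusters",
                                  "calinski_harabasz", "silhouette",
                                  "davies_bouldin"))
  expect_identical(nrow(rep1), 1L)
})
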