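test_that("reconstruction loss: exactness, scaling, shape checks", {
  x <- matrix(rnorm(12), 3)
  expect_identical(reconstruction_loss(x, x), 0)
  expect_identical(reconstruction_loss(c(0, 0), c(1, 1)), 2)
  r <- matrix(rnorm(12), 3)
  expect_equal(reconstruction_loss(x, x + r / 2),
               reconstruction_loss(x, x + r) / 4, tolerance = 1e-12)
  expect_error(reconstruction_loss(x, x[, 1:2]), "mismatch")
})

test_that("VAE loss: KL term reference values and positivity", {
  x <- matrix(rnorm(8), 2)
  # standard-normal posterior: KL exactly zero
  expect_identical(vae_loss(x, x, matrix(0, 2, 3), matrix(1, 2, 3), beta = 2),
                   0)
  # beta = 0 reduces to the reconstruction loss
  xh <- x + 0.5
  expect_identical(vae_loss(x, xh, matrix(1, 2, 3), matrix(0.3, 2, 3), 0),
                   reconstruction_loss(x, xh))
  # d = 1, E = 1, V = 1, beta = 2: KL = (2/2)(1 - 0 - 1 + 1) = 1
  expect_equal(vae_loss(x, x, matrix(1, 2, 1), matrix(1, 2, 1), beta = 2), 1,
               tolerance = 1e-12)
  expect_error(vae_loss(x, x, matrix(0, 2, 1), matrix(-1, 2, 1)), "positive")
  # v - log v - 1 >= 0 for all v > 0
  v <- exp(runif(1000, -6, 6))
  expect_true(all(v - log(v) - 1 >= 0))
  set.seed(2)
  for (i in 1:20) {
    mu <- matrix(rnorm(6), 2)
    vv <- matrix(exp(rnorm(6)), 2)
    expect_gte(vae_loss(x[, 1:3] * 0, x[, 1:3] * 0, mu, vv, 1), 0)
  }
})

make_rank2_table <- function(m = 500, p = 40, seed = 3, noise = 0.05) {
  set.seed(seed)
  L <- matrix(rnorm(m * 2), m)
  W <- matrix(rnorm(2 * p), 2)
  L %*% W + matrix(rnorm(m * p, sd = noise), m)
}

test_that("the AE compresses planted rank-2 structure", {
  X <- make_rank2_table()
  fit <- train_autoencoder(X, training_config(latent_dim = 2, epochs = 100,
                                              batch_size = 128, seed = 4))
  final <- reconstruction_loss(X, predict(fit, X))
  total_var <- sum(apply(X, 2, stats::var))
  expect_lt(final, 0.10 * total_var)
  # a linear PCA reconstruction bounds what any 2-dim code can achieve
  pc <- stats::prcomp(X, rank. = 2)
  pca_recon <- reconstruction_loss(
    X, sweep(pc$x %*% t(pc$rotation), 2, pc$center, "+"))
  expect_gte(final, pca_recon - 1e-8)
  # training reduces the loss
  expect_lt(mean(utils::tail(fit$loss_history, 5)),
            mean(utils::head(fit$loss_history, 5)))
})

test_that("training is reproducible from the seed", {
  X <- make_rank2_table(m = 150, p = 20)
  cfg <- training_config(latent_dim = 2, epochs = 10, batch_size = 64,
                         seed = 7)
  f1 <- suppressWarnings(train_autoencoder(X, cfg))
  f2 <- suppressWarnings(train_autoencoder(X, cfg))
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$loss_history, f2$loss_history)
  f3 <- suppressWarnings(train_autoencoder(X, cfg, variational = TRUE))
  f4 <- suppressWarnings(train_autoencoder(X, cfg, variational = TRUE))
  expect_identical(f3$embedding, f4$embedding)
})

test_that("encode is deterministic, row-equivariant and shape-correct", {
  X <- make_rank2_table(m = 150, p = 20)
  fit <- suppressWarnings(train_autoencoder(
    X, training_config(latent_dim = 3, epochs = 5, batch_size = 64, seed = 1),
    variational = TRUE))
  e1 <- encode(fit, X)
  e2 <- encode(fit, X)
  expect_identical(unclass(e1), unclass(e2))
  expect_identical(dim(e1), c(150L, 3L))
  perm <- sample(150)
  expect_equal(unclass(encode(fit, X[perm, ])), unclass(e1)[perm, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(encode(fit, X[, 1:10]), "columns")
})

test_that("AE and near-beta-zero VAE reach comparable reconstructions", {
  X <- make_rank2_table()
  ae <- train_autoencoder(X, training_config(latent_dim = 2, epochs = 100,
                                             batch_size = 128, seed = 4))
  vae <- train_autoencoder(X, training_config(latent_dim = 2, epochs = 100,
                                              batch_size = 128, seed = 4,
                                              beta = 0),
                           variational = TRUE)
  r_ae <- reconstruction_loss(X, predict(ae, X))
  r_vae <- reconstruction_loss(X, predict(vae, X))
  expect_lt(max(r_ae, r_vae) / min(r_ae, r_vae), 2)
})

test_that("VAE mean-embedding preserves the true latent neighbourhoods", {
  set.seed(8)
  m <- 300; d_true <- 2; p <- 20
  Z <- matrix(rnorm(m * d_true), m)
  A <- matrix(rnorm(d_true * p), d_true)
  X <- Z %*% A + matrix(rnorm(m * p, sd = 0.05), m)
  fit <- train_autoencoder(X, training_config(latent_dim = d_true,
                                              epochs = 120, batch_size = 128,
                                              seed = 9, beta = 0.1),
                           variational = TRUE)
  tw <- trustworthiness(Z, unclass(fit$embedding), k = 10L)
  expect_gt(tw, 0.9)
})

test_that("undersized tables reduce the batch size with a warning", {
  X <- make_rank2_table(m = 60, p = 10)
  expect_warning(
    fit <- train_autoencoder(X, training_config(latent_dim = 2, epochs = 3,
                                                batch_size = 256, seed = 2)),
    "reducing batch_size")
  expect_identical(fit$batch_size_used, 30L)
})
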