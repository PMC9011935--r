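#' @name embedding
#' @title Autoencoder and variational autoencoder embeddings
#'
#' @description
#' The fused feature table is compressed to a low-dimensional latent code
#' with a feed-forward autoencoder. The encoder applies six blocks of
#' (affine map, batch normalization, ReLU) followed by an affine head that
#' produces the `d` latent values (plain AE) or `2d` values split into a
#' mean `E(Z)` and a log-variance parameterizing `V(Z)` (VAE). The decoder
#' mirrors the encoder back to the input width. Training minimizes
#'
#' \deqn{L = \frac{1}{m}\sum_j \|x^j - \hat x^j\|^2
#'   \;+\; \frac{\beta}{2}\sum_i (V(Z) - \log V(Z) - 1 + E(Z)^2)_i}
#'
#' (the second, KL term averaged over the batch applies to the VAE only;
#' `beta = 0` recovers the plain reconstruction objective) with Adam at
#' learning rate 1e-3. Embeddings are always extracted in inference mode
#' (batch normalization uses running statistics; the VAE embedding is the
#' posterior mean, never a sample), so they are deterministic given the
#' trained model.
NULL

#' Training configuration for the autoencoder
#'
#' @param latent_dim Latent dimensionality `d` (the library sweep uses 16,
#'   32 and 64).
#' @param beta KL weight for the VAE objective (default 1; ignored by the
#'   plain AE).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Minibatch size (default 256; reduced with a warning
#'   when the table has fewer than two batches of rows).
#' @param seed Integer seed controlling initialization, shuffling and
#'   reparameterization sampling.
#' @param hidden_widths Output widths of the six encoder blocks.
#' @param patience Early stopping: stop when the epoch loss has improved by
#'   less than `min_delta` for `patience` consecutive epochs (default 10).
#' @param min_delta Minimum improvement counted by early stopping.
#' @return A list of class `training_config`.
#' @export
training_config <- function(latent_dim = 32L, beta = 1, learning_rate = 1e-3,
                            epochs = 100L, batch_size = 256L, seed = 1L,
                            hidden_widths = c(128L, 96L, 64L, 48L, 32L, 24L),
                            patience = 10L, min_delta = 1e-5) {
  stopifnot(latent_dim >= 1L, beta >= 0, learning_rate > 0, epochs >= 1L,
            batch_size >= 1L, length(hidden_widths) >= 1L,
            all(hidden_widths >= 1L))
  structure(list(latent_dim = as.integer(latent_dim), beta = beta,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 hidden_widths = as.integer(hidden_widths),
                 patience = as.integer(patience), min_delta = min_delta),
            class = "training_config")
}

#' Mean squared reconstruction error
#'
#' Mean over the batch of the per-row squared error summed over features.
#'
#' @param x Input batch (matrix, rows = samples) or vector.
#' @param x_hat Reconstruction of the same shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x, x_hat) {
  x <- rbind(x); x_hat <- rbind(x_hat)
  if (!all(dim(x) == dim(x_hat))) {
    stop("x and x_hat have mismatched shapes", call. = FALSE)
  }
  mean(rowSums((x - x_hat)^2))
}

#' Variational autoencoder loss
#'
#' Reconstruction loss plus the beta-weighted KL divergence of the diagonal
#' Gaussian posterior from the standard normal,
#' `(beta/2) * sum_i (V - log V - 1 + E^2)_i`, averaged over the batch. The
#' KL term is non-negative for every `V > 0` and vanishes exactly at
#' `E = 0, V = 1`.
#'
#' @inheritParams reconstruction_loss
#' @param mean Posterior means `E(Z)` (batch x d).
#' @param variance Posterior variances `V(Z)` (batch x d), strictly positive.
#' @param beta KL weight `beta >= 0`.
#' @return Scalar loss.
#' @export
vae_loss <- function(x, x_hat, mean, variance, beta = 1) {
  mean <- rbind(mean); variance <- rbind(variance)
  if (any(variance <= 0)) {
    stop("variance must be strictly positive; parameterize the encoder by ",
         "log-variance", call. = FALSE)
  }
  kl <- (beta / 2) * base::mean(rowSums(variance - log(variance) - 1 + mean^2))
  reconstruction_loss(x, x_hat) + kl
}

# --- layers -----------------------------------------------------------------

.he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

.new_block <- function(n_in, n_out, bn = TRUE) {
  list(W = .he_init(n_in, n_out), b = numeric(n_out), bn = bn,
       gamma = rep(1, n_out), beta = numeric(n_out),
       run_mean = numeric(n_out), run_var = rep(1, n_out))
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.block_forward <- function(blk, H, training, relu = TRUE) {
  A <- sweep(H %*% blk$W, 2L, blk$b, "+")
  cache <- list(H = H)
  if (blk$bn) {
    if (training) {
      mu <- colMeans(A)
      v <- colMeans(A^2) - mu^2
      blk$run_mean <- .BN_MOMENTUM * blk$run_mean + (1 - .BN_MOMENTUM) * mu
      blk$run_var <- .BN_MOMENTUM * blk$run_var + (1 - .BN_MOMENTUM) * v
    } else {
      mu <- blk$run_mean
      v <- blk$run_var
    }
    Ahat <- sweep(sweep(A, 2L, mu, "-"), 2L, sqrt(v + .BN_EPS), "/")
    Y <- sweep(sweep(Ahat, 2L, blk$gamma, "*"), 2L, blk$beta, "+")
    cache$A <- A; cache$Ahat <- Ahat; cache$mu <- mu; cache$v <- v
  } else {
    Y <- A
  }
  out <- if (relu) pmax(Y, 0) else Y
  cache$Y <- Y
  list(out = out, cache = cache, blk = blk)
}

.block_backward <- function(blk, cache, dOut, relu = TRUE) {
  dY <- if (relu) dOut * (cache$Y > 0) else dOut
  grads <- list()
  if (blk$bn) {
    m <- nrow(cache$A)
    inv_sd <- 1 / sqrt(cache$v + .BN_EPS)
    grads$gamma <- colSums(dY * cache$Ahat)
    grads$beta <- colSums(dY)
    dAhat <- sweep(dY, 2L, blk$gamma, "*")
    Acent <- sweep(cache$A, 2L, cache$mu, "-")
    dvar <- colSums(dAhat * Acent) * (-0.5) * inv_sd^3
    dmu <- colSums(dAhat) * (-inv_sd) + dvar * (-2 / m) * colSums(Acent)
    dA <- sweep(dAhat, 2L, inv_sd, "*") +
      sweep(Acent, 2L, dvar * 2 / m, "*") +
      matrix(dmu / m, nrow(dY), ncol(dY), byrow = TRUE)
  } else {
    dA <- dY
  }
  grads$W <- crossprod(cache$H, dA)
  grads$b <- colSums(dA)
  list(dH = tcrossprod(dA, blk$W), grads = grads)
}

# Adam update; state carries first/second moments per parameter matrix
.adam_step <- function(param, grad, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  if (is.null(state)) state <- list(m = param * 0, v = param * 0)
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.forward_net <- function(blocks, head, X, training) {
  caches <- vector("list", length(blocks))
  H <- X
  for (i in seq_along(blocks)) {
    fw <- .block_forward(blocks[[i]], H, training)
    blocks[[i]] <- fw$blk
    caches[[i]] <- fw$cache
    H <- fw$out
  }
  hw <- .block_forward(head, H, training, relu = FALSE)
  list(out = hw$out, blocks = blocks, head = hw$blk,
       caches = caches, head_cache = hw$cache)
}

.backward_net <- function(blocks, head, caches, head_cache, dOut) {
  bk <- .block_backward(head, head_cache, dOut, relu = FALSE)
  grads <- list(head = bk$grads)
  dH <- bk$dH
  gb <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    bk <- .block_backward(blocks[[i]], caches[[i]], dH)
    gb[[i]] <- bk$grads
    dH <- bk$dH
  }
  grads$blocks <- gb
  grads$dIn <- dH
  grads
}

# --- training ---------------------------------------------------------------

#' Train an autoencoder or variational autoencoder
#'
#' @param table A `feature_table` from [assemble_feature_table()] /
#'   [engineer_features()], or a plain numeric matrix (rows = molecules).
#' @param cfg A [training_config()].
#' @param variational `TRUE` for the VAE, `FALSE` for the plain AE.
#' @return An object of class `mol_autoencoder` with elements `type`
#'   (`"AE"`/`"VAE"`), `encoder`/`decoder` parameter lists, `cfg`,
#'   `loss_history` (per-epoch mean loss; for the VAE also
#'   `recon_history` and `kl_history`), and `embedding` — the m x d
#'   [encode()] output for the training table (class `embedding_matrix`).
#' @export
#' @examples
#' \donttest{
#' X <- matrix(rnorm(200 * 10), 200)
#' fit <- train_autoencoder(X, training_config(latent_dim = 2, epochs = 20,
#'                                             batch_size = 64))
#' dim(fit$embedding)
#' }
train_autoencoder <- function(table, cfg = training_config(),
                              variational = FALSE) {
  X <- if (inherits(table, "feature_table")) table$values else table
  stopifnot(is.matrix(X), is.numeric(X))
  m <- nrow(X); p <- ncol(X)
  d <- cfg$latent_dim
  batch_size <- cfg$batch_size
  if (m < 2L * batch_size) {
    batch_size <- max(1L, m %/% 2L)
    warning("fewer than two batches of rows; reducing batch_size to ",
            batch_size, call. = FALSE)
  }

  model <- .with_seed(cfg$seed, {
    widths <- cfg$hidden_widths
    enc <- list(); n_in <- p
    for (w in widths) { enc[[length(enc) + 1L]] <- .new_block(n_in, w); n_in <- w }
    enc_head <- .new_block(n_in, if (variational) 2L * d else d, bn = FALSE)
    dec <- list(); n_in <- d
    for (w in rev(widths)) { dec[[length(dec) + 1L]] <- .new_block(n_in, w); n_in <- w }
    dec_head <- .new_block(n_in, p, bn = FALSE)
    list(enc = enc, enc_head = enc_head, dec = dec, dec_head = dec_head)
  })

  opt <- new.env(parent = emptyenv())
  opt$state <- list()
  opt$t <- 0L
  step_params <- function(obj, grads, key) {
    for (nm in intersect(names(grads), c("W", "b", "gamma", "beta"))) {
      sk <- paste0(key, ".", nm)
      upd <- .adam_step(obj[[nm]], grads[[nm]], opt$state[[sk]],
                        cfg$learning_rate, opt$t)
      obj[[nm]] <- upd$param
      opt$state[[sk]] <- upd$state
    }
    obj
  }

  loss_history <- recon_history <- kl_history <- numeric(0)
  best <- Inf; stale <- 0L

  .with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(m)
      ep_loss <- ep_recon <- ep_kl <- 0; n_batches <- 0L
      for (start in seq(1L, m, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, m)]
        xb <- X[idx, , drop = FALSE]
        mb <- nrow(xb)

        fe <- .forward_net(model$enc, model$enc_head, xb, training = TRUE)
        model$enc <- fe$blocks; model$enc_head <- fe$head
        if (variational) {
          mu_z <- fe$out[, seq_len(d), drop = FALSE]
          logv <- fe$out[, d + seq_len(d), drop = FALSE]
          logv <- pmin(pmax(logv, -15), 15)
          v_z <- exp(logv)
          kl_terms <- v_z - logv - 1 + mu_z^2
          stopifnot(all(kl_terms >= -1e-9))  # v - log v - 1 >= 0 plus E^2
          eps_z <- matrix(stats::rnorm(mb * d), mb, d)
          z <- mu_z + eps_z * sqrt(v_z)
        } else {
          z <- fe$out
        }
        fd <- .forward_net(model$dec, model$dec_head, z, training = TRUE)
        model$dec <- fd$blocks; model$dec_head <- fd$head
        x_hat <- fd$out

        recon <- mean(rowSums((xb - x_hat)^2))
        kl <- if (variational)
          (cfg$beta / 2) * mean(rowSums(v_z - logv - 1 + mu_z^2)) else 0
        loss <- recon + kl
        if (!is.finite(loss)) {
          stop("training loss became non-finite at epoch ", epoch,
               "; try a smaller learning_rate", call. = FALSE)
        }
        ep_loss <- ep_loss + loss; ep_recon <- ep_recon + recon
        ep_kl <- ep_kl + kl; n_batches <- n_batches + 1L

        d_xhat <- 2 * (x_hat - xb) / mb
        gd <- .backward_net(model$dec, model$dec_head, fd$caches,
                            fd$head_cache, d_xhat)
        dz <- gd$dIn
        if (variational) {
          d_mu <- dz + (cfg$beta / mb) * mu_z
          d_logv <- dz * eps_z * sqrt(v_z) * 0.5 +
            (cfg$beta / (2 * mb)) * (v_z - 1)
          d_out <- cbind(d_mu, d_logv)
        } else {
          d_out <- dz
        }
        ge <- .backward_net(model$enc, model$enc_head, fe$caches,
                            fe$head_cache, d_out)

        opt$t <- opt$t + 1L
        model$dec_head <- step_params(model$dec_head, gd$head, "dec_head")
        for (i in seq_along(model$dec)) {
          model$dec[[i]] <- step_params(model$dec[[i]], gd$blocks[[i]],
                                        paste0("dec", i))
        }
        model$enc_head <- step_params(model$enc_head, ge$head, "enc_head")
        for (i in seq_along(model$enc)) {
          model$enc[[i]] <- step_params(model$enc[[i]], ge$blocks[[i]],
                                        paste0("enc", i))
        }
      }
      loss_history <- c(loss_history, ep_loss / n_batches)
      recon_history <- c(recon_history, ep_recon / n_batches)
      kl_history <- c(kl_history, ep_kl / n_batches)
      current <- ep_loss / n_batches
      if (best - current > cfg$min_delta) {
        best <- current; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
  })

  fit <- structure(list(
    type = if (variational) "VAE" else "AE",
    model = model,
    cfg = cfg,
    p = p,
    d = d,
    batch_size_used = batch_size,
    loss_history = loss_history,
    recon_history = recon_history,
    kl_history = kl_history), class = "mol_autoencoder")
  fit$embedding <- encode(fit, X)
  fit
}

#' Encode data with a trained autoencoder
#'
#' Deterministic inference-mode pass: batch normalization uses running
#' statistics and the VAE returns posterior means (no sampling).
#'
#' @param model A `mol_autoencoder`.
#' @param table A `feature_table` or matrix with the training column count.
#' @return An `embedding_matrix`: m x d numeric matrix, row-aligned with the
#'   input, with attributes `source` (`"AE"`/`"VAE"`) and `latent_dim`.
#' @export
encode <- function(model, table) {
  stopifnot(inherits(model, "mol_autoencoder"))
  X <- if (inherits(table, "feature_table")) table$values else table
  if (ncol(X) != model$p) {
    stop("input has ", ncol(X), " columns but the model was trained on ",
         model$p, call. = FALSE)
  }
  out <- .forward_net(model$model$enc, model$model$enc_head, X,
                      training = FALSE)$out
  emb <- out[, seq_len(model$d), drop = FALSE]
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("Z", seq_len(model$d))
  structure(emb, source = model$type, latent_dim = model$d,
            class = c("embedding_matrix", class(emb)))
}

#' Reconstruct data with a trained autoencoder
#'
#' @param object A `mol_autoencoder`.
#' @param newdata A `feature_table` or matrix; defaults to reconstructing
#'   nothing (error) — pass the data explicitly.
#' @param ... Unused.
#' @return Matrix of reconstructions, same shape as the input.
#' @export
predict.mol_autoencoder <- function(object, newdata, ...) {
  z <- encode(object, newdata)
  .forward_net(object$model$dec, object$model$dec_head, unclass(z),
               training = FALSE)$out
}

#' @export
print.mol_autoencoder <- function(x, ...) {
  cat(sprintf("<mol_autoencoder: %s>  p = %d -> d = %d\n", x$type, x$p, x$d))
  cat(sprintf("  %d epochs trained, final loss %.5g\n",
              length(x$loss_history), utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
plot.mol_autoencoder <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "loss",
                 main = paste(x$type, "training loss"), ...)
  invisible(x)
}
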