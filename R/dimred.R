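# Dimensionality reduction: PCA at a cumulative explained-variance threshold
# and a masked autoencoder scored on masked entries only.

#' Fit PCA with a cumulative explained-variance criterion
#'
#' Retains the smallest number of components whose cumulative explained
#' variance ratio reaches `threshold` (default 95%).
#'
#' @param table Feature table; metadata columns are preserved by `predict()`.
#' @param threshold Cumulative explained-variance threshold in (0, 1].
#' @return An object of class `flowfuse_pca` with the rotation, centers,
#'   explained-variance ratios and retained count `k`.
#' @export
pca_fit <- function(table, threshold = 0.95) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]", call. = FALSE)
  fm <- feature_matrix(table)
  if (nrow(fm$X) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  pc <- stats::prcomp(fm$X, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ratio) >= threshold)[1]
  structure(list(rotation = pc$rotation, center = pc$center,
                 explained = ratio, k = k, threshold = threshold,
                 feature_names = fm$feature_names),
            class = "flowfuse_pca")
}

#' Project a table onto the retained principal components
#'
#' @param object A `flowfuse_pca` model.
#' @param newdata Feature table with the training feature columns.
#' @param k Number of components (default the fitted `k`).
#' @param ... Unused.
#' @return Tibble of metadata columns plus `PC1..PCk`.
#' @export
predict.flowfuse_pca <- function(object, newdata, k = object$k, ...) {
  fm <- feature_matrix(newdata)
  if (!identical(fm$feature_names, object$feature_names)) {
    stop("feature columns do not match the fitted PCA", call. = FALSE)
  }
  S <- sweep(fm$X, 2, object$center) %*% object$rotation[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(k))
  dplyr::bind_cols(fm$meta, tibble::as_tibble(S))
}

#' Masked autoencoder configuration
#'
#' @param latent_dim Bottleneck width.
#' @param hidden Encoder/decoder hidden width (default 256).
#' @param mask_ratio Fraction of entries masked per batch (default 0.3).
#' @param dropout Dropout rate (default 0.2).
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Batch size (default 64).
#' @param lr Adam learning rate (default 0.001).
#' @param weight_decay L2 coefficient (default 1e-4).
#' @param patience Early-stopping patience on validation loss (default 5;
#'   `Inf` disables early stopping).
#' @param val_fraction Fraction of rows held out for early stopping
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A list of class `mae_config`.
#' @export
mae_config <- function(latent_dim, hidden = 256, mask_ratio = 0.3,
                       dropout = 0.2, epochs = 100, batch_size = 64,
                       lr = 0.001, weight_decay = 1e-4, patience = 5,
                       val_fraction = 0.1, seed = 1) {
  if (!(mask_ratio > 0 && mask_ratio < 1)) stop("mask_ratio must be in (0, 1)", call. = FALSE)
  structure(list(latent_dim = latent_dim, hidden = hidden,
                 mask_ratio = mask_ratio, dropout = dropout, epochs = epochs,
                 batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, patience = patience,
                 val_fraction = val_fraction, seed = seed),
            class = "mae_config")
}

# masked reconstruction loss: MSE restricted to masked entries
masked_mse <- function(Xhat, X, M) {
  s <- sum(M)
  if (s == 0) return(0)
  sum(((Xhat - X) * M)^2) / s
}

#' Train a masked autoencoder
#'
#' Per-batch entry-level Bernoulli masks at `mask_ratio`; masked entries are
#' zero-filled at the encoder input and the reconstruction loss is computed
#' on masked entries only.  Training stops early when the validation masked
#' loss has not improved for `patience` consecutive epochs.
#'
#' @param table Feature table.
#' @param cfg A [mae_config()].
#' @return An object of class `flowfuse_mae` with encoder/decoder layers,
#'   per-epoch loss history and the stopping epoch.
#' @export
mae_train <- function(table, cfg) {
  stopifnot(inherits(cfg, "mae_config"))
  fm <- feature_matrix(table)
  X <- fm$X
  d <- ncol(X)
  if (cfg$latent_dim >= d) stop("latent_dim must be smaller than the input dimension", call. = FALSE)
  if (nrow(X) < 2 * cfg$batch_size && nrow(X) < 8) {
    stop("too few rows to train", call. = FALSE)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  n_val <- max(1, round(cfg$val_fraction * nrow(X)))
  idx_val <- sample(nrow(X), n_val)
  Xtr <- X[-idx_val, , drop = FALSE]
  Xva <- X[idx_val, , drop = FALSE]

  enc <- list(nn_dense(d, cfg$hidden), nn_batchnorm(cfg$hidden), nn_act("relu"),
              nn_dropout(cfg$dropout), nn_dense(cfg$hidden, cfg$latent_dim))
  dec <- list(nn_dense(cfg$latent_dim, cfg$hidden), nn_batchnorm(cfg$hidden),
              nn_act("relu"), nn_dropout(cfg$dropout), nn_dense(cfg$hidden, d))
  s_enc <- adam_init(enc); s_dec <- adam_init(dec)

  history <- numeric(0)
  best <- Inf; best_model <- NULL; wait <- 0; step <- 0; stop_epoch <- cfg$epochs
  mask_of <- function(nr) matrix(stats::runif(nr * d) < cfg$mask_ratio, nr, d) * 1

  val_loss <- function(enc, dec) {
    M <- mask_of(nrow(Xva))
    f1 <- nn_forward(enc, Xva * (1 - M), training = FALSE)
    f2 <- nn_forward(dec, f1$out, training = FALSE)
    masked_mse(f2$out, Xva, M)
  }

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      Xb <- Xtr[bi, , drop = FALSE]
      M <- mask_of(nrow(Xb))
      f1 <- nn_forward(enc, Xb * (1 - M), training = TRUE)
      f2 <- nn_forward(dec, f1$out, training = TRUE)
      L <- masked_mse(f2$out, Xb, M)
      ep_loss <- ep_loss + L * nrow(Xb)
      dOut <- 2 * (f2$out - Xb) * M / max(sum(M), 1)
      b2 <- nn_backward(dec, f2$caches, dOut)
      b1 <- nn_backward(enc, f1$caches, b2$dX)
      step <- step + 1
      u <- adam_step(dec, b2$grads, s_dec, step, cfg$lr, weight_decay = cfg$weight_decay)
      dec <- u$layers; s_dec <- u$state
      u <- adam_step(enc, b1$grads, s_enc, step, cfg$lr, weight_decay = cfg$weight_decay)
      enc <- u$layers; s_enc <- u$state
    }
    enc <- nn_refresh_bn(enc, Xtr * (1 - mask_of(nrow(Xtr))))
    dec <- nn_refresh_bn(dec, nn_forward(enc, Xtr, training = FALSE)$out)
    vl <- val_loss(enc, dec)
    history <- c(history, vl)
    if (vl < best - 1e-12) {
      best <- vl; wait <- 0; best_model <- list(enc = enc, dec = dec)
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) { stop_epoch <- ep; break }
    }
    stop_epoch <- ep
  }
  if (is.null(best_model)) best_model <- list(enc = enc, dec = dec)
  structure(list(encoder = best_model$enc, decoder = best_model$dec,
                 config = cfg, history = history, stop_epoch = stop_epoch,
                 best_val_loss = best, feature_names = fm$feature_names),
            class = "flowfuse_mae")
}

#' Encode a table with a trained masked autoencoder
#'
#' Inference is deterministic: dropout is disabled and batch-norm uses its
#' running statistics.
#'
#' @param model A `flowfuse_mae`.
#' @param table Feature table with the training feature columns.
#' @return Tibble of metadata columns plus `Z1..Zk` latent coordinates.
#' @export
mae_encode <- function(model, table) {
  stopifnot(inherits(model, "flowfuse_mae"))
  fm <- feature_matrix(table)
  if (!identical(fm$feature_names, model$feature_names)) {
    stop("feature columns do not match the trained model", call. = FALSE)
  }
  Z <- nn_forward(model$encoder, fm$X, training = FALSE)$out
  colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  dplyr::bind_cols(fm$meta, tibble::as_tibble(Z))
}

#' Reference reduction presets
#'
#' The feature-set to reduced-dimension map used by the full pipeline:
#' method and target dimension per handcrafted or learned feature block.
#'
#' @return A tibble with columns `feature_set`, `method`, `input_dim`,
#'   `output_dim`.
#' @export
reduction_presets <- function() {
  tibble::tribble(
    ~feature_set,     ~method, ~input_dim, ~output_dim,
    "time",           "pca",   133L,  13L,
    "frequency",      "pca",   190L,   8L,
    "timefreq",       "pca",   342L,  37L,
    "mse",            "pca",   380L,   8L,
    "psd_image",      "mae",  1280L,  16L,
    "compare",        "mae",  6373L,  32L,
    "hubert",         "mae",  1024L,  32L,
    "tfidf",          "pca",  1000L,  32L,
    "bert",           "mae",   768L,  64L)
}
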