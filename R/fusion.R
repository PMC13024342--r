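# Two-stream fusion classifier with squeeze-and-excitation channel attention.

#' Fusion classifier configuration
#'
#' @param branch_dim Output width of each encoding branch (default 128).
#' @param se_ratio Bottleneck compression ratio of the SE module (default 8;
#'   must divide the concatenated width).
#' @param mlp_hidden Classification-head hidden width (default 64).
#' @param dropout Dropout rate (default 0.3).
#' @param batch_size Batch size (default 16).
#' @param lr Adam learning rate (default 0.001), halved on a validation-loss
#'   plateau (`lr_patience` epochs, factor 0.5).
#' @param weight_decay L2 coefficient (default 1e-4).
#' @param epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience on validation loss (default 20).
#' @param lr_patience Plateau patience for learning-rate halving (default 10).
#' @param val_fraction Internal validation fraction when no validation set
#'   is supplied (default 0.15).
#' @param seed Integer seed.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(branch_dim = 128, se_ratio = 8, mlp_hidden = 64,
                          dropout = 0.3, batch_size = 16, lr = 0.001,
                          weight_decay = 1e-4, epochs = 200, patience = 20,
                          lr_patience = 10, val_fraction = 0.15, seed = 1) {
  if ((2 * branch_dim) %% se_ratio != 0) {
    stop("se_ratio must divide the concatenated width", call. = FALSE)
  }
  structure(list(branch_dim = branch_dim, se_ratio = se_ratio,
                 mlp_hidden = mlp_hidden, dropout = dropout,
                 batch_size = batch_size, lr = lr,
                 weight_decay = weight_decay, epochs = epochs,
                 patience = patience, lr_patience = lr_patience,
                 val_fraction = val_fraction, seed = seed),
            class = "fusion_config")
}

se_init <- function(width, ratio) {
  mid <- width %/% ratio
  list(W1 = matrix(stats::rnorm(width * mid, sd = sqrt(2 / width)), width, mid),
       b1 = rep(0, mid),
       W2 = matrix(stats::rnorm(mid * width, sd = sqrt(2 / mid)), mid, width),
       b2 = rep(0, width))
}

#' Squeeze-and-excitation reweighting
#'
#' For flat feature vectors the squeeze over a singleton spatial axis is the
#' identity, so the channel weights are computed from the feature vector
#' itself through the bottleneck:
#' `w = sigmoid(W2 relu(W1 f))`, output `w * f` element-wise.  Every weight
#' lies strictly in (0, 1); all-zero parameters give weights of exactly 0.5.
#'
#' @param f Feature matrix (rows = samples) or vector.
#' @param params List with `W1`, `b1`, `W2`, `b2` (see `se_init`).
#' @return Reweighted features, same shape as `f`.
#' @export
se_reweight <- function(f, params) {
  v <- is.null(dim(f))
  if (v) f <- matrix(f, nrow = 1)
  if (ncol(f) != nrow(params$W1)) stop("width mismatch in SE module", call. = FALSE)
  u <- .rowb(f %*% params$W1, params$b1)
  a <- pmax(u, 0)
  w <- sigmoid(.rowb(a %*% params$W2, params$b2))
  out <- w * f
  if (v) out[1, ] else out
}

se_forward <- function(f, params) {
  u <- .rowb(f %*% params$W1, params$b1)
  a <- pmax(u, 0)
  w <- sigmoid(.rowb(a %*% params$W2, params$b2))
  list(out = w * f, cache = list(f = f, u = u, a = a, w = w))
}

se_backward <- function(params, cache, dout) {
  w <- cache$w; f <- cache$f; a <- cache$a; u <- cache$u
  dw <- dout * f
  dv <- dw * w * (1 - w)
  dW2 <- crossprod(a, dv); db2 <- colSums(dv)
  da <- tcrossprod(dv, params$W2)
  du <- da * (u > 0)
  dW1 <- crossprod(f, du); db1 <- colSums(du)
  df <- dout * w + tcrossprod(du, params$W1)
  list(df = df, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

.make_branch <- function(d_in, d_out, dropout) {
  list(nn_dense(d_in, d_out), nn_batchnorm(d_out), nn_act("relu"),
       nn_dropout(dropout))
}

fusion_net_init <- function(d1, d2, cfg, use_se) {
  two <- !is.null(d2)
  concat <- if (two) 2 * cfg$branch_dim else cfg$branch_dim
  list(branch1 = .make_branch(d1, cfg$branch_dim, cfg$dropout),
       branch2 = if (two) .make_branch(d2, cfg$branch_dim, cfg$dropout),
       se = if (use_se && two) se_init(concat, cfg$se_ratio),
       head = list(nn_dense(concat, cfg$mlp_hidden), nn_batchnorm(cfg$mlp_hidden),
                   nn_act("relu"), nn_dropout(cfg$dropout),
                   nn_dense(cfg$mlp_hidden, 3)),
       concat = concat, use_se = use_se && two, two = two)
}

fusion_net_forward <- function(net, X1, X2, training = FALSE) {
  f1 <- nn_forward(net$branch1, X1, training)
  if (net$two) {
    f2 <- nn_forward(net$branch2, X2, training)
    f <- cbind(f1$out, f2$out)
  } else {
    f2 <- NULL
    f <- f1$out
  }
  if (net$use_se) {
    se <- se_forward(f, net$se)
    g <- se$out
  } else se <- NULL
  if (!net$use_se) g <- f
  fh <- nn_forward(net$head, g, training)
  list(logits = fh$out,
       caches = list(b1 = f1$caches, b2 = if (net$two) f2$caches,
                     se = if (net$use_se) se$cache, head = fh$caches))
}

#' Fusion forward pass: class probabilities
#'
#' Runs both encoding branches, concatenation, optional SE reweighting and
#' the MLP head; rows of the result are softmax probabilities over
#' (AD, HC, MCI) summing to 1.
#'
#' @param model A trained `fusion_model` (or raw net from `fusion_net_init`).
#' @param X1,X2 Input matrices (X2 `NULL` for single-branch models).
#' @return Probability matrix `n x 3`.
#' @export
fusion_forward <- function(model, X1, X2 = NULL) {
  net <- if (inherits(model, "fusion_model")) model$net else model
  row_softmax(fusion_net_forward(net, X1, X2, training = FALSE)$logits)
}

#' Train the fusion classifier
#'
#' @param x1_table Primary input table (e.g. aligned speech latents) with a
#'   `label` column.
#' @param x2_table Secondary input table (e.g. generated EEG-like latents)
#'   or `NULL` for a single-branch classifier.
#' @param cfg A [fusion_config()].
#' @param use_se Apply SE channel attention to the concatenated features
#'   (default TRUE; ignored for single-branch models).
#' @param validation Optional list `(x1, x2, labels)` used for early
#'   stopping; when `NULL` an internal split of `val_fraction` is made.
#' @return An object of class `fusion_model`.
#' @export
fusion_fit <- function(x1_table, x2_table = NULL, cfg = fusion_config(),
                       use_se = TRUE, validation = NULL) {
  stopifnot(inherits(cfg, "fusion_config"))
  f1 <- feature_matrix(x1_table)
  y <- as.character(x1_table$label)
  X1 <- f1$X
  X2 <- if (!is.null(x2_table)) feature_matrix(x2_table)$X
  if (!is.null(X2) && nrow(X2) != nrow(X1)) stop("row mismatch", call. = FALSE)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  net <- fusion_net_init(ncol(X1), if (!is.null(X2)) ncol(X2), cfg, use_se)

  if (is.null(validation)) {
    # stratified internal validation split: balanced early-stopping monitor
    iv <- unlist(lapply(split(seq_len(nrow(X1)), y), function(ii) {
      sample(ii, max(1, round(cfg$val_fraction * length(ii))))
    }), use.names = FALSE)
    validation <- list(x1 = X1[iv, , drop = FALSE],
                       x2 = if (!is.null(X2)) X2[iv, , drop = FALSE],
                       labels = y[iv])
    X1 <- X1[-iv, , drop = FALSE]
    if (!is.null(X2)) X2 <- X2[-iv, , drop = FALSE]
    y <- y[-iv]
  } else {
    validation$x1 <- as.matrix(validation$x1)
    if (!is.null(validation$x2)) validation$x2 <- as.matrix(validation$x2)
  }

  sts <- list(b1 = adam_init(net$branch1),
              b2 = if (net$two) adam_init(net$branch2),
              head = adam_init(net$head),
              se = if (net$use_se) lapply(net$se, function(p) list(m = p * 0, v = p * 0)))
  yi <- match(y, CLASS_LEVELS)
  ce_loss <- function(logits, yidx) {
    P <- row_softmax(logits)
    -mean(log(pmax(P[cbind(seq_along(yidx), yidx)], 1e-12)))
  }
  val_loss <- function(net) {
    lg <- fusion_net_forward(net, validation$x1, validation$x2, training = FALSE)$logits
    ce_loss(lg, match(validation$labels, CLASS_LEVELS))
  }

  lr <- cfg$lr
  best <- Inf; best_net <- net; wait_stop <- 0; wait_lr <- 0
  history <- numeric(0); step <- 0; stop_epoch <- cfg$epochs
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(nrow(X1))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (bi in batches) {
      fw <- fusion_net_forward(net, X1[bi, , drop = FALSE],
                               if (net$two) X2[bi, , drop = FALSE], training = TRUE)
      P <- row_softmax(fw$logits)
      yb <- yi[bi]
      dlog <- P
      dlog[cbind(seq_along(yb), yb)] <- dlog[cbind(seq_along(yb), yb)] - 1
      dlog <- dlog / length(yb)
      bh <- nn_backward(net$head, fw$caches$head, dlog)
      dg <- bh$dX
      se_g <- NULL
      if (net$use_se) {
        sb <- se_backward(net$se, fw$caches$se, dg)
        dg <- sb$df
        se_g <- sb$grads
      }
      if (net$two) {
        d1 <- dg[, seq_len(cfg$branch_dim), drop = FALSE]
        d2 <- dg[, cfg$branch_dim + seq_len(cfg$branch_dim), drop = FALSE]
      } else { d1 <- dg; d2 <- NULL }
      bb1 <- nn_backward(net$branch1, fw$caches$b1, d1)
      if (net$two) bb2 <- nn_backward(net$branch2, fw$caches$b2, d2)
      step <- step + 1
      u <- adam_step(net$branch1, bb1$grads, sts$b1, step, lr, weight_decay = cfg$weight_decay)
      net$branch1 <- u$layers; sts$b1 <- u$state
      if (net$two) {
        u <- adam_step(net$branch2, bb2$grads, sts$b2, step, lr, weight_decay = cfg$weight_decay)
        net$branch2 <- u$layers; sts$b2 <- u$state
      }
      u <- adam_step(net$head, bh$grads, sts$head, step, lr, weight_decay = cfg$weight_decay)
      net$head <- u$layers; sts$head <- u$state
      if (net$use_se) {
        for (nm in names(net$se)) {
          g <- se_g[[nm]] + cfg$weight_decay * net$se[[nm]]
          s <- sts$se[[nm]]
          s$m <- 0.9 * s$m + 0.1 * g
          s$v <- 0.999 * s$v + 0.001 * g^2
          net$se[[nm]] <- net$se[[nm]] -
            lr * (s$m / (1 - 0.9^step)) / (sqrt(s$v / (1 - 0.999^step)) + 1e-8)
          sts$se[[nm]] <- s
        }
      }
    }
    net$branch1 <- nn_refresh_bn(net$branch1, X1)
    if (net$two) net$branch2 <- nn_refresh_bn(net$branch2, X2)
    g_full <- {
      o1 <- nn_forward(net$branch1, X1)$out
      f <- if (net$two) cbind(o1, nn_forward(net$branch2, X2)$out) else o1
      if (net$use_se) se_reweight(f, net$se) else f
    }
    net$head <- nn_refresh_bn(net$head, g_full)
    vl <- val_loss(net)
    history <- c(history, vl)
    if (vl < best - 1e-10) {
      best <- vl; best_net <- net; wait_stop <- 0; wait_lr <- 0
    } else {
      wait_stop <- wait_stop + 1; wait_lr <- wait_lr + 1
      if (wait_lr >= cfg$lr_patience) { lr <- lr / 2; wait_lr <- 0 }
      if (wait_stop >= cfg$patience) { stop_epoch <- ep; break }
    }
    stop_epoch <- ep
  }
  structure(list(net = best_net, config = cfg, history = history,
                 stop_epoch = stop_epoch, best_val_loss = best,
                 concat_width = best_net$concat,
                 feature_names1 = f1$feature_names,
                 two_branch = best_net$two, use_se = best_net$use_se),
            class = "fusion_model")
}

#' Predict class probabilities / labels from a fusion model
#'
#' @param object A `fusion_model`.
#' @param x1_table,x2_table Input tables matching the training inputs.
#' @param type `"prob"` for a probability tibble, `"class"` for labels.
#' @param ... Unused.
#' @return Tibble of probabilities (columns AD, HC, MCI) or a character
#'   vector of predicted labels.
#' @export
predict.fusion_model <- function(object, x1_table, x2_table = NULL,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X1 <- feature_matrix(x1_table)$X
  X2 <- if (!is.null(x2_table)) feature_matrix(x2_table)$X
  P <- fusion_forward(object, X1, X2)
  colnames(P) <- CLASS_LEVELS
  if (type == "class") CLASS_LEVELS[max.col(P)] else tibble::as_tibble(P)
}
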