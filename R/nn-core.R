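# Minimal dense-network engine used by the MAE, alignment, flow and fusion
# models.  Rows are samples, columns are features.  Every layer implements an
# explicit forward/backward pair; gradients are checked against finite
# differences in the test suite.

nn_dense <- function(d_in, d_out, init_sd = sqrt(2 / d_in)) {
  list(type = "dense",
       W = matrix(stats::rnorm(d_in * d_out, sd = init_sd), d_in, d_out),
       b = rep(0, d_out))
}

nn_batchnorm <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, d), beta = rep(0, d),
       running_mean = rep(0, d), running_var = rep(1, d),
       momentum = momentum, eps = eps)
}

nn_layernorm <- function(d, eps = 1e-5) {
  list(type = "layernorm", gamma = rep(1, d), beta = rep(0, d), eps = eps)
}

nn_act <- function(fun = c("relu", "silu", "sigmoid")) {
  list(type = "act", fun = match.arg(fun))
}

nn_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(type = "dropout", rate = rate)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

.act_forward <- function(fun, x) {
  switch(fun,
         relu = pmax(x, 0),
         silu = x * sigmoid(x),
         sigmoid = sigmoid(x))
}

.act_grad <- function(fun, x) {
  switch(fun,
         relu = (x > 0) * 1,
         silu = { s <- sigmoid(x); s * (1 + x * (1 - s)) },
         sigmoid = { s <- sigmoid(x); s * (1 - s) })
}

# broadcast a length-d vector across the rows of an n x d matrix
.rowb <- function(X, v, op = "+") {
  switch(op,
         "+" = X + rep(v, each = nrow(X)),
         "*" = X * rep(v, each = nrow(X)))
}

# Forward pass through a list of layers.  Returns the output and a cache list
# (one entry per layer) holding whatever backward needs.  `training` controls
# dropout and the batch-norm statistics source.
nn_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- .rowb(X %*% l$W, l$b)
    } else if (l$type == "act") {
      caches[[i]] <- list(X = X)
      X <- .act_forward(l$fun, X)
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        keep <- 1 - l$rate
        mask <- (matrix(stats::runif(length(X)), nrow(X)) < keep) / keep
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (l$type == "batchnorm") {
      if (training && nrow(X) > 1) {
        mu <- colMeans(X)
        vr <- colMeans(X^2) - mu^2
      } else {
        mu <- l$running_mean
        vr <- l$running_var
      }
      inv_sd <- 1 / sqrt(vr + l$eps)
      xhat <- .rowb(X - rep(mu, each = nrow(X)), inv_sd, "*")
      caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd, training = training && nrow(X) > 1)
      X <- .rowb(.rowb(xhat, l$gamma, "*"), l$beta)
    } else if (l$type == "layernorm") {
      mu <- rowMeans(X)
      vr <- rowMeans(X^2) - mu^2
      inv_sd <- 1 / sqrt(vr + l$eps)
      xhat <- (X - mu) * inv_sd
      caches[[i]] <- list(xhat = xhat, inv_sd = inv_sd)
      X <- .rowb(.rowb(xhat, l$gamma, "*"), l$beta)
    } else {
      stop("unknown layer type: ", l$type)
    }
  }
  list(out = X, caches = caches)
}

# Backward pass; returns gradient w.r.t. the input and per-layer parameter
# gradients (NULL for parameter-free layers).
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(cc$X, dout), b = colSums(dout))
      dout <- tcrossprod(dout, l$W)
    } else if (l$type == "act") {
      dout <- dout * .act_grad(l$fun, cc$X)
    } else if (l$type == "dropout") {
      if (!is.null(cc$mask)) dout <- dout * cc$mask
    } else if (l$type == "batchnorm") {
      xhat <- cc$xhat
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dxhat <- .rowb(dout, l$gamma, "*")
      if (cc$training) {
        n <- nrow(dout)
        t1 <- rep(colMeans(dxhat), each = n)
        t2 <- xhat * rep(colMeans(dxhat * xhat), each = n)
        dout <- .rowb(dxhat - t1 - t2, cc$inv_sd, "*")
      } else {
        dout <- .rowb(dxhat, cc$inv_sd, "*")
      }
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (l$type == "layernorm") {
      xhat <- cc$xhat
      dgamma <- colSums(dout * xhat)
      dbeta <- colSums(dout)
      dxhat <- .rowb(dout, l$gamma, "*")
      dout <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cc$inv_sd
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    }
  }
  list(dX = dout, grads = grads)
}

# Refresh running mean/var of all batch-norm layers from a full-data forward
# pass (dropout off).  Called once per epoch; cheaper and more stable than
# per-batch exponential updates for the small cohorts used here.
nn_refresh_bn <- function(layers, X) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      X <- .rowb(X %*% l$W, l$b)
    } else if (l$type == "act") {
      X <- .act_forward(l$fun, X)
    } else if (l$type == "batchnorm") {
      l$running_mean <- colMeans(X)
      l$running_var <- pmax(colMeans(X^2) - colMeans(X)^2, 1e-12)
      layers[[i]] <- l
      xhat <- .rowb(X - rep(l$running_mean, each = nrow(X)),
                    1 / sqrt(l$running_var + l$eps), "*")
      X <- .rowb(.rowb(xhat, l$gamma, "*"), l$beta)
    } else if (l$type == "layernorm") {
      mu <- rowMeans(X); vr <- rowMeans(X^2) - mu^2
      xhat <- (X - mu) / sqrt(vr + l$eps)
      X <- .rowb(.rowb(xhat, l$gamma, "*"), l$beta)
    }
    # dropout: identity at refresh time
  }
  layers
}

.trainable <- c(dense = TRUE, batchnorm = TRUE, layernorm = TRUE,
                act = FALSE, dropout = FALSE)

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "dense") {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else if (l$type %in% c("batchnorm", "layernorm")) {
      list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0)
    } else NULL
  })
}

# One Adam step (in-functional style: returns updated layers + state).
# weight_decay is classic L2 added to the dense-weight gradient.
adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    s <- state[[i]]
    if (l$type == "dense") {
      u <- upd(l$W, g$W + weight_decay * l$W, s$mW, s$vW)
      l$W <- u$p; s$mW <- u$m; s$vW <- u$v
      u <- upd(l$b, g$b, s$mb, s$vb)
      l$b <- u$p; s$mb <- u$m; s$vb <- u$v
    } else {
      u <- upd(l$gamma, g$gamma, s$mg, s$vg)
      l$gamma <- u$p; s$mg <- u$m; s$vg <- u$v
      u <- upd(l$beta, g$beta, s$mb, s$vb)
      l$beta <- u$p; s$mb <- u$m; s$vb <- u$v
    }
    layers[[i]] <- l
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# Flatten all trainable parameters into one numeric vector (used for
# fold-independence checks and model hashing).
nn_flatten <- function(layers) {
  unlist(lapply(layers, function(l) {
    if (l$type == "dense") c(l$W, l$b)
    else if (l$type %in% c("batchnorm", "layernorm")) c(l$gamma, l$beta)
    else NULL
  }), use.names = FALSE)
}

# Softmax over rows with the usual max-shift for stability.
row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
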