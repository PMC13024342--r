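# Conditional rectified flow: a velocity-field network trained with the
# flow-matching objective along straight noise-to-data paths, sampled with a
# few-step Euler integrator.

#' Velocity network / flow training configuration
#'
#' @param state_dim Dimension of the transported state (default 128).
#' @param cond_dim Dimension of the conditioning vector (default 128).
#' @param hidden Hidden width (default 256).
#' @param n_blocks Number of residual blocks (default 3).
#' @param epochs Training epochs (default 500).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Batch size (default 32).
#' @param steps Euler steps N for sampling (default 10).
#' @param seed Integer seed.
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(state_dim = 128, cond_dim = 128, hidden = 256,
                        n_blocks = 3, epochs = 500, lr = 0.001,
                        batch_size = 32, steps = 10, seed = 1) {
  stopifnot(steps >= 1, hidden > 0)
  structure(list(state_dim = state_dim, cond_dim = cond_dim, hidden = hidden,
                 n_blocks = n_blocks, epochs = epochs, lr = lr,
                 batch_size = batch_size, steps = steps, seed = seed),
            class = "flow_config")
}

#' Straight-path interpolation
#'
#' `x_t = t * x1 + (1 - t) * x0`: the intermediate state on the straight
#' transport path from noise `x0` to data `x1`.
#'
#' @param x0,x1 Vectors or conforming matrices (rows = samples).
#' @param t Scalar or per-row vector in \[0, 1\].
#' @return The interpolated state.
#' @export
interpolate_state <- function(x0, x1, t) {
  if (any(t < 0) || any(t > 1)) stop("t must lie in [0, 1]", call. = FALSE)
  t * x1 + (1 - t) * x0
}

#' Flow-matching loss
#'
#' Mean over the batch and over dimensions of the squared error between the
#' predicted velocity and the straight-path target velocity `x1 - x0`.
#' (Dimension-normalized convention; multiply by `ncol` for the summed
#' squared-norm convention.)
#'
#' @param v_pred Predicted velocity matrix (rows = samples).
#' @param x0,x1 Endpoint matrices.
#' @return Scalar loss.
#' @export
flow_matching_loss <- function(v_pred, x0, x1) {
  stopifnot(all(dim(v_pred) == dim(x0)), all(dim(x0) == dim(x1)))
  mean((v_pred - (x1 - x0))^2)
}

# --- velocity network -------------------------------------------------------
# state projection (linear) + two-layer SiLU time embedding + two-layer SiLU
# condition embedding, summed; then n residual blocks (two SiLU dense layers,
# post-residual layer normalization); linear output head.

velocity_net_init <- function(cfg) {
  h <- cfg$hidden
  net <- list(
    proj_x = list(nn_dense(cfg$state_dim, h)),
    emb_t = list(nn_dense(1, h), nn_act("silu"), nn_dense(h, h)),
    emb_c = list(nn_dense(cfg$cond_dim, h), nn_act("silu"), nn_dense(h, h)),
    blocks = lapply(seq_len(cfg$n_blocks), function(i) {
      list(body = list(nn_dense(h, h), nn_act("silu"), nn_dense(h, h)),
           ln = list(nn_layernorm(h)))
    }),
    head = list(nn_dense(h, cfg$state_dim)))
  net
}

velocity_net_states <- function(net) {
  list(proj_x = adam_init(net$proj_x), emb_t = adam_init(net$emb_t),
       emb_c = adam_init(net$emb_c),
       blocks = lapply(net$blocks, function(b)
         list(body = adam_init(b$body), ln = adam_init(b$ln))),
       head = adam_init(net$head))
}

velocity_forward <- function(net, X, tvec, C) {
  f_x <- nn_forward(net$proj_x, X)
  f_t <- nn_forward(net$emb_t, matrix(tvec, ncol = 1))
  f_c <- nn_forward(net$emb_c, C)
  h <- f_x$out + f_t$out + f_c$out
  blk_caches <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    b <- net$blocks[[i]]
    f_b <- nn_forward(b$body, h)
    f_l <- nn_forward(b$ln, h + f_b$out)
    blk_caches[[i]] <- list(body = f_b$caches, ln = f_l$caches)
    h <- f_l$out
  }
  f_h <- nn_forward(net$head, h)
  list(out = f_h$out,
       caches = list(x = f_x$caches, t = f_t$caches, c = f_c$caches,
                     blocks = blk_caches, head = f_h$caches))
}

velocity_backward <- function(net, caches, dout) {
  b_h <- nn_backward(net$head, caches$head, dout)
  dh <- b_h$dX
  blk_grads <- vector("list", length(net$blocks))
  for (i in rev(seq_along(net$blocks))) {
    b <- net$blocks[[i]]
    b_l <- nn_backward(b$ln, caches$blocks[[i]]$ln, dh)
    b_b <- nn_backward(b$body, caches$blocks[[i]]$body, b_l$dX)
    blk_grads[[i]] <- list(body = b_b$grads, ln = b_l$grads)
    dh <- b_l$dX + b_b$dX   # residual: gradient flows through skip and body
  }
  b_x <- nn_backward(net$proj_x, caches$x, dh)
  b_t <- nn_backward(net$emb_t, caches$t, dh)
  b_c <- nn_backward(net$emb_c, caches$c, dh)
  list(grads = list(proj_x = b_x$grads, emb_t = b_t$grads, emb_c = b_c$grads,
                    blocks = blk_grads, head = b_h$grads))
}

velocity_adam <- function(net, grads, st, step, lr) {
  u <- adam_step(net$proj_x, grads$proj_x, st$proj_x, step, lr)
  net$proj_x <- u$layers; st$proj_x <- u$state
  u <- adam_step(net$emb_t, grads$emb_t, st$emb_t, step, lr)
  net$emb_t <- u$layers; st$emb_t <- u$state
  u <- adam_step(net$emb_c, grads$emb_c, st$emb_c, step, lr)
  net$emb_c <- u$layers; st$emb_c <- u$state
  for (i in seq_along(net$blocks)) {
    u <- adam_step(net$blocks[[i]]$body, grads$blocks[[i]]$body,
                   st$blocks[[i]]$body, step, lr)
    net$blocks[[i]]$body <- u$layers; st$blocks[[i]]$body <- u$state
    u <- adam_step(net$blocks[[i]]$ln, grads$blocks[[i]]$ln,
                   st$blocks[[i]]$ln, step, lr)
    net$blocks[[i]]$ln <- u$layers; st$blocks[[i]]$ln <- u$state
  }
  u <- adam_step(net$head, grads$head, st$head, step, lr)
  net$head <- u$layers; st$head <- u$state
  list(net = net, st = st)
}

#' Evaluate a flow model's velocity field
#'
#' @param model A `flow_model`.
#' @param X State matrix (rows = samples).
#' @param tvec Scalar or per-row time in \[0, 1\].
#' @param C Condition matrix.
#' @return Velocity matrix, same shape as `X`.
#' @export
velocity_field <- function(model, X, tvec, C) {
  if (length(tvec) == 1) tvec <- rep(tvec, nrow(X))
  velocity_forward(model$net, X, tvec, C)$out
}

#' Euler ODE sampling
#'
#' Integrates `dx/dt = v(x, t, c)` from `x0` with `N` uniform Euler steps:
#' `x_{k+1} = x_k + (1/N) v(x_k, k/N, c)`.
#'
#' @param v_fun Velocity function `function(X, t, C)` returning a matrix, or
#'   a `flow_model` (its learned field is used).
#' @param C Condition matrix.
#' @param x0 Initial state matrix.
#' @param N Number of Euler steps (default 10).
#' @return Final state matrix.
#' @export
euler_sample <- function(v_fun, C, x0, N = 10) {
  stopifnot(N >= 1)
  if (inherits(v_fun, "flow_model")) {
    model <- v_fun
    v_fun <- function(X, t, C) velocity_field(model, X, t, C)
  }
  x <- x0
  for (k in 0:(N - 1)) {
    v <- v_fun(x, k / N, C)
    if (!all(is.finite(v))) stop("non-finite state during integration", call. = FALSE)
    x <- x + v / N
  }
  x
}

#' Train a conditional rectified flow
#'
#' Learns a velocity field transporting standard Gaussian noise to the EEG
#' latent distribution, conditioned on speech latents.  Each training pair
#' takes `x1` as an aligned EEG latent and `c` as an aligned speech latent
#' drawn from the same class (random same-class matching per epoch);
#' `t ~ Uniform(0, 1)` and `x0 ~ N(0, I)` per sample.
#'
#' @param speech_latents,eeg_latents Tables with a `label` column and
#'   numeric latent columns.
#' @param cfg A [flow_config()]; `state_dim`/`cond_dim` are overridden by
#'   the table widths.
#' @return An object of class `flow_model` with the velocity network,
#'   config and per-epoch loss history.
#' @export
train_flow <- function(speech_latents, eeg_latents, cfg = flow_config()) {
  stopifnot(inherits(cfg, "flow_config"))
  fs <- feature_matrix(speech_latents)
  fe <- feature_matrix(eeg_latents)
  ys <- as.character(speech_latents$label)
  ye <- as.character(eeg_latents$label)
  shared <- intersect(unique(ys), unique(ye))
  if (length(shared) == 0) stop("no common classes between the tables", call. = FALSE)
  cfg$state_dim <- ncol(fe$X); cfg$cond_dim <- ncol(fs$X)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  net <- velocity_net_init(cfg)
  st <- velocity_net_states(net)

  # keep only speech rows whose class exists in the EEG table
  keep <- ys %in% shared
  Xs <- fs$X[keep, , drop = FALSE]; ys <- ys[keep]
  idx_by_class <- split(seq_len(nrow(fe$X)), ye)

  history <- numeric(cfg$epochs)
  step <- 0
  for (ep in seq_len(cfg$epochs)) {
    # random same-class pairing for this epoch
    pair <- vapply(ys, function(k) {
      ii <- idx_by_class[[k]]
      ii[sample.int(length(ii), 1)]
    }, integer(1))
    ord <- sample(nrow(Xs))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      C <- Xs[bi, , drop = FALSE]
      X1 <- fe$X[pair[bi], , drop = FALSE]
      n <- nrow(C)
      X0 <- matrix(stats::rnorm(n * cfg$state_dim), n, cfg$state_dim)
      tv <- stats::runif(n)
      Xt <- interpolate_state(X0, X1, tv)
      fwd <- velocity_forward(net, Xt, tv, C)
      target <- X1 - X0
      L <- mean((fwd$out - target)^2)
      ep_loss <- ep_loss + L * n
      dout <- 2 * (fwd$out - target) / length(target)
      bwd <- velocity_backward(net, fwd$caches, dout)
      step <- step + 1
      u <- velocity_adam(net, bwd$grads, st, step, cfg$lr)
      net <- u$net; st <- u$st
    }
    history[ep] <- ep_loss / nrow(Xs)
  }
  structure(list(net = net, config = cfg, history = history,
                 cond_features = fs$feature_names,
                 state_features = fe$feature_names),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> %d-d state | %d-d condition, hidden %d, %d epochs (final loss %.4f)\n",
              x$config$state_dim, x$config$cond_dim, x$config$hidden,
              length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Generate EEG-like latents for a table of speech latents
#'
#' Draws `x0 ~ N(0, I)` under `seed` for every speech row and integrates the
#' learned velocity field with `steps` Euler iterations.
#'
#' @param model A `flow_model`.
#' @param speech_latents Table whose numeric columns match the training
#'   condition width.
#' @param seed Integer seed for the initial noise.
#' @param steps Euler steps (default the model's configured N = 10).
#' @return Tibble of metadata columns plus `G1..G<state_dim>`.
#' @export
flow_generate <- function(model, speech_latents, seed = 1,
                          steps = model$config$steps) {
  stopifnot(inherits(model, "flow_model"))
  fs <- feature_matrix(speech_latents)
  if (ncol(fs$X) != model$config$cond_dim) {
    stop("condition width does not match the trained model", call. = FALSE)
  }
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  n <- nrow(fs$X)
  X0 <- matrix(stats::rnorm(n * model$config$state_dim), n, model$config$state_dim)
  G <- euler_sample(model, fs$X, X0, steps)
  colnames(G) <- paste0("G", seq_len(ncol(G)))
  dplyr::bind_cols(fs$meta, tibble::as_tibble(G))
}
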