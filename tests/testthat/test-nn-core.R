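# Gradient correctness of the dense-network engine against central finite
# differences, and optimizer sanity.

fd_grad <- function(loss, get, set, layers, idx, eps = 1e-6) {
  vapply(idx, function(q) {
    lp <- set(layers, q, get(layers, q) + eps)
    lm <- set(layers, q, get(layers, q) - eps)
    (loss(lp) - loss(lm)) / (2 * eps)
  }, numeric(1))
}

test_that("backward pass matches finite differences for every layer type", {
  set.seed(42)
  layers <- list(flowfuse:::nn_dense(5, 7), flowfuse:::nn_batchnorm(7),
                 flowfuse:::nn_act("relu"), flowfuse:::nn_dense(7, 4),
                 flowfuse:::nn_layernorm(4), flowfuse:::nn_act("silu"),
                 flowfuse:::nn_dense(4, 2), flowfuse:::nn_act("sigmoid"))
  X <- matrix(rnorm(40), 8, 5)
  loss <- function(ls) sum(flowfuse:::nn_forward(ls, X, training = TRUE)$out^2)
  f <- flowfuse:::nn_forward(layers, X, training = TRUE)
  bk <- flowfuse:::nn_backward(layers, f$caches, 2 * f$out)

  for (li in c(1, 2, 4, 5, 7)) {
    par <- if (layers[[li]]$type == "dense") c("W", "b") else c("gamma", "beta")
    for (nm in par) {
      idx <- seq_len(min(6, length(layers[[li]][[nm]])))
      num <- fd_grad(loss,
                     function(ls, q) ls[[li]][[nm]][q],
                     function(ls, q, v) { ls[[li]][[nm]][q] <- v; ls },
                     layers, idx)
      ana <- as.numeric(bk$grads[[li]][[nm]])[idx]
      expect_lt(max(abs(num - ana) / pmax(1, abs(num))), 1e-6)
    }
  }
  # input gradient
  num_dX <- vapply(1:10, function(q) {
    Xp <- X; Xp[q] <- Xp[q] + 1e-6
    Xm <- X; Xm[q] <- Xm[q] - 1e-6
    (sum(flowfuse:::nn_forward(layers, Xp, training = TRUE)$out^2) -
       sum(flowfuse:::nn_forward(layers, Xm, training = TRUE)$out^2)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(num_dX - as.numeric(bk$dX)[1:10])), 1e-5)
})

test_that("SE module backward matches finite differences", {
  set.seed(9)
  params <- flowfuse:::se_init(8, 4)
  f <- matrix(rnorm(24), 3, 8)
  loss_of <- function(p) sum(flowfuse:::se_forward(f, p)$out^2)
  fw <- flowfuse:::se_forward(f, params)
  bk <- flowfuse:::se_backward(params, fw$cache, 2 * fw$out)
  for (nm in c("W1", "b1", "W2", "b2")) {
    idx <- seq_len(min(6, length(params[[nm]])))
    num <- vapply(idx, function(q) {
      pp <- params; pp[[nm]][q] <- pp[[nm]][q] + 1e-6
      pm <- params; pm[[nm]][q] <- pm[[nm]][q] - 1e-6
      (loss_of(pp) - loss_of(pm)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(num - as.numeric(bk$grads[[nm]])[idx])), 1e-5)
  }
  # gradient w.r.t. the input features
  num_df <- vapply(1:8, function(q) {
    fp <- f; fp[q] <- fp[q] + 1e-6
    fm <- f; fm[q] <- fm[q] - 1e-6
    (sum(flowfuse:::se_forward(fp, params)$out^2) -
       sum(flowfuse:::se_forward(fm, params)$out^2)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(num_df - as.numeric(bk$df)[1:8])), 1e-5)
})

test_that("velocity network backward matches finite differences", {
  set.seed(5)
  cfg <- flow_config(state_dim = 4, cond_dim = 3, hidden = 6, n_blocks = 2)
  net <- flowfuse:::velocity_net_init(cfg)
  X <- matrix(rnorm(12), 3, 4)
  C <- matrix(rnorm(9), 3, 3)
  tv <- runif(3)
  loss_of <- function(n) sum(flowfuse:::velocity_forward(n, X, tv, C)$out^2)
  fw <- flowfuse:::velocity_forward(net, X, tv, C)
  bk <- flowfuse:::velocity_backward(net, fw$caches, 2 * fw$out)
  probe <- list(
    list(path = c("proj_x", 1L), g = bk$grads$proj_x[[1]]$W, nm = "W"),
    list(path = c("emb_t", 1L), g = bk$grads$emb_t[[1]]$W, nm = "W"),
    list(path = c("emb_c", 3L), g = bk$grads$emb_c[[3]]$W, nm = "W"),
    list(path = c("head", 1L), g = bk$grads$head[[1]]$W, nm = "W"))
  for (pr in probe) {
    idx <- seq_len(min(5, length(pr$g)))
    num <- vapply(idx, function(q) {
      np <- net; np[[pr$path[1]]][[as.integer(pr$path[2])]][[pr$nm]][q] <-
        np[[pr$path[1]]][[as.integer(pr$path[2])]][[pr$nm]][q] + 1e-6
      nm_ <- net; nm_[[pr$path[1]]][[as.integer(pr$path[2])]][[pr$nm]][q] <-
        nm_[[pr$path[1]]][[as.integer(pr$path[2])]][[pr$nm]][q] - 1e-6
      (loss_of(np) - loss_of(nm_)) / 2e-6
    }, numeric(1))
    expect_lt(max(abs(num - as.numeric(pr$g)[idx]) / pmax(1, abs(num))), 1e-5)
  }
  # residual-block body weight
  g_blk <- bk$grads$blocks[[1]]$body[[1]]$W
  idx <- seq_len(5)
  num <- vapply(idx, function(q) {
    np <- net; np$blocks[[1]]$body[[1]]$W[q] <- np$blocks[[1]]$body[[1]]$W[q] + 1e-6
    nm_ <- net; nm_$blocks[[1]]$body[[1]]$W[q] <- nm_$blocks[[1]]$body[[1]]$W[q] - 1e-6
    (loss_of(np) - loss_of(nm_)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(num - as.numeric(g_blk)[idx]) / pmax(1, abs(num))), 1e-5)
})

test_that("Adam minimizes a simple least-squares objective", {
  set.seed(3)
  layers <- list(flowfuse:::nn_dense(4, 1))
  st <- flowfuse:::adam_init(layers)
  X <- matrix(rnorm(200), 50, 4)
  w_true <- c(1, -2, 0.5, 3)
  y <- X %*% w_true
  for (t in 1:400) {
    f <- flowfuse:::nn_forward(layers, X)
    d <- 2 * (f$out - y) / 50
    bk <- flowfuse:::nn_backward(layers, f$caches, d)
    u <- flowfuse:::adam_step(layers, bk$grads, st, t, lr = 0.05)
    layers <- u$layers; st <- u$state
  }
  expect_lt(max(abs(layers[[1]]$W - w_true)), 0.05)
})
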