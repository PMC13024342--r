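# Alignment losses, batching, GRL semantics and training behaviour.

test_that("GRL is the identity forward and a reversed scale backward", {
  x <- matrix(rnorm(6), 2, 3)
  expect_identical(grl(x, 0.1), x)
  g <- matrix(1:6, 2, 3)
  expect_equal(grl_backward(g, 0.25), -0.25 * g)
  # composed with a scalar probe f(x) = sum(x^2): d/dx f(grl(x)) = -lambda 2x
  expect_equal(grl_backward(2 * x, 0.5), -0.5 * 2 * x)
})

test_that("GRL schedule starts at zero and ends at the ceiling", {
  expect_equal(flowfuse:::grl_factor(0, 0.1, "linear"), 0)
  expect_equal(flowfuse:::grl_factor(1, 0.1, "linear"), 0.1)
  expect_equal(flowfuse:::grl_factor(0, 0.1, "dann"), 0)
  expect_lt(abs(flowfuse:::grl_factor(1, 0.1, "dann") - 0.1), 1e-4)
})

test_that("weighted cross-entropy reduces to the unweighted mean for
           balanced classes and matches hand computation", {
  set.seed(1)
  logits <- matrix(rnorm(12), 4, 3)
  labels <- c("AD", "HC", "MCI", "AD")
  bal <- c(AD = 1 / 3, HC = 1 / 3, MCI = 1 / 3)
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  plain <- -mean(log(P[cbind(1:4, match(labels, c("AD", "HC", "MCI")))]))
  expect_equal(weighted_cross_entropy(logits, labels, bal), plain,
               tolerance = 1e-12)
  # perfect one-hot predictions -> ~0
  big <- matrix(-50, 2, 3)
  big[1, 1] <- 50; big[2, 2] <- 50
  expect_lt(weighted_cross_entropy(big, c("AD", "HC"), bal), 1e-6)
  # two-class toy with proportions (1/4, 3/4): weights (4, 4/3)
  lg <- matrix(c(2, 0, 0,
                 0, 1, 0), 2, 3, byrow = TRUE)
  lab <- c("AD", "HC")
  pr <- c(AD = 0.25, HC = 0.75, MCI = 1)  # MCI unused
  ce1 <- -log(exp(2) / (exp(2) + 2))
  ce2 <- -log(exp(1) / (exp(1) + 2))
  hand <- (4 * ce1 + (4 / 3) * ce2) / (4 + 4 / 3)
  expect_equal(weighted_cross_entropy(lg, lab, pr), hand, tolerance = 1e-12)
  expect_error(weighted_cross_entropy(lg, lab, c(AD = 1)), "missing")
})

test_that("center loss is the mean first-power Euclidean distance", {
  centers <- matrix(0, 3, 2, dimnames = list(c("AD", "HC", "MCI"), NULL))
  Z <- matrix(c(0, 0), 1, 2)
  expect_equal(center_loss(Z, "AD", centers), 0)
  Z1 <- matrix(c(3, 4), 1, 2)
  expect_equal(center_loss(Z1, "HC", centers), 5)
  Z3 <- rbind(c(1, 0), c(0, 2), c(3, 0))
  expect_equal(center_loss(Z3, c("AD", "AD", "AD"), centers), 2)
})

test_that("consistency loss matches hand-computed class-mean MSE and masks
           MCI", {
  Zs <- rbind(c(1, 0), c(1, 0))
  Ze <- rbind(c(0, 0), c(0, 0))
  v <- consistency_loss(Zs, c("AD", "AD"), Ze, c("AD", "AD"))
  expect_equal(as.numeric(v), 0.5)
  expect_false(attr(v, "skipped"))
  # identical means -> 0
  expect_equal(as.numeric(consistency_loss(Zs, c("AD", "AD"), Zs, c("AD", "AD"))), 0)
  # MCI never contributes even when shared
  v2 <- consistency_loss(Zs, c("MCI", "MCI"), Ze, c("MCI", "MCI"))
  expect_equal(as.numeric(v2), 0)
  expect_true(attr(v2, "skipped"))
  # empty EEG side -> skipped
  v3 <- consistency_loss(Zs, c("AD", "AD"), Ze[0, , drop = FALSE], character(0))
  expect_true(attr(v3, "skipped"))
})

test_that("pseudo-MCI interpolation is an exact convex combination", {
  z_ad <- c(2, 4); z_hc <- c(0, 0)
  expect_equal(pseudo_mci(z_ad, z_hc, 0.5), c(1, 2))
  expect_equal(pseudo_mci(z_ad, z_hc, 1 - 1e-9), z_ad, tolerance = 1e-6)
  expect_error(pseudo_mci(z_ad, z_hc, 1), "alpha")
  set.seed(2)
  alphas <- rbeta(1000, 2, 2)
  out <- vapply(alphas, function(a) pseudo_mci(z_ad, z_hc, a), numeric(2))
  expect_true(all(out[1, ] >= 0 & out[1, ] <= 2))
  expect_true(all(out[2, ] >= 0 & out[2, ] <= 4))
})

test_that("total loss is the exact weighted sum with the default weights", {
  cfg <- alignment_config()
  expect_equal(total_loss(1, 1, 1, 1, cfg), 6.15)
  expect_equal(total_loss(0, 0, 0, 0, cfg), 0)
  expect_equal(total_loss(2, 0, 0, 1, cfg), 7.0)
})

test_that("paired batches cover speech exactly once and cycle EEG without
           starvation", {
  b <- paired_batches(280, 52, batch_size = 64, seed = 3)
  expect_length(b, 5)
  sp <- unlist(lapply(b, `[[`, "speech"))
  expect_setequal(sp, 1:280)
  expect_equal(length(sp), 280)
  ee <- unlist(lapply(b, `[[`, "eeg"))
  # 5 batches x 52 EEG rows per batch = 260 draws from 52 rows: the iterator
  # reset at least 4 times and every row appears
  expect_setequal(unique(ee), 1:52)
  expect_gte(length(ee) / 52, 5)
  expect_identical(paired_batches(280, 52, 64, seed = 3), b)
  expect_false(identical(paired_batches(280, 52, 64, seed = 4), b))
})

test_that("alignment training separates classes, merges modalities and logs
           an exact loss identity", {
  coh <- tiny_cohort(n = 60, seed = 7)
  sp <- standardize_features(coh$speech)
  ee <- standardize_features(coh$eeg)
  cfg <- tiny_alignment_config(epochs = 60, seed = 3)
  m <- train_alignment(sp, ee, cfg)
  # Eq. identity at every logged epoch
  h <- m$history
  expect_equal(h$L_total,
               h$L_cls + cfg$lambda_center * h$L_center +
                 cfg$lambda_domain * h$L_domain +
                 cfg$lambda_consist * h$L_consist,
               tolerance = 1e-9)
  expect_equal(h$lambda_grl[1], 0)
  expect_equal(h$lambda_grl[nrow(h)], cfg$grl_ceiling)
  # encoding contracts
  zs <- align_encode(m, sp, "speech")
  expect_equal(ncol(zs) - 3, cfg$subspace_dim)
  expect_identical(zs, align_encode(m, sp, "speech"))
  ze <- align_encode(m, ee, "eeg")
  # perturbing the EEG encoder must not change speech encodings
  m2 <- m
  m2$encoder_eeg[[1]]$W <- m2$encoder_eeg[[1]]$W + 1
  expect_identical(align_encode(m2, sp, "speech"), zs)
  expect_false(identical(align_encode(m2, ee, "eeg"), ze))
  # cross-modal class centers moved closer together than at initialization
  dist_between <- function(zs, ze) {
    mean(vapply(c("AD", "HC"), function(k) {
      sqrt(sum((colMeans(as.matrix(zs[zs$label == k, -(1:3)])) -
                  colMeans(as.matrix(ze[ze$label == k, -(1:3)])))^2))
    }, numeric(1)))
  }
  cfg0 <- cfg; cfg0$epochs <- 1
  m0 <- train_alignment(sp, ee, cfg0)
  d_trained <- dist_between(zs, ze)
  d_init <- dist_between(align_encode(m0, sp, "speech"),
                         align_encode(m0, ee, "eeg"))
  expect_lt(d_trained, d_init)
  # class structure: nearest-center accuracy on the training cohort
  Z <- as.matrix(zs[, -(1:3)])
  pred <- c("AD", "HC", "MCI")[apply(Z, 1, function(z)
    which.min(colSums((t(m$centers) - z)^2)))]
  expect_gt(mean(pred == zs$label), 0.8)
  expect_error(train_alignment(sp[sp$label != "MCI", ], ee, cfg), "three")
})

test_that("training is deterministic under the config seed", {
  coh <- tiny_cohort(n = 20, seed = 9)
  sp <- standardize_features(coh$speech)
  ee <- standardize_features(coh$eeg)
  cfg <- tiny_alignment_config(epochs = 5, seed = 11)
  m1 <- train_alignment(sp, ee, cfg)
  m2 <- train_alignment(sp, ee, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(flowfuse:::nn_flatten(m1$encoder_speech),
                   flowfuse:::nn_flatten(m2$encoder_speech))
})
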