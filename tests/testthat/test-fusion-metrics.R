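# SE fusion classifier and the one-vs-rest metric machinery.

test_that("SE reweighting obeys the sigmoid-gate closed forms", {
  params <- flowfuse:::se_init(8, 4)
  params$W1[] <- 0; params$b1[] <- 0; params$W2[] <- 0; params$b2[] <- 0
  f <- matrix(rnorm(16), 2, 8)
  expect_equal(se_reweight(f, params), 0.5 * f)
  set.seed(1)
  params2 <- flowfuse:::se_init(8, 4)
  out <- se_reweight(f, params2)
  expect_equal(dim(out), dim(f))
  w <- out / f
  expect_true(all(w > 0 & w < 1))
  expect_error(se_reweight(matrix(0, 1, 5), params2), "width")
})

test_that("fusion forward yields probabilities and the published concat
           width under defaults", {
  set.seed(2)
  cfg <- fusion_config()
  net <- flowfuse:::fusion_net_init(20, 12, cfg, use_se = TRUE)
  expect_equal(net$concat, 256)
  expect_equal(nrow(net$se$W1), 256)
  expect_equal(ncol(net$se$W1), 32)   # bottleneck 256 -> 32 at ratio 8
  P <- fusion_forward(net, matrix(rnorm(5 * 20), 5), matrix(rnorm(5 * 12), 5))
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-6)
  expect_true(all(P >= 0))
  expect_error(fusion_config(branch_dim = 10, se_ratio = 8), "divide")
})

test_that("fusion classifier learns a separable synthetic problem", {
  set.seed(3)
  n <- 80
  mk <- function(mu, lab) {
    tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6, mu, 0.4), n, 6))) |>
      dplyr::mutate(label = lab)
  }
  x1 <- dplyr::bind_rows(mk(-1.5, "AD"), mk(0, "MCI"), mk(1.5, "HC"))
  x2 <- dplyr::bind_rows(mk(1, "AD"), mk(0, "MCI"), mk(-1, "HC"))
  idx <- sample(nrow(x1)); ntr <- 180
  tr <- idx[seq_len(ntr)]; te <- idx[-seq_len(ntr)]
  fus <- fusion_fit(x1[tr, ], x2[tr, ], tiny_fusion_config(epochs = 60, seed = 4))
  pred <- predict(fus, x1[te, ], x2[te, ], type = "class")
  expect_gte(mean(pred == x1$label[te]), 0.95)
  pr <- predict(fus, x1[te, ], x2[te, ], type = "prob")
  expect_equal(rowSums(as.matrix(pr)), rep(1, length(te)), tolerance = 1e-6)
})

test_that("perfect predictions give unit metrics", {
  y <- rep(c("AD", "HC", "MCI"), each = 4)
  r <- classification_metrics(y, y)
  expect_equal(r$accuracy, 1)
  expect_true(all(r$per_class$sensitivity == 1))
  expect_true(all(r$per_class$specificity == 1))
  expect_true(all(r$per_class$f1 == 1))
})

test_that("F1 follows the harmonic-mean identity", {
  # class AD: precision 0.5, recall 1 -> F1 = 2/3
  y_true <- c("AD", "AD", "HC", "HC")
  y_pred <- c("AD", "AD", "AD", "AD")
  r <- suppressWarnings(classification_metrics(y_true, y_pred))
  ad <- r$per_class[r$per_class$class == "AD", ]
  expect_equal(ad$precision, 0.5)
  expect_equal(ad$sensitivity, 1)
  expect_equal(ad$f1, 2 / 3)
  # identity holds on a random confusion matrix
  set.seed(5)
  cm <- matrix(rpois(9, 20), 3, 3)
  pc <- confusion_metrics(cm)
  expect_equal(pc$f1,
               2 * pc$precision * pc$sensitivity / (pc$precision + pc$sensitivity),
               tolerance = 1e-9)
  # one-vs-rest consistency: TP + FN equals the row sum
  for (k in 1:3) {
    expect_equal(pc$support[k], sum(cm[k, ]))
  }
})

test_that("fold-averaged fractional confusion matrices are handled and an
           absent class is excluded with a warning", {
  cm <- matrix(c(10.5, 0.5, 1, 0.2, 12, 0.8, 0.3, 0.7, 9), 3, 3, byrow = TRUE)
  pc <- confusion_metrics(cm)
  expect_true(all(pc$sensitivity > 0 & pc$sensitivity <= 1))
  y_true <- rep(c("AD", "HC"), each = 5)
  y_pred <- rep(c("AD", "HC"), each = 5)
  expect_warning(r <- classification_metrics(y_true, y_pred), "absent")
  expect_true(is.na(r$per_class$sensitivity[r$per_class$class == "MCI"]))
  expect_equal(r$macro_sensitivity, 1)
})

test_that("macro AUC reflects ranking quality", {
  set.seed(6)
  y <- rep(c("AD", "HC", "MCI"), each = 30)
  P_good <- matrix(0.1, 90, 3, dimnames = list(NULL, c("AD", "HC", "MCI")))
  P_good[cbind(1:90, match(y, c("AD", "HC", "MCI")))] <- 0.8
  r_good <- classification_metrics(y, probs = P_good)
  expect_equal(r_good$macro_auc, 1)
  P_rand <- matrix(runif(270), 90, 3, dimnames = list(NULL, c("AD", "HC", "MCI")))
  P_rand <- P_rand / rowSums(P_rand)
  r_rand <- classification_metrics(y, probs = P_rand)
  expect_lt(abs(r_rand$macro_auc - 0.5), 0.15)
})

test_that("metric aggregation reproduces mean and SD from stored reports", {
  y <- rep(c("AD", "HC", "MCI"), each = 10)
  r1 <- classification_metrics(y, y)
  y2 <- y; y2[1] <- "HC"
  r2 <- classification_metrics(y, y2)
  agg <- aggregate_metrics(list(r1, r2))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, mean(c(r1$accuracy, r2$accuracy)))
  expect_equal(acc$sd, sd(c(r1$accuracy, r2$accuracy)))
})
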