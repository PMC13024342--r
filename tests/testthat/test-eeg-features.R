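# Handcrafted EEG biomarkers: dimension identities, closed-form examples and
# brute-force oracle equivalence.

make_rec <- function(X, fs = 500) eeg_recording(X, fs)

test_that("time-domain statistics match closed forms", {
  rec <- make_rec(rbind(rep(5, 100), rep(c(1, -1), 50)))
  tf <- time_domain_features(rec)
  expect_equal(tf$mean_ch1, 5)
  expect_equal(tf$peak_ch1, 5)
  expect_equal(tf$var_ch1, 0)
  expect_equal(tf$sd_ch1, 0)
  expect_equal(tf$skew_ch1, 0)  # constant-signal convention
  expect_equal(tf$kurt_ch1, 0)
  expect_equal(tf$rms_ch1, 5)
  expect_equal(tf$mean_ch2, 0)
  expect_equal(tf$rms_ch2, 1)
  expect_equal(tf$peak_ch2, 1)
})

test_that("feature vectors have the published dimensions for 19 channels", {
  rec <- generate_band_structured_eeg(band_power_profile("HC"),
                                      duration = 4, seed = 1)
  expect_equal(ncol(time_domain_features(rec)) - 1, 133)
  expect_equal(ncol(frequency_domain_features(rec)) - 1, 190)
  expect_equal(ncol(dwt_features(rec)) - 1, 342)
  expect_equal(ncol(multiscale_entropy(rec)) - 1, 380)
  expect_equal(ncol(roi_connectivity(pli_matrix(rec))) - 1, 10)
})

test_that("pure tone: alpha power and median frequency match the
           periodogram oracle", {
  fs <- 500
  x <- sin(2 * pi * 10 * seq_len(8 * fs) / fs)
  rec <- make_rec(rbind(x), fs)
  ff <- frequency_domain_features(rec)
  expect_gte(ff$relpow_alpha_ch1, 0.99)
  mf_oracle <- medfreq_oracle(x, fs, 0.5, 100)
  expect_lt(abs(ff$medfreq_ch1 - 10), 0.5)   # within one 2-s-window PSD bin
  expect_lt(abs(mf_oracle - 10), 0.25)
  # band powers agree with direct periodogram integration (relative terms)
  bp_or <- vapply(eeg_band_set(), function(b)
    periodogram_band_oracle(x, fs, b[1], min(b[2], fs / 2)), numeric(1))
  rel_or <- bp_or / sum(bp_or)
  rel <- as.numeric(ff[paste0("relpow_", names(eeg_band_set()), "_ch1")])
  expect_equal(rel, as.numeric(rel_or), tolerance = 0.01)
})

test_that("white noise: relative powers track bandwidth shares and spectral
           entropy is near 1", {
  set.seed(11)
  fs <- 200
  x <- rnorm(90 * fs)
  rec <- make_rec(rbind(x), fs)
  ff <- frequency_domain_features(rec)
  # analyzed range is 0.5-100 Hz capped at Nyquist -> 0.5 to 100 -> width 99.5
  widths <- c(delta = 3.5, theta = 4, alpha = 5, beta = 17, gamma = 70)
  total <- sum(widths)
  for (b in names(widths)) {
    expect_lt(abs(ff[[paste0("relpow_", b, "_ch1")]] - widths[[b]] / total), 0.05)
  }
  expect_gt(ff$spec_entropy_ch1, 0.9)
})

test_that("relative powers sum to one", {
  rec <- generate_band_structured_eeg(band_power_profile("AD"), n_channels = 3,
                                      duration = 4, seed = 8)
  ff <- frequency_domain_features(rec)
  for (ch in c("ch1", "ch2", "ch3")) {
    s <- sum(as.numeric(ff[paste0("relpow_", names(eeg_band_set()), "_", ch)]))
    expect_equal(s, 1, tolerance = 1e-9)
  }
})

test_that("spectral entropy closed forms", {
  expect_equal(spectral_entropy(rep(3, 7)), 1)
  expect_equal(spectral_entropy(c(0, 5, 0, 0)), 0)
  # -(0.5 log2 0.5 + 2 * 0.25 log2 0.25) / log2(3) = 1.5 / log2(3)
  expect_equal(spectral_entropy(c(0.5, 0.25, 0.25)), 1.5 / log2(3),
               tolerance = 1e-3)
  expect_error(spectral_entropy(c(0, 0)), "all-zero")
  expect_error(spectral_entropy(5), "2")
})

test_that("DWT conserves energy and handles degenerate input", {
  set.seed(21)
  x <- rnorm(1024)
  cf <- dwt_db4(x, 5)
  expect_equal(sum(vapply(cf, function(v) sum(v^2), numeric(1))),
               sum(x^2), tolerance = 1e-8)
  rec0 <- make_rec(rbind(rep(0, 256)))
  df0 <- dwt_features(rec0)
  expect_true(all(as.numeric(df0[-1]) == 0))
  expect_error(dwt_db4(rnorm(16), 5), "short")
})

test_that("coarse graining follows the floor-window-mean rule", {
  expect_identical(coarse_grain(1:6, 1), 1:6)
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_length(coarse_grain(1:7, 3), 2)
  expect_error(coarse_grain(1:3, 5), "exceeds")
})

test_that("sample entropy equals the naive pair-counting oracle", {
  # alternating pattern: every m-match extends, SampEn = 0
  x_alt <- rep(c(1, 2), 50)
  expect_equal(sample_entropy(x_alt, 2, 0.2), 0)
  expect_equal(sample_entropy(x_alt, 2, 0.2), sampen_oracle(x_alt, 2, 0.2))
  set.seed(31)
  x <- rnorm(200)
  r <- 0.15 * sd(x)
  expect_equal(sample_entropy(x, 2, r), sampen_oracle(x, 2, r),
               tolerance = 1e-12)
  x2 <- rnorm(300)
  expect_equal(sample_entropy(x2, 3, 0.3 * sd(x2)),
               sampen_oracle(x2, 3, 0.3 * sd(x2)), tolerance = 1e-12)
  # a constant series collapses the relative tolerance to zero
  expect_error(sample_entropy(rep(1, 50), 2, 0), "positive")
  # widely spaced monotone series: no template matches at all (B = 0)
  expect_error(sample_entropy((1:20) * 10, 2, 0.1), "degenerate")
})

test_that("sample entropy is invariant to affine rescaling with relative r", {
  set.seed(32)
  x <- rnorm(150)
  r_rel <- function(v) 0.2 * sd(v)
  y <- 5 * x + 3
  expect_equal(sample_entropy(x, 2, r_rel(x)), sample_entropy(y, 2, r_rel(y)),
               tolerance = 1e-12)
})

test_that("multiscale entropy is consistent at scale 1 and decreases for
           coarse-grained white noise", {
  set.seed(33)
  X <- matrix(rnorm(2 * 1500), 2)
  rec <- make_rec(X, 250)
  mse <- multiscale_entropy(rec, scales = c(1, 10))
  r <- 0.15 * sqrt(mean((X[1, ] - mean(X[1, ]))^2))
  expect_equal(mse$mse_scale1_ch1, sample_entropy(X[1, ], 2, r),
               tolerance = 1e-12)
  expect_lt(mse$mse_scale10_ch1, mse$mse_scale1_ch1)
  expect_lt(mse$mse_scale10_ch2, mse$mse_scale1_ch2)
})

test_that("PLI closed forms and matrix properties", {
  fs <- 250
  tt <- seq_len(8 * fs) / fs
  base <- sin(2 * pi * 10 * tt)
  # identical channels -> zero phase difference -> PLI 0
  rec_same <- make_rec(rbind(base, base), fs)
  P0 <- pli_matrix(rec_same)
  expect_equal(P0[1, 2], 0)
  # constant 90 degree offset -> PLI ~ 1
  rec_off <- make_rec(rbind(base, sin(2 * pi * 10 * tt + pi / 2)), fs)
  P1 <- pli_matrix(rec_off)
  expect_gte(P1[1, 2], 0.99)
  # properties on a noisy multichannel recording
  rec <- generate_band_structured_eeg(band_power_profile("HC"), n_channels = 5,
                                      duration = 6, seed = 13)
  P <- pli_matrix(rec)
  expect_true(isSymmetric(P))
  expect_true(all(diag(P) == 0))
  expect_true(all(P >= 0 & P <= 1))
  # amplitude scaling of a channel leaves PLI unchanged
  rec_scaled <- eeg_recording(rec$data * c(7, 1, 1, 1, 1), rec$fs,
                              rec$channel_names)
  expect_equal(pli_matrix(rec_scaled), P, tolerance = 1e-10)
  expect_error(pli_matrix(rec, band = c(8, 400)), "Nyquist")
})

test_that("ROI connectivity averages the right cross-region pairs", {
  # 4-channel toy: two regions of two channels each
  M <- matrix(c(0, .1, .2, .3,
                .1, 0, .4, .5,
                .2, .4, 0, .6,
                .3, .5, .6, 0), 4, 4,
              dimnames = list(c("F3", "F4", "P3", "P4"),
                              c("F3", "F4", "P3", "P4")))
  out <- roi_connectivity(M, roi_map = c(F3 = "Frontal", F4 = "Frontal",
                                         P3 = "Parietal", P4 = "Parietal"))
  expect_equal(out$pli_Frontal_Parietal, mean(c(.2, .3, .4, .5)))
  # constant off-diagonal matrix -> every pair mean equals the constant
  C <- matrix(0.42, 19, 19,
              dimnames = list(eeg_channels_1020(), eeg_channels_1020()))
  diag(C) <- 0
  outc <- roi_connectivity(C)
  expect_true(all(abs(as.numeric(outc[-1]) - 0.42) < 1e-12))
  expect_equal(ncol(outc) - 1, 10)
})

test_that("z-score standardization honours the train/apply contract", {
  set.seed(41)
  tab <- tibble::tibble(subject_id = as.character(1:20),
                        label = rep(c("AD", "HC"), 10),
                        f1 = rnorm(20, 5, 2), f2 = rnorm(20, -3, 0.5))
  std <- fit_standardizer(tab)
  z <- predict(std, tab)
  expect_lt(max(abs(colMeans(as.matrix(z[c("f1", "f2")])))), 1e-9)
  expect_lt(max(abs(apply(as.matrix(z[c("f1", "f2")]), 2, sd) - 1)), 1e-9)
  held <- tibble::tibble(subject_id = "x", label = "AD", f1 = 7, f2 = -2)
  zh <- predict(std, held)
  expect_equal(zh$f1, (7 - mean(tab$f1)) / sd(tab$f1))
  # idempotence of re-fitting on standardized data
  z2 <- standardize_features(z)
  expect_equal(as.matrix(z2[c("f1", "f2")]), as.matrix(z[c("f1", "f2")]),
               tolerance = 1e-9)
  # zero-variance guard
  tab$f3 <- 1
  expect_warning(fit_standardizer(tab), "zero-variance")
})
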