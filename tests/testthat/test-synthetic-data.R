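# Synthetic cohort and band-structured EEG generators.

test_that("cohort has the contracted shapes and label asymmetry", {
  coh <- generate_continuum_cohort(continuum_spec(n_per_class = 10, seed = 1))
  expect_equal(nrow(coh$speech), 30)
  expect_equal(nrow(coh$eeg), 20)
  expect_setequal(unique(coh$speech$label), c("AD", "HC", "MCI"))
  expect_setequal(unique(coh$eeg$label), c("AD", "HC"))
  expect_false(any(coh$eeg$label == "MCI"))
  expect_equal(as.numeric(table(coh$speech$label)), rep(10, 3))
})

test_that("zero noise collapses every row onto its class anchor image", {
  spec <- continuum_spec(n_per_class = 5, noise_sd = 0, seed = 2)
  coh <- generate_continuum_cohort(spec)
  ad_rows <- as.matrix(dplyr::select(
    dplyr::filter(coh$speech, label == "AD"), -subject_id, -label, -modality))
  target <- as.numeric(flowfuse:::affine_apply(spec$speech_map,
                                               matrix(spec$anchor_AD, 1)))
  for (i in seq_len(nrow(ad_rows))) {
    expect_equal(as.numeric(ad_rows[i, ]), target, tolerance = 1e-12)
  }
  # continuum geometry: MCI latent is the exact convex combination
  z_mci <- as.matrix(dplyr::select(
    dplyr::filter(coh$latents, label == "MCI"), dplyr::starts_with("z")))
  expected <- spec$anchor_HC + spec$mci_position * (spec$anchor_AD - spec$anchor_HC)
  expect_equal(as.numeric(z_mci[1, ]), expected, tolerance = 1e-12)
})

test_that("empirical MCI speech mean sits at the interpolated anchor image", {
  spec <- continuum_spec(n_per_class = 200, noise_sd = 0.1, seed = 3)
  coh <- generate_continuum_cohort(spec)
  mci <- as.matrix(dplyr::select(
    dplyr::filter(coh$speech, label == "MCI"), -subject_id, -label, -modality))
  anchor <- spec$anchor_HC + spec$mci_position * (spec$anchor_AD - spec$anchor_HC)
  target <- as.numeric(flowfuse:::affine_apply(spec$speech_map, matrix(anchor, 1)))
  se <- 0.1 / sqrt(200)
  dev <- abs(colMeans(mci) - target)
  expect_true(all(dev < 4 * se))
  # overwhelming majority within 3 SE (a few coordinates may graze the band)
  expect_gt(mean(dev < 3 * se), 0.97)
})

test_that("cohort generation is deterministic under the spec seed", {
  a <- generate_continuum_cohort(continuum_spec(n_per_class = 8, seed = 5))
  b <- generate_continuum_cohort(continuum_spec(n_per_class = 8, seed = 5))
  expect_identical(a$speech, b$speech)
  expect_identical(a$eeg, b$eeg)
})

test_that("invalid continuum specs are rejected", {
  expect_error(continuum_spec(mci_position = 0), "mci_position")
  expect_error(continuum_spec(mci_position = 1), "mci_position")
  expect_error(continuum_spec(anchor_HC = c(NA, rep(0, 7))), "finite")
  expect_error(continuum_spec(speech_map = list(A = matrix(Inf, 8, 128),
                                                b = rep(0, 128))),
               "speech_map")
})

test_that("single-band profile concentrates relative power in that band", {
  p <- band_power_profile(amplitudes = c(delta = 0, theta = 0, alpha = 1,
                                         beta = 0, gamma = 0), noise_sd = 0)
  rec <- generate_band_structured_eeg(p, n_channels = 2, duration = 8, seed = 1)
  ff <- frequency_domain_features(rec)
  expect_gte(ff$relpow_alpha_ch1, 0.99)
  expect_gte(ff$relpow_alpha_ch2, 0.99)
})

test_that("AD-like profile has higher delta relative power than HC-like", {
  rec_ad <- generate_band_structured_eeg(band_power_profile("AD"),
                                         duration = 8, seed = 2)
  rec_hc <- generate_band_structured_eeg(band_power_profile("HC"),
                                         duration = 8, seed = 2)
  f_ad <- frequency_domain_features(rec_ad)
  f_hc <- frequency_domain_features(rec_hc)
  expect_gt(mean(as.numeric(dplyr::select(f_ad, dplyr::starts_with("relpow_delta")))),
            mean(as.numeric(dplyr::select(f_hc, dplyr::starts_with("relpow_delta")))))
  # and lower alpha
  expect_lt(mean(as.numeric(dplyr::select(f_ad, dplyr::starts_with("relpow_alpha")))),
            mean(as.numeric(dplyr::select(f_hc, dplyr::starts_with("relpow_alpha")))))
})

test_that("EEG generation is bit-identical under the same seed and stable
           when channels are appended", {
  p <- band_power_profile("HC")
  a <- generate_band_structured_eeg(p, n_channels = 4, duration = 4, seed = 9)
  b <- generate_band_structured_eeg(p, n_channels = 4, duration = 4, seed = 9)
  expect_identical(a$data, b$data)
  wider <- generate_band_structured_eeg(p, n_channels = 6, duration = 4, seed = 9)
  expect_identical(wider$data[1:4, ], a$data[1:4, ])
})

test_that("generator rejects invalid sampling setups", {
  p <- band_power_profile("HC")
  expect_error(generate_band_structured_eeg(p, fs = 40, duration = 8), "fs")
  expect_error(generate_band_structured_eeg(p, duration = 2), "duration")
  expect_error(band_power_profile(amplitudes = c(delta = 0, theta = 0,
                                                 alpha = 0, beta = 0,
                                                 gamma = 0)),
               "positive")
})
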