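# Synthetic inputs: latent-continuum feature cohorts and band-structured EEG.
#
# The cohort generator encodes the disease-continuum assumption the alignment
# and generation stages rely on: class anchors for HC and AD live in a small
# latent space, the MCI anchor is a convex combination of the two, and each
# modality observes an affine image of the latent position plus isotropic
# Gaussian noise.  EEG features exist only for AD and HC, mirroring the
# missing-MCI asymmetry of real paired corpora.

#' Specification of a synthetic latent-continuum cohort
#'
#' @param latent_dim Dimension of the generating latent space.
#' @param anchor_HC,anchor_AD Latent anchor vectors for the HC and AD classes.
#'   Defaults place them at \code{-1} and \code{+1} on every coordinate.
#' @param mci_position Position of the MCI anchor on the HC to AD segment,
#'   strictly inside (0, 1).  Default 0.5 (no quantitative clinical placement
#'   is assumed).
#' @param speech_dim,eeg_dim Output dimension of the two modality maps.
#' @param speech_map,eeg_map Optional affine maps, each a list with `A`
#'   (latent_dim x out_dim matrix) and `b` (length out_dim offset).  When
#'   omitted, random Gaussian maps with entries of scale
#'   \code{1/sqrt(latent_dim)} are drawn from the spec seed.
#' @param noise_sd Isotropic Gaussian noise SD added in each modality's
#'   feature space: either one scalar for both modalities or a named
#'   vector `c(speech = ..., eeg = ...)` (default 0.3 for both).
#' @param n_per_class Subjects per class (speech); EEG has the same count for
#'   AD and HC only.
#' @param seed Integer seed; identical specs produce identical cohorts.
#'
#' @return An object of class `continuum_spec`.
#' @export
continuum_spec <- function(latent_dim = 8,
                           anchor_HC = rep(-1, latent_dim),
                           anchor_AD = rep(1, latent_dim),
                           mci_position = 0.5,
                           speech_dim = 128, eeg_dim = 32,
                           speech_map = NULL, eeg_map = NULL,
                           noise_sd = 0.3, n_per_class = 50, seed = 1) {
  if (!all(is.finite(anchor_HC)) || !all(is.finite(anchor_AD))) {
    stop("anchors must be finite", call. = FALSE)
  }
  if (length(anchor_HC) != latent_dim || length(anchor_AD) != latent_dim) {
    stop("anchor length must equal latent_dim", call. = FALSE)
  }
  if (!(mci_position > 0 && mci_position < 1)) {
    stop("mci_position must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (speech_dim < 1 || eeg_dim < 1) stop("modality dimensions must be positive", call. = FALSE)
  if (any(noise_sd < 0)) stop("noise_sd must be nonnegative", call. = FALSE)
  if (length(noise_sd) == 1) {
    noise_sd <- c(speech = unname(noise_sd), eeg = unname(noise_sd))
  } else if (!all(c("speech", "eeg") %in% names(noise_sd))) {
    stop("vector noise_sd must name both modalities", call. = FALSE)
  }
  make_map <- function(d_out) {
    list(A = matrix(stats::rnorm(latent_dim * d_out, sd = 1 / sqrt(latent_dim)),
                    latent_dim, d_out),
         b = rep(0, d_out))
  }
  if (is.null(speech_map) || is.null(eeg_map)) {
    old <- .Random.seed_get()
    set.seed(seed)
    if (is.null(speech_map)) speech_map <- make_map(speech_dim)
    if (is.null(eeg_map)) eeg_map <- make_map(eeg_dim)
    .Random.seed_set(old)
  }
  check_map <- function(m, d_out, nm) {
    if (!is.list(m) || !all(c("A", "b") %in% names(m)) ||
        !all(is.finite(m$A)) || !all(is.finite(m$b)) ||
        nrow(m$A) != latent_dim || ncol(m$A) != d_out || length(m$b) != d_out) {
      stop("invalid ", nm, ": need finite A (latent_dim x dim) and b (dim)", call. = FALSE)
    }
  }
  check_map(speech_map, speech_dim, "speech_map")
  check_map(eeg_map, eeg_dim, "eeg_map")
  structure(list(latent_dim = latent_dim, anchor_HC = anchor_HC,
                 anchor_AD = anchor_AD, mci_position = mci_position,
                 speech_dim = speech_dim, eeg_dim = eeg_dim,
                 speech_map = speech_map, eeg_map = eeg_map,
                 noise_sd = noise_sd, n_per_class = n_per_class, seed = seed),
            class = "continuum_spec")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

affine_apply <- function(map, Z) {
  sweep(Z %*% map$A, 2, map$b, "+")
}

#' Generate a synthetic speech/EEG feature cohort on a latent continuum
#'
#' Speech features are drawn for all three classes around the affine images
#' of the HC, MCI and AD anchors; EEG features are drawn for AD and HC only.
#' The MCI anchor is `anchor_HC + mci_position * (anchor_AD - anchor_HC)`.
#'
#' @param spec A [continuum_spec()].
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `speech` (n = 3 * n_per_class rows), `eeg` (2 * n_per_class rows, labels
#'   AD/HC only) and `latents` (the generating latent positions).
#' @export
generate_continuum_cohort <- function(spec) {
  stopifnot(inherits(spec, "continuum_spec"))
  n <- spec$n_per_class
  anchor_MCI <- spec$anchor_HC + spec$mci_position * (spec$anchor_AD - spec$anchor_HC)
  anchors <- rbind(AD = spec$anchor_AD, HC = spec$anchor_HC, MCI = anchor_MCI)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed)

  # latent positions: each subject sits exactly at its class anchor; all
  # within-class variation is modality noise (keeps the zero-noise geometry
  # exact and the class-mean targets closed-form)
  classes_speech <- rep(c("AD", "HC", "MCI"), each = n)
  Z_speech <- anchors[classes_speech, , drop = FALSE]
  classes_eeg <- rep(c("AD", "HC"), each = n)
  Z_eeg <- anchors[classes_eeg, , drop = FALSE]

  noise <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  Xs <- affine_apply(spec$speech_map, Z_speech) +
    noise(nrow(Z_speech), spec$speech_dim, spec$noise_sd[["speech"]])
  Xe <- affine_apply(spec$eeg_map, Z_eeg) +
    noise(nrow(Z_eeg), spec$eeg_dim, spec$noise_sd[["eeg"]])

  colnames(Xs) <- paste0("s", seq_len(spec$speech_dim))
  colnames(Xe) <- paste0("e", seq_len(spec$eeg_dim))
  speech <- dplyr::bind_cols(
    tibble::tibble(subject_id = paste0("sp", seq_len(nrow(Xs))),
                   label = classes_speech, modality = "speech"),
    tibble::as_tibble(Xs))
  eeg <- dplyr::bind_cols(
    tibble::tibble(subject_id = paste0("ee", seq_len(nrow(Xe))),
                   label = classes_eeg, modality = "eeg"),
    tibble::as_tibble(Xe))
  latents <- dplyr::bind_cols(
    tibble::tibble(subject_id = c(speech$subject_id, eeg$subject_id),
                   label = c(classes_speech, classes_eeg),
                   modality = c(rep("speech", nrow(Xs)), rep("eeg", nrow(Xe)))),
    tibble::as_tibble(rbind(Z_speech, Z_eeg), .name_repair = ~ paste0("z", seq_len(spec$latent_dim))))
  stopifnot(!any(eeg$label == "MCI"))
  structure(list(speech = speech, eeg = eeg, latents = latents, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d speech rows (AD/HC/MCI), %d EEG rows (AD/HC), latent_dim %d, noise_sd %s\n",
              nrow(x$speech), nrow(x$eeg), x$spec$latent_dim,
              paste(format(x$spec$noise_sd), collapse = "/")))
  invisible(x)
}

#' Band power profile for synthetic EEG
#'
#' Per-band carrier amplitudes for the five clinical rhythms.  The AD-like
#' profile elevates delta/theta and suppresses alpha relative to the HC-like
#' profile, reproducing the low-frequency power enhancement and
#' high-frequency suppression that characterises the patient group.
#'
#' @param group `"AD"` or `"HC"`, or `NULL` to pass explicit amplitudes.
#' @param amplitudes Optional named numeric vector
#'   (delta, theta, alpha, beta, gamma), all nonnegative.
#' @param noise_sd SD of additive white noise (same units as amplitudes).
#' @return An object of class `band_power_profile`.
#' @export
band_power_profile <- function(group = c("AD", "HC"), amplitudes = NULL,
                               noise_sd = 0.5) {
  if (is.null(amplitudes)) {
    group <- match.arg(group)
    amplitudes <- switch(group,
      AD = c(delta = 9, theta = 7, alpha = 2, beta = 2, gamma = 1),
      HC = c(delta = 4, theta = 4, alpha = 7, beta = 3, gamma = 1.5))
  } else {
    group <- if (!is.null(group) && length(group) == 1) group else "custom"
    amplitudes <- amplitudes[c("delta", "theta", "alpha", "beta", "gamma")]
    if (anyNA(amplitudes)) stop("amplitudes must name all five bands", call. = FALSE)
  }
  if (any(amplitudes < 0) || !any(amplitudes > 0)) {
    stop("amplitudes must be nonnegative with at least one positive", call. = FALSE)
  }
  structure(list(group = group, amplitudes = amplitudes, noise_sd = noise_sd),
            class = "band_power_profile")
}

# carrier frequency per band (Hz): representative centre frequencies of the
# five rhythms, fixed so band attribution of each carrier is unambiguous
.band_carriers <- c(delta = 2, theta = 6, alpha = 10, beta = 15, gamma = 25)

#' Generate a band-structured multichannel EEG signal
#'
#' Each channel is a sum of five band-limited sinusoidal carriers (one per
#' rhythm, amplitude from the profile, independent uniform random phase per
#' channel per band) plus white Gaussian noise.  Deterministic under `seed`;
#' per-channel random draws use a counter-based sub-seed so increasing
#' `n_channels` never perturbs earlier channels.
#'
#' @param profile A [band_power_profile()].
#' @param n_channels Number of channels (default 19).
#' @param fs Sampling rate in Hz (default 500); must exceed twice the highest
#'   carrier frequency.
#' @param duration Length in seconds (minimum 4).
#' @param seed Integer seed.
#' @param subject_id,label Passed through to the recording.
#' @return An [eeg_recording()].
#' @export
generate_band_structured_eeg <- function(profile, n_channels = 19, fs = 500,
                                         duration = 8, seed = 1,
                                         subject_id = NA_character_,
                                         label = NA_character_) {
  stopifnot(inherits(profile, "band_power_profile"))
  if (fs <= 2 * max(.band_carriers)) {
    stop("fs must exceed twice the highest carrier frequency", call. = FALSE)
  }
  if (duration < 4) {
    stop("duration must be at least 4 s to resolve the lowest band", call. = FALSE)
  }
  n <- round(fs * duration)
  tt <- seq_len(n) / fs
  amps <- profile$amplitudes
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  X <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    set.seed((seed * 1009L + ch) %% .Machine$integer.max)
    phases <- stats::runif(length(amps), 0, 2 * pi)
    sig <- rep(0, n)
    for (b in seq_along(amps)) {
      sig <- sig + amps[b] * sin(2 * pi * .band_carriers[b] * tt + phases[b])
    }
    if (profile$noise_sd > 0) sig <- sig + stats::rnorm(n, sd = profile$noise_sd)
    X[ch, ] <- sig
  }
  chn <- if (n_channels == 19) eeg_channels_1020() else paste0("ch", seq_len(n_channels))
  eeg_recording(X, fs, chn, subject_id = subject_id, label = label)
}
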