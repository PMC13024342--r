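# Frequency-domain descriptors: Welch PSD, relative band powers, band
# ratios, median frequency, normalized spectral entropy.

#' Welch power spectral density
#'
#' Mean-removed Hann-windowed segments (default 2 s, 50% overlap), one-sided
#' density scaling.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_seconds Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window `"hann"` (default) or `"rect"`; with a rectangular window
#'   and a single full-length segment the estimator reduces exactly to the
#'   periodogram.
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5,
                      window = c("hann", "rect")) {
  window <- match.arg(window)
  nper <- min(length(x), round(seg_seconds * fs))
  if (nper < 8) stop("signal too short for PSD estimation", call. = FALSE)
  step <- max(1, round(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  } else rep(1, nper)
  norm <- fs * sum(w^2)
  nfreq <- nper %/% 2 + 1
  acc <- rep(0, nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / norm
    # one-sided: double everything except DC (and Nyquist when nper even)
    sp[-1] <- sp[-1] * 2
    if (nper %% 2 == 0) sp[nfreq] <- sp[nfreq] / 2
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = acc / length(starts))
}

#' Band power by rectangular bin integration
#'
#' Sums the PSD bins with `lo <= f < hi` times the bin width.
#'
#' @param freq Frequency vector (Hz, uniform spacing).
#' @param psd PSD values aligned with `freq`.
#' @param lo,hi Band edges in Hz (half-open interval).
#' @return Scalar band power.
#' @export
band_power <- function(freq, psd, lo, hi) {
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Median frequency of a PSD
#'
#' The smallest frequency in `[lo, hi)` at which the cumulative PSD reaches
#' half the total over that range.
#'
#' @inheritParams band_power
#' @return Scalar frequency in Hz.
#' @export
median_frequency <- function(freq, psd, lo, hi) {
  keep <- freq >= lo & freq < hi
  f <- freq[keep]; p <- psd[keep]
  cum <- cumsum(p)
  if (cum[length(cum)] <= 0) return(NA_real_)
  f[which(cum >= cum[length(cum)] / 2)[1]]
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the normalized PSD bin distribution divided by the
#' theoretical maximum `log(K)` for `K` bins; base-invariant, in \[0, 1\].
#'
#' @param psd_bins Nonnegative numeric vector of PSD values (at least 2 bins).
#' @return Scalar in \[0, 1\].
#' @export
spectral_entropy <- function(psd_bins) {
  if (length(psd_bins) < 2) stop("need at least 2 PSD bins", call. = FALSE)
  if (any(psd_bins < 0)) stop("PSD bins must be nonnegative", call. = FALSE)
  tot <- sum(psd_bins)
  if (tot <= 0) stop("all-zero PSD: spectral entropy undefined", call. = FALSE)
  p <- psd_bins / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(psd_bins))
}

#' Frequency-domain features
#'
#' Ten descriptors per channel: relative power in each of the five bands
#' (band power over the summed five-band power), the theta/alpha and
#' delta/alpha absolute-power ratios, the (delta+theta)/(alpha+beta)
#' low-to-high energy ratio, the median frequency (smallest frequency at
#' which the cumulative PSD over the analyzed range reaches half its total),
#' and the normalized spectral entropy of the analyzed range.  With 19
#' channels the vector has length 190.
#'
#' The analyzed range is 0.5 Hz to the gamma upper edge capped at Nyquist.
#' Zero denominators in ratios are guarded with a small epsilon and flagged
#' with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param bands A band set from [eeg_band_set()].
#' @param seg_seconds Welch segment length in seconds.
#' @return A one-row tibble of named features plus `subject_id`.
#' @export
frequency_domain_features <- function(rec, bands = eeg_band_set(),
                                      seg_seconds = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  hi_edge <- min(bands$gamma[2], nyq)
  lo_edge <- bands$delta[1]
  band_lims <- lapply(bands, function(b) c(b[1], min(b[2], hi_edge)))
  eps <- 1e-12
  warned <- FALSE
  per_channel <- function(x) {
    ps <- welch_psd(x, rec$fs, seg_seconds)
    keep <- ps$freq >= lo_edge & ps$freq < hi_edge
    f <- ps$freq[keep]; p <- ps$psd[keep]
    bp <- vapply(band_lims, function(b) band_power(ps$freq, ps$psd, b[1], b[2]),
                 numeric(1))
    tot <- sum(bp)
    if (tot <= 0) { warned <<- TRUE; tot <- eps }
    rel <- bp / tot
    safe_ratio <- function(num, den) {
      if (den <= 0) { warned <<- TRUE; den <- eps }
      num / den
    }
    ratios <- c(
      theta_alpha = safe_ratio(bp["theta"], bp["alpha"]),
      delta_alpha = safe_ratio(bp["delta"], bp["alpha"]),
      low_high = safe_ratio(bp["delta"] + bp["theta"], bp["alpha"] + bp["beta"]))
    medf <- median_frequency(ps$freq, ps$psd, lo_edge, hi_edge)
    se <- if (sum(p) > 0) spectral_entropy(p) else 0
    c(stats::setNames(rel, paste0("relpow_", names(bands))),
      stats::setNames(as.numeric(ratios), c("ratio_theta_alpha", "ratio_delta_alpha",
                                            "ratio_low_high")),
      medfreq = as.numeric(medf), spec_entropy = se)
  }
  S <- apply(rec$data, 1, per_channel)   # 10 x C
  if (warned) warning("zero band power encountered; epsilon guard applied")
  vals <- as.numeric(t(S))
  nms <- as.vector(outer(rec$channel_names, rownames(S),
                         function(ch, st) paste(st, ch, sep = "_")))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nms)))
  dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id), out)
}
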