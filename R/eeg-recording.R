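#' Standard 10-20 channel labels
#'
#' The 19-electrode montage used by resting-state clinical EEG recordings
#' (Fp1 ... O2), in canonical order.
#'
#' @return Character vector of 19 channel names.
#' @export
eeg_channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Multichannel EEG recording container
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param subject_id Optional subject identifier.
#' @param label Optional diagnostic label, `"AD"` or `"HC"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          subject_id = NA_character_, label = NA_character_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("EEG data must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 19) eeg_channels_1020()
                     else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("channel count does not match channel-name count", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c("AD", "HC")) {
    stop("label must be 'AD' or 'HC' (or NA)", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' The five clinical rhythm bands.  Intervals are half-open `[lo, hi)`;
#' the gamma upper edge is capped at the Nyquist frequency at analysis time.
#'
#' @param gamma_high Upper gamma edge in Hz (default 100).
#' @return A named list of `c(lo, hi)` pairs in Hz.
#' @export
eeg_band_set <- function(gamma_high = 100) {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, gamma_high))
}

#' Default region-of-interest map for the 10-20 montage
#'
#' Assigns each of the 19 standard electrodes to one of five scalp regions.
#'
#' @return Named character vector: channel name -> region.
#' @export
eeg_roi_map <- function() {
  c(Fp1 = "Frontal", Fp2 = "Frontal", F7 = "Frontal", F3 = "Frontal",
    Fz = "Frontal", F4 = "Frontal", F8 = "Frontal",
    C3 = "Central", Cz = "Central", C4 = "Central",
    T3 = "Temporal", T4 = "Temporal", T5 = "Temporal", T6 = "Temporal",
    P3 = "Parietal", Pz = "Parietal", P4 = "Parietal",
    O1 = "Occipital", O2 = "Occipital")
}

# internal: coerce a feature table (tibble/data.frame) into its numeric
# feature matrix plus metadata columns.  Metadata columns are subject_id,
# label, modality when present; everything else must be numeric.
feature_matrix <- function(table) {
  meta_cols <- intersect(c("subject_id", "label", "modality"), names(table))
  feat <- table[setdiff(names(table), meta_cols)]
  bad <- !vapply(feat, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric feature columns: ", paste(names(feat)[bad], collapse = ", "),
         call. = FALSE)
  }
  list(X = as.matrix(feat), meta = table[meta_cols], feature_names = names(feat))
}
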