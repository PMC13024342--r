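# Phase lag index connectivity in the alpha band and ROI aggregation.

# analytic signal via the FFT method
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase lag index matrix
#'
#' Band-pass filters each channel with a zero-phase FIR filter (order about
#' `3 * fs / f_low`), takes the instantaneous phase from the analytic
#' signal, and computes `|mean(sign(sin(phase_i - phase_j)))|` for every
#' channel pair, after discarding one filter length at each edge.  The
#' result is symmetric with zero diagonal and entries in \[0, 1\];
#' identically zero phase difference (e.g. duplicated channels) gives 0.
#'
#' @param rec An [eeg_recording()].
#' @param band Length-2 numeric, pass band in Hz (default alpha, 8-13).
#' @return `n_channels x n_channels` symmetric matrix.
#' @export
pli_matrix <- function(rec, band = c(8, 13)) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (band[2] >= nyq || band[1] <= 0) {
    stop("band must lie strictly within (0, Nyquist)", call. = FALSE)
  }
  ord <- round(3 * rec$fs / band[1])
  ord <- ord + ord %% 2            # even order -> odd-length symmetric FIR
  if (ncol(rec$data) <= 3 * ord) {
    stop("recording shorter than the filter transient", call. = FALSE)
  }
  fir <- as.numeric(signal::fir1(ord, band / nyq, type = "pass"))
  C <- nrow(rec$data)
  phases <- matrix(0, C, ncol(rec$data))
  for (ch in seq_len(C)) {
    xf <- signal::filtfilt(fir, 1, rec$data[ch, ])
    phases[ch, ] <- Arg(analytic_signal(xf))
  }
  keep <- (ord + 1):(ncol(phases) - ord)
  P <- matrix(0, C, C, dimnames = list(rec$channel_names, rec$channel_names))
  for (i in seq_len(C - 1)) {
    for (j in (i + 1):C) {
      dphi <- phases[i, keep] - phases[j, keep]
      P[i, j] <- P[j, i] <- abs(mean(sign(sin(dphi))))
    }
  }
  P
}

#' ROI-to-ROI connectivity features
#'
#' Mean PLI over all electrode pairs between two regions of interest, one
#' value per unordered region pair in a fixed canonical order
#' (Frontal, Central, Temporal, Parietal, Occipital) -- 10 values for the
#' default 5-region map.
#'
#' @param pli Symmetric PLI matrix with channel names as dimnames.
#' @param roi_map Named character vector channel -> region
#'   (default [eeg_roi_map()]).
#' @param subject_id Carried through to the output.
#' @return A one-row tibble of named features plus `subject_id`.
#' @export
roi_connectivity <- function(pli, roi_map = eeg_roi_map(),
                             subject_id = NA_character_) {
  chans <- rownames(pli)
  if (is.null(chans)) stop("PLI matrix needs channel dimnames", call. = FALSE)
  if (!all(chans %in% names(roi_map))) {
    stop("unmapped channels: ",
         paste(setdiff(chans, names(roi_map)), collapse = ", "), call. = FALSE)
  }
  regions <- c("Frontal", "Central", "Temporal", "Parietal", "Occipital")
  regions <- regions[regions %in% roi_map[chans]]
  groups <- split(chans, factor(roi_map[chans], levels = regions))
  if (any(lengths(groups) == 0)) stop("region with zero channels", call. = FALSE)
  pairs <- utils::combn(regions, 2)
  vals <- apply(pairs, 2, function(pr) {
    mean(pli[groups[[pr[1]]], groups[[pr[2]]], drop = FALSE])
  })
  nms <- apply(pairs, 2, function(pr) paste0("pli_", pr[1], "_", pr[2]))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nms)))
  dplyr::bind_cols(tibble::tibble(subject_id = subject_id), out)
}
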