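#' Fit a z-score standardizer on training rows
#'
#' Computes per-feature mean and SD from the supplied (training) table only;
#' the fitted object can then be applied to held-out rows with `predict()`.
#' Zero-variance features are guarded with a small epsilon and flagged with
#' a warning.
#'
#' @param table Feature table (data frame / tibble); non-feature columns
#'   `subject_id`, `label`, `modality` are passed through untouched.
#' @param eps Guard for zero SDs.
#' @return An object of class `feature_standardizer`.
#' @export
fit_standardizer <- function(table, eps = 1e-8) {
  fm <- feature_matrix(table)
  if (nrow(fm$X) < 2) stop("need at least 2 training rows", call. = FALSE)
  mu <- colMeans(fm$X)
  sd <- apply(fm$X, 2, stats::sd)
  if (any(sd <= 0)) {
    warning("zero-variance features standardized with epsilon guard")
    sd[sd <= 0] <- eps
  }
  structure(list(mean = mu, sd = sd, feature_names = fm$feature_names),
            class = "feature_standardizer")
}

#' Apply a fitted standardizer
#'
#' @param object A `feature_standardizer`.
#' @param newdata Feature table with the same feature columns.
#' @param ... Unused.
#' @return The table with features replaced by `(x - mean) / sd` using the
#'   training statistics.
#' @export
predict.feature_standardizer <- function(object, newdata, ...) {
  fm <- feature_matrix(newdata)
  if (!identical(fm$feature_names, object$feature_names)) {
    stop("feature columns do not match the fitted standardizer", call. = FALSE)
  }
  Z <- sweep(sweep(fm$X, 2, object$mean), 2, object$sd, "/")
  dplyr::bind_cols(fm$meta, tibble::as_tibble(Z))
}

#' Standardize a table using its own (or training) statistics
#'
#' Convenience wrapper: fits on `stats_from` (default the table itself) and
#' applies to `table`.
#'
#' @param table Feature table to transform.
#' @param stats_from Table supplying the statistics (default `table`).
#' @return Standardized tibble with metadata columns preserved.
#' @export
standardize_features <- function(table, stats_from = table) {
  predict(fit_standardizer(stats_from), table)
}

#' Extract the full handcrafted EEG feature set
#'
#' Runs the time-domain, frequency-domain, wavelet, multiscale-entropy and
#' ROI-connectivity extractors on one or more recordings and binds the
#' results into one row per subject.
#'
#' @param recs An [eeg_recording()] or a list of them.
#' @param domains Character subset of
#'   `c("time", "freq", "dwt", "mse", "pli")`.
#' @param mse_scales Scales for the multiscale entropy block.
#' @return A tibble, one row per recording.
#' @export
extract_eeg_features <- function(recs,
                                 domains = c("time", "freq", "dwt", "mse", "pli"),
                                 mse_scales = 1:20) {
  if (inherits(recs, "eeg_recording")) recs <- list(recs)
  domains <- match.arg(domains, several.ok = TRUE)
  one <- function(rec) {
    parts <- list(tibble::tibble(subject_id = rec$subject_id,
                                 label = rec$label))
    if ("time" %in% domains) parts <- c(parts, list(time_domain_features(rec)[-1]))
    if ("freq" %in% domains) parts <- c(parts, list(frequency_domain_features(rec)[-1]))
    if ("dwt" %in% domains) parts <- c(parts, list(dwt_features(rec)[-1]))
    if ("mse" %in% domains) parts <- c(parts, list(multiscale_entropy(rec, scales = mse_scales)[-1]))
    if ("pli" %in% domains) {
      parts <- c(parts, list(roi_connectivity(pli_matrix(rec), subject_id = rec$subject_id)[-1]))
    }
    dplyr::bind_cols(parts)
  }
  dplyr::bind_rows(lapply(recs, one))
}
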