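# Readers for the supported on-disk formats: labelled CSV feature tables,
# numeric matrices with a JSON sidecar, and EDF recordings.

#' Read a labelled feature table from CSV
#'
#' Expects a header with `subject_id` and `label` columns plus numeric
#' feature columns.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df))) {
    stop("CSV must contain subject_id and label columns", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a feature table to CSV
#'
#' @param table Tibble/data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG matrix from CSV with a JSON sidecar
#'
#' The CSV holds the channels x samples matrix (no header); the sidecar
#' `<path>.json` supplies `fs` and optionally `channel_names`,
#' `subject_id`, `label`.
#'
#' @param path CSV path.
#' @param sidecar JSON path (default `paste0(path, ".json")`).
#' @return An [eeg_recording()].
#' @export
read_eeg_matrix <- function(path, sidecar = paste0(path, ".json")) {
  X <- as.matrix(utils::read.csv(path, header = FALSE))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar must supply fs", call. = FALSE)
  eeg_recording(X, fs = meta$fs,
                channel_names = meta$channel_names,
                subject_id = meta$subject_id %||% NA_character_,
                label = meta$label %||% NA_character_)
}

#' Read an EDF recording
#'
#' Minimal reader for uncompressed EDF (16-bit little-endian samples, one
#' continuous record sequence); supports channel selection by name and
#' applies the per-channel physical calibration.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep
#'   (default all non-annotation channels).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr(8)
  patient <- hdr(80); recording <- hdr(80)
  startdate <- hdr(8); starttime <- hdr(8)
  n_header <- as.integer(hdr(8))
  hdr(44)  # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  fld <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)  # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)  # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)  # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  keep <- if (is.null(channels)) {
    which(!grepl("annotation", labels, ignore.case = TRUE))
  } else {
    m <- match(channels, labels)
    if (anyNA(m)) stop("channels not found: ",
                       paste(channels[is.na(m)], collapse = ", "), call. = FALSE)
    m
  }
  out <- lapply(keep, function(i) vector("list", n_records))
  names(out) <- labels[keep]
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2, endian = "little")
      ki <- match(i, keep)
      if (!is.na(ki)) out[[ki]][[r]] <- raw * gain[i] + offset[i]
    }
  }
  X <- do.call(rbind, lapply(out, function(ch) unlist(ch, use.names = FALSE)))
  fs <- nsamp[keep[1]] / record_dur
  eeg_recording(X, fs = fs, channel_names = labels[keep],
                subject_id = patient)
}
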