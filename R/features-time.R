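#' Time-domain statistical features
#'
#' Seven per-channel statistics (mean, peak, variance, standard deviation,
#' skewness, kurtosis, root mean square) stacked feature-major: all means
#' first, then all peaks, and so on.  With 19 channels the vector has length
#' 133.
#'
#' Conventions: peak is the maximum absolute amplitude; variance and SD are
#' population (denominator n); skewness is the standardized third moment and
#' kurtosis the excess fourth moment, both defined as 0 for a constant
#' channel.
#'
#' @param rec An [eeg_recording()].
#' @return A one-row tibble of named features, plus `subject_id`.
#' @export
time_domain_features <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 2) stop("need at least 2 samples per channel", call. = FALSE)
  stats7 <- function(x) {
    m <- mean(x)
    v <- mean((x - m)^2)
    s <- sqrt(v)
    if (s > 0) {
      sk <- mean((x - m)^3) / s^3
      ku <- mean((x - m)^4) / s^4 - 3
    } else {
      sk <- 0; ku <- 0
    }
    c(mean = m, peak = max(abs(x)), var = v, sd = s,
      skew = sk, kurt = ku, rms = sqrt(mean(x^2)))
  }
  S <- apply(rec$data, 1, stats7)       # 7 x C
  vals <- as.numeric(t(S))              # feature-major: all means, all peaks, ...
  nms <- as.vector(outer(rec$channel_names, rownames(S),
                         function(ch, st) paste(st, ch, sep = "_")))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nms)))
  dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id), out)
}
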