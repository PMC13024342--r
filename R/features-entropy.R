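# Multiscale sample entropy.

#' Coarse-grain a series
#'
#' Replaces non-overlapping windows of length `tau` by their arithmetic
#' mean; output length is `floor(length(x) / tau)`.
#'
#' @param x Numeric vector.
#' @param tau Positive integer scale factor, at most `length(x)`.
#' @return Numeric vector of length `floor(length(x)/tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be >= 1", call. = FALSE)
  if (tau > length(x)) stop("tau exceeds series length", call. = FALSE)
  if (tau == 1) return(x)
  m <- length(x) %/% tau
  colMeans(matrix(x[seq_len(m * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts unordered pairs of length-`m` templates
#' within Chebyshev distance strictly less than `r`, and `A` counts the
#' same pairs after extending both templates by one point.  Self-matches
#' are excluded; templates are the `N - m` windows that admit an
#' extension.
#'
#' @param x Numeric vector of length at least `m + 2`.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance (absolute units; must be positive).
#' @return Nonnegative scalar, or an error when `A` or `B` is zero (e.g. a
#'   constant series collapses the tolerance).
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (length(x) < m + 2) stop("series too short for embedding", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    stop("degenerate series: no template matches within tolerance (A=",
         A, ", B=", B, ")", call. = FALSE)
  }
  -log(A / B)
}

#' Multiscale sample entropy features
#'
#' For each channel, the series is coarse-grained at every scale in
#' `scales` and sample entropy is computed on each coarse-grained series.
#' The tolerance is fixed per channel as `r_factor` times the population SD
#' of the original (scale-1) channel.  Features are concatenated
#' channel-major: all scales of channel 1, then channel 2, ...  With 19
#' channels and scales 1..20 the vector has length 380.
#'
#' @param rec An [eeg_recording()].
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance multiplier on the channel SD (default 0.15).
#' @param scales Integer scales (default 1:20).
#' @param on_degenerate `"fail"` to error on a degenerate scale, or
#'   `"sentinel"` to record `NA` there and continue (with a warning).
#' @return A one-row tibble of named features plus `subject_id`.
#' @export
multiscale_entropy <- function(rec, m = 2, r_factor = 0.15, scales = 1:20,
                               on_degenerate = c("fail", "sentinel")) {
  stopifnot(inherits(rec, "eeg_recording"))
  on_degenerate <- match.arg(on_degenerate)
  if (length(scales) == 0 || min(scales) < 1) stop("scales must be >= 1", call. = FALSE)
  if (ncol(rec$data) < max(scales) * (m + 2)) {
    stop("channel too short for the largest scale", call. = FALSE)
  }
  degen <- FALSE
  per_channel <- function(x) {
    r <- r_factor * sqrt(mean((x - mean(x))^2))
    vapply(scales, function(tau) {
      y <- coarse_grain(x, tau)
      val <- tryCatch(sample_entropy(y, m, r), error = function(e) NA_real_)
      if (is.na(val)) {
        if (on_degenerate == "fail") {
          stop("degenerate coarse-grained series at scale ", tau, call. = FALSE)
        }
        degen <<- TRUE
      }
      val
    }, numeric(1))
  }
  S <- apply(rec$data, 1, per_channel)   # n_scales x C
  if (degen) warning("degenerate scales recorded as NA")
  vals <- as.numeric(S)                  # channel-major
  nms <- as.vector(vapply(rec$channel_names, function(ch)
    paste0("mse_scale", scales, "_", ch), character(length(scales))))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nms)))
  dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id), out)
}
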