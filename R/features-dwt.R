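# Discrete wavelet transform sub-band features (db4, 5 levels, periodized).
#
# The decomposition is the orthonormal pyramid with circular (periodized)
# boundary handling, so the sub-band energies sum exactly to the signal
# energy -- the property the test suite asserts.  Daubechies-4 analysis taps:
.db4_lo <- c(-0.01059740178499728, 0.032883011666982945, 0.030841381835986965,
             -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
             0.7148465705525415, 0.23037781330885523)
.db4_hi <- c(-0.23037781330885523, 0.7148465705525415, -0.6308807679295904,
             -0.02798376941698385, 0.18703481171888114, 0.030841381835986965,
             -0.032883011666982945, -0.01059740178499728)

# one analysis step: circular correlation with taps h, downsample by 2
.dwt_step <- function(x, h) {
  N <- length(x)
  if (N %% 2 == 1) { x <- c(x, x[1]); N <- N + 1 }  # periodic pad to even
  L <- length(h)
  M <- N %/% 2
  out <- numeric(M)
  # vectorized circular correlation at even shifts
  for (n in seq_len(L)) {
    idx <- ((2 * seq_len(M) - 2 + n - 1) %% N) + 1
    out <- out + h[n] * x[idx]
  }
  out
}

#' Periodized db4 wavelet decomposition
#'
#' @param x Numeric vector (length at least `2^levels`).
#' @param levels Number of decomposition levels (default 5).
#' @return Named list of coefficient vectors `A<levels>`, `D<levels>` ... `D1`.
#' @export
dwt_db4 <- function(x, levels = 5) {
  if (length(x) < 2^levels) {
    stop("signal too short for ", levels, "-level decomposition", call. = FALSE)
  }
  a <- x
  details <- list()
  for (lev in seq_len(levels)) {
    details[[paste0("D", lev)]] <- .dwt_step(a, .db4_hi)
    a <- .dwt_step(a, .db4_lo)
  }
  c(stats::setNames(list(a), paste0("A", levels)), rev(details))
}

# Shannon entropy (natural log) of the normalized squared-coefficient
# distribution; 0 * log 0 = 0, all-zero sub-band -> 0 by convention.
.coef_entropy <- function(cf) {
  e <- cf^2
  tot <- sum(e)
  if (tot <= 0) return(0)
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' DWT sub-band features
#'
#' Per channel and per sub-band (A5, D5, D4, D3, D2, D1): energy (sum of
#' squared coefficients), population standard deviation of the coefficients,
#' and Shannon entropy of the normalized squared-coefficient distribution --
#' 18 values per channel, length 342 for 19 channels.
#'
#' @param rec An [eeg_recording()].
#' @param levels Decomposition depth (default 5).
#' @return A one-row tibble of named features plus `subject_id`.
#' @export
dwt_features <- function(rec, levels = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  band_order <- c(paste0("A", levels), paste0("D", levels:1))
  per_channel <- function(x) {
    cf <- dwt_db4(x, levels)
    unlist(lapply(band_order, function(nm) {
      v <- cf[[nm]]
      c(energy = sum(v^2),
        sd = sqrt(mean((v - mean(v))^2)),
        entropy = .coef_entropy(v))
    }))
  }
  S <- apply(rec$data, 1, per_channel)  # 18 x C
  rownames(S) <- as.vector(vapply(band_order, function(nm)
    paste0(c("energy_", "sd_", "entropy_"), nm), character(3)))
  vals <- as.numeric(t(S))
  nms <- as.vector(outer(rec$channel_names, rownames(S),
                         function(ch, st) paste(st, ch, sep = "_")))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, nms)))
  dplyr::bind_cols(tibble::tibble(subject_id = rec$subject_id), out)
}
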