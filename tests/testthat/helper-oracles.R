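# Independent brute-force oracles and small fixtures used across tests.

# naive O(N^2) sample-entropy pair counter, written directly from the
# definition (strict Chebyshev inequality, self-matches excluded)
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      db <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (db < r) {
        B <- B + 1
        if (max(db, abs(x[i + m] - x[j + m])) < r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# plain periodogram band power oracle: direct |FFT|^2 bin sums over [lo, hi)
periodogram_band_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  P <- abs(fft(x))^2 / (n * fs)
  nf <- n %/% 2 + 1
  P <- P[seq_len(nf)]
  P[-1] <- 2 * P[-1]
  if (n %% 2 == 0) P[nf] <- P[nf] / 2
  f <- (seq_len(nf) - 1) * fs / n
  sum(P[f >= lo & f < hi]) * fs / n
}

# periodogram median frequency oracle over [lo, hi)
medfreq_oracle <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  P <- abs(fft(x))^2
  nf <- n %/% 2 + 1
  P <- P[seq_len(nf)]
  f <- (seq_len(nf) - 1) * fs / n
  keep <- f >= lo & f < hi
  f <- f[keep]; P <- P[keep]
  f[which(cumsum(P) >= sum(P) / 2)[1]]
}

# small, fast cohort used by most model tests
tiny_cohort <- function(n = 40, seed = 7, noise_sd = 0.3,
                        speech_dim = 24, eeg_dim = 12) {
  generate_continuum_cohort(continuum_spec(
    n_per_class = n, speech_dim = speech_dim, eeg_dim = eeg_dim,
    noise_sd = noise_sd, seed = seed))
}

# small alignment config for fast tests
tiny_alignment_config <- function(epochs = 40, seed = 3, ...) {
  alignment_config(subspace_dim = 16, speech_hidden = 32, epochs = epochs,
                   seed = seed, ...)
}

tiny_flow_config <- function(epochs = 60, seed = 4, ...) {
  flow_config(hidden = 64, n_blocks = 2, epochs = epochs, seed = seed, ...)
}

tiny_fusion_config <- function(epochs = 40, seed = 6, ...) {
  fusion_config(branch_dim = 16, mlp_hidden = 16, epochs = epochs,
                seed = seed, ...)
}
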