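# Independent oracles used across the test suite.

# Simple local-maximum beat detector: candidate peaks above half a robust
# beat-height estimate (median of per-second maxima, so isolated large
# amplitude excursions cannot mask ordinary beats), greedily accepted with
# a refractory period (seconds).
detect_peaks <- function(x, fs, refractory = 0.4) {
  sec <- floor((seq_along(x) - 1) / fs)
  thr <- 0.5 * stats::median(tapply(x, sec, max))
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[x[cand] >= x[cand - 1] & x[cand] >= x[cand + 1]]
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- refractory * fs
  for (p in cand) {
    if (all(abs(keep - p) >= min_gap)) keep <- c(keep, p)
  }
  sort(keep)
}

# Per-beat J-peak amplitude coefficient of variation of one recording.
beat_amplitude_cv <- function(rec) {
  pk <- detect_peaks(rec$samples, rec$fs)
  amps <- rec$samples[pk]
  stats::sd(amps) / mean(amps)
}

# Brute-force time-domain CWT oracle.
#
# The analytic wavelet at each scale is obtained by fine trapezoidal
# quadrature of the continuous inverse Fourier integral of the Morse
# response (truncated at Nyquist), explicitly wrapped to the signal's
# circular period; coefficients are then a direct O(n^2) circular
# convolution. Valid for center frequencies far from both the Nyquist
# cutoff and the record length, where spectral truncation and wrap
# residuals are negligible.
cwt_oracle <- function(x, bank, oversample = 64, wraps = 4) {
  n <- length(x)
  fs <- bank$fs
  x <- x - mean(x)
  n_scales <- length(bank$scales)
  out <- matrix(0, n_scales, n)
  omega_max <- pi * fs
  n_q <- n * oversample
  omega <- seq(0, omega_max, length.out = n_q + 1)
  d_omega <- omega[2] - omega[1]
  period <- n / fs
  for (j in seq_len(n_scales)) {
    psi_om <- morse_psi(bank$scales[j] * omega, bank$params)
    h <- vapply(seq_len(n) - 1, function(m) {
      tot <- 0 + 0i
      for (r in -wraps:wraps) {
        tau <- m / fs + r * period
        ker <- psi_om * exp(1i * omega * tau)
        # trapezoid rule
        tot <- tot + (sum(ker) - 0.5 * (ker[1] + ker[n_q + 1])) * d_omega
      }
      tot / (2 * pi * fs)
    }, complex(1))
    w <- vapply(seq_len(n) - 1, function(m) {
      sum(x * h[((m - (seq_len(n) - 1)) %% n) + 1])
    }, complex(1))
    out[j, ] <- Mod(w)
  }
  out
}

# small deterministic synthetic image set for classifier plumbing tests:
# two trivially separable texture classes
toy_images <- function(n_per_class, seed = 1) {
  withr::with_seed(seed, {
    mk <- function(bright) {
      base <- matrix(stats::runif(1024, 0, 60), 32, 32)
      if (bright) base[8:24, 8:24] <- base[8:24, 8:24] + 150
      as.vector(base)
    }
    x <- rbind(
      t(vapply(seq_len(n_per_class), function(i) mk(FALSE), numeric(1024))),
      t(vapply(seq_len(n_per_class), function(i) mk(TRUE), numeric(1024)))
    )
    list(images = x,
         labels = rep(c("HC", "HPT"), each = n_per_class))
  })
}
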