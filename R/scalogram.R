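#' Generalized Morse wavelet parameters
#'
#' The analytic generalized Morse family is parameterized by the shape
#' \eqn{\gamma} and the time-bandwidth product \eqn{P^2}; the decay exponent
#' is \eqn{\beta = P^2 / \gamma}. The defaults (3, 60) give a symmetric,
#' nearly Gaussian envelope well suited to cardiac time-frequency analysis.
#'
#' @param gamma Shape parameter, > 0.
#' @param p2 Time-bandwidth product \eqn{P^2}, must exceed `gamma` so that
#'   \eqn{\beta > 1} and the wavelet has zero mean.
#' @param voices Voices per octave (scales per frequency doubling), integer
#'   >= 1.
#' @return Object of class `morse_params` with fields `gamma`, `p2`, `beta`,
#'   `voices` and the peak angular frequency `omega_p = (beta/gamma)^(1/gamma)`.
#' @export
morse_params <- function(gamma = 3, p2 = 60, voices = 12) {
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (p2 <= gamma) stop("p2 must exceed gamma (beta > 1 admissibility)",
                        call. = FALSE)
  voices <- as.integer(voices)
  if (voices < 1L) stop("voices must be a positive integer", call. = FALSE)
  beta <- p2 / gamma
  structure(list(gamma = gamma, p2 = p2, beta = beta, voices = voices,
                 omega_p = (beta / gamma)^(1 / gamma)),
            class = "morse_params")
}

#' Generalized Morse wavelet frequency response
#'
#' Evaluates the analytic Morse wavelet in the frequency domain,
#' \deqn{\Psi(\omega) = 2 H(\omega) (\omega/\omega_p)^\beta
#'       \exp\{(\beta/\gamma)(1 - (\omega/\omega_p)^\gamma)\},}
#' peak-normalized so that \eqn{\Psi(\omega_p) = 2} and identically zero for
#' \eqn{\omega \le 0} (exact analyticity).
#'
#' @param omega Angular frequency grid (rad/s), any sign.
#' @param params A [morse_params()] object.
#' @return Numeric vector of the same length as `omega`.
#' @export
morse_psi <- function(omega, params = morse_params()) {
  stopifnot(inherits(params, "morse_params"))
  out <- numeric(length(omega))
  pos <- omega > 0
  r <- omega[pos] / params$omega_p
  out[pos] <- 2 * r^params$beta *
    exp((params$beta / params$gamma) * (1 - r^params$gamma))
  out
}

#' Build a CWT filter bank
#'
#' Center frequencies descend geometrically from `fmax` with ratio
#' `2^(-1/voices)`, stopping at the last frequency >= `fmin`; each scale's
#' frequency-domain filter is the Morse response evaluated at
#' `scale * omega` on the FFT grid of an epoch, with the scale chosen so the
#' response peaks at the scale's center frequency.
#'
#' @param fs Sampling frequency, Hz.
#' @param n_samples Epoch length in samples.
#' @param params A [morse_params()] object.
#' @param fmin,fmax Frequency band limits in Hz; `fmax` must not exceed the
#'   Nyquist frequency `fs/2`.
#' @return Object of class `bcg_filterbank` with `center_freqs` (descending)
#'   and the `n_scales x n_samples` matrix `filters`.
#' @export
build_filterbank <- function(fs, n_samples, params = morse_params(),
                             fmin = 0.5, fmax = 50) {
  if (fmin <= 0 || fmin >= fmax) stop("need 0 < fmin < fmax", call. = FALSE)
  if (fmax > fs / 2) stop("fmax exceeds the Nyquist frequency", call. = FALSE)
  v <- params$voices
  n_scales <- floor(v * log2(fmax / fmin)) + 1L
  center_freqs <- fmax * 2^(-(seq_len(n_scales) - 1L) / v)
  # FFT angular frequency grid (rad/s), negative half mapped below zero
  k <- 0:(n_samples - 1L)
  fgrid <- ifelse(k <= n_samples / 2, k, k - n_samples) * fs / n_samples
  omega <- 2 * pi * fgrid
  scales <- params$omega_p / (2 * pi * center_freqs)
  filters <- matrix(0, n_scales, n_samples)
  for (j in seq_len(n_scales)) {
    filters[j, ] <- morse_psi(scales[j] * omega, params)
  }
  structure(list(fs = fs, n_samples = n_samples, params = params,
                 center_freqs = center_freqs, scales = scales,
                 filters = filters),
            class = "bcg_filterbank")
}

#' Continuous wavelet transform of one epoch
#'
#' FFT-based analytic CWT: for each scale the coefficients are the inverse
#' FFT of the epoch spectrum multiplied by that scale's filter (circular
#' boundary handling on the mean-removed epoch). Returns the magnitude
#' scalogram.
#'
#' @param epoch A `bcg_epoch` or numeric vector whose length matches the
#'   filter bank.
#' @param bank A [build_filterbank()] object.
#' @return Object of class `bcg_scalogram`: non-negative `magnitude` matrix
#'   (scales x times, row 1 = highest frequency), `center_freqs`, `times`.
#' @export
cwt_epoch <- function(epoch, bank) {
  stopifnot(inherits(bank, "bcg_filterbank"))
  x <- if (inherits(epoch, "bcg_epoch")) epoch$samples else as.numeric(epoch)
  n <- length(x)
  if (n != bank$n_samples) {
    stop("epoch length (", n, ") does not match filter bank (",
         bank$n_samples, ")", call. = FALSE)
  }
  X <- stats::fft(x - mean(x))
  n_scales <- nrow(bank$filters)
  mag <- matrix(0, n_scales, n)
  for (j in seq_len(n_scales)) {
    w <- stats::fft(X * Conj(bank$filters[j, ]), inverse = TRUE) / n
    mag[j, ] <- Mod(w)
  }
  structure(list(magnitude = mag, center_freqs = bank$center_freqs,
                 times = (seq_len(n) - 1) / bank$fs, fs = bank$fs),
            class = "bcg_scalogram")
}

# simple 64-step jet-like colormap used by the optional RGB rendering path
.jet_map <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

#' Render a scalogram as a square grayscale image
#'
#' Applies log compression `log(1 + m)`, min-max scales to [0, 255] over the
#' whole image, and bilinearly resamples the scales-by-times magnitude matrix
#' to `side x side` pixels with row 0 the highest frequency. A constant
#' magnitude maps to an all-zero image by convention.
#'
#' The default path maps magnitude directly to gray. `colormap = "jet"`
#' instead renders through a jet colormap and converts back to grayscale by
#' the Rec.601 luminance (0.2989 R + 0.5870 G + 0.1140 B), mimicking pipelines
#' that export colored scalogram plots before grayscale conversion.
#'
#' @param scal A `bcg_scalogram`.
#' @param side Output image side in pixels (default 224).
#' @param colormap `"gray"` (default) or `"jet"`.
#' @return Object of class `bcg_scalogram_image`: integer `pixels` matrix in
#'   [0, 255] and `side`.
#' @export
render_scalogram <- function(scal, side = 224, colormap = c("gray", "jet")) {
  stopifnot(inherits(scal, "bcg_scalogram"))
  colormap <- match.arg(colormap)
  m <- log1p(scal$magnitude)
  lo <- min(m); hi <- max(m)
  u <- if (hi > lo) (m - lo) / (hi - lo) else matrix(0, nrow(m), ncol(m))
  if (colormap == "jet") {
    rgb <- .jet_map(as.vector(u))
    u <- matrix(0.2989 * rgb[, 1] + 0.5870 * rgb[, 2] + 0.1140 * rgb[, 3],
                nrow(m), ncol(m))
  }
  px <- resize_bilinear(u, side, side)
  # re-apply min-max after rasterization so the rendered image spans the
  # full 0-255 range even when interpolation smooths the extrema
  lo <- min(px); hi <- max(px)
  px <- if (hi > lo) (px - lo) / (hi - lo) * 255 else matrix(0, side, side)
  px <- round(px)
  structure(list(pixels = px, side = side), class = "bcg_scalogram_image")
}

#' Resize a square grayscale image
#'
#' Bilinear (pixel-center aligned) interpolation to `side x side`; output
#' values are clipped to [0, 255] and rounded.
#'
#' @param img A `bcg_scalogram_image`.
#' @param side Target side in pixels.
#' @return A `bcg_scalogram_image` of the requested size.
#' @export
resize_image <- function(img, side = 32) {
  stopifnot(inherits(img, "bcg_scalogram_image"))
  if (side <= 0) stop("side must be positive", call. = FALSE)
  if (side == img$side) return(img)
  px <- round(pmin(pmax(resize_bilinear(img$pixels, side, side), 0), 255))
  structure(list(pixels = px, side = side), class = "bcg_scalogram_image")
}

# Separable bilinear resampling with pixel-center alignment: output pixel i
# samples source coordinate (i - 0.5) * n/out + 0.5, clamped to the grid.
resize_bilinear <- function(mat, out_r, out_c) {
  src_coord <- function(n_out, n_in) {
    x <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(x, 1), n_in)
  }
  interp_rows <- function(m, n_out) {
    n_in <- nrow(m)
    if (n_in == 1L) return(m[rep(1L, n_out), , drop = FALSE])
    x <- src_coord(n_out, n_in)
    i0 <- pmin(floor(x), n_in - 1L)
    w <- x - i0
    m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1L, , drop = FALSE] * w
  }
  m <- interp_rows(mat, out_r)
  t(interp_rows(t(m), out_c))
}

#' Write a grayscale scalogram image as PNG
#'
#' @param img A `bcg_scalogram_image`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_scalogram_png <- function(img, path) {
  stopifnot(inherits(img, "bcg_scalogram_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
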