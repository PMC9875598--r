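#' Second-order Butterworth biquad design
#'
#' Designs the digital coefficients of a 2nd-order Butterworth low-pass or
#' high-pass filter via the bilinear transform with frequency pre-warping
#' (the standard biquad with quality factor `1/sqrt(2)`).
#'
#' @param cutoff_hz Corner frequency (-3 dB) in Hz.
#' @param fs Sample rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` (each length 3,
#'   `a[1] == 1`).
#' @export
butter2 <- function(cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  if (cutoff_hz >= fs / 2)
    stop("cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  K <- tan(pi * cutoff_hz / fs)
  s2 <- sqrt(2)
  den <- 1 + s2 * K + K^2
  a <- c(1, 2 * (K^2 - 1) / den, (1 - s2 * K + K^2) / den)
  if (type == "low") {
    b <- c(K^2, 2 * K^2, K^2) / den
  } else {
    b <- c(1, -2, 1) / den
  }
  list(b = b, a = a)
}

#' Magnitude response of a digital biquad
#'
#' @param coef List with `b`, `a` from [butter2()].
#' @param f_hz Frequencies at which to evaluate (Hz).
#' @param fs Sample rate (Hz).
#' @return Magnitude `|H(f)|` (single pass).
#' @export
biquad_gain <- function(coef, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  z <- exp(-1i * w)
  H <- (coef$b[1] + coef$b[2] * z + coef$b[3] * z^2) /
    (coef$a[1] + coef$a[2] * z + coef$a[3] * z^2)
  Mod(H)
}

#' Zero-phase (forward-backward) biquad filtering
#'
#' Applies a biquad forward and backward so the net phase response is zero
#' and peak latencies are preserved; the magnitude response is applied
#' twice. Edge transients are controlled by odd-reflection padding of
#' `pad` samples at both ends plus steady-state initial conditions (the
#' scipy `filtfilt` convention), so a constant input maps exactly to its
#' steady-state response even on records much shorter than the corner
#' period.
#'
#' @param x Numeric signal.
#' @param coef List with `b`, `a`.
#' @param pad Padding length; default `min(9, length(x) - 1)`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt2 <- function(x, coef, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(9L, n - 1L)
  if (pad > 0) {
    head_ext <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_ext <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xe <- c(head_ext, x, tail_ext)
  } else {
    xe <- x
  }
  zi <- biquad_zi(coef)
  y <- .biquad_filter(xe, coef$b, coef$a, zi * xe[1])
  yr <- rev(y)
  y <- rev(.biquad_filter(yr, coef$b, coef$a, zi * yr[1]))
  if (pad > 0) y <- y[(pad + 1):(pad + n)]
  y
}

# steady-state filter state for unit constant input (lfilter_zi)
biquad_zi <- function(coef) {
  h1 <- sum(coef$b) / sum(coef$a)
  z2 <- coef$b[3] - coef$a[3] * h1
  z1 <- coef$b[2] - coef$a[2] * h1 + z2
  c(z1, z2)
}

#' Band-limit a signal with the two-corner Butterworth cascade
#'
#' High-pass then low-pass, each 2nd order, each applied zero-phase.
#'
#' @param x Numeric signal.
#' @param band Numeric length-2 `c(high_pass_hz, low_pass_hz)`.
#' @param fs Sample rate (Hz).
#' @return Filtered signal.
#' @export
apply_band <- function(x, band, fs) {
  hp <- butter2(band[1], fs, "high")
  lp <- butter2(band[2], fs, "low")
  filtfilt2(filtfilt2(x, hp), lp)
}

#' Corner frequencies of the two analysis bands
#'
#' `"short_latency"` isolates the fast 3-ms peak (150-1,000 Hz);
#' `"long_latency"` the slower 10-ms peak (1-150 Hz).
#' @param band `"short_latency"` or `"long_latency"`.
#' @return `c(high_pass_hz, low_pass_hz)`.
#' @export
band_corners <- function(band = c("short_latency", "long_latency")) {
  band <- match.arg(band)
  if (band == "short_latency") c(150, 1000) else c(1, 150)
}
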