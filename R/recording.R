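#' Stimulation settings
#'
#' The stimulation mode throughout is a monopolar cathodic pulse with
#' return on the implant case. Clinical stimulation runs at 130 Hz; evoked
#' potentials are recorded at 10 Hz so consecutive responses do not
#' overlap. Pulse width is 60 microseconds.
#'
#' @param frequency_hz Pulse rate (Hz); > 0.
#' @param pulse_width_us Pulse width (microseconds); > 0.
#' @param intensity_mA Stimulation current (mA); >= 0.
#' @return A `stim_settings` object.
#' @export
stim_settings <- function(frequency_hz = 10, pulse_width_us = 60,
                          intensity_mA = 1) {
  if (frequency_hz <= 0) stop("frequency must be > 0")
  if (pulse_width_us <= 0) stop("pulse width must be > 0")
  if (intensity_mA < 0) stop("intensity must be >= 0")
  structure(list(mode = "monopolar_cathodic_case_return",
                 frequency_hz = frequency_hz,
                 pulse_width_us = pulse_width_us,
                 intensity_mA = intensity_mA),
            class = "stim_settings")
}

resolve_montage <- function(montage) {
  if (is.character(montage)) {
    montage <- switch(montage,
      biosemi64 = montage_biosemi64(),
      reduced = montage_reduced(),
      stop("unknown montage name: ", montage)
    )
  }
  validate_montage(montage)
}

# fractional overlap of sample bin [a, b) with interval [c, d), in units of (b - a)
.bin_overlap <- function(a, b, c, d) pmax(0, pmin(b, d) - pmax(a, c)) / (b - a)

#' Stimulation-artifact kernel
#'
#' A biphasic rectangular pulse (cathodic then anodic phase, each
#' `pulse_width_us` long, rendered with fractional sample coverage)
#' convolved with an exponential recovery tail of time constant `tau_s`.
#' Normalised so the largest absolute sample is 1 (first deflection
#' negative).
#'
#' @param fs Sample rate (Hz).
#' @param pulse_width_us Phase width (microseconds).
#' @param tau_s Tail time constant (seconds); default 0.8 ms.
#' @return Numeric kernel starting at pulse onset.
#' @export
artifact_kernel <- function(fs, pulse_width_us = 60, tau_s = 0.8e-3) {
  pw <- pulse_width_us * 1e-6
  # oversample so both pulse phases are resolved even when the recording
  # sample interval exceeds the pulse width, then integrate-and-dump back
  os <- max(1L, 2L^ceiling(log2(max(1, 8 / (pw * fs)))))
  dt <- 1 / (fs * os)
  nb <- ceiling(2 * pw / dt) + 1L
  a <- (seq_len(nb) - 1) * dt
  base <- -.bin_overlap(a, a + dt, 0, pw) + .bin_overlap(a, a + dt, pw, 2 * pw)
  nt <- ceiling(12 * tau_s / dt) + 1L
  decay <- exp(-(seq_len(nt) - 1) * dt / tau_s)
  k <- .conv_open(base, decay)
  if (os > 1L) {
    pad <- ceiling(length(k) / os) * os - length(k)
    k <- colMeans(matrix(c(k, numeric(pad)), nrow = os))
  }
  k / max(abs(k))
}

# gaussian bump peaking exactly on a sample so injected amplitudes are
# recoverable bit-exactly on clean data
gauss_kernel <- function(fs, peak_s, fwhm_s) {
  peak_idx <- round(peak_s * fs)
  n <- peak_idx + round(3 * fwhm_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  exp(-4 * log(2) * ((t - peak_idx / fs) / fwhm_s)^2)
}

.conv_open <- function(x, k) {
  n <- length(x) + length(k) - 1L
  m <- stats::nextn(n)
  X <- stats::fft(c(x, numeric(m - length(x))))
  K <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(n)] / m
}

# pink (1/f power) noise via spectral shaping; flat below 1 Hz, zero mean
one_over_f_noise <- function(n, fs, rms) {
  if (rms == 0) return(numeric(n))
  m <- stats::nextn(n)
  f <- pmin(seq_len(m) - 1, m - (seq_len(m) - 1)) * fs / m
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0
  X <- stats::fft(stats::rnorm(m)) * shape
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  x * rms / stats::sd(x)
}

#' Simulate a stimulation-EEG recording
#'
#' Renders one monopolar recording for a hemisphere: stimulation pulses at
#' exact multiples of the inter-stimulus interval starting `onset_s` after
#' record start, a decaying biphasic artifact on every channel (fixed
#' per-hemisphere spatial scale pattern, largest on the IPG channel EXG1,
#' same temporal shape on the mastoids), evoked-response bumps peaking 3 ms
#' (motor channel) and 10 ms (prefrontal channel) after each pulse with
#' fixed spatial spread, and 1/f background noise. Evoked amplitudes are
#' the configuration's ground-truth couplings scaled by intensity: zero at
#' or below the 1 mA activation threshold, linear above, equal to the
#' coupling at the reference intensity.
#'
#' @param ground_truth A hemisphere ground truth from
#'   [simulate_hemisphere()].
#' @param configuration A `configuration_id` present in the ground truth.
#' @param settings A [stim_settings()]; frequency 10 Hz for EP runs.
#' @param duration_s Stimulation duration (s); the record is padded by
#'   0.1 s after the last pulse window.
#' @param fs Sample rate (Hz); the hardware default is 16384.
#' @param montage `"biosemi64"`, `"reduced"`, or a montage data frame.
#' @param noise_rms_uV Per-channel background-noise RMS (microvolts).
#' @param onset_s Time of the first pulse (s); default 0.05 so the first
#'   epoch keeps a pre-stimulus baseline.
#' @param seed Integer RNG seed; identical inputs give bit-identical
#'   output.
#' @return A `dbs_recording`: list with `samples` (channels x time matrix,
#'   microvolts), `fs`, `montage`, `settings`, `side`, `hemisphere_id`,
#'   `configuration_id` and a `truth` element holding the pulse sample
#'   indices and injected peak amplitudes for oracle checks.
#' @export
simulate_recording <- function(ground_truth, configuration, settings,
                               duration_s = 50, fs = 16384,
                               montage = "biosemi64", noise_rms_uV = 2,
                               onset_s = 0.05, seed = 1) {
  stopifnot(inherits(settings, "stim_settings"), duration_s > 0)
  montage <- resolve_montage(montage)
  gt <- ground_truth
  ci <- match(configuration, gt$couplings$configuration_id)
  if (is.na(ci)) stop("unknown configuration_id: ", configuration)

  n <- round((onset_s + duration_s + 0.1) * fs)
  n_pulses <- floor(duration_s * settings$frequency_hz + 1e-9)
  pulse_idx <- round((onset_s + (seq_len(n_pulses) - 1) /
                        settings$frequency_hz) * fs) + 1L

  train <- numeric(n)
  train[pulse_idx] <- 1

  I <- settings$intensity_mA
  amp_scale <- intensity_factor(I, gt$effect)
  p3_amp <- gt$couplings$p3_coupling_uV[ci] * amp_scale
  p10_amp <- gt$couplings$p10_coupling_uV[ci] * amp_scale

  art_sig <- .conv_open(train, artifact_kernel(fs, settings$pulse_width_us))[seq_len(n)]
  p3_sig <- .conv_open(train, gauss_kernel(fs, 3e-3, 1.5e-3))[seq_len(n)]
  p10_sig <- .conv_open(train, gauss_kernel(fs, 10e-3, 4e-3))[seq_len(n)]

  p3_gain <- ep_spread_pattern(peak_channel(gt$side, "P3"))
  p10_gain <- ep_spread_pattern(peak_channel(gt$side, "P10"))

  missing_scales <- setdiff(montage$label, names(gt$artifact_scales_uV))
  if (length(missing_scales))
    stop("ground truth has no artifact scale for channel(s): ",
         paste(missing_scales, collapse = ", "))

  set.seed(seed)
  samples <- matrix(0, nrow = nrow(montage), ncol = n,
                    dimnames = list(montage$label, NULL))
  for (i in seq_len(nrow(montage))) {
    lab <- montage$label[i]
    x <- gt$artifact_scales_uV[[lab]] * I * art_sig
    if (montage$role[i] == "scalp") {
      if (!is.na(p3_gain[lab])) x <- x + p3_amp * p3_gain[[lab]] * p3_sig
      if (!is.na(p10_gain[lab])) x <- x + p10_amp * p10_gain[[lab]] * p10_sig
    }
    samples[i, ] <- x + one_over_f_noise(n, fs, noise_rms_uV)
  }

  structure(list(
    samples = samples, fs = fs, montage = montage, settings = settings,
    side = gt$side, hemisphere_id = gt$hemisphere_id,
    configuration_id = configuration,
    truth = list(pulse_idx = pulse_idx, p3_amp_uV = p3_amp,
                 p10_amp_uV = p10_amp)
  ), class = "dbs_recording")
}

# linear amplitude scaling above the activation threshold, zero below;
# equals 1 at the reference intensity
intensity_factor <- function(intensity_mA, effect) {
  thr <- effect$threshold_mA
  ref <- effect$reference_mA
  pmax(0, intensity_mA - thr) / (ref - thr)
}

#' @export
print.dbs_recording <- function(x, ...) {
  cat(sprintf(
    "<dbs_recording> %s/%s: %d ch x %d samples @ %g Hz, %g mA @ %g Hz stim\n",
    x$hemisphere_id, x$configuration_id, nrow(x$samples), ncol(x$samples),
    x$fs, x$settings$intensity_mA, x$settings$frequency_hz))
  invisible(x)
}
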