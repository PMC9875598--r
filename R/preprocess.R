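#' Detect stimulation onsets on the IPG trigger channel
#'
#' Onsets are the first threshold crossings of each artifact event on the
#' trigger channel (EXG1). The threshold is `median(|x|) + k * mad(|x|)`;
#' after a crossing, detection is locked out for half the inter-stimulus
#' interval so one pulse yields one onset.
#'
#' @param recording A `dbs_recording`.
#' @param k Threshold factor over the MAD (default 8).
#' @return Strictly increasing integer sample indices of the detected
#'   onsets. Warns if the inter-trigger-interval coefficient of variation
#'   exceeds 10%.
#' @export
detect_triggers <- function(recording, k = 8) {
  trig <- which(recording$montage$role == "ipg_trigger")
  if (length(trig) != 1L) stop("recording has no unique ipg_trigger channel")
  x <- abs(recording$samples[trig, ])
  thr <- stats::median(x) + k * stats::mad(x)
  # (near-)noise-free channels have a degenerate MAD; fall back to half the
  # peak height rather than chase numerical dust
  if (thr <= 1e-4 * max(x)) thr <- max(x) / 2
  if (thr <= 0) stop("no triggers detected on the IPG channel")
  above <- x >= thr
  if (!any(above)) stop("no triggers detected on the IPG channel")
  lockout <- floor(recording$fs / (2 * recording$settings$frequency_hz))
  idx <- which(above)
  onsets <- idx[1]
  last <- idx[1]
  for (i in idx[-1]) {
    if (i > last + lockout) {
      onsets <- c(onsets, i)
      last <- i
    }
  }
  if (length(onsets) > 2) {
    iti <- diff(onsets)
    cv <- stats::sd(iti) / mean(iti)
    if (is.finite(cv) && cv > 0.10)
      warning(sprintf("inter-trigger interval CV = %.1f%% exceeds 10%%", 100 * cv))
  }
  onsets
}

#' Cut stimulus-locked epochs
#'
#' Extracts one fixed-length window per onset; onsets whose window would
#' extend outside the record are dropped (with a message reporting the
#' count). The default window is -1 to +99 ms so each 100 ms epoch carries
#' a 1 ms pre-stimulus baseline.
#'
#' @param recording A `dbs_recording`.
#' @param onsets Integer onset samples, e.g. from [detect_triggers()].
#' @param window_ms `c(start, end)` of the epoch relative to onset (ms);
#'   `end - start` must be 100 ms.
#' @return A `dbs_epochs` object: `epochs` array (epoch x channel x time,
#'   microvolts), `time_ms`, `fs`, `montage`, provenance `flags`, and the
#'   stimulation metadata carried through.
#' @export
epoch_recording <- function(recording, onsets, window_ms = c(-1, 99)) {
  stopifnot(length(window_ms) == 2, diff(window_ms) == 100)
  fs <- recording$fs
  pre <- round(-window_ms[1] * 1e-3 * fs)
  nt <- round(diff(window_ms) * 1e-3 * fs)
  n <- ncol(recording$samples)
  start <- onsets - pre
  keep <- start >= 1 & (start + nt - 1) <= n
  if (sum(!keep) > 0)
    message(sum(!keep), " onset(s) dropped: epoch window out of bounds")
  onsets <- onsets[keep]
  if (length(onsets) == 0) stop("no onsets leave a full epoch window in-bounds")
  nch <- nrow(recording$samples)
  ep <- array(0, dim = c(length(onsets), nch, nt),
              dimnames = list(NULL, rownames(recording$samples), NULL))
  for (e in seq_along(onsets)) {
    sl <- (onsets[e] - pre):(onsets[e] - pre + nt - 1)
    ep[e, , ] <- recording$samples[, sl]
  }
  structure(list(
    epochs = ep,
    time_ms = (seq_len(nt) - 1 - pre) / fs * 1000,
    fs = fs, montage = recording$montage, settings = recording$settings,
    side = recording$side, hemisphere_id = recording$hemisphere_id,
    configuration_id = recording$configuration_id,
    flags = list(baseline_corrected = FALSE, artifact_removed = FALSE,
                 band = "none")
  ), class = "dbs_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the 1 ms pre-stimulus
#' interval \[-1, 0) ms. Errors if already applied (the correction is not
#' idempotent bookkeeping-wise) or if the window lacks a baseline.
#'
#' @param epochset A `dbs_epochs`.
#' @return The corrected `dbs_epochs` with `baseline_corrected = TRUE`.
#' @export
baseline_correct <- function(epochset) {
  stopifnot(inherits(epochset, "dbs_epochs"))
  if (epochset$flags$baseline_corrected)
    stop("epochs are already baseline-corrected")
  bl <- epochset$time_ms >= -1 & epochset$time_ms < 0
  if (!any(bl)) stop("epoch window does not include the [-1, 0) ms baseline")
  means <- apply(epochset$epochs[, , bl, drop = FALSE], c(1, 2), mean)
  epochset$epochs <- epochset$epochs - as.vector(means)  # recycles over time
  epochset$flags$baseline_corrected <- TRUE
  epochset
}

#' Remove the stimulation artifact by template subtraction and interpolation
#'
#' The artifact template is the grand average (across epochs) of the mean
#' of the two mastoid channels, which see the artifact but negligible
#' neural response. For each scalp channel a single scale factor is fitted
#' by least squares between the template and that channel's epoch average
#' over `fit_ms`, and the scaled template is subtracted from every epoch.
#' Samples inside `interp_ms` (the residual pulse spike) are then replaced
#' by linear interpolation between the window-edge samples, per epoch and
#' channel. Template subtraction precedes interpolation because
#' interpolation would destroy the spike shape the fit needs.
#'
#' @param epochset A baseline-corrected `dbs_epochs`.
#' @param interp_ms Interpolation window `c(start, end)` in ms.
#' @param fit_ms Template-fit window `c(start, end)` in ms.
#' @return The cleaned `dbs_epochs` with `artifact_removed = TRUE`.
#' @export
remove_artifact <- function(epochset, interp_ms = c(-0.1, 1.5),
                            fit_ms = c(-0.1, 8)) {
  stopifnot(inherits(epochset, "dbs_epochs"))
  if (!epochset$flags$baseline_corrected)
    stop("epochs must be baseline-corrected before artifact removal")
  if (epochset$flags$artifact_removed)
    stop("artifact removal already applied")
  mast <- which(epochset$montage$role == "mastoid_template")
  if (length(mast) != 2L) stop("epoch tensor lacks the two mastoid channels")
  scalp <- which(epochset$montage$role == "scalp")
  t_ms <- epochset$time_ms

  nep <- dim(epochset$epochs)[1]
  nt <- dim(epochset$epochs)[3]
  chan_mat <- function(ch) matrix(epochset$epochs[, ch, ], nrow = nep, ncol = nt)
  template <- colMeans(chan_mat(mast[1]) + chan_mat(mast[2])) / 2
  fw <- t_ms >= fit_ms[1] & t_ms <= fit_ms[2]
  ss <- sum(template[fw]^2)
  if (ss <= .Machine$double.eps * length(template))
    stop("degenerate artifact template: no energy inside the fit window")

  for (ch in scalp) {
    chavg <- colMeans(chan_mat(ch))
    s <- sum(template[fw] * chavg[fw]) / ss
    epochset$epochs[, ch, ] <- chan_mat(ch) -
      matrix(s * template, nrow = nep, ncol = nt, byrow = TRUE)
  }

  iw <- which(t_ms >= interp_ms[1] & t_ms <= interp_ms[2])
  if (length(iw)) {
    i0 <- min(iw) - 1L
    i1 <- max(iw) + 1L
    if (i0 < 1L || i1 > length(t_ms))
      stop("interpolation window must leave an anchor sample on both sides")
    w <- (iw - i0) / (i1 - i0)
    left <- epochset$epochs[, scalp, i0, drop = FALSE]
    right <- epochset$epochs[, scalp, i1, drop = FALSE]
    for (m in seq_along(iw)) {
      epochset$epochs[, scalp, iw[m]] <-
        (1 - w[m]) * left[, , 1] + w[m] * right[, , 1]
    }
  }
  epochset$flags$artifact_removed <- TRUE
  epochset
}

#' Band-separate epochs with zero-phase Butterworth filters
#'
#' Applies the 2nd-order Butterworth high-pass and low-pass pair of the
#' requested analysis band to every epoch and channel, forward-backward so
#' peak latencies are not shifted: 150-1,000 Hz for the short-latency
#' (3 ms) peak, 1-150 Hz for the long-latency (10 ms) peak. A band may be
#' set only once per epoch set.
#'
#' @param epochset A `dbs_epochs`.
#' @param band `"short_latency"` or `"long_latency"`.
#' @return The filtered `dbs_epochs` with `flags$band` set.
#' @export
bandpass_epochs <- function(epochset, band = c("short_latency", "long_latency")) {
  stopifnot(inherits(epochset, "dbs_epochs"))
  band <- match.arg(band)
  if (epochset$flags$band != "none")
    stop("band already set to ", epochset$flags$band,
         "; band-separation may be applied only once")
  corners <- band_corners(band)
  hp <- butter2(corners[1], epochset$fs, "high")
  lp <- butter2(corners[2], epochset$fs, "low")
  d <- dim(epochset$epochs)
  # time along rows, one column per epoch x channel trace
  M <- matrix(aperm(epochset$epochs, c(3, 1, 2)), nrow = d[3])
  M <- .filtfilt_mat(M, list(hp$b, lp$b), list(hp$a, lp$a), 9L)
  epochset$epochs <- aperm(array(M, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  dimnames(epochset$epochs) <- list(NULL, epochset$montage$label, NULL)
  epochset$flags$band <- band
  epochset
}

#' Full preprocessing chain for one recording
#'
#' trigger detection, epoching, baseline correction, artifact removal and
#' band separation, in the enforced order. Returns one epoch set per
#' requested band (the unfiltered artifact-cleaned set is duplicated
#' before band-separation, which may be applied only once per set).
#'
#' @param recording A `dbs_recording`.
#' @param bands Character vector of bands to produce.
#' @param interp_ms,fit_ms See [remove_artifact()].
#' @param window_ms See [epoch_recording()].
#' @return Named list of `dbs_epochs`, one per band.
#' @export
preprocess_recording <- function(recording,
                                 bands = c("short_latency", "long_latency"),
                                 interp_ms = c(-0.1, 1.5), fit_ms = c(-0.1, 8),
                                 window_ms = c(-1, 99)) {
  onsets <- detect_triggers(recording)
  ep <- epoch_recording(recording, onsets, window_ms)
  ep <- baseline_correct(ep)
  ep <- remove_artifact(ep, interp_ms, fit_ms)
  out <- lapply(bands, function(b) bandpass_epochs(ep, b))
  names(out) <- bands
  out
}
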