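#' Average epochs into an evoked response
#'
#' Pointwise mean over epochs; metadata (band, stimulation settings,
#' hemisphere side, epoch count) is carried through.
#'
#' @param epochset A fully preprocessed `dbs_epochs` (at least one epoch).
#' @return A `dbs_evoked`: `waveform` (channel x time matrix, microvolts),
#'   `time_ms`, `fs`, `montage`, `band`, `n_epochs`, plus stimulation
#'   metadata.
#' @export
average_epochs <- function(epochset) {
  stopifnot(inherits(epochset, "dbs_epochs"))
  d <- dim(epochset$epochs)
  if (d[1] < 1) stop("need at least one epoch")
  wf <- apply(epochset$epochs, c(2, 3), mean)
  rownames(wf) <- epochset$montage$label
  structure(list(
    waveform = wf, time_ms = epochset$time_ms, fs = epochset$fs,
    montage = epochset$montage, band = epochset$flags$band,
    n_epochs = d[1], settings = epochset$settings, side = epochset$side,
    hemisphere_id = epochset$hemisphere_id,
    configuration_id = epochset$configuration_id
  ), class = "dbs_evoked")
}

#' Analysis channel of an evoked response
#'
#' Dispatches to [peak_channel()] using the evoked response's hemisphere
#' side and errors if that channel is absent from the montage.
#'
#' @param evoked A `dbs_evoked`.
#' @param peak_type `"P3"` or `"P10"`.
#' @return A channel label present in the evoked waveform.
#' @export
select_channel <- function(evoked, peak_type) {
  if (is.null(evoked$side)) stop("hemisphere side unknown")
  ch <- peak_channel(evoked$side, peak_type)
  if (!ch %in% rownames(evoked$waveform))
    stop("channel ", ch, " missing from the evoked waveform")
  ch
}

peak_window_ms <- function(peak_type) {
  switch(peak_type, P3 = c(2, 5), P10 = c(8, 15),
         stop("unknown peak type: ", peak_type))
}

peak_band <- function(peak_type) {
  switch(peak_type, P3 = "short_latency", P10 = "long_latency")
}

#' Extract a P3 or P10 peak measurement
#'
#' Amplitude is the maximum of the absolute waveform (the analyses use
#' absolute peak amplitudes; set `absolute = FALSE` for the signed
#' positive maximum) on the prescribed channel within the peak window:
#' 2-5 ms for P3 on the short-latency band, 8-15 ms for P10 on the
#' long-latency band. Latency is the arg-max, ties broken toward the
#' earliest sample.
#'
#' @param evoked A `dbs_evoked` whose band matches the peak type.
#' @param peak_type `"P3"` or `"P10"`.
#' @param absolute Use `|waveform|` (default) rather than the signed
#'   waveform.
#' @return A one-row data frame: `peak_type`, `amplitude_uV`,
#'   `latency_ms`, `channel`, `hemisphere_id`, `configuration_id`.
#' @export
extract_peak <- function(evoked, peak_type = c("P3", "P10"), absolute = TRUE) {
  stopifnot(inherits(evoked, "dbs_evoked"))
  peak_type <- match.arg(peak_type)
  if (evoked$band != peak_band(peak_type))
    stop("band mismatch: ", peak_type, " requires the ", peak_band(peak_type),
         " band, epochs carry '", evoked$band, "'")
  win <- peak_window_ms(peak_type)
  idx <- which(evoked$time_ms >= win[1] & evoked$time_ms <= win[2])
  if (length(idx) == 0) stop("peak window lies outside the epoch span")
  ch <- select_channel(evoked, peak_type)
  y <- evoked$waveform[ch, idx]
  v <- if (absolute) abs(y) else y
  best <- idx[which.max(v)]  # which.max returns the first maximum: earliest tie
  data.frame(
    peak_type = peak_type,
    amplitude_uV = if (absolute) abs(evoked$waveform[ch, best])
                   else evoked$waveform[ch, best],
    latency_ms = evoked$time_ms[best],
    channel = ch,
    hemisphere_id = evoked$hemisphere_id %||% NA_character_,
    configuration_id = evoked$configuration_id %||% NA_character_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-epoch amplitudes at a fixed latency
#'
#' The absolute value of every single epoch on one channel at the given
#' latency (nearest sample); the single-epoch measurement feeding the
#' intensity screen.
#'
#' @param epochset A preprocessed, band-separated `dbs_epochs`.
#' @param channel Channel label.
#' @param latency_ms Latency (ms, relative to stimulus onset).
#' @return Numeric vector, one value per epoch.
#' @export
epoch_amplitudes <- function(epochset, channel, latency_ms) {
  stopifnot(inherits(epochset, "dbs_epochs"))
  ch <- match(channel, epochset$montage$label)
  if (is.na(ch)) stop("channel not in montage: ", channel)
  i <- which.min(abs(epochset$time_ms - latency_ms))
  abs(epochset$epochs[, ch, i])
}

#' Stimulation-intensity screen (one-way ANOVA)
#'
#' Tests whether stimulation intensity affects the single-epoch peak
#' amplitudes across the three recorded intensities (sub-threshold
#' control, rigidity-suppression intensity, highest tolerated intensity).
#' A hemisphere/peak combination is analysed further only if the effect is
#' significant; otherwise the lead is judged too far from the generating
#' structure to yield a solid peak.
#'
#' @param amplitude_groups List of (three) numeric vectors of per-epoch
#'   amplitudes, one per intensity.
#' @param alpha Significance level (default 0.05).
#' @return List with `F`, `df1`, `df2`, `p` and `include` (`p < alpha`).
#' @export
intensity_screen <- function(amplitude_groups, alpha = 0.05) {
  stopifnot(is.list(amplitude_groups), length(amplitude_groups) >= 2)
  ns <- lengths(amplitude_groups)
  if (any(ns < 2)) stop("every intensity group needs at least 2 epochs")
  y <- unlist(amplitude_groups, use.names = FALSE)
  g <- rep(seq_along(amplitude_groups), ns)
  N <- length(y); k <- length(amplitude_groups)
  gm <- tapply(y, g, mean)
  ssb <- sum(ns * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  if (ssw <= .Machine$double.eps * max(1, sum(y^2)))
    stop("degenerate screen: zero within-group variance, F undefined")
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, df1 = k - 1, df2 = N - k, p = p, include = p < alpha)
}

#' Run the intensity screen for one hemisphere and peak type
#'
#' Preprocesses the per-intensity epoch sets in the peak's analysis band,
#' samples each intensity's epochs at that intensity's own averaged-EP
#' peak latency, and applies [intensity_screen()].
#'
#' @param epochsets List of band-separated `dbs_epochs`, one per
#'   intensity (same hemisphere, clinical configuration).
#' @param peak_type `"P3"` or `"P10"`.
#' @param alpha Significance level.
#' @return The [intensity_screen()] result.
#' @export
screen_hemisphere <- function(epochsets, peak_type, alpha = 0.05) {
  groups <- lapply(epochsets, function(ep) {
    ev <- average_epochs(ep)
    pk <- extract_peak(ev, peak_type)
    epoch_amplitudes(ep, pk$channel, pk$latency_ms)
  })
  intensity_screen(groups, alpha)
}
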