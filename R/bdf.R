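#' Minimal BDF (BioSemi 24-bit) recording I/O
#'
#' Writes/reads a `dbs_recording` as a single-data-record BDF file, the
#' native format of the BioSemi ActiveTwo amplifier. Physical units are
#' microvolts; each channel gets its own physical range, so the 24-bit
#' digital range keeps sub-microvolt resolution even next to
#' millivolt-scale stimulation artifacts. Only the subset required here is
#' implemented (one data record, uniform sample rate, no annotations).
#'
#' @param recording A `dbs_recording`.
#' @param path Output path (conventionally `.bdf`).
#' @return `write_bdf()` returns `path` invisibly; `read_bdf()` returns a
#'   `dbs_recording` (with `settings` restored from the header's recording
#'   field when present).
#' @export
write_bdf <- function(recording, path) {
  stopifnot(inherits(recording, "dbs_recording"))
  x <- recording$samples
  ns <- nrow(x)
  n <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, width) {
    s <- substr(s, 1, width)
    paste0(s, strrep(" ", width - nchar(s)))
  }
  wtxt <- function(s, width) writeBin(charToRaw(pad(s, width)), con)

  writeBin(as.raw(255L), con)
  wtxt("BIOSEMI", 7)
  meta <- sprintf("dbsep fs=%g freq=%g pw=%g int=%g side=%s cfg=%s",
                  recording$fs, recording$settings$frequency_hz,
                  recording$settings$pulse_width_us,
                  recording$settings$intensity_mA,
                  recording$side %||% "NA",
                  recording$configuration_id %||% "NA")
  wtxt(recording$hemisphere_id %||% "X", 80)   # patient id
  wtxt(meta, 80)                               # recording id
  wtxt("01.01.26", 8)
  wtxt("00.00.00", 8)
  wtxt(sprintf("%d", 256 * (ns + 1)), 8)
  wtxt("24BIT", 44)
  wtxt("1", 8)                                 # number of data records
  wtxt(sprintf("%.6f", n / recording$fs), 8)   # record duration (s)
  wtxt(sprintf("%d", ns), 4)

  pmin_ <- floor(apply(x, 1, min))
  pmax_ <- ceiling(apply(x, 1, max))
  same <- pmax_ <= pmin_
  pmax_[same] <- pmin_[same] + 1
  for (i in seq_len(ns)) wtxt(recording$montage$label[i], 16)
  for (i in seq_len(ns)) wtxt(recording$montage$role[i], 80)
  for (i in seq_len(ns)) wtxt("uV", 8)
  for (i in seq_len(ns)) wtxt(sprintf("%d", pmin_[i]), 8)
  for (i in seq_len(ns)) wtxt(sprintf("%d", pmax_[i]), 8)
  for (i in seq_len(ns)) wtxt("-8388608", 8)
  for (i in seq_len(ns)) wtxt("8388607", 8)
  for (i in seq_len(ns)) wtxt("HP:DC", 80)
  for (i in seq_len(ns)) wtxt(sprintf("%d", n), 8)
  for (i in seq_len(ns)) wtxt("", 32)

  dmin <- -8388608; dmax <- 8388607
  for (i in seq_len(ns)) {
    v <- round((x[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                 (dmax - dmin) + dmin)
    v[v < 0] <- v[v < 0] + 16777216
    b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' @rdname write_bdf
#' @export
read_bdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 1)
  if (as.integer(magic) != 255L) stop("not a BDF file: ", path)
  rtxt <- function(width) {
    trimws(rawToChar(readBin(con, "raw", width)))
  }
  if (rtxt(7) != "BIOSEMI") stop("not a BioSemi BDF file: ", path)
  patient <- rtxt(80)
  rec_id <- rtxt(80)
  rtxt(8); rtxt(8); rtxt(8); rtxt(44)
  n_rec <- as.integer(rtxt(8))
  dur <- as.numeric(rtxt(8))
  ns <- as.integer(rtxt(4))
  labels <- vapply(seq_len(ns), function(i) rtxt(16), character(1))
  roles <- vapply(seq_len(ns), function(i) rtxt(80), character(1))
  vapply(seq_len(ns), function(i) rtxt(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rtxt(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rtxt(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rtxt(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rtxt(8), character(1)))
  vapply(seq_len(ns), function(i) rtxt(80), character(1))
  nspr <- as.integer(vapply(seq_len(ns), function(i) rtxt(8), character(1)))
  vapply(seq_len(ns), function(i) rtxt(32), character(1))

  meta <- list()
  if (grepl("^dbsep ", rec_id)) {
    for (kv in strsplit(sub("^dbsep ", "", rec_id), " ")[[1]]) {
      p <- strsplit(kv, "=")[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else nspr[1] / dur

  samples <- matrix(0, nrow = ns, ncol = nspr[1] * n_rec,
                    dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      b <- as.integer(readBin(con, "raw", 3 * nspr[i]))
      u <- b[seq(1, length(b), 3)] + 256 * b[seq(2, length(b), 3)] +
        65536 * b[seq(3, length(b), 3)]
      u[u >= 8388608] <- u[u >= 8388608] - 16777216
      phys <- (u - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) +
        pmin_[i]
      samples[i, ((r - 1) * nspr[i] + 1):(r * nspr[i])] <- phys
    }
  }
  montage <- data.frame(label = labels, role = roles, stringsAsFactors = FALSE)
  settings <- if (!is.null(meta$freq)) {
    stim_settings(as.numeric(meta$freq), as.numeric(meta$pw),
                  as.numeric(meta$int))
  } else NULL
  structure(list(
    samples = samples, fs = fs, montage = montage, settings = settings,
    side = if (!is.null(meta$side) && meta$side != "NA") meta$side else NULL,
    hemisphere_id = if (nchar(patient)) patient else NULL,
    configuration_id = if (!is.null(meta$cfg) && meta$cfg != "NA") meta$cfg
                       else NULL,
    truth = NULL
  ), class = "dbs_recording")
}
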