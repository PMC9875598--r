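#' EEG montages and channel roles
#'
#' A recording montage is a data frame with one row per channel carrying the
#' 10-20 label and its role in the pipeline: `"scalp"` for recording
#' channels, `"ipg_trigger"` for the surface channel over the implantable
#' pulse generator (EXG1, used to time-lock epochs), and
#' `"mastoid_template"` for the two mastoid channels (EXG2/EXG3) that see
#' the stimulation artifact but negligible neural response and therefore
#' provide the subtraction template.
#'
#' `montage_biosemi64()` is the full 64-channel 10-20 layout of a BioSemi
#' ActiveTwo system plus the three auxiliary channels. `montage_reduced()`
#' is a 16-scalp-channel frontal subset (always containing F3/F4, AF7/AF8
#' and their spread neighbours) used to keep large simulated cohorts cheap;
#' it changes nothing downstream because all analysed channels are present.
#'
#' @return A data frame with columns `label` and `role`.
#' @export
montage_biosemi64 <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
    "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
    "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
    "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
    "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
    "P10", "PO8", "PO4", "O2"
  )
  rbind(
    data.frame(label = labels, role = "scalp", stringsAsFactors = FALSE),
    aux_channels()
  )
}

#' @rdname montage_biosemi64
#' @export
montage_reduced <- function() {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FC3",
    "Fp2", "AF8", "AF4", "F2", "F4", "F6", "F8", "FC4"
  )
  rbind(
    data.frame(label = labels, role = "scalp", stringsAsFactors = FALSE),
    aux_channels()
  )
}

aux_channels <- function() {
  data.frame(
    label = c("EXG1", "EXG2", "EXG3"),
    role = c("ipg_trigger", "mastoid_template", "mastoid_template"),
    stringsAsFactors = FALSE
  )
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage), all(c("label", "role") %in% names(montage)))
  if (anyDuplicated(montage$label)) stop("duplicate channel labels in montage")
  if (sum(montage$role == "ipg_trigger") != 1L)
    stop("montage must contain exactly one ipg_trigger channel")
  if (sum(montage$role == "mastoid_template") != 2L)
    stop("montage must contain exactly two mastoid_template channels")
  invisible(montage)
}

# Fixed spatial-spread pattern of the evoked responses: gain 1 on the primary
# channel plus fractional gains on fixed neighbours (no volume-conduction
# forward model; this is a mixing pattern, not physics).
ep_spread_pattern <- function(primary) {
  neighbours <- switch(primary,
    "F3"  = c(F1 = 0.40, F5 = 0.40, FC3 = 0.35, AF3 = 0.30),
    "F4"  = c(F2 = 0.40, F6 = 0.40, FC4 = 0.35, AF4 = 0.30),
    "AF7" = c(AF3 = 0.40, F7 = 0.40, Fp1 = 0.35, F5 = 0.30),
    "AF8" = c(AF4 = 0.40, F8 = 0.40, Fp2 = 0.35, F6 = 0.30),
    stop("no spread pattern defined for channel ", primary)
  )
  c(stats::setNames(1.0, primary), neighbours)
}

#' Analysis channel for a peak type and hemisphere
#'
#' Short-latency peaks (P3, ~3 ms) are read from the motor-cortex channel
#' ipsilateral to the stimulated hemisphere (F3 left / F4 right);
#' long-latency peaks (P10, ~10 ms) from the ipsilateral prefrontal channel
#' (AF7 left / AF8 right).
#'
#' @param side `"left"` or `"right"` stimulated hemisphere.
#' @param peak_type `"P3"` or `"P10"`.
#' @return A single channel label.
#' @export
peak_channel <- function(side, peak_type) {
  side <- match.arg(side, c("left", "right"))
  peak_type <- match.arg(peak_type, c("P3", "P10"))
  if (peak_type == "P3") {
    if (side == "left") "F3" else "F4"
  } else {
    if (side == "left") "AF7" else "AF8"
  }
}
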