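#' Directional DBS lead geometry (1-3-3-1)
#'
#' Builds the contact geometry of an eight-contact directional lead with a
#' distal ring, two triply segmented middle levels (120 degree spacing) and
#' a proximal ring, in right-anterior-superior (RAS) millimetre coordinates.
#' Contact height is 1.5 mm with 0.5 mm inter-level gaps, so level centres
#' sit at 0.75, 2.75, 4.75 and 6.75 mm above the lead tip. Contacts are
#' numbered distal to proximal, C1-C8 for left leads and C9-C16 for right
#' leads.
#'
#' @param tip RAS coordinates (mm) of the lead tip, length 3.
#' @param axis Unit direction of the lead shaft (distal to proximal);
#'   normalised internally.
#' @param rotation_deg Azimuthal rotation (degrees) of the first segment of
#'   each segmented level about the lead axis.
#' @param side `"left"` or `"right"`; sets the contact numbering offset.
#' @param contact_radius_mm Radial offset of segmented-contact centres from
#'   the shaft axis (half the 1.3 mm lead diameter by default).
#' @return An object of class `dbs_lead`: list with `contacts` (data frame
#'   of label, level, segment, x, y, z), `tip`, `axis`, `side`.
#' @export
lead_geometry <- function(tip = c(0, 0, 0), axis = c(0, 0, 1),
                          rotation_deg = 0, side = "left",
                          contact_radius_mm = 0.65) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(length(tip) == 3, length(axis) == 3)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("lead axis must be non-zero")
  axis <- axis / nrm

  # orthonormal frame (u, v) perpendicular to the shaft
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(
    axis[2] * u[3] - axis[3] * u[2],
    axis[3] * u[1] - axis[1] * u[3],
    axis[1] * u[2] - axis[2] * u[1]
  )

  level_z <- c(0.75, 2.75, 4.75, 6.75)
  offset <- if (side == "left") 0L else 8L
  rows <- list()
  k <- 0L
  for (level in 1:4) {
    centre <- tip + level_z[level] * axis
    if (level %in% c(2L, 3L)) {
      for (seg in 1:3) {
        ang <- (rotation_deg + (seg - 1) * 120) * pi / 180
        pos <- centre + contact_radius_mm * (cos(ang) * u + sin(ang) * v)
        k <- k + 1L
        rows[[k]] <- data.frame(
          label = paste0("C", k + offset), level = level, segment = seg,
          x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE
        )
      }
    } else {
      k <- k + 1L
      rows[[k]] <- data.frame(
        label = paste0("C", k + offset), level = level, segment = NA_integer_,
        x = centre[1], y = centre[2], z = centre[3], stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(contacts = do.call(rbind, rows), tip = tip, axis = axis, side = side),
    class = "dbs_lead"
  )
}

#' Enumerate the tested contact configurations of a 1-3-3-1 lead
#'
#' The monopolar protocol tests each of the eight physical contacts
#' individually plus the two segmented levels in ring mode (their three
#' segments driven with equal current), yielding ten configurations.
#' Ordering is deterministic: distal to proximal, with each ring placed
#' directly after its three segments.
#'
#' @param lead A `dbs_lead` from [lead_geometry()], or the string
#'   `"1-3-3-1"` to enumerate on a default left lead.
#' @return A data frame with one row per configuration: `configuration_id`,
#'   `type` (`"single"`/`"ring"`), `level`, and list-columns `contacts`
#'   (contact labels) and `weights` (current fractions, summing to 1).
#' @export
enumerate_configurations <- function(lead = "1-3-3-1") {
  if (is.character(lead)) {
    if (!identical(lead, "1-3-3-1"))
      stop("unsupported lead layout: ", lead,
           " (only the 1-3-3-1 directional lead is supported)")
    lead <- lead_geometry()
  }
  stopifnot(inherits(lead, "dbs_lead"))
  ct <- lead$contacts
  if (nrow(ct) != 8L || !all(table(ct$level) == c(1, 3, 3, 1)))
    stop("unsupported lead layout: expected 8 contacts in a 1-3-3-1 arrangement")

  ids <- character(0); types <- character(0); levels <- integer(0)
  contacts <- list(); weights <- list()
  add <- function(id, type, level, cts, w) {
    ids <<- c(ids, id); types <<- c(types, type); levels <<- c(levels, level)
    contacts[[length(contacts) + 1L]] <<- cts
    weights[[length(weights) + 1L]] <<- w
  }
  for (level in 1:4) {
    lev_ct <- ct[ct$level == level, , drop = FALSE]
    for (i in seq_len(nrow(lev_ct)))
      add(lev_ct$label[i], "single", level, lev_ct$label[i], 1)
    if (nrow(lev_ct) == 3L)
      add(paste0("R", level), "ring", level, lev_ct$label, rep(1 / 3, 3))
  }
  out <- data.frame(configuration_id = ids, type = types, level = levels,
                    stringsAsFactors = FALSE)
  out$contacts <- contacts
  out$weights <- weights
  out
}

configuration_weights <- function(lead, configuration_id) {
  cfgs <- enumerate_configurations(lead)
  i <- match(configuration_id, cfgs$configuration_id)
  if (is.na(i)) stop("unknown configuration_id: ", configuration_id)
  list(contacts = cfgs$contacts[[i]], weights = cfgs$weights[[i]])
}
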