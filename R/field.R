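#' Voxel grid specification
#'
#' Defines an isotropic voxel grid in RAS millimetre coordinates with a
#' voxel-centre convention: voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (i-1, j-1, k-1) * voxel_mm`.
#'
#' @param center RAS centre of the cube (mm).
#' @param size_mm Edge length of the cubic grid (mm).
#' @param voxel_mm Isotropic voxel size (mm).
#' @return A `dbs_grid` object: list with `origin`, `voxel_mm`, `dim`.
#' @export
grid_spec <- function(center = c(0, 0, 3.75), size_mm = 40, voxel_mm = 0.5) {
  stopifnot(voxel_mm > 0, size_mm > 0, length(center) == 3)
  n <- floor(size_mm / voxel_mm) + 1L
  origin <- center - (n - 1) / 2 * voxel_mm
  structure(list(origin = origin, voxel_mm = voxel_mm, dim = rep(n, 3L)),
            class = "dbs_grid")
}

#' Grid spanning a lead with a margin
#'
#' Convenience wrapper for [grid_spec()] centred on the mid-point of the
#' contact span of a lead.
#' @param lead A `dbs_lead`.
#' @inheritParams grid_spec
#' @export
grid_for_lead <- function(lead, size_mm = 40, voxel_mm = 0.5) {
  grid_spec(center = lead$tip + 3.75 * lead$axis, size_mm = size_mm,
            voxel_mm = voxel_mm)
}

grid_coords <- function(grid) {
  lapply(1:3, function(d) grid$origin[d] + (seq_len(grid$dim[d]) - 1) * grid$voxel_mm)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dim == b$dim) && abs(a$voxel_mm - b$voxel_mm) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

new_field_image <- function(values, grid, configuration_id = NA_character_,
                            current_mA = NA_real_) {
  structure(list(values = values, grid = grid,
                 configuration_id = configuration_id, current_mA = current_mA),
            class = "dbs_field")
}

new_mask_image <- function(values, grid) {
  if (!all(values %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(list(values = values, grid = grid), class = "dbs_mask")
}

#' Point-source electric-field magnitude on a voxel grid
#'
#' Models each active contact as a point current source at its centre in an
#' infinite homogeneous isotropic medium of conductivity `sigma_S_m`
#' (default 0.2 S/m, a standard grey-matter value). The field of one source
#' of current `I` at distance `r` has magnitude `I / (4 pi sigma r^2)`;
#' contributions of multiple sources are summed as vectors before taking
#' the magnitude. Distances below `clamp_mm` are clamped to `clamp_mm` so
#' the singularity at the contact centre stays finite. Output units are
#' V/mm. The field is exactly linear in `current_mA`.
#'
#' @param lead A `dbs_lead` from [lead_geometry()].
#' @param configuration A `configuration_id` (see
#'   [enumerate_configurations()]) or a named numeric vector of current
#'   weights per contact label (must sum to 1).
#' @param current_mA Total stimulation current (mA); 1 mA for overlap
#'   scoring.
#' @param grid A `dbs_grid`; default encloses the lead with a 40 mm cube.
#' @param sigma_S_m Medium conductivity (S/m).
#' @param clamp_mm Singularity clamp radius (mm).
#' @return A `dbs_field` whose `values` are a 3-D array of field magnitude
#'   in V/mm.
#' @export
electric_field <- function(lead, configuration, current_mA = 1,
                           grid = grid_for_lead(lead), sigma_S_m = 0.2,
                           clamp_mm = 0.2) {
  stopifnot(inherits(lead, "dbs_lead"), current_mA >= 0)
  if (is.character(configuration)) {
    cw <- configuration_weights(lead, configuration)
    weights <- stats::setNames(cw$weights, cw$contacts)
    cfg_id <- configuration
  } else {
    weights <- configuration
    cfg_id <- NA_character_
  }
  weights <- weights[weights != 0]
  if (length(weights) == 0) stop("configuration has zero total weight")
  if (abs(sum(weights) - 1) > 1e-9) stop("configuration weights must sum to 1")

  ct <- lead$contacts
  idx <- match(names(weights), ct$label)
  if (anyNA(idx)) stop("unknown contact label(s): ",
                       paste(names(weights)[is.na(idx)], collapse = ", "))

  cc <- grid_coords(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  # voxel coordinates, recycled in array order (x fastest)
  X <- rep(cc[[1]], times = ny * nz)
  Y <- rep(rep(cc[[2]], each = nx), times = nz)
  Z <- rep(cc[[3]], each = nx * ny)

  Ex <- numeric(length(X)); Ey <- numeric(length(X)); Ez <- numeric(length(X))
  I_A <- current_mA * 1e-3
  for (j in seq_along(idx)) {
    dx <- X - ct$x[idx[j]]; dy <- Y - ct$y[idx[j]]; dz <- Z - ct$z[idx[j]]
    r <- sqrt(dx^2 + dy^2 + dz^2)            # mm
    r_eff <- pmax(r, clamp_mm)
    # magnitude I/(4 pi sigma r^2) with r in metres, direction (dx,dy,dz)/r
    mag <- weights[j] * I_A / (4 * pi * sigma_S_m * (r_eff * 1e-3)^2)
    scale <- ifelse(r > 0, mag / r, 0)       # at r == 0 direction undefined
    Ex <- Ex + scale * dx
    Ey <- Ey + scale * dy
    Ez <- Ez + scale * dz
    # voxels exactly on a source centre: assign clamp magnitude radially along z
    at0 <- which(r == 0)
    if (length(at0)) Ez[at0] <- Ez[at0] + mag[at0]
  }
  vals <- array(sqrt(Ex^2 + Ey^2 + Ez^2) / 1000, dim = grid$dim)  # V/m -> V/mm
  new_field_image(vals, grid, cfg_id, current_mA)
}

#' Ring-mode field of a segmented level
#'
#' Equivalent to [electric_field()] with weight 1/3 on each of the three
#' segments of the requested level.
#'
#' @inheritParams electric_field
#' @param level Segmented level, 2 or 3.
#' @export
ring_mode_field <- function(lead, level, current_mA = 1,
                            grid = grid_for_lead(lead), sigma_S_m = 0.2,
                            clamp_mm = 0.2) {
  if (!level %in% c(2, 3))
    stop("level ", level, " is not segmented; ring mode needs level 2 or 3")
  ct <- lead$contacts[lead$contacts$level == level, ]
  w <- stats::setNames(rep(1 / 3, 3), ct$label)
  f <- electric_field(lead, w, current_mA, grid, sigma_S_m, clamp_mm)
  f$configuration_id <- paste0("R", level)
  f
}

#' Overlap of an electric field with a binary mask
#'
#' Multiplies the field with the mask voxel-wise and sums, i.e. the total
#' field mass (summed V/mm) inside the mask. Field and mask must live on
#' the identical grid; no resampling is attempted.
#'
#' @param field A `dbs_field`.
#' @param mask A `dbs_mask`.
#' @return The scalar overlap score (summed V/mm; >= 0).
#' @export
overlap_score <- function(field, mask) {
  stopifnot(inherits(field, "dbs_field"), inherits(mask, "dbs_mask"))
  if (!same_grid(field$grid, mask$grid))
    stop("field and mask are not on the same voxel grid")
  sum(field$values * mask$values)
}

#' Ellipsoidal binary mask on a grid
#'
#' Synthetic stand-ins for atlas structures (the motor sweet spot and the
#' substantia nigra): voxels whose centres fall inside the ellipsoid are 1.
#'
#' @param grid A `dbs_grid`.
#' @param center Ellipsoid centre (RAS mm).
#' @param semiaxes Semi-axis lengths (mm), length 3.
#' @return A `dbs_mask`.
#' @export
ellipsoid_mask <- function(grid, center, semiaxes) {
  stopifnot(length(center) == 3, length(semiaxes) == 3, all(semiaxes > 0))
  cc <- grid_coords(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  X <- rep(cc[[1]], times = ny * nz)
  Y <- rep(rep(cc[[2]], each = nx), times = nz)
  Z <- rep(cc[[3]], each = nx * ny)
  inside <- ((X - center[1]) / semiaxes[1])^2 +
    ((Y - center[2]) / semiaxes[2])^2 +
    ((Z - center[3]) / semiaxes[3])^2 <= 1
  new_mask_image(array(as.numeric(inside), dim = grid$dim), grid)
}
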