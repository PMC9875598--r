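#' Generative effect parameters of the synthetic cohort
#'
#' Ground-truth structure linking field overlap and evoked-response
#' couplings to monopolar-review outcomes. For a configuration with
#' normalised sweet-spot overlap `ov` (0-1 within hemisphere) and P10
#' coupling `p10c` (microvolts), the noise-free outcomes are
#'
#' \preformatted{
#'   tTW = ttw_intercept + ttw_overlap_slope * ov - ttw_p10_slope * p10c
#'   bTW = btw_intercept - btw_overlap_slope * ov + btw_p10_slope * p10c
#' }
#'
#' plus a hemisphere random intercept (SD `intercept_sd_mA`, independent
#' for tTW and bTW) and residual noise (SD `residual_sd_mA`), clipped at
#' 0 mA, with TW = tTW - bTW floored at 0. Couplings are monotone in the
#' mask overlaps: P3 linear in normalised sweet-spot overlap (peak
#' `p3_max_uV`), P10 a concave power (`p10_gamma`) of normalised
#' substantia-nigra overlap (peak `p10_max_uV`), so that dorsal contacts
#' retain a detectable P10. Couplings are expressed at the reference
#' intensity `reference_mA`; responses scale linearly with intensity above
#' `threshold_mA` and vanish below it (sub-threshold 0.5 mA control).
#'
#' @param ... Named overrides of the defaults listed above.
#' @return An `ep_effect` parameter list.
#' @export
effect_params <- function(...) {
  p <- list(
    p3_max_uV = 4, p10_max_uV = 6, p10_gamma = 0.5,
    ttw_intercept = 3.0, ttw_overlap_slope = 2.5, ttw_p10_slope = 0.25,
    btw_intercept = 1.2, btw_overlap_slope = 0.8, btw_p10_slope = 0.2,
    intercept_sd_mA = 0.5, residual_sd_mA = 0.5,
    threshold_mA = 1, reference_mA = 3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown effect parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (p$intercept_sd_mA < 0 || p$residual_sd_mA < 0)
    stop("standard deviations must be >= 0")
  slopes <- c(p$ttw_overlap_slope, p$ttw_p10_slope,
              p$btw_overlap_slope, p$btw_p10_slope)
  if (any(slopes < 0))
    stop("slopes are magnitudes with fixed sign structure and must be >= 0")
  if (p$p3_max_uV < 0 || p$p10_max_uV < 0) stop("couplings must be >= 0")
  if (p$reference_mA <= p$threshold_mA)
    stop("reference intensity must exceed the activation threshold")
  structure(p, class = "ep_effect")
}

#' Synthetic hemisphere anatomy: lead pose, masks, field overlaps
#'
#' Places a directional lead with a per-hemisphere pose perturbation in a
#' template space whose origin is the nominal lead tip, builds ellipsoidal
#' stand-ins for the motor sweet spot (dorsolateral, fixed in template
#' space) and the substantia nigra (ventral to the nominal trajectory),
#' and scores the 1 mA electric-field overlap of all ten contact
#' configurations with both masks.
#'
#' @param side `"left"` or `"right"`.
#' @param tip_offset_mm Lead tip displacement from the nominal target
#'   (mm, RAS); this is the per-hemisphere anatomical variability.
#' @param rotation_deg Azimuthal rotation of segment 1.
#' @param voxel_mm,size_mm Field grid resolution and extent.
#' @param sigma_S_m Medium conductivity for the field model.
#' @param sweet_center,sweet_semiaxes,sn_center,sn_semiaxes Mask geometry
#'   (mm, template space).
#' @return A `dbs_anatomy` list: `lead`, `grid`, `sweet_mask`, `sn_mask`,
#'   and `overlaps` (data frame with raw and within-hemisphere-normalised
#'   overlap per configuration).
#' @export
hemisphere_anatomy <- function(side = "left", tip_offset_mm = c(0, 0, 0),
                               rotation_deg = 0, voxel_mm = 0.5,
                               size_mm = 40, sigma_S_m = 0.2,
                               sweet_center = c(1.5, 0.5, 6.0),
                               sweet_semiaxes = c(2.5, 2.0, 3.5),
                               sn_center = c(0, 0, -2.5),
                               sn_semiaxes = c(3.0, 2.5, 3.0)) {
  lead <- lead_geometry(tip = tip_offset_mm, axis = c(0, 0, 1),
                        rotation_deg = rotation_deg, side = side)
  grid <- grid_spec(center = c(0, 0, 3.75), size_mm = size_mm,
                    voxel_mm = voxel_mm)
  sweet <- ellipsoid_mask(grid, sweet_center, sweet_semiaxes)
  # the substantia nigra sits ventral to the lead trajectory; it follows the
  # lead's lateral offset so its overlap gradient stays axial (see vignette)
  sn <- ellipsoid_mask(grid, sn_center + c(tip_offset_mm[1:2], 0), sn_semiaxes)

  cfgs <- enumerate_configurations(lead)
  ov_sweet <- numeric(nrow(cfgs)); ov_sn <- numeric(nrow(cfgs))
  for (i in seq_len(nrow(cfgs))) {
    w <- stats::setNames(cfgs$weights[[i]], cfgs$contacts[[i]])
    f <- electric_field(lead, w, current_mA = 1, grid = grid,
                        sigma_S_m = sigma_S_m)
    ov_sweet[i] <- overlap_score(f, sweet)
    ov_sn[i] <- overlap_score(f, sn)
  }
  overlaps <- data.frame(
    configuration_id = cfgs$configuration_id,
    overlap = ov_sweet,
    sn_overlap = ov_sn,
    overlap_norm = if (max(ov_sweet) > 0) ov_sweet / max(ov_sweet) else ov_sweet,
    sn_norm = if (max(ov_sn) > 0) ov_sn / max(ov_sn) else ov_sn,
    stringsAsFactors = FALSE
  )
  structure(list(lead = lead, grid = grid, sweet_mask = sweet, sn_mask = sn,
                 overlaps = overlaps, side = side),
            class = "dbs_anatomy")
}

#' Simulate one hemisphere: ground truth and monopolar-review outcomes
#'
#' Derives deterministic evoked-response couplings from the hemisphere's
#' anatomy (so identical anatomy gives identical ground truth regardless
#' of seed), then draws hemisphere random intercepts and per-configuration
#' residual noise to produce the monopolar-review record of each of the
#' ten configurations. Outcomes are clipped at 0 mA and the therapeutic
#' window rule TW = max(tTW - bTW, 0) is applied. The fixed spatial
#' pattern of the stimulation artifact (per-channel microvolt scale at
#' 1 mA) is also drawn here, once per hemisphere.
#'
#' @param hemisphere_id Identifier string.
#' @param anatomy A `dbs_anatomy` from [hemisphere_anatomy()].
#' @param effect An [effect_params()] list.
#' @param has_p3_source,has_p10_source If `FALSE`, all couplings of that
#'   peak are 0 (lead too far from the generating structure).
#' @param seed Integer seed for the stochastic part (intercepts, residual
#'   noise, artifact pattern).
#' @param montage Montage whose channels need artifact scales.
#' @return List with `ground_truth` (couplings, overlaps, intercepts,
#'   artifact scales, clinical configuration and screen intensities) and
#'   `review` (data frame: hemisphere_id, configuration_id, bTW_mA,
#'   tTW_mA, TW_mA).
#' @export
simulate_hemisphere <- function(hemisphere_id, anatomy, effect = effect_params(),
                                has_p3_source = TRUE, has_p10_source = TRUE,
                                seed = 1, montage = "biosemi64") {
  stopifnot(inherits(anatomy, "dbs_anatomy"), inherits(effect, "ep_effect"))
  montage <- resolve_montage(montage)
  ov <- anatomy$overlaps

  p3c <- if (has_p3_source) effect$p3_max_uV * ov$overlap_norm else numeric(nrow(ov))
  p10c <- if (has_p10_source) effect$p10_max_uV * ov$sn_norm^effect$p10_gamma
          else numeric(nrow(ov))
  # the side-effect-related coupling entering the outcome model is anatomical
  # (substantia-nigra recruitment), present whether or not a measurable P10
  # cortical source exists; the source flag only gates what the EEG sees
  p10_anat <- effect$p10_max_uV * ov$sn_norm^effect$p10_gamma

  set.seed(seed)
  u_t <- stats::rnorm(1, 0, effect$intercept_sd_mA)
  u_b <- stats::rnorm(1, 0, effect$intercept_sd_mA)
  n <- nrow(ov)
  ttw <- effect$ttw_intercept + effect$ttw_overlap_slope * ov$overlap_norm -
    effect$ttw_p10_slope * p10_anat + u_t +
    stats::rnorm(n, 0, effect$residual_sd_mA)
  btw <- effect$btw_intercept - effect$btw_overlap_slope * ov$overlap_norm +
    effect$btw_p10_slope * p10_anat + u_b +
    stats::rnorm(n, 0, effect$residual_sd_mA)
  ttw <- pmax(ttw, 0)
  btw <- pmax(btw, 0)
  tw <- pmax(ttw - btw, 0)

  scalp <- montage$role == "scalp"
  scales <- numeric(nrow(montage))
  scales[scalp] <- stats::runif(sum(scalp), 50, 150)
  scales[montage$role == "mastoid_template"] <- stats::runif(2, 375, 750)
  scales[montage$role == "ipg_trigger"] <- 2000
  names(scales) <- montage$label

  clin_i <- which.max(ov$overlap)
  clin_cfg <- ov$configuration_id[clin_i]
  # screen intensities: sub-threshold control, rigidity-suppression
  # intensity (bTW of the clinical configuration) and the highest tolerated
  # intensity (its tTW), in the clinic's 0.1 mA resolution
  intensities <- c(0.5,
                   max(round(btw[clin_i], 1), 0.6),
                   max(round(ttw[clin_i], 1), 1.5))

  review <- data.frame(
    hemisphere_id = hemisphere_id,
    configuration_id = ov$configuration_id,
    bTW_mA = btw, tTW_mA = ttw, TW_mA = tw,
    stringsAsFactors = FALSE
  )
  ground_truth <- structure(list(
    hemisphere_id = hemisphere_id,
    side = anatomy$side,
    has_p3_source = has_p3_source,
    has_p10_source = has_p10_source,
    couplings = data.frame(
      configuration_id = ov$configuration_id,
      p3_coupling_uV = p3c, p10_coupling_uV = p10c,
      overlap = ov$overlap, overlap_norm = ov$overlap_norm,
      sn_overlap = ov$sn_overlap, sn_norm = ov$sn_norm,
      stringsAsFactors = FALSE
    ),
    random_intercepts_mA = c(tTW = u_t, bTW = u_b),
    artifact_scales_uV = scales,
    clinical_configuration = clin_cfg,
    screen_intensities_mA = intensities,
    effect = effect
  ), class = "dbs_hemisphere_truth")
  list(ground_truth = ground_truth, review = review)
}
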