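#' Cohort run configuration
#'
#' One flat configuration drives an end-to-end run; there are no hidden
#' defaults elsewhere. The recording-fidelity defaults mirror the
#' acquisition protocol (16,384 Hz, 50 s of 10 Hz stimulation giving 500
#' epochs, 64-channel montage); large simulated cohorts in tests typically
#' lower `fs`, `duration_s` and the montage, which changes runtime but not
#' the structure of any downstream count.
#'
#' @param ... Named overrides of: `n_hemispheres` (12), `n_p3_missing`
#'   (3), `n_p10_missing` (1), `fs` (16384), `duration_s` (50), `montage`
#'   (`"biosemi64"`), `noise_rms_uV` (4), `onset_s` (0.05),
#'   `tip_jitter_mm` (0.5), `screen_alpha` (0.05), `interp_ms`, `fit_ms`,
#'   `window_ms`, `field` (list: `voxel_mm`, `size_mm`, `sigma_S_m`),
#'   `effect` (list passed to [effect_params()]), `seed` (1).
#' @return A validated `dbsep_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_hemispheres = 12L, n_p3_missing = 3L, n_p10_missing = 1L,
    fs = 16384, duration_s = 50, montage = "biosemi64",
    noise_rms_uV = 2, onset_s = 0.05, tip_jitter_mm = 0.5,
    screen_alpha = 0.05,
    interp_ms = c(-0.1, 1.5), fit_ms = c(-0.1, 8), window_ms = c(-1, 99),
    field = list(voxel_mm = 0.5, size_mm = 40, sigma_S_m = 0.2),
    effect = list(),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    if (nm %in% c("field", "effect")) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_hemispheres < 1) stop("config needs at least 1 hemisphere")
  if (cfg$n_p3_missing + 0 > cfg$n_hemispheres ||
      cfg$n_p10_missing > cfg$n_hemispheres)
    stop("more source-less hemispheres than hemispheres")
  if (cfg$screen_alpha <= 0 || cfg$screen_alpha >= 1)
    stop("screen_alpha must lie in (0, 1)")
  if (cfg$duration_s <= 0 || cfg$fs <= 0) stop("fs and duration must be > 0")
  do.call(effect_params, cfg$effect)  # validates effect block
  structure(cfg, class = c("dbsep_config", "list"))
}

#' Read a cohort configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep the defaults of
#' [cohort_config()].
#' @param path YAML file path.
#' @return A `dbsep_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(cohort_config, y)
}

# deterministic per-stage seeds derived from the master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the cohort ground truth (no EEG rendering)
#'
#' Places every hemisphere's anatomy, assigns which hemispheres lack a P3
#' or P10 cortical source, and generates ground truth plus
#' monopolar-review outcomes. This is the cheap half of the generator; EEG
#' recordings are rendered per configuration on demand.
#'
#' @param config A [cohort_config()].
#' @return List of per-hemisphere lists (`ground_truth`, `review`,
#'   `anatomy`).
#' @export
simulate_cohort <- function(config) {
  config <- validate_config(config)
  n <- config$n_hemispheres
  seeds <- derive_seeds(config$seed, 3L * n + 2L)
  set.seed(seeds[1])
  p3_missing <- sample.int(n, config$n_p3_missing)
  set.seed(seeds[2])
  p10_missing <- sample.int(n, config$n_p10_missing)
  sides <- rep(c("left", "right"), length.out = n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[2L + i])
    tip <- stats::rnorm(3, 0, config$tip_jitter_mm)
    rot <- stats::runif(1, -60, 60)
    anatomy <- hemisphere_anatomy(
      side = sides[i], tip_offset_mm = tip, rotation_deg = rot,
      voxel_mm = config$field$voxel_mm, size_mm = config$field$size_mm,
      sigma_S_m = config$field$sigma_S_m
    )
    sim <- simulate_hemisphere(
      hemisphere_id = sprintf("h%02d", i), anatomy = anatomy,
      effect = do.call(effect_params, config$effect),
      has_p3_source = !(i %in% p3_missing),
      has_p10_source = !(i %in% p10_missing),
      seed = seeds[2L + n + i], montage = config$montage
    )
    out[[i]] <- list(ground_truth = sim$ground_truth, review = sim$review,
                     anatomy = anatomy)
  }
  out
}

#' Run the full pipeline on a simulated cohort
#'
#' For every hemisphere: render the per-configuration recordings at the
#' highest tolerated intensity, preprocess them in both analysis bands,
#' extract P3/P10 peaks, run the three-intensity screen on the clinical
#' configuration, score field overlaps, assemble the group table, fit the
#' full model grid and compare models per response by AIC. Deterministic
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory; when given, the group table,
#'   per-model fits, comparison tables, a text report and a provenance
#'   manifest are written there.
#' @return List: `hemispheres`, `peaks`, `screen`, `overlaps`, `review`,
#'   `group_table`, `fits`, `comparisons`, `report`, `config`.
#' @export
run_cohort <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  hemis <- simulate_cohort(config)
  n <- length(hemis)
  rec_seeds <- derive_seeds(config$seed + 1L, n * 12L)

  peaks <- list(); screens <- list()
  for (i in seq_len(n)) {
    gt <- hemis[[i]]$ground_truth
    cfg_ids <- gt$couplings$configuration_id
    I3 <- gt$screen_intensities_mA[3]
    clin <- gt$clinical_configuration

    clin_sets <- NULL
    for (j in seq_along(cfg_ids)) {
      rec <- simulate_recording(
        gt, cfg_ids[j], stim_settings(10, 60, I3),
        duration_s = config$duration_s, fs = config$fs,
        montage = config$montage, noise_rms_uV = config$noise_rms_uV,
        onset_s = config$onset_s, seed = rec_seeds[(i - 1L) * 12L + j]
      )
      sets <- preprocess_recording(rec, interp_ms = config$interp_ms,
                                   fit_ms = config$fit_ms,
                                   window_ms = config$window_ms)
      for (pt in c("P3", "P10")) {
        ev <- average_epochs(sets[[peak_band(pt)]])
        peaks[[length(peaks) + 1L]] <- extract_peak(ev, pt)
      }
      if (cfg_ids[j] == clin) clin_sets <- sets
    }

    # screen recordings at the control and rigidity intensities; the
    # highest-intensity set is reused from the main pass
    lower <- lapply(1:2, function(m) {
      rec <- simulate_recording(
        gt, clin, stim_settings(10, 60, gt$screen_intensities_mA[m]),
        duration_s = config$duration_s, fs = config$fs,
        montage = config$montage, noise_rms_uV = config$noise_rms_uV,
        onset_s = config$onset_s, seed = rec_seeds[(i - 1L) * 12L + 10L + m]
      )
      preprocess_recording(rec, interp_ms = config$interp_ms,
                           fit_ms = config$fit_ms,
                           window_ms = config$window_ms)
    })
    for (pt in c("P3", "P10")) {
      band <- peak_band(pt)
      sets3 <- list(lower[[1]][[band]], lower[[2]][[band]], clin_sets[[band]])
      sc <- screen_hemisphere(sets3, pt, alpha = config$screen_alpha)
      screens[[length(screens) + 1L]] <- data.frame(
        hemisphere_id = gt$hemisphere_id, peak_type = pt,
        F = sc$F, p = sc$p, include = sc$include,
        has_source = if (pt == "P3") gt$has_p3_source else gt$has_p10_source,
        stringsAsFactors = FALSE
      )
    }
  }
  peaks <- do.call(rbind, peaks)
  screen <- do.call(rbind, screens)

  inc <- stats::setNames(screen$include,
                         paste(screen$hemisphere_id, screen$peak_type))
  peaks$screen_p <- screen$p[match(paste(peaks$hemisphere_id, peaks$peak_type),
                                   paste(screen$hemisphere_id, screen$peak_type))]
  peaks$included <- inc[paste(peaks$hemisphere_id, peaks$peak_type)]

  overlaps <- do.call(rbind, lapply(hemis, function(h)
    data.frame(hemisphere_id = h$ground_truth$hemisphere_id,
               configuration_id = h$ground_truth$couplings$configuration_id,
               overlap = h$ground_truth$couplings$overlap,
               stringsAsFactors = FALSE)))
  review <- do.call(rbind, lapply(hemis, function(h) h$review))

  group_table <- build_group_table(peaks, overlaps, review)
  fits <- fit_all_models(group_table, on_error = "keep")
  ok <- !vapply(fits, inherits, logical(1), "dbsep_lmm_error")
  comparisons <- lapply(c(tTW = "tTW", bTW = "bTW", TW = "TW"), function(r) {
    sel <- fits[ok & vapply(fits, function(f) f$response,
                            character(1)) == r]
    if (length(sel)) compare_models(sel) else NULL
  })
  report <- model_report(fits)

  result <- list(hemispheres = hemis, peaks = peaks, screen = screen,
                 overlaps = overlaps, review = review,
                 group_table = group_table, fits = fits,
                 comparisons = comparisons, report = report, config = config)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f)
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(result$group_table, "group_table.csv")
  wcsv(result$review, "review.csv")
  wcsv(result$overlaps, "overlaps.csv")
  wcsv(result$peaks, "peaks.csv")
  wcsv(result$screen, "screen.csv")
  fit_ok <- result$fits[!vapply(result$fits, inherits, logical(1),
                                "dbsep_lmm_error")]
  coefs <- do.call(rbind, lapply(fit_ok, function(f) {
    d <- f$coefficients
    d$formula <- f$formula; d$AIC <- f$AIC
    d$R2_conditional <- f$R2_conditional; d$R2_marginal <- f$R2_marginal
    d$n <- f$n; d$singular <- f$singular
    d
  }))
  wcsv(coefs, "model_fits.csv")
  for (r in names(result$comparisons))
    if (!is.null(result$comparisons[[r]]))
      wcsv(result$comparisons[[r]], paste0("comparison_", r, ".csv"))
  writeLines(result$report, file.path(out_dir, "report.txt"))

  cfg_yaml <- yaml::as.yaml(unclass(result$config))
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  manifest <- list(
    package = "dbsep",
    version = as.character(utils::packageVersion("dbsep")),
    r_version = R.version.string,
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = result$config$seed,
    n_rows = nrow(result$group_table)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Fast table-level cohort simulation for model validation
#'
#' Generates group tables straight from the generative model, bypassing
#' the EEG rendering: measured amplitudes are the ground-truth couplings
#' plus absolute measurement noise, and the intensity screen is assumed to
#' recover the configured source pattern. Used for parameter-recovery
#' studies where hundreds of replicates are needed.
#'
#' @param anatomies List of `dbs_anatomy` (reused across replicates; the
#'   expensive field computation happens once).
#' @param effect An [effect_params()] list.
#' @param seed Integer seed for outcomes and measurement noise.
#' @param p3_missing,p10_missing Integer indices of hemispheres without
#'   the corresponding source.
#' @param amplitude_noise_uV SD of the amplitude measurement noise.
#' @return A group table as from [build_group_table()].
#' @export
simulate_group_table <- function(anatomies, effect = effect_params(), seed = 1,
                                 p3_missing = integer(0),
                                 p10_missing = integer(0),
                                 amplitude_noise_uV = 0.3) {
  n <- length(anatomies)
  seeds <- derive_seeds(seed, n + 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_hemisphere(
      hemisphere_id = sprintf("h%02d", i), anatomy = anatomies[[i]],
      effect = effect,
      has_p3_source = !(i %in% p3_missing),
      has_p10_source = !(i %in% p10_missing),
      seed = seeds[i], montage = "reduced"
    )
    cp <- sim$ground_truth$couplings
    m <- nrow(cp)
    set.seed(seeds[n + 1L] + i)
    p3 <- if (i %in% p3_missing) NA_real_ else
      abs(cp$p3_coupling_uV + stats::rnorm(m, 0, amplitude_noise_uV))
    p10 <- if (i %in% p10_missing) NA_real_ else
      abs(cp$p10_coupling_uV + stats::rnorm(m, 0, amplitude_noise_uV))
    d <- sim$review
    d$overlap <- cp$overlap
    d$P3_uV <- p3
    d$P10_uV <- p10
    rows[[i]] <- d
  }
  do.call(rbind, rows)
}
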