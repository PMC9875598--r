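# Shared fixtures. Everything is generated in code; expensive objects are
# memoised per test run. Recording-fidelity parameters are scaled down
# from the hardware defaults (16,384 Hz / 50 s / 64 ch) to keep the suite
# fast; counts and contracts under test do not depend on the scale.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# small montage with all analysis channels and their template/trigger aux
tiny_montage <- function() {
  rbind(
    data.frame(label = c("F3", "F4", "AF7", "AF8", "AF3", "F5"),
               role = "scalp", stringsAsFactors = FALSE),
    data.frame(label = c("EXG1", "EXG2", "EXG3"),
               role = c("ipg_trigger", "mastoid_template", "mastoid_template"),
               stringsAsFactors = FALSE)
  )
}

scaled_config <- function(...) {
  cohort_config(fs = 8192, duration_s = 12.5, montage = "reduced",
                field = list(voxel_mm = 1), ...)
}

# one hemisphere with every source present, on the scaled grid
tiny_hemisphere <- function() {
  memo("tiny_hemisphere", {
    simulate_cohort(scaled_config(n_hemispheres = 1, n_p3_missing = 0,
                                  n_p10_missing = 0, seed = 7))[[1]]
  })
}

# default anatomy on the 0.5 mm grid (used by field tests)
default_anatomy <- function() memo("default_anatomy", hemisphere_anatomy())

# twelve scaled anatomies reused by the model-recovery suites
cohort_anatomies <- function() {
  memo("cohort_anatomies", {
    lapply(simulate_cohort(scaled_config(n_hemispheres = 12, n_p3_missing = 0,
                                         n_p10_missing = 0, seed = 5)),
           function(h) h$anatomy)
  })
}

# hand-built epoch set (epoch x channel x time), bypassing the recording
# stage, for unit tests of the preprocessing operators
make_epochs <- function(epochs, fs = 8192, montage = tiny_montage(),
                        window_ms = c(-1, 99),
                        flags = list(baseline_corrected = FALSE,
                                     artifact_removed = FALSE, band = "none"),
                        side = "left") {
  nt <- dim(epochs)[3]
  pre <- round(-window_ms[1] * 1e-3 * fs)
  structure(list(
    epochs = epochs, time_ms = (seq_len(nt) - 1 - pre) / fs * 1000,
    fs = fs, montage = montage, settings = stim_settings(10, 60, 2),
    side = side, hemisphere_id = "hx", configuration_id = "C1",
    flags = flags
  ), class = "dbs_epochs")
}

# deterministic group table generated straight from a linear mixed model,
# for unit tests of the fitting machinery (independent of the anatomy)
linear_table <- function(n_hemi = 6, n_cfg = 10, slope = 2, intercept_sd = 0,
                         resid_sd = 0, seed = 3) {
  set.seed(seed)
  d <- expand.grid(hemisphere_id = sprintf("h%02d", seq_len(n_hemi)),
                   configuration_id = sprintf("C%d", seq_len(n_cfg)),
                   stringsAsFactors = FALSE)
  d$P3_uV <- runif(nrow(d), 0, 4)
  d$P10_uV <- runif(nrow(d), 0, 4)
  d$overlap <- runif(nrow(d), 0, 80)
  u <- rnorm(n_hemi, 0, intercept_sd)
  d$tTW_mA <- 1 + slope * d$P3_uV + u[match(d$hemisphere_id,
                                            unique(d$hemisphere_id))] +
    rnorm(nrow(d), 0, resid_sd)
  d$bTW_mA <- 0
  d$TW_mA <- pmax(d$tTW_mA - d$bTW_mA, 0)
  d
}
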