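# trigger detection, epoching, baseline, artifact removal, band separation

make_recording <- function(duration_s = 12.5, fs = 8192, seed = 11,
                           noise_rms_uV = 4, configuration = "C5",
                           intensity = 5) {
  gt <- tiny_hemisphere()$ground_truth
  simulate_recording(gt, configuration, stim_settings(10, 60, intensity),
                     duration_s = duration_s, fs = fs,
                     montage = tiny_montage(), noise_rms_uV = noise_rms_uV,
                     seed = seed)
}

test_that("every trigger is detected within one sample of the true pulse", {
  rec <- memo("rec_main", make_recording())
  on <- detect_triggers(rec)
  expect_equal(length(on), length(rec$truth$pulse_idx))
  expect_lte(max(abs(on - rec$truth$pulse_idx)), 1)
  expect_true(all(diff(on) > 0))
})

test_that("an event-free trigger channel raises a no-triggers error", {
  rec <- make_recording(duration_s = 1, seed = 3)
  rec$samples[rec$montage$role == "ipg_trigger", ] <- 0
  expect_error(detect_triggers(rec), "no triggers")
})

test_that("jittered pulse timing triggers the interval-CV warning", {
  rec <- make_recording(duration_s = 2, seed = 4)
  trig <- which(rec$montage$role == "ipg_trigger")
  x <- numeric(ncol(rec$samples))
  set.seed(1)
  spikes <- round(cumsum(runif(15, 0.04, 0.16)) * rec$fs)
  spikes <- spikes[spikes <= length(x)]
  x[spikes] <- 5000
  rec$samples[trig, ] <- x + rnorm(length(x))
  expect_warning(detect_triggers(rec), "CV")
})

test_that("epoching honours the window and drops out-of-bounds onsets", {
  rec <- memo("rec_main", make_recording())
  on <- detect_triggers(rec)
  ep <- epoch_recording(rec, on)
  expect_equal(dim(ep$epochs)[1], 125L)
  expect_equal(dim(ep$epochs)[3], round(0.1 * rec$fs))
  expect_lt(abs(diff(range(ep$time_ms)) + 1000 / rec$fs - 100), 1000 / rec$fs)
  # an onset 0.2 ms after record start cannot fit the 1 ms baseline
  expect_message(
    ep2 <- epoch_recording(rec, c(round(0.0002 * rec$fs), on)),
    "dropped"
  )
  expect_equal(dim(ep2$epochs)[1], 125L)
  expect_error(epoch_recording(rec, integer(0)), "no onsets")
  expect_error(epoch_recording(rec, on, window_ms = c(-1, 50)))
})

test_that("epoching a constant record reproduces constants (slicing oracle)", {
  rec <- make_recording(duration_s = 1, seed = 5)
  rec$samples[] <- rep(seq_len(nrow(rec$samples)), ncol(rec$samples))
  ep <- epoch_recording(rec, c(5000, 6000))
  for (ch in seq_len(nrow(rec$samples)))
    expect_true(all(ep$epochs[, ch, ] == ch))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  mont <- tiny_montage()
  nt <- round(0.1 * 8192)
  ep <- make_epochs(array(7.5, dim = c(4, nrow(mont), nt)))
  bc <- baseline_correct(ep)
  expect_true(all(bc$epochs == 0))
  expect_true(bc$flags$baseline_corrected)
  expect_error(baseline_correct(bc), "already")

  # zero baseline, bump later: unchanged
  ep2 <- make_epochs(array(0, dim = c(2, nrow(mont), nt)))
  bump_idx <- which(ep2$time_ms > 5 & ep2$time_ms < 8)
  ep2$epochs[, , bump_idx] <- 3
  bc2 <- baseline_correct(ep2)
  expect_identical(bc2$epochs, ep2$epochs)

  # random epochs: recomputed baseline means vanish
  set.seed(8)
  ep3 <- make_epochs(array(rnorm(5 * nrow(mont) * nt), c(5, nrow(mont), nt)))
  bc3 <- baseline_correct(ep3)
  bl <- bc3$time_ms >= -1 & bc3$time_ms < 0
  resid <- apply(bc3$epochs[, , bl, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("an exactly scaled artifact is removed to numerical precision", {
  mont <- tiny_montage()
  fs <- 8192
  nt <- round(0.1 * fs)
  nep <- 6
  t_ms <- (seq_len(nt) - 1 - round(0.001 * fs)) / fs * 1000
  art <- ifelse(t_ms >= 0, exp(-pmax(t_ms, 0) / 0.8), 0) * 500
  ep <- array(0, c(nep, nrow(mont), nt))
  for (ch in which(mont$role == "scalp")) ep[, ch, ] <-
    matrix(3.7 * art, nep, nt, byrow = TRUE)
  for (ch in which(mont$role == "mastoid_template")) ep[, ch, ] <-
    matrix(art, nep, nt, byrow = TRUE)
  es <- make_epochs(ep, flags = list(baseline_corrected = TRUE,
                                     artifact_removed = FALSE, band = "none"))
  out <- remove_artifact(es)
  outside <- es$time_ms > 1.5
  expect_lt(max(abs(out$epochs[, mont$role == "scalp", outside])), 1e-6)
  expect_true(out$flags$artifact_removed)
  expect_error(remove_artifact(out), "already")
})

test_that("with zero scalp artifact the scalp data pass through", {
  mont <- tiny_montage()
  fs <- 8192
  nt <- round(0.1 * fs)
  t_ms <- (seq_len(nt) - 1 - round(0.001 * fs)) / fs * 1000
  art <- ifelse(t_ms >= 0, exp(-pmax(t_ms, 0) / 0.8), 0) * 800
  ep <- array(0, c(3, nrow(mont), nt))
  f3 <- which(mont$label == "F3")
  bump <- 2 * exp(-4 * log(2) * ((t_ms - 3) / 1.5)^2)
  ep[, f3, ] <- matrix(bump, 3, nt, byrow = TRUE)
  for (ch in which(mont$role == "mastoid_template")) ep[, ch, ] <-
    matrix(art, 3, nt, byrow = TRUE)
  es <- make_epochs(ep, flags = list(baseline_corrected = TRUE,
                                     artifact_removed = FALSE, band = "none"))
  out <- remove_artifact(es)
  outside <- es$time_ms > 1.5
  expect_lt(max(abs(out$epochs[, f3, outside] - ep[, f3, outside])), 0.05)
})

test_that("a zero-energy template raises the degenerate-template error", {
  mont <- tiny_montage()
  ep <- array(0, c(2, nrow(mont), round(0.1 * 8192)))
  ep[, which(mont$label == "F3"), 300] <- 1
  es <- make_epochs(ep, flags = list(baseline_corrected = TRUE,
                                     artifact_removed = FALSE, band = "none"))
  expect_error(remove_artifact(es), "degenerate")
  expect_error(remove_artifact(make_epochs(ep)), "baseline")
})

test_that("scalp-only additions outside the fit window pass through exactly", {
  # the operator is linear; an evoked bump supported beyond the template-fit
  # window leaves the fitted scale untouched, so R(A + E) = R(A) + E
  rec <- memo("rec_main", make_recording())
  ep <- baseline_correct(epoch_recording(rec, detect_triggers(rec)))
  f3 <- which(ep$montage$label == "F3")
  extra <- 4 * exp(-4 * log(2) * ((ep$time_ms - 40) / 5)^2)  # beyond 8 ms
  ep2 <- ep
  ep2$epochs[, f3, ] <- ep2$epochs[, f3, ] +
    matrix(extra, dim(ep$epochs)[1], length(extra), byrow = TRUE)
  r1 <- remove_artifact(ep)
  r2 <- remove_artifact(ep2)
  outside <- ep$time_ms > 1.5
  expect_equal(r2$epochs[, f3, outside],
               r1$epochs[, f3, outside] +
                 matrix(extra[outside], dim(ep$epochs)[1], sum(outside),
                        byrow = TRUE),
               tolerance = 1e-9)
})

test_that("artifact energy drops by >= 20 dB and the peak survives", {
  rec <- memo("rec_main", make_recording())
  ep <- baseline_correct(epoch_recording(rec, detect_triggers(rec)))
  f3 <- which(ep$montage$label == "F3")
  pre <- colMeans(ep$epochs[, f3, ])
  out <- remove_artifact(ep)
  post <- colMeans(out$epochs[, f3, ])
  early <- ep$time_ms >= 0 & ep$time_ms <= 2
  expect_gt(10 * log10(sum(pre[early]^2) / sum(post[early]^2)), 20)
  win <- ep$time_ms >= 2 & ep$time_ms <= 5
  expect_lt(abs(max(abs(post[win])) - rec$truth$p3_amp_uV) /
              rec$truth$p3_amp_uV, 0.10)
})

test_that("band separation is single-shot and order is enforced", {
  rec <- make_recording(duration_s = 2, seed = 6)
  ep <- baseline_correct(epoch_recording(rec, detect_triggers(rec)))
  ep <- remove_artifact(ep)
  n0 <- dim(ep$epochs)[1]
  sh <- bandpass_epochs(ep, "short_latency")
  expect_equal(sh$flags$band, "short_latency")
  expect_equal(dim(sh$epochs)[1], n0)  # epoch-count conservation
  expect_error(bandpass_epochs(sh, "long_latency"), "already set")
})

test_that("the preprocessing chain conserves epochs into both bands", {
  rec <- memo("rec_main", make_recording())
  sets <- preprocess_recording(rec)
  expect_named(sets, c("short_latency", "long_latency"))
  for (s in sets) {
    expect_equal(dim(s$epochs)[1], 125L)
    expect_true(s$flags$baseline_corrected)
    expect_true(s$flags$artifact_removed)
  }
})
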