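# evoked averaging, peak extraction and the intensity screen

evoked_from <- function(waveform, band = "short_latency", side = "left",
                        fs = 8192, n_epochs = 1) {
  # waveform: channel x time with tiny_montage() labels
  nt <- ncol(waveform)
  pre <- round(0.001 * fs)
  structure(list(
    waveform = waveform, time_ms = (seq_len(nt) - 1 - pre) / fs * 1000,
    fs = fs, montage = tiny_montage(), band = band, n_epochs = n_epochs,
    settings = stim_settings(10, 60, 3), side = side,
    hemisphere_id = "hx", configuration_id = "C1"
  ), class = "dbs_evoked")
}

blank_waveform <- function(fs = 8192) {
  nt <- round(0.1 * fs)
  matrix(0, nrow(tiny_montage()), nt,
         dimnames = list(tiny_montage()$label, NULL))
}

test_that("averaging is the pointwise mean with metadata carried through", {
  mont <- tiny_montage()
  nt <- round(0.1 * 8192)
  x <- array(rnorm(nrow(mont) * nt), c(1, nrow(mont), nt))
  ep <- make_epochs(x, flags = list(baseline_corrected = TRUE,
                                    artifact_removed = TRUE,
                                    band = "short_latency"))
  ev <- average_epochs(ep)
  expect_equal(unname(ev$waveform), x[1, , ])
  expect_equal(ev$n_epochs, 1L)
  expect_equal(ev$band, "short_latency")

  x2 <- array(0, c(2, nrow(mont), nt))
  x2[1, , ] <- x[1, , ]; x2[2, , ] <- -x[1, , ]
  ep2 <- make_epochs(x2, flags = ep$flags)
  expect_true(all(average_epochs(ep2)$waveform == 0))
})

test_that("the mean of noisy kernel copies converges at the 1/sqrt(n) rate", {
  set.seed(21)
  fs <- 8192; nt <- round(0.1 * fs); n <- 400
  mont <- tiny_montage()
  t_ms <- (seq_len(nt) - 1 - round(0.001 * fs)) / fs * 1000
  kernel <- 2 * exp(-4 * log(2) * ((t_ms - 3) / 1.5)^2)
  rms <- 1.5
  x <- array(rnorm(n * nrow(mont) * nt, sd = rms), c(n, nrow(mont), nt))
  f3 <- which(mont$label == "F3")
  x[, f3, ] <- x[, f3, ] + matrix(kernel, n, nt, byrow = TRUE)
  ev <- average_epochs(make_epochs(x, flags = list(baseline_corrected = TRUE,
                                                   artifact_removed = TRUE,
                                                   band = "short_latency")))
  expect_lt(max(abs(ev$waveform[f3, ] - kernel)), 3 * rms / sqrt(n) * 1.6)
})

test_that("analysis channels follow the ipsilateral mapping", {
  expect_equal(peak_channel("left", "P3"), "F3")
  expect_equal(peak_channel("right", "P3"), "F4")
  expect_equal(peak_channel("left", "P10"), "AF7")
  expect_equal(peak_channel("right", "P10"), "AF8")
  expect_error(peak_channel("medial", "P3"))
  ev <- evoked_from(blank_waveform())
  expect_equal(select_channel(ev, "P3"), "F3")
  ev$side <- NULL
  expect_error(select_channel(ev, "P3"), "side")
  ev2 <- evoked_from(blank_waveform()[1:3, , drop = FALSE], side = "right")
  expect_error(select_channel(ev2, "P10"), "missing")
})

test_that("peak extraction finds the windowed absolute maximum", {
  fs <- 8192
  w <- blank_waveform(fs)
  ev0 <- evoked_from(w, "short_latency")
  t_ms <- ev0$time_ms
  t3 <- t_ms[which.min(abs(t_ms - 3))]  # peak on a grid sample
  w["F3", ] <- 2 * exp(-4 * log(2) * ((t_ms - t3) / 1.5)^2)
  pk <- extract_peak(evoked_from(w), "P3")
  expect_equal(pk$amplitude_uV, 2, tolerance = 1e-9)
  expect_equal(pk$latency_ms, t3)
  expect_equal(pk$channel, "F3")

  # flat waveform: zero amplitude, tie broken to the window start
  pk0 <- extract_peak(ev0, "P3")
  expect_equal(pk0$amplitude_uV, 0)
  expect_equal(pk0$latency_ms, min(t_ms[t_ms >= 2]))

  # two bumps: the larger, later one wins
  w2 <- blank_waveform(fs)
  w2["F3", ] <- 1.9 * exp(-4 * log(2) * ((t_ms - 2.5) / 0.8)^2) +
    2.1 * exp(-4 * log(2) * ((t_ms - 4.2) / 0.8)^2)
  pk2 <- extract_peak(evoked_from(w2), "P3")
  expect_equal(pk2$amplitude_uV, max(abs(w2["F3", t_ms >= 2 & t_ms <= 5])))
  expect_lt(abs(pk2$latency_ms - 4.2), 0.1)

  # negative deflections count via the absolute value, unless disabled
  w3 <- blank_waveform(fs)
  t35 <- t_ms[which.min(abs(t_ms - 3.5))]
  t25 <- t_ms[which.min(abs(t_ms - 2.5))]
  w3["F3", ] <- -3 * exp(-4 * log(2) * ((t_ms - t35) / 1)^2) +
    1 * exp(-4 * log(2) * ((t_ms - t25) / 0.5)^2)
  win <- t_ms >= 2 & t_ms <= 5
  expect_equal(extract_peak(evoked_from(w3), "P3")$amplitude_uV,
               max(abs(w3["F3", win])))
  expect_equal(extract_peak(evoked_from(w3), "P3",
                            absolute = FALSE)$amplitude_uV,
               max(w3["F3", win]))
  expect_error(extract_peak(evoked_from(w3, "long_latency"), "P3"),
               "band mismatch")
})

test_that("peak extraction equals a brute-force scan on random waveforms", {
  set.seed(5)
  fs <- 8192
  for (r in 1:20) {
    w <- blank_waveform(fs)
    t_ms <- evoked_from(w)$time_ms
    w["AF7", ] <- rnorm(ncol(w))
    ev <- evoked_from(w, "long_latency")
    pk <- extract_peak(ev, "P10")
    idx <- which(t_ms >= 8 & t_ms <= 15)
    brute_amp <- -Inf; brute_lat <- NA
    for (i in idx) {
      if (abs(w["AF7", i]) > brute_amp) {
        brute_amp <- unname(abs(w["AF7", i])); brute_lat <- t_ms[i]
      }
    }
    expect_equal(pk$amplitude_uV, brute_amp)
    expect_equal(pk$latency_ms, brute_lat)
  }
})

test_that("amplitude is homogeneous of degree one in the waveform", {
  set.seed(9)
  w <- blank_waveform()
  w["F3", ] <- rnorm(ncol(w))
  base <- extract_peak(evoked_from(w), "P3")
  for (c_ in c(0.5, 2, 17)) {
    ws <- w; ws["F3", ] <- c_ * w["F3", ]
    pk <- extract_peak(evoked_from(ws), "P3")
    expect_equal(pk$amplitude_uV, c_ * base$amplitude_uV)
    expect_equal(pk$latency_ms, base$latency_ms)
  }
})

test_that("the intensity screen keeps its nominal size under the null", {
  set.seed(12)
  hits <- 0; B <- 400
  for (b in 1:B) {
    groups <- replicate(3, abs(rnorm(50)), simplify = FALSE)
    hits <- hits + intensity_screen(groups)$include
  }
  expect_gt(hits / B, 0.01)
  expect_lt(hits / B, 0.10)
})

test_that("the screen has full power at the prescribed effect sizes", {
  # means 0.1 / 1.0 / 2.0 with SD 0.5 and n = 400: the noncentral-F
  # noncentrality is n * sum((mu - mean(mu))^2) / sigma^2 ~ 2900, so power
  # is 1 to machine precision
  set.seed(13)
  for (b in 1:10) {
    groups <- list(rnorm(400, 0.1, 0.5), rnorm(400, 1, 0.5),
                   rnorm(400, 2, 0.5))
    sc <- intensity_screen(groups)
    expect_true(sc$include)
    expect_lt(sc$p, 1e-10)
  }
})

test_that("degenerate and undersized screens error", {
  expect_error(intensity_screen(list(c(0, 0), c(0, 0), c(0, 0))),
               "degenerate")
  expect_error(intensity_screen(list(1, c(1, 2), c(1, 2))), "at least 2")
  # F statistic agrees with the base-R ANOVA on one example
  set.seed(2)
  g <- list(rnorm(30), rnorm(30, 0.5), rnorm(30, 1))
  sc <- intensity_screen(g)
  d <- data.frame(y = unlist(g), f = factor(rep(1:3, each = 30)))
  ref <- stats::anova(stats::lm(y ~ f, d))
  expect_equal(sc$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(sc$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("per-epoch amplitudes are absolute values at the nearest sample", {
  mont <- tiny_montage()
  nt <- round(0.1 * 8192)
  x <- array(0, c(3, nrow(mont), nt))
  f3 <- which(mont$label == "F3")
  ep <- make_epochs(x)
  i <- which.min(abs(ep$time_ms - 3))
  x[, f3, i] <- c(-2, 1, 4)
  ep <- make_epochs(x)
  expect_equal(epoch_amplitudes(ep, "F3", 3), c(2, 1, 4))
  expect_error(epoch_amplitudes(ep, "Cz", 3), "not in montage")
})
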