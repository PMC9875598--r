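# group-table assembly, mixed-model fitting and AIC comparison

peaks_from_gt <- function(hemis, p3_excluded = character(0),
                          p10_excluded = character(0)) {
  do.call(rbind, lapply(hemis, function(h) {
    cp <- h$ground_truth$couplings
    hid <- h$ground_truth$hemisphere_id
    rbind(
      data.frame(hemisphere_id = hid, configuration_id = cp$configuration_id,
                 peak_type = "P3", amplitude_uV = cp$p3_coupling_uV,
                 included = !(hid %in% p3_excluded)),
      data.frame(hemisphere_id = hid, configuration_id = cp$configuration_id,
                 peak_type = "P10", amplitude_uV = cp$p10_coupling_uV,
                 included = !(hid %in% p10_excluded))
    )
  }))
}

cohort_pieces <- function() {
  memo("cohort_pieces", {
    anats <- cohort_anatomies()
    hemis <- lapply(seq_along(anats), function(i)
      simulate_hemisphere(sprintf("h%02d", i), anats[[i]], seed = 100 + i))
    hemis <- lapply(hemis, function(s)
      list(ground_truth = s$ground_truth, review = s$review))
    overlaps <- do.call(rbind, lapply(hemis, function(h)
      data.frame(hemisphere_id = h$ground_truth$hemisphere_id,
                 configuration_id = h$ground_truth$couplings$configuration_id,
                 overlap = h$ground_truth$couplings$overlap)))
    review <- do.call(rbind, lapply(hemis, function(h) h$review))
    list(hemis = hemis, overlaps = overlaps, review = review)
  })
}

test_that("the group table has one row per hemisphere x configuration", {
  cp <- cohort_pieces()
  tab <- build_group_table(peaks_from_gt(cp$hemis), cp$overlaps, cp$review)
  expect_equal(nrow(tab), 120L)
  expect_equal(sum(!is.na(tab$P3_uV)), 120L)
  expect_false(anyDuplicated(paste(tab$hemisphere_id,
                                   tab$configuration_id)) > 0)
})

test_that("screen exclusions produce the per-model row counts", {
  cp <- cohort_pieces()
  peaks <- peaks_from_gt(cp$hemis, p3_excluded = c("h01", "h02", "h03"),
                         p10_excluded = "h04")
  tab <- build_group_table(peaks, cp$overlaps, cp$review)
  expect_equal(nrow(tab), 120L)
  expect_equal(sum(!is.na(tab$P3_uV)), 90L)
  expect_equal(sum(!is.na(tab$P10_uV)), 110L)
  expect_equal(fit_lmm(tab, "tTW", "P3")$n, 90L)
  expect_equal(fit_lmm(tab, "tTW", "P10")$n, 110L)
  expect_equal(fit_lmm(tab, "tTW", "overlap")$n, 120L)
})

test_that("empty peak input leaves predictors missing and P3 fits error", {
  cp <- cohort_pieces()
  empty <- peaks_from_gt(cp$hemis)[0, ]
  tab <- build_group_table(empty, cp$overlaps, cp$review)
  expect_equal(nrow(tab), 120L)
  expect_true(all(is.na(tab$P3_uV)) && all(is.na(tab$P10_uV)))
  expect_error(fit_lmm(tab, "tTW", "P3"), "hemispheres")
  expect_s3_class(fit_lmm(tab, "tTW", "overlap"), "dbsep_lmm")
})

test_that("inconsistent inputs are rejected", {
  cp <- cohort_pieces()
  peaks <- peaks_from_gt(cp$hemis)
  expect_error(build_group_table(peaks, rbind(cp$overlaps, cp$overlaps[1, ]),
                                 cp$review), "duplicate")
  expect_error(build_group_table(rbind(peaks, peaks[1, ]), cp$overlaps,
                                 cp$review), "duplicate")
  bad_review <- cp$review
  bad_review$TW_mA[5] <- bad_review$TW_mA[5] + 1
  expect_error(build_group_table(peaks, cp$overlaps, bad_review),
               "TW = max")
})

test_that("a noise-free linear relation is fitted exactly", {
  tab <- linear_table(slope = 2)
  f <- fit_lmm(tab, "tTW", "P3")
  expect_equal(f$coefficients$estimate[f$coefficients$term == "P3"], 2,
               tolerance = 1e-6)
  expect_equal(f$R2_conditional, 1, tolerance = 1e-9)
  expect_equal(f$formula, "tTW ~ P3 + (1|hemisphere)")
})

test_that("fits are invariant to row order", {
  tab <- linear_table(slope = 1.5, intercept_sd = 0.5, resid_sd = 0.4,
                      seed = 7)
  f1 <- fit_lmm(tab, "tTW", c("P3", "overlap"))
  set.seed(1)
  f2 <- fit_lmm(tab[sample(nrow(tab)), ], "tTW", c("P3", "overlap"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$AIC, f2$AIC, tolerance = 1e-8)
})

test_that("insufficient grouping structure errors", {
  tab <- linear_table(n_hemi = 1)
  expect_error(fit_lmm(tab, "tTW", "P3"), "at least 2 hemispheres")
  tab2 <- linear_table(n_hemi = 3, n_cfg = 2)
  tab2 <- tab2[-1, ]
  expect_error(fit_lmm(tab2, "tTW", "P3"), "2 rows per hemisphere")
})

test_that("ML nesting holds: fuller models never lose likelihood", {
  for (seed in 1:3) {
    tab <- simulate_group_table(cohort_anatomies(), seed = seed,
                                amplitude_noise_uV = 0.3)
    for (resp in c("tTW", "bTW", "TW")) {
      red <- fit_lmm(tab, resp, "overlap")
      full <- fit_lmm(tab, resp, c("P10", "overlap"))
      expect_gte(full$logLik, red$logLik - 1e-6)
    }
  }
})

test_that("model comparison ranks by AIC and supports common rows", {
  tab <- simulate_group_table(cohort_anatomies(), seed = 42,
                              p3_missing = 1:3, amplitude_noise_uV = 0.3)
  f <- fit_lmm(tab, "tTW", "overlap")
  cmp_self <- compare_models(list(f, f))
  expect_equal(cmp_self$dAIC, c(0, 0))
  fits <- list(fit_lmm(tab, "tTW", "P3"), fit_lmm(tab, "tTW", "overlap"))
  expect_false(fits[[1]]$n == fits[[2]]$n)
  cmp <- compare_models(fits)
  expect_equal(sum(cmp$best), 1L)
  expect_equal(min(cmp$dAIC), 0)
  cmp_common <- compare_models(fits, common_rows = TRUE)
  expect_equal(cmp_common$n, c(90, 90))
  fb <- fit_lmm(tab, "bTW", "overlap")
  expect_error(compare_models(list(f, fb)), "share the response")
})

test_that("the model grid covers five blocks by three responses", {
  g <- model_grid()
  expect_equal(nrow(g), 15L)
  expect_setequal(unique(g$response), c("tTW", "bTW", "TW"))
  tab <- simulate_group_table(cohort_anatomies(), seed = 2,
                              amplitude_noise_uV = 0.3)
  fits <- fit_all_models(tab)
  expect_length(fits, 15L)
  rep_lines <- model_report(fits)
  expect_equal(sum(grepl("^== Predictors", rep_lines)), 5L)
  expect_equal(sum(grepl("Equation", rep_lines)), 5L)
  expect_true(any(grepl("tTW ~ P3 \\+ EF overlap", rep_lines)))
})

test_that("conditional R2 stays within [0, 1] across random tables", {
  for (seed in 4:8) {
    tab <- simulate_group_table(cohort_anatomies(), seed = seed,
                                amplitude_noise_uV = 0.5)
    f <- fit_lmm(tab, "TW", c("P3", "overlap"))
    expect_gte(f$R2_conditional, 0)
    expect_lte(f$R2_conditional, 1)
    expect_gte(f$R2_marginal, 0)
    expect_lte(f$R2_marginal, 1)
  }
})
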