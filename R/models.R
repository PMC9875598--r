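#' Assemble the group-level analysis table
#'
#' Inner-joins peak measurements, field-overlap scores and monopolar-review
#' outcomes on (hemisphere, configuration). Peak amplitudes of hemispheres
#' excluded by the intensity screen are set missing (per peak type, so a
#' hemisphere can contribute P10 rows but not P3 rows); rows with missing
#' predictors are excluded per model, not globally. The therapeutic-window
#' rule TW = max(tTW - bTW, 0) is re-checked against the input.
#'
#' @param peaks Data frame with columns `hemisphere_id`,
#'   `configuration_id`, `peak_type`, `amplitude_uV` and `included`
#'   (intensity-screen flag).
#' @param overlaps Data frame with `hemisphere_id`, `configuration_id`,
#'   `overlap`.
#' @param review Data frame with `hemisphere_id`, `configuration_id`,
#'   `bTW_mA`, `tTW_mA`, `TW_mA`.
#' @return A data frame with one row per hemisphere x configuration:
#'   outcomes, `P3_uV`, `P10_uV` (NA where screened out or unmeasured) and
#'   `overlap`.
#' @export
build_group_table <- function(peaks, overlaps, review) {
  key <- function(d) paste(d$hemisphere_id, d$configuration_id, sep = "//")
  if (anyDuplicated(key(overlaps))) stop("duplicate keys in overlap table")
  if (anyDuplicated(key(review))) stop("duplicate keys in review table")

  wide <- function(pt) {
    d <- peaks[peaks$peak_type == pt, , drop = FALSE]
    if (nrow(d) == 0)
      return(data.frame(hemisphere_id = character(0),
                        configuration_id = character(0), amp = numeric(0)))
    if (anyDuplicated(key(d))) stop("duplicate keys in ", pt, " peak table")
    d$amp <- ifelse(d$included, d$amplitude_uV, NA_real_)
    d[, c("hemisphere_id", "configuration_id", "amp")]
  }
  p3 <- wide("P3"); names(p3)[3] <- "P3_uV"
  p10 <- wide("P10"); names(p10)[3] <- "P10_uV"

  out <- merge(review, overlaps, by = c("hemisphere_id", "configuration_id"))
  out <- merge(out, p3, by = c("hemisphere_id", "configuration_id"),
               all.x = TRUE)
  out <- merge(out, p10, by = c("hemisphere_id", "configuration_id"),
               all.x = TRUE)
  tw <- pmax(out$tTW_mA - out$bTW_mA, 0)
  if (any(abs(tw - out$TW_mA) > 1e-6))
    stop("review table violates TW = max(tTW - bTW, 0)")
  out[order(out$hemisphere_id, out$configuration_id), , drop = FALSE]
}

predictor_column <- function(p) {
  switch(p, P3 = "P3_uV", P10 = "P10_uV", overlap = "overlap",
         stop("unknown predictor: ", p))
}

predictor_label <- function(p) {
  switch(p, P3 = "P3", P10 = "P10", overlap = "EF overlap")
}

#' Fit a hemisphere-random-intercept linear mixed model
#'
#' Fits `response ~ predictors + (1 | hemisphere)` by maximum likelihood
#' (not REML, so AIC values are comparable across fixed-effect
#' structures). Rows with a missing value in any used predictor are
#' dropped for this model only. Fixed-effect t statistics are
#' coefficient/SE with residual degrees of freedom `n - #fixed-effects`
#' (two-sided p). R-squared is reported in two flavours: conditional (the
#' squared correlation between fitted values including the random
#' intercepts and the observations) and marginal (fixed-effect variance
#' over total variance). Singular fits are flagged, not hidden.
#'
#' @param table A group table from [build_group_table()].
#' @param response `"tTW"`, `"bTW"` or `"TW"`.
#' @param predictors Character subset of `c("P3", "P10", "overlap")`.
#' @return A `dbsep_lmm` object.
#' @export
fit_lmm <- function(table, response = c("tTW", "bTW", "TW"),
                    predictors = "P3") {
  response <- match.arg(response)
  stopifnot(all(predictors %in% c("P3", "P10", "overlap")),
            length(predictors) >= 1)
  ycol <- paste0(response, "_mA")
  cols <- vapply(predictors, predictor_column, character(1))
  keep <- stats::complete.cases(table[, c(ycol, cols), drop = FALSE])
  d <- table[keep, , drop = FALSE]
  n_hemi <- length(unique(d$hemisphere_id))
  if (n_hemi < 2) stop("need at least 2 hemispheres with complete data")
  if (nrow(d) > 0 && min(table(d$hemisphere_id)) < 2)
    stop("need at least 2 rows per hemisphere after missing-data exclusion")

  dat <- data.frame(y = d[[ycol]], hemisphere = factor(d$hemisphere_id))
  for (i in seq_along(predictors)) dat[[predictors[i]]] <- d[[cols[i]]]
  fml <- stats::as.formula(paste("y ~", paste(predictors, collapse = " + "),
                                 "+ (1 | hemisphere)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = dat, REML = FALSE)
  ))
  singular <- suppressWarnings(isTRUE(lme4::isSingular(fit, tol = 1e-4)))

  fe <- lme4::fixef(fit)
  # on degenerate (zero-residual) fits the vcov factorisation can fail;
  # coefficients and likelihood are still valid, so only SEs become NA
  se <- tryCatch(
    suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
    error = function(e) rep(NA_real_, length(fe))
  )
  k <- length(fe)
  n <- nrow(dat)
  df <- n - k
  tval <- fe / se
  pval <- 2 * stats::pt(-abs(tval), df)

  yhat <- stats::fitted(fit)
  r2_cond <- stats::cor(yhat, dat$y)^2
  X <- stats::model.matrix(fit)
  var_fix <- stats::var(as.vector(X %*% fe))
  vc <- lme4::VarCorr(fit)
  var_ran <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  var_res <- attr(vc, "sc")^2
  r2_marg <- var_fix / (var_fix + var_ran + var_res)

  formula_str <- paste0(response, " ~ ",
                        paste(vapply(predictors, predictor_label,
                                     character(1)), collapse = " + "),
                        " + (1|hemisphere)")
  structure(list(
    response = response, predictors = predictors, formula = formula_str,
    coefficients = data.frame(
      term = names(fe), estimate = unname(fe), se = unname(se),
      t = unname(tval), df = df, p = unname(pval), stringsAsFactors = FALSE
    ),
    AIC = stats::AIC(fit), logLik = as.numeric(stats::logLik(fit)),
    R2_conditional = r2_cond, R2_marginal = r2_marg,
    n = n, n_hemispheres = n_hemi, singular = singular,
    model = fit,
    data = table, rows = paste(d$hemisphere_id, d$configuration_id, sep = "//")
  ), class = "dbsep_lmm")
}

#' @export
print.dbsep_lmm <- function(x, ...) {
  cat("Linear mixed model (ML):", x$formula, "\n")
  cat(sprintf("n = %d rows, %d hemispheres%s\n", x$n, x$n_hemispheres,
              if (x$singular) "  [singular fit]" else ""))
  cat(sprintf("AIC = %.2f   R2(conditional) = %.2f   R2(marginal) = %.2f\n",
              x$AIC, x$R2_conditional, x$R2_marginal))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare mixed-model fits of one response by AIC
#'
#' Ranks fits sharing a response by AIC. Because AIC values are only
#' comparable on a common data set, `common_rows = TRUE` refits every
#' model on the intersection of rows where all compared predictors are
#' non-missing; the default keeps each model's own rows (the per-model
#' missing-data policy that produces the differing group sizes).
#'
#' @param fits List of `dbsep_lmm` objects with a common response.
#' @param common_rows Refit on the common complete-case row set first.
#' @return Data frame: `formula`, `n`, `AIC`, `dAIC` (vs. the best, i.e.
#'   lowest, AIC), `R2_conditional`, `R2_marginal`, `min_p`, `best`.
#' @export
compare_models <- function(fits, common_rows = FALSE) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "dbsep_lmm")))
  resp <- unique(vapply(fits, function(f) f$response, character(1)))
  if (length(resp) != 1) stop("all compared fits must share the response")
  if (common_rows) {
    tab <- fits[[1]]$data
    preds <- unique(unlist(lapply(fits, function(f) f$predictors)))
    cols <- vapply(preds, predictor_column, character(1))
    keep <- stats::complete.cases(tab[, cols, drop = FALSE])
    fits <- lapply(fits, function(f)
      fit_lmm(tab[keep, , drop = FALSE], f$response, f$predictors))
  }
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  slope_p <- vapply(fits, function(f) {
    p <- f$coefficients$p[f$coefficients$term != "(Intercept)"]
    if (length(p)) min(p) else NA_real_
  }, numeric(1))
  data.frame(
    formula = vapply(fits, function(f) f$formula, character(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    AIC = aic, dAIC = aic - min(aic),
    R2_conditional = vapply(fits, function(f) f$R2_conditional, numeric(1)),
    R2_marginal = vapply(fits, function(f) f$R2_marginal, numeric(1)),
    min_p = slope_p,
    best = aic == min(aic),
    stringsAsFactors = FALSE
  )
}

#' The full model grid of the analysis
#'
#' Five predictor blocks (P3, P10, EF overlap, P3 + EF overlap,
#' P10 + EF overlap) for each of the three therapeutic-window responses.
#' @return Data frame with `response` and list-column `predictors`.
#' @export
model_grid <- function() {
  blocks <- list("P3", "P10", "overlap", c("P3", "overlap"),
                 c("P10", "overlap"))
  out <- expand.grid(block = seq_along(blocks),
                     response = c("tTW", "bTW", "TW"),
                     stringsAsFactors = FALSE)
  data.frame(response = out$response,
             predictors = I(blocks[out$block]),
             stringsAsFactors = FALSE)
}

#' Fit every model of the grid on a group table
#'
#' @param table A group table.
#' @param grid A model grid (default [model_grid()]).
#' @param on_error `"stop"` propagates fit errors; `"keep"` records a
#'   failed fit as a `dbsep_lmm_error` stub (with the message) so one
#'   unfittable model does not abort a cohort run.
#' @return Named list of `dbsep_lmm` fits (`"<response>: <predictors>"`).
#' @export
fit_all_models <- function(table, grid = model_grid(),
                           on_error = c("stop", "keep")) {
  on_error <- match.arg(on_error)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- if (on_error == "stop") {
      fit_lmm(table, grid$response[i], grid$predictors[[i]])
    } else {
      tryCatch(fit_lmm(table, grid$response[i], grid$predictors[[i]]),
               error = function(e) structure(
                 list(response = grid$response[i],
                      predictors = grid$predictors[[i]],
                      message = conditionMessage(e)),
                 class = "dbsep_lmm_error"))
    }
    names(fits)[i] <- paste0(grid$response[i], ": ",
                             paste(grid$predictors[[i]], collapse = "+"))
  }
  fits
}

#' Text report of the model fits in the standard block layout
#'
#' One block per predictor set, columns tTW / bTW / TW, rows Equation,
#' AIC, tStat, R2 (conditional), p-value.
#'
#' @param fits Named list from [fit_all_models()].
#' @return Character vector of report lines.
#' @export
model_report <- function(fits) {
  grid <- model_grid()
  blocks <- unique(vapply(grid$predictors, paste, character(1), collapse = "+"))
  lines <- character(0)
  fmt_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
  for (b in blocks) {
    lines <- c(lines, sprintf("== Predictors: %s ==", b))
    for (what in c("Equation", "AIC", "tStat", "R2", "p-value")) {
      cells <- vapply(c("tTW", "bTW", "TW"), function(r) {
        f <- fits[[paste0(r, ": ", b)]]
        if (is.null(f)) return("-")
        if (inherits(f, "dbsep_lmm_error"))
          return(if (what == "Equation") paste("unavailable:", f$message)
                 else "-")
        co <- f$coefficients[f$coefficients$term != "(Intercept)", ]
        switch(what,
          Equation = f$formula,
          AIC = sprintf("%.2f", f$AIC),
          tStat = paste(sprintf("(%s) %.2f", co$term, co$t), collapse = " | "),
          R2 = sprintf("%.2f", f$R2_conditional),
          `p-value` = paste(sprintf("(%s) %s", co$term, fmt_p(co$p)),
                            collapse = " | ")
        )
      }, character(1))
      lines <- c(lines, sprintf("  %-9s %s", what,
                                paste(cells, collapse = "  ||  ")))
    }
  }
  lines
}
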