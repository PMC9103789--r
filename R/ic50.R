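# IC50 estimation by four-parameter logistic regression on log10 inhibitor
# concentration, and the IC50-shift classification of time-dependent
# inhibition (shift = IC50 without NADPH preincubation / IC50 with
# preincubation; a shift > 1.5 flags TDI).

#' Fit an IC50 curve to a normalized inhibition dataset
#'
#' Fits the four-parameter logistic model
#' \deqn{y = bottom + (top - bottom) / (1 + (c / IC50)^{h})}
#' to normalized activity versus inhibitor concentration (equivalently a
#' sigmoid in log10 concentration with Hill slope h > 0 for inhibition). By
#' default `top` is fixed at 1 and `bottom` at 0, appropriate for data
#' normalized to the control group; `fix_asymptotes = FALSE` frees both.
#' Zero-concentration control records anchor the normalization and are
#' excluded from the log-concentration fit.
#'
#' @param ds a normalized `ic50` [assay_dataset()] with at least 5 distinct
#'   positive inhibitor levels.
#' @param fix_asymptotes logical; fix top = 1 and bottom = 0 (default).
#' @return object of class `ic50_fit` with elements `ic50` (uM), `hill_slope`,
#'   `top`, `bottom`, `se_ic50` (uM, delta-method), `converged`, `data` and the
#'   underlying `fit`.
#' @details If the observed activity never drops below 0.8 of control across
#'   the tested range the curve is flat at the assayed concentrations and the
#'   fit aborts with a "no inhibition detected" error rather than returning an
#'   unidentified IC50.
#' @export
fit_ic50 <- function(ds, fix_asymptotes = TRUE) {
  validate_assay_dataset(ds)
  if (attr(ds, "assay_kind") != "ic50") stop_cypddi("not an ic50 dataset")
  if (!isTRUE(attr(ds, "normalized")))
    stop_cypddi("fit_ic50 requires a normalized dataset (see normalize_to_control)")
  pos <- ds[ds$inhibitor_conc_uM > 0, , drop = FALSE]
  if (length(unique(pos$inhibitor_conc_uM)) < 5L)
    stop_cypddi("need >= 5 distinct positive inhibitor levels")
  mean_by_conc <- tapply(pos$response, pos$inhibitor_conc_uM, mean)
  conc_levels <- as.numeric(names(mean_by_conc))
  if (min(mean_by_conc) > 0.8)
    stop_cypddi("no inhibition detected: activity stays above 0.8 of control ",
                "across the tested concentrations",
                class = "cypddi_no_inhibition")
  # start values: concentration whose mean response is nearest mid-decline
  mid <- (max(mean_by_conc) + min(mean_by_conc)) / 2
  start_ic50 <- conc_levels[which.min(abs(mean_by_conc - mid))]
  dat <- data.frame(conc = pos$inhibitor_conc_uM, y = pos$response)
  fit <- tryCatch({
    if (fix_asymptotes)
      minpack.lm::nlsLM(y ~ 1 / (1 + (conc / exp(lic50))^h), data = dat,
                        start = list(lic50 = log(start_ic50), h = 1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ bot + (top - bot) / (1 + (conc / exp(lic50))^h),
                        data = dat,
                        start = list(lic50 = log(start_ic50), h = 1,
                                     top = max(mean_by_conc), bot = min(mean_by_conc)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stop_cypddi("IC50 fit did not converge: ", conditionMessage(e),
                class = "cypddi_fit_error"))
  cf <- coef(fit)
  ic50 <- exp(cf[["lic50"]])
  se_l <- tryCatch(summary(fit)$coefficients["lic50", "Std. Error"],
                   error = function(e) NA_real_)
  structure(list(ic50 = ic50,
                 hill_slope = cf[["h"]],
                 top = if (fix_asymptotes) 1 else cf[["top"]],
                 bottom = if (fix_asymptotes) 0 else cf[["bot"]],
                 se_ic50 = ic50 * se_l,      # delta method on log scale
                 converged = TRUE,
                 data = dat, fit = fit),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit: IC50 = %.4g uM (SE %.3g), Hill slope = %.3g, top = %.3g, bottom = %.3g\n",
              x$ic50, x$se_ic50, x$hill_slope, x$top, x$bottom))
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill_slope = object$hill_slope,
    top = object$top, bottom = object$bottom)
}

#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$bottom + (object$top - object$bottom) /
    (1 + (conc / object$ic50)^object$hill_slope)
}

#' @export
plot.ic50_fit <- function(x, ...) {
  dat <- x$data
  grid <- 10^seq(log10(min(dat$conc)), log10(max(dat$conc)), length.out = 200)
  graphics::plot(dat$conc, dat$y, log = "x",
                 xlab = "inhibitor (uM)", ylab = "fraction of control activity",
                 main = sprintf("IC50 = %.3g uM", x$ic50), ...)
  graphics::lines(grid, predict(x, data.frame(conc = grid)))
  invisible(x)
}

#' IC50 shift between preincubated and non-preincubated assays
#'
#' shift = IC50 (no NADPH preincubation) / IC50 (30-min NADPH preincubation).
#' A shift greater than 1.5 indicates time-dependent inhibition.
#'
#' @param no_preinc IC50 without preincubation: an `ic50_fit` or a positive
#'   number (uM).
#' @param preinc IC50 with preincubation, same forms.
#' @return object of class `ic50_shift` with `ic50_no_preinc`, `ic50_preinc`,
#'   `shift` and `tdi_flag` (`shift > 1.5`).
#' @export
ic50_shift <- function(no_preinc, preinc) {
  as_ic50 <- function(x, arg) {
    v <- if (inherits(x, "ic50_fit")) x$ic50 else x
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_cypddi(arg, " must be a positive IC50 (uM) or an ic50_fit")
    v
  }
  a <- as_ic50(no_preinc, "no_preinc")
  b <- as_ic50(preinc, "preinc")
  shift <- a / b
  structure(list(ic50_no_preinc = a, ic50_preinc = b,
                 shift = shift, tdi_flag = shift > 1.5),
            class = "ic50_shift")
}

#' @export
print.ic50_shift <- function(x, ...) {
  cat(sprintf("IC50 shift: %.4g / %.4g uM = %.2f -> %s\n",
              x$ic50_no_preinc, x$ic50_preinc, round_half_up(x$shift, 2),
              if (x$tdi_flag) "time-dependent inhibition (shift > 1.5)"
              else "no TDI flag"))
  invisible(x)
}
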