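# Time-dependent (mechanism-based) inactivation kinetics. For each inhibitor
# level the observed inactivation rate kobs is the negated slope of
# ln(remaining activity) against preincubation time; kobs saturates with
# inhibitor concentration as kobs = kinact * [I] / (KI + [I]), from which
# kinact (maximal inactivation rate, 1/min) and KI (half-maximal inactivation
# concentration, uM) are estimated by nonlinear least squares, with the
# Kitz-Wilson double-reciprocal line (1/kobs vs 1/[I]) as a linear cross-check.

#' Observed inactivation rate at one inhibitor level
#'
#' Least-squares slope of ln(normalized activity) versus preincubation time,
#' negated. By default the slope of the inhibitor-free control series is
#' subtracted first, removing NADPH-independent activity loss over the
#' preincubation; the corrected rate is clipped at zero.
#'
#' @param ds a normalized `tdi` [assay_dataset()].
#' @param conc inhibitor concentration (uM) whose series to fit; must have at
#'   least 3 preincubation times.
#' @param control_correct subtract the `inhibitor_conc = 0` control slope
#'   (default `TRUE`).
#' @return kobs in 1/min (single number, >= 0).
#' @export
fit_kobs <- function(ds, conc, control_correct = TRUE) {
  validate_assay_dataset(ds)
  if (attr(ds, "assay_kind") != "tdi") stop_cypddi("not a tdi dataset")
  if (!isTRUE(attr(ds, "normalized")))
    stop_cypddi("fit_kobs requires a normalized dataset (see normalize_to_control)")
  slope_at <- function(ci) {
    sub <- ds[ds$inhibitor_conc_uM == ci, , drop = FALSE]
    if (length(unique(sub$preincubation_min)) < 3L)
      stop_cypddi("need >= 3 preincubation times at inhibitor ", ci, " uM")
    if (any(sub$response <= 0))
      stop_cypddi("nonpositive activity at inhibitor ", ci,
                  " uM: log-linear decay undefined")
    unname(stats::coef(stats::lm(log(response) ~ preincubation_min,
                                 data = sub))[2L])
  }
  k <- -slope_at(conc)
  if (control_correct && conc != 0) k <- k - (-slope_at(0))
  max(k, 0)
}

#' Fit the saturable inactivation model to kobs values
#'
#' Nonlinear least squares of kobs = kinact * I / (KI + I) over the positive
#' inhibitor concentrations, started from (and cross-checked against) the
#' Kitz-Wilson linearization 1/kobs = 1/kinact + (KI/kinact) / I. Also
#' reports the inactivation efficiency kinact/KI in mL/min/umol.
#'
#' @param kobs_by_conc named numeric vector (names = inhibitor uM) or a
#'   two-column data.frame `conc`, `kobs`; at least 4 positive concentrations.
#' @return object of class `inactivation_fit`: `KI` (uM), `kinact` (1/min),
#'   `efficiency` (mL/min/umol), `kobs_by_conc`, `kitz_wilson` (the linear
#'   cross-check estimates) and the `fit` object.
#' @seealso [fit_tdi()] for the full dataset-to-parameters pipeline,
#'   [efficiency()].
#' @export
fit_inactivation <- function(kobs_by_conc) {
  if (is.data.frame(kobs_by_conc)) {
    conc <- kobs_by_conc$conc; kobs <- kobs_by_conc$kobs
  } else {
    conc <- as.numeric(names(kobs_by_conc)); kobs <- unname(kobs_by_conc)
  }
  if (anyNA(conc)) stop_cypddi("kobs_by_conc must be named by concentration")
  pos <- conc > 0
  conc <- conc[pos]; kobs <- kobs[pos]
  if (length(conc) < 4L) stop_cypddi("need >= 4 positive concentrations")
  if (all(kobs <= 0))
    stop_cypddi("no inactivation: all kobs are zero", class = "cypddi_fit_error")
  # Kitz-Wilson start values from the strictly positive kobs
  kw <- NULL
  ok <- kobs > 0
  if (sum(ok) >= 2L) {
    lin <- stats::lm(I(1 / kobs[ok]) ~ I(1 / conc[ok]))
    a <- stats::coef(lin)[[1L]]; b <- stats::coef(lin)[[2L]]
    if (a > 0 && b > 0) kw <- c(kinact = 1 / a, KI = b / a)
  }
  start <- if (!is.null(kw)) list(kinact = kw[["kinact"]], KI = kw[["KI"]])
           else list(kinact = max(kobs), KI = stats::median(conc))
  fit <- tryCatch(
    minpack.lm::nlsLM(kobs ~ kinact * conc / (KI + conc),
                      data = data.frame(conc = conc, kobs = kobs),
                      start = start, lower = c(kinact = 1e-12, KI = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop_cypddi("inactivation fit did not converge: ", conditionMessage(e),
                  if (!is.null(kw)) sprintf(" (Kitz-Wilson fallback: kinact %.4g, KI %.4g)",
                                            kw[["kinact"]], kw[["KI"]]),
                  class = "cypddi_fit_error"))
  cf <- stats::coef(fit)
  structure(list(KI = cf[["KI"]], kinact = cf[["kinact"]],
                 efficiency = efficiency(cf[["kinact"]], cf[["KI"]]),
                 kobs_by_conc = stats::setNames(kobs, conc),
                 kitz_wilson = kw, fit = fit),
            class = "inactivation_fit")
}

#' Full TDI pipeline: dataset to inactivation parameters
#'
#' Normalizes (if needed), estimates kobs at every positive inhibitor level
#' with [fit_kobs()], then fits the saturable model with [fit_inactivation()].
#' Per-level r-squared of the log-linear decay regressions is attached as a
#' diagnostic. Inhibitor concentrations are the preincubation-stage (nominal)
#' ones: in the two-step protocol inactivation happens during preincubation,
#' before the aliquot dilution.
#'
#' @param ds a `tdi` [assay_dataset()].
#' @param control_correct passed to [fit_kobs()].
#' @return an `inactivation_fit` with an added `r2_per_decay` element.
#' @export
fit_tdi <- function(ds, control_correct = TRUE) {
  if (!isTRUE(attr(ds, "normalized"))) ds <- normalize_to_control(ds)
  conc <- sort(setdiff(unique(ds$inhibitor_conc_uM), 0))
  kobs <- vapply(conc, function(ci) fit_kobs(ds, ci, control_correct), numeric(1L))
  r2 <- vapply(conc, function(ci) {
    sub <- ds[ds$inhibitor_conc_uM == ci, , drop = FALSE]
    suppressWarnings(
      summary(stats::lm(log(response) ~ preincubation_min, data = sub)))$r.squared
  }, numeric(1L))
  out <- fit_inactivation(stats::setNames(kobs, conc))
  out$r2_per_decay <- stats::setNames(r2, conc)
  out
}

#' Inactivation efficiency kinact/KI
#'
#' The potency index of a mechanism-based inactivator: the ratio of the
#' maximal inactivation rate to the half-maximal inactivation concentration,
#' converted from (1/min) / uM to mL/min/umol by the factor 1000.
#'
#' @param kinact maximal inactivation rate constant, 1/min.
#' @param KI half-maximal inactivation concentration, uM.
#' @return efficiency in mL/min/umol.
#' @export
#' @examples
#' efficiency(0.044, 0.43)   # 102.33 mL/min/umol
efficiency <- function(kinact, KI) {
  if (!all(kinact > 0) || !all(KI > 0))
    stop_cypddi("kinact and KI must be positive")
  kinact / KI * 1000
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat(sprintf("Inactivation fit: kinact = %.4g 1/min, KI = %.4g uM, kinact/KI = %.2f mL/min/umol\n",
              x$kinact, x$KI, round_half_up(x$efficiency, 2)))
  if (!is.null(x$kitz_wilson))
    cat(sprintf("  Kitz-Wilson cross-check: kinact = %.4g, KI = %.4g\n",
                x$kitz_wilson[["kinact"]], x$kitz_wilson[["KI"]]))
  invisible(x)
}

#' @export
coef.inactivation_fit <- function(object, ...)
  c(kinact = object$kinact, KI = object$KI, efficiency = object$efficiency)

#' @export
predict.inactivation_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) as.numeric(names(object$kobs_by_conc))
          else newdata$conc
  object$kinact * conc / (object$KI + conc)
}

#' @export
plot.inactivation_fit <- function(x, ...) {
  conc <- as.numeric(names(x$kobs_by_conc))
  grid <- seq(0, max(conc), length.out = 200)
  graphics::plot(conc, x$kobs_by_conc, xlab = "[I] (uM)", ylab = "kobs (1/min)",
                 main = sprintf("kinact = %.3g 1/min, KI = %.3g uM", x$kinact, x$KI),
                 ...)
  graphics::lines(grid, x$kinact * grid / (x$KI + grid))
  invisible(x)
}
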