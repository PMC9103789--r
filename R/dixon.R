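# Dixon-plot estimation of the competitive inhibition constant Ki: ordinary
# least-squares lines of 1/v against inhibitor concentration, one line per
# substrate level; under competitive inhibition all lines intersect at
# [I] = -Ki, so Ki is read off the (weighted) common intersection abscissa.

#' Estimate a competitive Ki from a Dixon plot
#'
#' For each substrate level S, regresses the reciprocal velocity 1/v on the
#' inhibitor concentration by ordinary least squares. Under the competitive
#' model v = Vmax S / (Km (1 + I/Ki) + S), 1/v is exactly linear in I with a
#' slope proportional to 1/S, and every pair of substrate lines intersects at
#' I = -Ki. The estimator computes all pairwise line intersections and returns
#' Ki = -(weighted mean abscissa), weighting each pair by the inverse of the
#' delta-method variance of its abscissa, so intersections of nearly parallel
#' (poorly separated) line pairs contribute little.
#'
#' A common intersection left of zero is accepted when the weighted SD of the
#' abscissae is below 25% of |mean| and the mean is negative; otherwise, or
#' when no line has a statistically nonzero slope (all slope |t| < 2),
#' `mechanism_label` is `"none_detected"` and `ki` is `NA` — the signature of
#' an inhibitor with no measurable reversible component.
#'
#' @param ds a `dixon` [assay_dataset()] with strictly positive velocities,
#'   at least 3 substrate levels and at least 3 inhibitor levels including 0.
#' @return object of class `dixon_fit`: `ki` (uM), `lines` (per-substrate
#'   slope/intercept/t table), `intersections` (pairwise abscissae and
#'   weights), `intersection_x`, `intersection_spread` (weighted SD) and
#'   `mechanism_label`.
#' @export
fit_dixon <- function(ds) {
  validate_assay_dataset(ds)
  if (attr(ds, "assay_kind") != "dixon") stop_cypddi("not a dixon dataset")
  if (any(ds$response <= 0))
    stop_cypddi("Dixon fit needs strictly positive velocities (1/v undefined)")
  s_levels <- sort(unique(ds$substrate_conc_uM))
  if (length(s_levels) < 2L) stop_cypddi("need >= 2 substrate levels")
  fits <- lapply(s_levels, function(s) {
    sub <- ds[ds$substrate_conc_uM == s, , drop = FALSE]
    fit <- stats::lm(I(1 / response) ~ inhibitor_conc_uM, data = sub)
    cf <- stats::coef(fit)
    v <- suppressWarnings(stats::vcov(fit))    # zero on noiseless data
    se <- sqrt(v[2L, 2L])
    tval <- cf[2L] / se
    if (!is.finite(tval)) {                    # zero residual variance
      tval <- if (abs(cf[2L]) > 0) 1e6 else 0  # perfect line vs exactly flat
    }
    list(s = s, a = cf[[1L]], b = cf[[2L]], t = tval,
         va = v[1L, 1L], vb = v[2L, 2L], vab = v[1L, 2L])
  })
  lines <- do.call(rbind, lapply(fits, function(l)
    data.frame(substrate_conc_uM = l$s, intercept = l$a, slope = l$b,
               slope_t = l$t)))
  if (max(abs(lines$slope_t)) < 2) {
    return(structure(list(ki = NA_real_, lines = lines, intersections = NULL,
                          intersection_x = NA_real_,
                          intersection_spread = NA_real_,
                          mechanism_label = "none_detected"),
                     class = "dixon_fit"))
  }
  pairs <- utils::combn(length(fits), 2L)
  inter <- apply(pairs, 2L, function(ix) {
    l1 <- fits[[ix[1L]]]; l2 <- fits[[ix[2L]]]
    db <- l1$b - l2$b
    if (abs(db) < .Machine$double.eps * 100) return(c(NA_real_, NA_real_))
    x <- -(l1$a - l2$a) / db
    # delta-method variance of the intersection abscissa
    vx <- (l1$va + l2$va + x^2 * (l1$vb + l2$vb) +
             2 * x * (l1$vab + l2$vab)) / db^2
    c(x, if (is.finite(vx) && vx > 0) 1 / vx else 1e12)
  })
  xs <- inter[1L, ]; w <- inter[2L, ]
  keep <- is.finite(xs) & is.finite(w) & w > 0
  if (!any(keep)) {
    return(structure(list(ki = NA_real_, lines = lines, intersections = NULL,
                          intersection_x = NA_real_,
                          intersection_spread = NA_real_,
                          mechanism_label = "none_detected"),
                     class = "dixon_fit"))
  }
  xs <- xs[keep]; w <- w[keep] / sum(w[keep])
  xbar <- sum(w * xs)
  spread <- sqrt(sum(w * (xs - xbar)^2))
  common <- xbar < 0 && (length(xs) == 1L || spread < 0.25 * abs(xbar))
  structure(list(ki = if (common) -xbar else NA_real_,
                 lines = lines,
                 intersections = data.frame(x = xs, weight = w),
                 intersection_x = xbar,
                 intersection_spread = spread,
                 mechanism_label = if (common) "competitive" else "none_detected"),
            class = "dixon_fit")
}

#' @export
print.dixon_fit <- function(x, ...) {
  if (x$mechanism_label == "competitive")
    cat(sprintf("Dixon fit: competitive inhibition, Ki = %.4g uM (intersection spread %.3g uM, %d lines)\n",
                x$ki, x$intersection_spread, nrow(x$lines)))
  else
    cat("Dixon fit: no consistent reversible inhibition detected\n")
  invisible(x)
}

#' @export
coef.dixon_fit <- function(object, ...) c(ki = object$ki)

#' @export
plot.dixon_fit <- function(x, ds = NULL, ...) {
  xr <- c(if (x$mechanism_label == "competitive") -1.5 * x$ki else -1, 0)
  if (!is.null(ds)) xr[2L] <- max(ds$inhibitor_conc_uM)
  graphics::plot(NA, xlim = xr,
                 ylim = range(x$lines$intercept + x$lines$slope %o% xr),
                 xlab = "[I] (uM)", ylab = "1/v", main = "Dixon plot", ...)
  for (i in seq_len(nrow(x$lines)))
    graphics::abline(x$lines$intercept[i], x$lines$slope[i])
  if (x$mechanism_label == "competitive")
    graphics::abline(v = -x$ki, lty = 2)
  invisible(x)
}
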