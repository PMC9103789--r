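# internal helpers shared across modules

#' @keywords internal
#' @noRd
stop_cypddi <- function(..., class = "cypddi_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (spec, seed).
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_cypddi("seed must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Multiplicative lognormal noise with unit mean and coefficient of variation cv.
#' @keywords internal
#' @noRd
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop_cypddi("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Trapezoidal AUC on an (x, y) grid; no extrapolation beyond the grid.
#' @keywords internal
#' @noRd
trapz_auc <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Half-up rounding for displayed values
#'
#' Rounds half away from zero (so 1.005 at 2 digits gives 1.01), the convention
#' used for the displayed fold errors, shifts and AUC ratios in the report
#' tables. Use only for display; internal computations keep full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(1.1393, 0.125), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
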