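# Synthetic assay-data generators with known ground truth. Default designs
# copy the in vitro protocols the fitting functions are meant for: Dixon
# incubations over a tacrolimus substrate grid, two-step TDI preincubation
# time courses, and IC50 concentration ranges. Noise is multiplicative
# lognormal with unit mean and a coefficient-of-variation parameter, since
# assay responses are positive; an additive-Gaussian variant is available
# behind `noise = "gaussian"`. Every generator is a pure function of its
# arguments and the seed (the caller's RNG state is untouched).

#' Generate a synthetic Dixon (reversible inhibition) dataset
#'
#' Velocities follow the competitive model
#' v = Vmax S / (Km (1 + I/Ki) + S), times multiplicative lognormal noise.
#'
#' @param ki true competitive inhibition constant, uM.
#' @param vmax maximal velocity, pmol/min/mg.
#' @param km Michaelis constant of the probe reaction, uM.
#' @param substrate_uM substrate concentration grid, uM.
#' @param inhibitor_uM inhibitor grid including 0, uM.
#' @param replicates replicates per design point.
#' @param cv lognormal noise CV (0 = noiseless).
#' @param noise `"lognormal"` (default) or `"gaussian"` (additive, sd = cv x
#'   model velocity).
#' @param seed integer seed, recorded in the dataset's `generator` attribute.
#' @return a validated `dixon` [assay_dataset()].
#' @export
generate_dixon_dataset <- function(ki,
                                   vmax = 100, km = 1.2,
                                   substrate_uM = c(0.25, 0.5, 1, 2),
                                   inhibitor_uM = c(0, 1, 2, 4),
                                   replicates = 3, cv = 0,
                                   noise = c("lognormal", "gaussian"),
                                   seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(ki > 0, vmax > 0, km > 0)
  design <- expand.grid(substrate_conc_uM = substrate_uM,
                        inhibitor_conc_uM = inhibitor_uM,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
  v <- vmax * design$substrate_conc_uM /
    (km * (1 + design$inhibitor_conc_uM / ki) + design$substrate_conc_uM)
  design$response <- with_seed(seed, apply_noise(v, cv, noise))
  design$preincubation_min <- 0
  ds <- assay_dataset(design, "dixon", probe = "tacrolimus",
                      protein_conc = 0.2)
  attr(ds, "generator") <- list(kind = "dixon", ki = ki, vmax = vmax, km = km,
                                cv = cv, noise = noise, seed = seed)
  ds
}

#' Generate a synthetic TDI preincubation time-course dataset
#'
#' Remaining activity decays as activity(I, t) = exp(-(kobs(I) + loss) t) with
#' kobs(I) = kinact I / (KI + I); `control_loss` models NADPH-independent
#' activity loss affecting every series, including the inhibitor-free control.
#' Responses are normalized activity (fraction of control).
#'
#' @param KI half-maximal inactivation concentration, uM.
#' @param kinact maximal inactivation rate, 1/min.
#' @param inhibitor_uM preincubation-stage inhibitor grid including 0, uM.
#' @param times_min preincubation times, a subset of {0, 5, 10, 20, 30} min.
#' @param control_loss first-order NADPH-independent loss rate, 1/min.
#' @param replicates,cv,noise,seed as in [generate_dixon_dataset()].
#' @return a validated, normalized `tdi` [assay_dataset()].
#' @export
generate_tdi_dataset <- function(KI, kinact,
                                 inhibitor_uM = c(0, 0.1, 0.2, 0.5, 1, 2),
                                 times_min = c(0, 5, 10, 20, 30),
                                 control_loss = 0,
                                 replicates = 3, cv = 0,
                                 noise = c("lognormal", "gaussian"),
                                 seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(KI > 0, kinact > 0, control_loss >= 0)
  design <- expand.grid(inhibitor_conc_uM = inhibitor_uM,
                        preincubation_min = times_min,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
  kobs <- kinact * design$inhibitor_conc_uM / (KI + design$inhibitor_conc_uM)
  act <- exp(-(kobs + control_loss) * design$preincubation_min)
  design$response <- with_seed(seed, apply_noise(act, cv, noise))
  design$substrate_conc_uM <- 200   # probe substrate, activity-stage
  ds <- assay_dataset(design, "tdi", normalized = TRUE)
  attr(ds, "generator") <- list(kind = "tdi", KI = KI, kinact = kinact,
                                control_loss = control_loss, cv = cv,
                                noise = noise, seed = seed)
  ds
}

#' Generate a synthetic IC50 concentration-response dataset
#'
#' Normalized activity follows the logistic curve
#' y = bottom + (top - bottom) / (1 + (c/IC50)^hill) with multiplicative
#' noise. Use [generate_ic50_pair()] for matched preincubation /
#' no-preincubation designs with two IC50 truths.
#'
#' @param ic50 true IC50, uM.
#' @param hill Hill slope (> 0).
#' @param top,bottom asymptotes (fractions of control).
#' @param inhibitor_uM concentration grid including 0, uM.
#' @param preincubation_min label recorded on every record (0 = no NADPH
#'   preincubation, 30 = preincubated).
#' @param replicates,cv,noise,seed as in [generate_dixon_dataset()].
#' @return a validated, normalized `ic50` [assay_dataset()].
#' @export
generate_ic50_dataset <- function(ic50, hill = 1, top = 1, bottom = 0,
                                  inhibitor_uM = c(0, 0.0625, 0.125, 0.25, 0.5,
                                                   1, 2, 4, 8, 10, 20),
                                  preincubation_min = 0,
                                  replicates = 3, cv = 0,
                                  noise = c("lognormal", "gaussian"),
                                  seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(ic50 > 0, hill > 0, bottom <= top)
  design <- expand.grid(inhibitor_conc_uM = inhibitor_uM,
                        replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
  y <- bottom + (top - bottom) /
    (1 + (design$inhibitor_conc_uM / ic50)^hill)
  design$response <- with_seed(seed, apply_noise(y, cv, noise))
  design$substrate_conc_uM <- 200
  design$preincubation_min <- preincubation_min
  ds <- assay_dataset(design, "ic50", normalized = TRUE)
  attr(ds, "generator") <- list(kind = "ic50", ic50 = ic50, hill = hill,
                                top = top, bottom = bottom, cv = cv,
                                noise = noise, seed = seed)
  ds
}

#' Matched IC50 datasets without and with NADPH preincubation
#'
#' @param ic50_no_preinc,ic50_preinc the two IC50 truths, uM.
#' @param ... passed to [generate_ic50_dataset()] (the preincubated dataset
#'   uses `seed + 1` so the two datasets are independently noised).
#' @param seed integer seed.
#' @return list with elements `no_preinc` and `preinc`.
#' @export
generate_ic50_pair <- function(ic50_no_preinc, ic50_preinc, ..., seed = 1L) {
  list(no_preinc = generate_ic50_dataset(ic50_no_preinc, ...,
                                         preincubation_min = 0, seed = seed),
       preinc = generate_ic50_dataset(ic50_preinc, ...,
                                      preincubation_min = 30, seed = seed + 1L))
}

#' Sample noisy "observed" points from a simulated concentration profile
#'
#' Emulates a predicted-versus-observed comparison: picks time points from a
#' simulated profile and multiplies by lognormal noise.
#'
#' @param result a `pbpk_sim` from [simulate_pk()].
#' @param compound compound name present in the simulation.
#' @param times_h sampling times (defaults to 12 points spanning the grid).
#' @param cv lognormal noise CV.
#' @param seed integer seed.
#' @return data.frame `time_h`, `compound`, `conc_ng_per_mL` (tidy profile
#'   table).
#' @export
generate_pk_observations <- function(result, compound, times_h = NULL,
                                     cv = 0.1, seed = 1L) {
  prof <- profile_table(result, compound)
  if (nrow(prof) == 0L) stop_cypddi("profile is empty")
  if (is.null(times_h))
    times_h <- seq(min(prof$time_h), max(prof$time_h), length.out = 12L)[-1L]
  conc <- stats::approx(prof$time_h, prof$conc_ng_per_mL, xout = times_h)$y
  conc <- conc * with_seed(seed, lognormal_noise(length(conc), cv))
  data.frame(time_h = times_h, compound = compound, conc_ng_per_mL = conc)
}

#' @keywords internal
#' @noRd
apply_noise <- function(mu, cv, noise) {
  if (cv == 0) return(mu)
  if (noise == "lognormal") mu * lognormal_noise(length(mu), cv)
  else pmax(mu + stats::rnorm(length(mu), 0, cv * mu), 0)
}
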