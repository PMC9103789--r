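# Built-in parameter sets for the worked example: the two Wuzhi-capsule
# lignans schizandrol A (SZA) and schizandrol B (SZB) as perpetrators, their
# CYP3A4/CYP3A5 inhibition specifications, and a representative synthetic
# tacrolimus victim configuration whose clearance split is meant to be pinned
# by calibrate_baseline() rather than taken at face value.

#' Schizandrol A compound parameters
#'
#' Physicochemical and ADME parameters for SZA (single oral dose 33.6 mg in
#' the worked example). SZA's own elimination is treated as a single lumped
#' pathway (`other` = 1), since only its role as a perpetrator matters here.
#'
#' @return a [compound_params()].
#' @export
sza_params <- function() {
  compound_params("SZA", mw = 432.52, logP = 3.390, fu_plasma = 0.083,
                  bp_ratio = 1.254, fa = 0.500, ka = 0.218, peff = 0.5,
                  vss = 2.516, kp_scalar = 0.5, clint_hlm = 50,
                  enzyme_fractions = c(CYP3A4 = 0, CYP3A5 = 0, other = 1))
}

#' Schizandrol B compound parameters
#'
#' @return a [compound_params()] for SZB (single oral dose 10.8 mg in the
#'   worked example).
#' @export
szb_params <- function() {
  compound_params("SZB", mw = 416.47, logP = 3.380, fu_plasma = 0.084,
                  bp_ratio = 0.785, fa = 0.734, ka = 0.437, peff = 1.0,
                  vss = 2.225, kp_scalar = 1, clint_hlm = 4.5,
                  enzyme_fractions = c(CYP3A4 = 0, CYP3A5 = 0, other = 1))
}

#' SZA inhibition specification
#'
#' SZA shows time-dependent inactivation of CYP3A4 only (KI = 15.38 uM,
#' kinact = 0.024 1/min in CYP3A5 *3/*3 microsomes) and no reversible
#' component, so only `TDI_only` scenarios are defined for it. With
#' `source = "pooled"` the pooled-microsome values (KI = 15.625 uM,
#' kinact = 0.029 1/min, lumped CYP3A) are used instead, applied to CYP3A4.
#'
#' @param source `"genotyped"` (default) or `"pooled"`.
#' @return an [interaction_spec()], mode `TDI_only`.
#' @export
sza_spec <- function(source = c("genotyped", "pooled")) {
  source <- match.arg(source)
  if (source == "genotyped")
    interaction_spec(cyp3a4 = list(KI = 15.38, kinact = 0.024),
                     mode = "TDI_only", perpetrator = "SZA")
  else
    interaction_spec(cyp3a4 = list(KI = 15.625, kinact = 0.029),
                     mode = "TDI_only", perpetrator = "SZA")
}

#' SZB inhibition specification
#'
#' SZB is both a reversible competitive inhibitor and a mechanism-based
#' inactivator of both enzymes. Genotyped-microsome values: CYP3A4 Ki =
#' 2.03 uM, KI = 0.69 uM, kinact = 0.37 1/min; CYP3A5 Ki = 2.18 uM, KI =
#' 0.5 uM, kinact = 0.009 1/min. Pooled-microsome alternative: lumped CYP3A
#' Ki = 5.82 uM, KI = 0.43 uM, kinact = 0.044 1/min (applied to CYP3A4).
#'
#' @param source `"genotyped"` (default) or `"pooled"`.
#' @return an [interaction_spec()], mode `RI_and_TDI`.
#' @export
szb_spec <- function(source = c("genotyped", "pooled")) {
  source <- match.arg(source)
  if (source == "genotyped")
    interaction_spec(cyp3a4 = list(ki = 2.03, KI = 0.69, kinact = 0.37),
                     cyp3a5 = list(ki = 2.18, KI = 0.5, kinact = 0.009),
                     mode = "RI_and_TDI", perpetrator = "SZB")
  else
    interaction_spec(cyp3a4 = list(ki = 5.82, KI = 0.43, kinact = 0.044),
                     mode = "RI_and_TDI", perpetrator = "SZB")
}

#' Synthetic tacrolimus victim configuration
#'
#' A representative tacrolimus parameter set assembled from commonly cited
#' ranges (high blood:plasma partitioning, low plasma unbound fraction, ~25%
#' oral availability): it is a synthetic stand-in, not a published model.
#' Its `clint_hlm` and CYP3A4/CYP3A5 split are placeholders —
#' [calibrate_baseline()] replaces them so that simulated control exposures
#' match the genotype-specific targets; only `enzyme_fractions[["other"]]`
#' (the non-CYP3A share, 5%) survives calibration.
#'
#' @return a [compound_params()].
#' @export
tacrolimus_params <- function() {
  compound_params("tacrolimus", mw = 804.02, fu_plasma = 0.013,
                  bp_ratio = 15, fa = 0.25, ka = 4.48,
                  vss = 18, kp_scalar = 1, clint_hlm = 1000,
                  enzyme_fractions = c(CYP3A4 = 0.475, CYP3A5 = 0.475,
                                       other = 0.05))
}

#' The perpetrator bundle used by the scenario grid
#'
#' @param source inhibition-parameter source passed to [sza_spec()] /
#'   [szb_spec()].
#' @return named list suitable for [run_scenario_grid()]: per inhibitor the
#'   compound, spec and the single (33.6 / 10.8 mg) and twice-daily
#'   (16.8 / 5.4 mg) doses.
#' @export
default_perpetrators <- function(source = "genotyped") {
  list(SZA = list(compound = sza_params(), spec = sza_spec(source),
                  single_dose_mg = 33.6, bid_dose_mg = 16.8),
       SZB = list(compound = szb_params(), spec = szb_spec(source),
                  single_dose_mg = 10.8, bid_dose_mg = 5.4))
}
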