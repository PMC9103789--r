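# Compound, physiology and dosing parameter containers for the minimal PBPK
# model, plus intrinsic-clearance scale-up (microsomal CLint -> whole-liver
# CLint per enzyme) and the well-stirred hepatic clearance model.

CYP_ENZYMES <- c("CYP3A4", "CYP3A5", "other")

#' Compound parameter set
#'
#' The physicochemical / ADME parameter block the simulator needs for one
#' compound. Volumes are plasma-referenced; `bp_ratio` converts between blood
#' and plasma concentrations where a whole-blood output is requested.
#'
#' @param name compound name.
#' @param mw molecular weight, g/mol.
#' @param logP octanol:water log partition coefficient (informational).
#' @param fu_plasma unbound fraction in plasma (0-1).
#' @param bp_ratio blood-to-plasma concentration ratio.
#' @param fa fraction of the oral dose absorbed (0-1].
#' @param ka first-order absorption rate constant, 1/h.
#' @param peff effective intestinal permeability, 1e-4 cm/s (carried but not
#'   used by the first-order absorption model).
#' @param vss steady-state distribution volume, L/kg (plasma-referenced).
#' @param kp_scalar scalar on tissue:plasma partitioning; the central volume
#'   is `vss * kp_scalar * body_weight`.
#' @param clint_hlm microsomal intrinsic clearance, uL/min/mg protein.
#' @param enzyme_fractions named fractions of `clint_hlm` carried by
#'   `CYP3A4`, `CYP3A5` and `other`; must sum to 1.
#' @return object of class `compound_params`.
#' @export
compound_params <- function(name, mw, fu_plasma, bp_ratio, fa, ka, vss,
                            clint_hlm,
                            enzyme_fractions = c(CYP3A4 = 0, CYP3A5 = 0, other = 1),
                            kp_scalar = 1, logP = NA_real_, peff = NA_real_) {
  ef <- enzyme_fractions
  if (is.list(ef)) ef <- unlist(ef)
  ef <- ef[CYP_ENZYMES]
  ef[is.na(ef)] <- 0
  names(ef) <- CYP_ENZYMES
  stopifnot(fa > 0, fa <= 1, fu_plasma >= 0, fu_plasma <= 1, vss > 0,
            ka > 0, mw > 0, bp_ratio > 0, kp_scalar > 0, clint_hlm >= 0)
  if (abs(sum(ef) - 1) > 1e-9)
    stop_cypddi("enzyme_fractions must sum to 1 (got ", sum(ef), ")")
  structure(list(name = name, mw = mw, logP = logP, fu_plasma = fu_plasma,
                 bp_ratio = bp_ratio, fa = fa, ka = ka, peff = peff,
                 vss = vss, kp_scalar = kp_scalar, clint_hlm = clint_hlm,
                 enzyme_fractions = ef),
            class = "compound_params")
}

#' Physiology parameter set
#'
#' Defaults describe a representative healthy Chinese adult: 60 kg body
#' weight, 1650 g liver, 40 mg microsomal protein per g liver (MPPGL),
#' hepatic blood flow 90 L/h, CYP3A4 abundance scalar 1, CYP3A5 scalar 0.5
#' for *1/*3 expressers (0 for *3/*3 non-expressers), and a 36-h enzyme
#' turnover half-life (kdeg = 0.0193 1/h) for both CYP3A enzymes.
#'
#' @param body_weight kg.
#' @param liver_mass g.
#' @param mppgl mg microsomal protein per g liver.
#' @param hepatic_blood_flow L/h.
#' @param cyp_abundance named relative activity scalars per enzyme.
#' @param kdeg named enzyme degradation rate constants, 1/h.
#' @return object of class `physiology_params`.
#' @export
physiology_params <- function(body_weight = 60, liver_mass = 1650, mppgl = 40,
                              hepatic_blood_flow = 90,
                              cyp_abundance = c(CYP3A4 = 1, CYP3A5 = 0.5, other = 1),
                              kdeg = c(CYP3A4 = 0.0193, CYP3A5 = 0.0193)) {
  ca <- unlist(cyp_abundance)[CYP_ENZYMES]
  ca[is.na(ca)] <- 1
  names(ca) <- CYP_ENZYMES
  kd <- unlist(kdeg)[c("CYP3A4", "CYP3A5")]
  kd[is.na(kd)] <- 0.0193
  names(kd) <- c("CYP3A4", "CYP3A5")
  stopifnot(body_weight > 0, liver_mass > 0, mppgl > 0,
            hepatic_blood_flow > 0, all(ca >= 0), all(kd > 0))
  structure(list(body_weight = body_weight, liver_mass = liver_mass,
                 mppgl = mppgl, hepatic_blood_flow = hepatic_blood_flow,
                 cyp_abundance = ca, kdeg = kd),
            class = "physiology_params")
}

#' Oral dosing regimen
#'
#' @param compound compound name (must match a supplied `compound_params`).
#' @param dose_mg dose per administration, mg.
#' @param times_h administration times, h, strictly increasing.
#' @param label optional scenario label.
#' @param route `"oral"` (first-order depot) or `"infusion"` (zero-order into
#'   the central compartment; `dose_mg` is then the amount infused over
#'   `infusion_duration_h` starting at each time).
#' @param infusion_duration_h infusion length, h (infusion route only).
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(compound, dose_mg, times_h = 0, label = compound,
                         route = c("oral", "infusion"),
                         infusion_duration_h = NA_real_) {
  route <- match.arg(route)
  if (dose_mg <= 0) stop_cypddi("dose_mg must be > 0")
  if (is.unsorted(times_h, strictly = TRUE) && length(times_h) > 1L)
    stop_cypddi("times_h must be strictly increasing")
  if (route == "infusion" && !(is.finite(infusion_duration_h) && infusion_duration_h > 0))
    stop_cypddi("infusion route needs a positive infusion_duration_h")
  structure(list(compound = compound, route = route, dose_mg = dose_mg,
                 times_h = times_h, label = label,
                 infusion_duration_h = infusion_duration_h),
            class = "dose_regimen")
}

#' Scale microsomal intrinsic clearance to whole-liver clearance per enzyme
#'
#' CLint,liver(e) = clint_hlm x enzyme_fraction(e) x MPPGL x liver mass x
#' abundance(e) x 60 / 1e6, converting uL/min to L/h.
#'
#' @param compound a [compound_params()].
#' @param phys a [physiology_params()].
#' @return named numeric, L/h per enzyme (`CYP3A4`, `CYP3A5`, `other`).
#' @export
#' @examples
#' cp <- compound_params("x", mw = 400, fu_plasma = 0.1, bp_ratio = 1,
#'                       fa = 1, ka = 1, vss = 1, clint_hlm = 50,
#'                       enzyme_fractions = c(CYP3A4 = 1, CYP3A5 = 0, other = 0))
#' scale_clearance(cp, physiology_params())  # CYP3A4: 198 L/h
scale_clearance <- function(compound, phys) {
  compound$clint_hlm * compound$enzyme_fractions *
    phys$mppgl * phys$liver_mass * phys$cyp_abundance * 60 / 1e6
}

#' Well-stirred hepatic clearance
#'
#' CLh = Qh fu_b CLint / (Qh + fu_b CLint) with fu_b = fu_plasma / B:P and
#' CLint the (inhibition-adjusted) total whole-liver intrinsic clearance.
#' Returns whole-blood hepatic clearance; tends to 0 as CLint goes to 0 and
#' to Qh (the perfusion limit) as CLint grows.
#'
#' @param clint_total total whole-liver intrinsic clearance, L/h (e.g.
#'   `sum(scale_clearance(...))`, adjusted for inhibition).
#' @param compound a [compound_params()] (supplies fu_plasma and B:P).
#' @param phys a [physiology_params()] (supplies Qh).
#' @return hepatic blood clearance, L/h.
#' @export
hepatic_clearance <- function(clint_total, compound, phys) {
  if (any(clint_total < 0)) stop_cypddi("clint_total must be >= 0")
  fub <- compound$fu_plasma / compound$bp_ratio
  qh <- phys$hepatic_blood_flow
  qh * fub * clint_total / (qh + fub * clint_total)
}

#' Fold error between a predicted and an observed value
#'
#' max(predicted, observed) / min(predicted, observed); always >= 1 and
#' symmetric in its arguments. Values below 2 are conventionally read as
#' acceptable model accuracy.
#'
#' @param predicted,observed positive numbers (vectorized).
#' @return fold error, dimensionless.
#' @export
#' @examples
#' fold_error(126.88, 111.37)  # 1.14
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0))
    stop_cypddi("fold_error needs positive values")
  pmax(predicted, observed) / pmin(predicted, observed)
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf("<compound_params> %s: MW %.5g, fu,p %.3g, B/P %.3g, fa %.3g, ka %.3g 1/h, Vss %.3g L/kg (Kp scalar %.3g), CLint,HLM %.4g uL/min/mg\n",
              x$name, x$mw, x$fu_plasma, x$bp_ratio, x$fa, x$ka, x$vss,
              x$kp_scalar, x$clint_hlm))
  cat("  enzyme fractions: ",
      paste(sprintf("%s %.3g", names(x$enzyme_fractions), x$enzyme_fractions),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a compound parameter set from a YAML or JSON config
#'
#' Accepts a file with the fields of [compound_params()]; extra fields are
#' ignored. Packaged example configs live in `inst/extdata/` (`sza.yaml`,
#' `szb.yaml`, `tacrolimus.yaml`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `compound_params`.
#' @export
read_compound_config <- function(path) {
  if (!file.exists(path)) stop_cypddi("config not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(compound_params)))
  do.call(compound_params, cfg[keep])
}
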