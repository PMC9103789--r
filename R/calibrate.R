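# Baseline calibration of the victim model. The victim's source-level
# clearance parameters are not observable here, so its two free parameters -
# total microsomal CLint and the CYP3A5 share of it - are pinned by
# root-finding on the deterministic simulator so that the simulated oral
# victim AUC reproduces the target control exposures in CYP3A5
# non-expressers and expressers.

#' Calibrate the victim's clearance split against control AUC targets
#'
#' Solves for (`clint_hlm`, CYP3A5 enzyme fraction) of the victim such that
#' the simulated whole-blood AUC of a single oral victim dose matches
#' `auc_targets` in both genotype scenarios. The victim's `other` (non-CYP3A)
#' clearance fraction is held at its configured value; the CYP3A share is
#' split between CYP3A4 and CYP3A5. The non-expresser AUC depends only on
#' the CYP3A4 + other clearance, so the inner root pins `clint_hlm` given a
#' CYP3A5 fraction and the outer root pins the CYP3A5 fraction from the
#' expresser AUC.
#'
#' @param victim victim `compound_params` (its `clint_hlm` and CYP3A4/3A5
#'   fractions are overwritten; `enzyme_fractions[["other"]]` is kept).
#' @param phys a [physiology_params()].
#' @param scenarios list of two [genotype_scenario()]s, one `non_expresser`
#'   and one `expresser`.
#' @param auc_targets named targets, ng/mL.h, whole blood:
#'   `c(non_expresser = ..., expresser = ...)`.
#' @param dose_mg victim oral dose used for calibration, mg.
#' @param window_h AUC window from the dose, h.
#' @param dt output grid spacing, h.
#' @param tol_rel relative AUC tolerance of the root finder.
#' @return object of class `ddi_calibration`: `victim` (updated parameters),
#'   `scenarios` (with fm values filled in), `achieved` AUCs and the targets.
#' @export
calibrate_baseline <- function(victim, phys = physiology_params(), scenarios,
                               auc_targets = c(non_expresser = 118.07,
                                               expresser = 62.50),
                               dose_mg = 2, window_h = 120, dt = 0.05,
                               tol_rel = 1e-4) {
  labels <- vapply(scenarios, `[[`, character(1L), "label")
  if (!all(c("non_expresser", "expresser") %in% labels))
    stop_cypddi("scenarios must include one non_expresser and one expresser",
                class = "cypddi_calibration_error")
  names(scenarios) <- labels
  fo <- victim$enzyme_fractions[["other"]]
  sim_auc <- function(clint, f5, scalar) {
    vic <- victim
    vic$clint_hlm <- clint
    vic$enzyme_fractions <- c(CYP3A4 = 1 - f5 - fo, CYP3A5 = f5, other = fo)
    ph <- phys
    ph$cyp_abundance[["CYP3A5"]] <- scalar
    sim <- simulate_pk(vic, dose_regimen(vic$name, dose_mg, 0), ph,
                       duration_h = window_h, dt = dt)
    pk_metrics(sim, vic$name, blood = TRUE)$auc
  }
  scal <- vapply(scenarios, `[[`, numeric(1L), "cyp3a5_abundance_scalar")
  lcl_bounds <- log(c(1, 1e5))   # clint_hlm, uL/min/mg
  clint_for_ne <- function(f5) {
    f <- function(lcl) sim_auc(exp(lcl), f5, scal[["non_expresser"]]) -
      auc_targets[["non_expresser"]]
    flo <- f(lcl_bounds[1L]); fhi <- f(lcl_bounds[2L])
    if (sign(flo) == sign(fhi))
      stop_cypddi("calibration error: non-expresser target ",
                  auc_targets[["non_expresser"]],
                  " outside achievable AUC range [",
                  sprintf("%.4g", auc_targets[["non_expresser"]] + fhi), ", ",
                  sprintf("%.4g", auc_targets[["non_expresser"]] + flo), "]",
                  class = "cypddi_calibration_error")
    exp(stats::uniroot(f, lcl_bounds, f.lower = flo, f.upper = fhi,
                       tol = 1e-6)$root)
  }
  g <- function(f5) sim_auc(clint_for_ne(f5), f5, scal[["expresser"]]) -
    auc_targets[["expresser"]]
  f5_bounds <- c(1e-3, 1 - fo - 1e-3)
  glo <- g(f5_bounds[1L]); ghi <- g(f5_bounds[2L])
  if (sign(glo) == sign(ghi))
    stop_cypddi("calibration error: expresser target ",
                auc_targets[["expresser"]],
                " outside achievable AUC range [",
                sprintf("%.4g", auc_targets[["expresser"]] + min(glo, ghi)), ", ",
                sprintf("%.4g", auc_targets[["expresser"]] + max(glo, ghi)), "]",
                class = "cypddi_calibration_error")
  f5 <- stats::uniroot(g, f5_bounds, f.lower = glo, f.upper = ghi,
                       tol = 1e-6)$root
  clint <- clint_for_ne(f5)
  victim$clint_hlm <- clint
  victim$enzyme_fractions <- c(CYP3A4 = 1 - f5 - fo, CYP3A5 = f5, other = fo)
  achieved <- c(non_expresser = sim_auc(clint, f5, scal[["non_expresser"]]),
                expresser = sim_auc(clint, f5, scal[["expresser"]]))
  rel_err <- abs(achieved - auc_targets[names(achieved)]) /
    auc_targets[names(achieved)]
  if (any(rel_err > max(tol_rel, 0.01)))
    stop_cypddi("calibration did not reach targets within 1%",
                class = "cypddi_calibration_error")
  for (nm in names(scenarios)) {
    ph <- phys
    ph$cyp_abundance[["CYP3A5"]] <- scal[[nm]]
    cl <- scale_clearance(victim, ph)
    fm <- cl / sum(cl)
    scenarios[[nm]]$fm_cyp3a4 <- fm[["CYP3A4"]]
    scenarios[[nm]]$fm_cyp3a5 <- fm[["CYP3A5"]]
    scenarios[[nm]]$fm_other <- fm[["other"]]
  }
  structure(list(victim = victim, scenarios = scenarios,
                 achieved = achieved, targets = auc_targets,
                 clint_hlm = clint, f_cyp3a5 = f5),
            class = "ddi_calibration")
}

#' @export
print.ddi_calibration <- function(x, ...) {
  cat(sprintf("Victim calibration: CLint,HLM = %.4g uL/min/mg, CYP3A5 fraction = %.3f\n",
              x$clint_hlm, x$f_cyp3a5))
  for (nm in names(x$achieved))
    cat(sprintf("  %s: AUC %.2f ng/mL.h (target %.2f); fm CYP3A4 %.3f / CYP3A5 %.3f / other %.3f\n",
                nm, x$achieved[[nm]], x$targets[[nm]],
                x$scenarios[[nm]]$fm_cyp3a4, x$scenarios[[nm]]$fm_cyp3a5,
                x$scenarios[[nm]]$fm_other))
  invisible(x)
}
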