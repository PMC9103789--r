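# Drug-drug interaction layer: inhibition specifications combining reversible
# (Ki) and time-dependent (KI, kinact) components per CYP3A enzyme, genotype
# scenarios for CYP3A5 expressers/non-expressers, paired control/inhibited
# simulations with AUC ratios, and a static mechanistic AUCR oracle used as
# an independent cross-check of the dynamic model.

DDI_MODES <- c("RI_only", "TDI_only", "RI_and_TDI")

#' Inhibition specification for a perpetrator
#'
#' Per-enzyme inhibition parameters of a perpetrator on CYP3A4 and/or CYP3A5.
#' Each enzyme entry is a list with elements `ki` (reversible competitive
#' constant, uM), `KI` (half-maximal inactivation concentration, uM) and
#' `kinact` (maximal inactivation rate, 1/min); omit an enzyme entirely to
#' leave it untouched. The mode selects which components act: `RI_only`
#' requires `ki`, `TDI_only` requires `KI` and `kinact`, `RI_and_TDI`
#' requires all three, for every enzyme present.
#'
#' @param cyp3a4,cyp3a5 lists with `ki`, `KI`, `kinact` (any subset), or
#'   `NULL`.
#' @param mode one of `"RI_only"`, `"TDI_only"`, `"RI_and_TDI"`.
#' @param perpetrator,victim compound names used by [simulate_pk()].
#' @return object of class `interaction_spec`.
#' @export
interaction_spec <- function(cyp3a4 = NULL, cyp3a5 = NULL,
                             mode = c("RI_and_TDI", "RI_only", "TDI_only"),
                             perpetrator = NA_character_,
                             victim = NA_character_) {
  mode <- match.arg(mode)
  enzymes <- list(CYP3A4 = cyp3a4, CYP3A5 = cyp3a5)
  enzymes <- enzymes[!vapply(enzymes, is.null, logical(1L))]
  if (!length(enzymes))
    stop_cypddi("at least one enzyme entry is required",
                class = "cypddi_config_error")
  for (nm in names(enzymes)) {
    e <- enzymes[[nm]]
    need <- switch(mode, RI_only = "ki", TDI_only = c("KI", "kinact"),
                   RI_and_TDI = c("ki", "KI", "kinact"))
    missing_par <- setdiff(need, names(e)[!vapply(e, is.null, logical(1L))])
    if (length(missing_par))
      stop_cypddi("mode ", mode, " requires ", paste(missing_par, collapse = ", "),
                  " for ", nm, class = "cypddi_config_error")
    for (p in intersect(c("ki", "KI", "kinact"), names(e)))
      if (!is.null(e[[p]]) && !(is.numeric(e[[p]]) && e[[p]] > 0))
        stop_cypddi(nm, "$", p, " must be a positive number",
                    class = "cypddi_config_error")
  }
  structure(list(enzymes = enzymes, mode = mode,
                 perpetrator = perpetrator, victim = victim),
            class = "interaction_spec")
}

#' Reversible and time-dependent inhibition terms at one inhibitor level
#'
#' At unbound inhibitor concentration `iu_uM`, the reversible factor is
#' `1/(1 + Iu/Ki)` (1 when reversible inhibition is inactive or the enzyme is
#' not targeted) and the inactivation rate is
#' `kobs = 60 kinact Iu / (KI + Iu)` in 1/h (0 when TDI is inactive).
#'
#' @param iu_uM unbound liver concentration of the perpetrator, uM (>= 0).
#' @param spec an [interaction_spec()].
#' @param enzyme `"CYP3A4"` or `"CYP3A5"`.
#' @return named numeric `c(ri_factor, kobs)` with `kobs` in 1/h.
#' @export
inhibition_terms <- function(iu_uM, spec, enzyme = c("CYP3A4", "CYP3A5")) {
  enzyme <- match.arg(enzyme)
  iu_uM <- unname(iu_uM)
  if (length(iu_uM) != 1L || iu_uM < 0) stop_cypddi("iu_uM must be a single value >= 0")
  e <- spec$enzymes[[enzyme]]
  ri <- 1; kobs <- 0
  if (!is.null(e)) {
    if (spec$mode %in% c("RI_only", "RI_and_TDI") && !is.null(e$ki))
      ri <- 1 / (1 + iu_uM / e$ki)
    if (spec$mode %in% c("TDI_only", "RI_and_TDI") && !is.null(e$KI))
      kobs <- 60 * e$kinact * iu_uM / (e$KI + iu_uM)
  }
  c(ri_factor = ri, kobs = kobs)
}

#' Enzyme turnover rate of change under inactivation
#'
#' dE/dt = kdeg (1 - E) - kobs E for the active enzyme fraction E. The steady
#' state is E = kdeg / (kdeg + kobs); with kobs = 0 the fraction relaxes back
#' to 1 at rate kdeg.
#'
#' @param active_fraction active enzyme fraction (0-1).
#' @param kdeg degradation rate constant, 1/h.
#' @param kobs inactivation rate, 1/h.
#' @return d(fraction)/dt, 1/h.
#' @export
enzyme_turnover_rhs <- function(active_fraction, kdeg, kobs) {
  kdeg * (1 - active_fraction) - kobs * active_fraction
}

#' CYP3A5 genotype scenario
#'
#' @param label `"expresser"` (CYP3A5 *1/*3) or `"non_expresser"` (*3/*3).
#' @param cyp3a5_abundance_scalar relative CYP3A5 activity (0 for
#'   non-expressers).
#' @param fm_cyp3a4,fm_cyp3a5,fm_other baseline fractions of victim clearance
#'   per pathway; must sum to 1, and `fm_cyp3a5` must be 0 for non-expressers.
#'   May be left `NA` before calibration ([calibrate_baseline()] fills them).
#' @return object of class `genotype_scenario`.
#' @export
genotype_scenario <- function(label = c("expresser", "non_expresser"),
                              cyp3a5_abundance_scalar = if (label == "non_expresser") 0 else 0.5,
                              fm_cyp3a4 = NA_real_, fm_cyp3a5 = NA_real_,
                              fm_other = NA_real_) {
  label <- match.arg(label)
  fm <- c(CYP3A4 = fm_cyp3a4, CYP3A5 = fm_cyp3a5, other = fm_other)
  if (!anyNA(fm)) {
    if (abs(sum(fm) - 1) > 1e-9) stop_cypddi("fm values must sum to 1")
    if (label == "non_expresser" && fm[["CYP3A5"]] != 0)
      stop_cypddi("non-expresser must have fm_cyp3a5 = 0")
  }
  if (label == "non_expresser" && cyp3a5_abundance_scalar != 0)
    stop_cypddi("non-expresser must have cyp3a5_abundance_scalar = 0")
  structure(list(label = label,
                 cyp3a5_abundance_scalar = cyp3a5_abundance_scalar,
                 fm_cyp3a4 = fm[["CYP3A4"]], fm_cyp3a5 = fm[["CYP3A5"]],
                 fm_other = fm[["other"]]),
            class = "genotype_scenario")
}

#' Static mechanistic AUCR oracle
#'
#' Under a constant unbound inhibitor concentration the AUC ratio of the
#' victim is
#' \deqn{AUCR = 1 / (\sum_e fm_e \cdot ri_e \cdot kdeg/(kdeg + kobs_e) + fm_{other})}
#' with the sums over the targeted enzymes. Exact only at constant inhibitor
#' exposure; the dynamic simulation converges to it under a constant-rate
#' infusion of the perpetrator.
#'
#' @param iu_uM constant unbound inhibitor concentration, uM.
#' @param spec an [interaction_spec()].
#' @param genotype a [genotype_scenario()] with fm values set.
#' @param kdeg enzyme degradation rate constant, 1/h.
#' @return the predicted AUC ratio (dimensionless, >= 1 for an inhibitor).
#' @export
static_aucr_oracle <- function(iu_uM, spec, genotype, kdeg = 0.0193) {
  fm <- c(CYP3A4 = genotype$fm_cyp3a4, CYP3A5 = genotype$fm_cyp3a5)
  if (anyNA(c(fm, genotype$fm_other)))
    stop_cypddi("genotype scenario has no fm values (run calibrate_baseline)")
  denom <- genotype$fm_other
  for (e in names(fm)) {
    terms <- inhibition_terms(iu_uM, spec, e)
    denom <- denom + fm[[e]] * terms[["ri_factor"]] *
      kdeg / (kdeg + terms[["kobs"]])
  }
  1 / denom
}

#' One DDI scenario result
#'
#' Container pairing control and inhibited victim exposures; also the
#' constructor used to tabulate externally supplied AUC pairs.
#'
#' @param auc_control,auc_inhibited victim AUCs, ng/mL.h.
#' @param inhibitor,regimen,genotype,mode scenario labels.
#' @return object of class `ddi_result` with `aucr = auc_inhibited /
#'   auc_control` and `percent_increase = (aucr - 1) x 100`.
#' @export
ddi_result <- function(auc_control, auc_inhibited, inhibitor = NA_character_,
                       regimen = NA_character_, genotype = NA_character_,
                       mode = NA_character_) {
  aucr <- auc_inhibited / auc_control
  structure(list(auc_control = auc_control, auc_inhibited = auc_inhibited,
                 aucr = aucr, percent_increase = (aucr - 1) * 100,
                 scenario = list(inhibitor = inhibitor, regimen = regimen,
                                 genotype = genotype, mode = mode)),
            class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("DDI %s + %s dose, %s, %s: AUC %.2f -> %.2f ng/mL.h, AUCR %.2f (+%.0f%%)\n",
              s$inhibitor, s$regimen, s$genotype, s$mode,
              x$auc_control, x$auc_inhibited, round_half_up(x$aucr, 2),
              round_half_up(x$percent_increase, 0)))
  invisible(x)
}

#' Run one control/inhibited DDI simulation pair
#'
#' Simulates the victim with and without the perpetrator on identical output
#' grids and returns the AUC ratio over a 120-h window following the victim
#' dose (whole-blood victim exposure). Dosing designs: `"single"` gives both
#' compounds at t = 0; `"multiple"` gives the perpetrator twice daily for
#' 13.5 days (27 doses at t = 0, 12, ..., 312 h) and the victim once at
#' t = 324 h (day 14).
#'
#' @param victim calibrated victim `compound_params` (see
#'   [calibrate_baseline()]).
#' @param perpetrator perpetrator `compound_params`.
#' @param spec an [interaction_spec()] for the perpetrator (mode may be
#'   overridden by `mode`).
#' @param genotype a [genotype_scenario()].
#' @param regimen `"single"` or `"multiple"`.
#' @param mode inhibition mode, defaults to the spec's.
#' @param perp_dose_mg perpetrator dose per administration, mg (defaults: the
#'   regimen-specific doses must be supplied by the caller).
#' @param victim_dose_mg victim dose, mg.
#' @param phys a [physiology_params()]; its CYP3A5 abundance is overridden by
#'   the genotype scalar.
#' @param window_h AUC window after the victim dose, h.
#' @param dt output grid spacing, h.
#' @return a [ddi_result()] with the two `pbpk_sim` objects attached as
#'   `control_sim` / `inhibited_sim`.
#' @export
run_ddi <- function(victim, perpetrator, spec, genotype,
                    regimen = c("single", "multiple"),
                    mode = spec$mode, perp_dose_mg, victim_dose_mg = 2,
                    phys = physiology_params(), window_h = 120, dt = 0.05) {
  regimen <- match.arg(regimen)
  spec <- interaction_spec(cyp3a4 = spec$enzymes$CYP3A4,
                           cyp3a5 = spec$enzymes$CYP3A5, mode = mode,
                           perpetrator = perpetrator$name, victim = victim$name)
  phys$cyp_abundance[["CYP3A5"]] <- genotype$cyp3a5_abundance_scalar
  if (regimen == "single") {
    perp_times <- 0; victim_time <- 0
  } else {
    perp_times <- seq(0, by = 12, length.out = 27L); victim_time <- 324
  }
  duration <- victim_time + window_h
  reg_v <- dose_regimen(victim$name, victim_dose_mg, victim_time)
  ctrl <- simulate_pk(victim, reg_v, phys, duration_h = duration, dt = dt)
  # a zero perpetrator dose keeps the interaction machinery on with nothing
  # to drive it: the inhibited arm must then reproduce the control
  regs <- if (perp_dose_mg > 0)
    list(reg_v, dose_regimen(perpetrator$name, perp_dose_mg, perp_times))
  else list(reg_v)
  inh <- simulate_pk(list(victim, perpetrator), regs,
                     phys, interaction = spec, duration_h = duration, dt = dt)
  win <- c(victim_time, victim_time + window_h)
  auc_c <- pk_metrics(ctrl, victim$name, win, blood = TRUE)$auc
  auc_i <- pk_metrics(inh, victim$name, win, blood = TRUE)$auc
  out <- ddi_result(auc_c, auc_i, inhibitor = perpetrator$name,
                    regimen = regimen, genotype = genotype$label, mode = mode)
  out$control_sim <- ctrl
  out$inhibited_sim <- inh
  out
}

#' Tabulate DDI results
#'
#' @param results list of [ddi_result()] objects.
#' @return data.frame with one row per result: scenario labels, AUCs, AUCR
#'   and percent increase. Errors on duplicated scenario labels.
#' @export
scenario_table <- function(results) {
  cols <- c("inhibitor", "regimen", "genotype", "mode")
  if (!length(results))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 8)),
      c(cols, "auc_control", "auc_inhibited", "aucr", "percent_increase")))
  tab <- do.call(rbind, lapply(results, function(r) {
    s <- r$scenario
    data.frame(inhibitor = s$inhibitor, regimen = s$regimen,
               genotype = s$genotype, mode = s$mode,
               auc_control = r$auc_control, auc_inhibited = r$auc_inhibited,
               aucr = r$aucr, percent_increase = r$percent_increase)
  }))
  key <- do.call(paste, c(tab[cols], sep = "|"))
  if (anyDuplicated(key))
    stop_cypddi("duplicate scenario labels: ",
                paste(unique(key[duplicated(key)]), collapse = "; "))
  tab
}

#' Run the full genotype x inhibitor x regimen x case scenario grid
#'
#' Runs every combination of 2 genotypes, 2 inhibitors, 2 dosing regimens and
#' the 3 inhibition cases (#1 reversible only, #2 time-dependent only, #3
#' both) that the perpetrator's parameters support, and returns the 24-row
#' scenario table. Cells whose case needs a parameter the perpetrator lacks
#' (e.g. reversible-only for a pure inactivator) are reported with `NA` AUCs.
#'
#' @param calibration result of [calibrate_baseline()].
#' @param perpetrators named list: for each inhibitor, a list with elements
#'   `compound` (a `compound_params`), `spec` (the full [interaction_spec()],
#'   mode `RI_and_TDI` or `TDI_only` as supported), `single_dose_mg` and
#'   `bid_dose_mg`.
#' @param phys,dt passed to [run_ddi()].
#' @return data.frame in the layout of [scenario_table()], 24 rows.
#' @export
run_scenario_grid <- function(calibration, perpetrators,
                                phys = physiology_params(), dt = 0.05) {
  results <- list()
  for (g in calibration$scenarios) {
    for (pname in names(perpetrators)) {
      p <- perpetrators[[pname]]
      for (reg in c("single", "multiple")) {
        dose <- if (reg == "single") p$single_dose_mg else p$bid_dose_mg
        for (mode in DDI_MODES) {
          feasible <- tryCatch({
            interaction_spec(cyp3a4 = p$spec$enzymes$CYP3A4,
                             cyp3a5 = p$spec$enzymes$CYP3A5, mode = mode)
            TRUE
          }, error = function(e) FALSE)
          res <- if (feasible)
            run_ddi(calibration$victim, p$compound, p$spec, g, reg,
                    mode = mode, perp_dose_mg = dose, phys = phys, dt = dt)
          else ddi_result(NA_real_, NA_real_, inhibitor = pname, regimen = reg,
                          genotype = g$label, mode = mode)
          res$control_sim <- res$inhibited_sim <- NULL
          results[[length(results) + 1L]] <- res
        }
      }
    }
  }
  scenario_table(results)
}
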