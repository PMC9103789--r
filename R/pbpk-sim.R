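# Minimal dynamic PBPK model: oral depot -> liver -> central (optional
# peripheral), with well-stirred hepatic elimination driven by the unbound
# liver concentration (elimination flux = fu_plasma x CLint x C_liver) and
# first-order CYP turnover states that let reversible inhibition (Ki) and
# mechanism-based inactivation (KI, kinact) of a perpetrator modulate the
# victim's per-enzyme intrinsic clearance during the integration.
#
# Concentrations are plasma-referenced; whole-blood outputs are obtained by
# multiplying with the compound's B:P ratio. Amounts are mg, volumes L,
# times h.

N_STATES_PER_COMPOUND <- 5L  # depot, liver, central, peripheral, eliminated

#' Simulate concentration-time profiles for one or more compounds
#'
#' Integrates the depot -> liver -> central model for every supplied compound
#' simultaneously. Oral doses are instantaneous additions of `fa x dose` to
#' the depot; absorption into the liver is first-order (`ka`), the liver
#' exchanges with the central compartment at the hepatic blood flow, and
#' elimination is `fu_plasma x CLint_total x C_liver` with the per-enzyme
#' CLint from [scale_clearance()]. When an [interaction_spec()] is supplied,
#' the perpetrator's unbound liver concentration drives a reversible factor
#' `1/(1 + Iu/Ki)` and an inactivation rate `kobs = 60 kinact Iu/(KI + Iu)`
#' on the victim's CYP3A4/CYP3A5 clearance via enzyme turnover states
#' `dE/dt = kdeg (1 - E) - kobs E`.
#'
#' @param compounds a `compound_params` or list of them.
#' @param regimens a `dose_regimen` or list of them; every regimen must
#'   reference a supplied compound.
#' @param phys a [physiology_params()].
#' @param interaction optional [interaction_spec()] naming perpetrator and
#'   victim.
#' @param duration_h simulated span, h.
#' @param dt output grid spacing, h (default 0.05).
#' @param rtol,atol solver tolerances (adaptive stiff integrator, `lsoda`).
#' @return object of class `pbpk_sim`: `time_h`, `conc` (plasma ng/mL matrix,
#'   one column per compound), `conc_blood`, `amounts` (mg, per state),
#'   `enzyme` (active-fraction trajectories), `administered` (cumulative mg
#'   entering the system per compound) and the inputs.
#' @export
simulate_pk <- function(compounds, regimens, phys = physiology_params(),
                        interaction = NULL, duration_h = 24,
                        dt = 0.05, rtol = 1e-8, atol = 1e-10) {
  if (inherits(compounds, "compound_params")) compounds <- list(compounds)
  if (inherits(regimens, "dose_regimen")) regimens <- list(regimens)
  cnames <- vapply(compounds, `[[`, character(1L), "name")
  if (anyDuplicated(cnames)) stop_cypddi("duplicate compound names")
  names(compounds) <- cnames
  for (reg in regimens)
    if (!reg$compound %in% cnames)
      stop_cypddi("regimen references unknown compound: ", reg$compound)
  if (!is.null(interaction)) {
    if (!inherits(interaction, "interaction_spec"))
      stop_cypddi("interaction must be an interaction_spec")
    if (!all(c(interaction$perpetrator, interaction$victim) %in% cnames))
      stop_cypddi("interaction perpetrator/victim must name supplied compounds")
  }
  nc <- length(compounds)
  vli <- phys$liver_mass / 1000          # liver volume, L (density ~ 1)
  qh <- phys$hepatic_blood_flow
  pars <- lapply(compounds, function(cp) {
    list(ka = cp$ka,
         vc = cp$vss * cp$kp_scalar * phys$body_weight,
         fu = cp$fu_plasma,
         clint = scale_clearance(cp, phys),    # L/h per enzyme
         mw = cp$mw,
         q_periph = if (is.null(cp$q_periph)) 0 else cp$q_periph,
         v_periph = if (is.null(cp$v_periph)) 1 else cp$v_periph)
  })
  # dosing: t = 0 doses go into the initial state, later doses are solver
  # events; infusions are zero-order windows evaluated in the RHS
  y0 <- rep(0, nc * N_STATES_PER_COMPOUND + 2L)
  state_names <- c(t(outer(cnames, c("dep", "liv", "cen", "per", "elim"),
                           paste, sep = ".")), "E.CYP3A4", "E.CYP3A5")
  names(y0) <- state_names
  y0[c("E.CYP3A4", "E.CYP3A5")] <- 1
  ev <- NULL
  infusions <- list()
  for (reg in regimens) {
    ci <- match(reg$compound, cnames)
    if (reg$route == "oral") {
      amt <- compounds[[ci]]$fa * reg$dose_mg
      dep_state <- state_names[(ci - 1L) * N_STATES_PER_COMPOUND + 1L]
      t0 <- reg$times_h == 0
      if (any(t0)) y0[dep_state] <- y0[dep_state] + amt * sum(t0)
      if (any(!t0))
        ev <- rbind(ev, data.frame(var = dep_state, time = reg$times_h[!t0],
                                   value = amt, method = "add"))
    } else {
      infusions[[length(infusions) + 1L]] <-
        list(ci = ci, start = reg$times_h,
             end = reg$times_h + reg$infusion_duration_h,
             rate = reg$dose_mg / reg$infusion_duration_h)
    }
  }
  times <- seq(0, duration_h, by = dt)
  if (!is.null(ev)) {
    ev <- ev[ev$time <= duration_h, , drop = FALSE]
    ev <- ev[order(ev$time), , drop = FALSE]
    if (nrow(ev) == 0L) ev <- NULL else times <- sort(union(times, ev$time))
  }
  inter <- interaction
  vic_i <- if (!is.null(inter)) match(inter$victim, cnames) else 0L
  perp_i <- if (!is.null(inter)) match(inter$perpetrator, cnames) else 0L
  kdeg <- phys$kdeg

  rhs <- function(t, y, p) {
    dy <- numeric(length(y))
    e_frac <- c(CYP3A4 = y[[length(y) - 1L]], CYP3A5 = y[[length(y)]])
    ri <- c(CYP3A4 = 1, CYP3A5 = 1)
    kobs_h <- c(CYP3A4 = 0, CYP3A5 = 0)
    if (!is.null(inter)) {
      pp <- pars[[perp_i]]
      off <- (perp_i - 1L) * N_STATES_PER_COMPOUND
      c_li_perp <- y[[off + 2L]] / vli                 # mg/L plasma
      iu_uM <- pp$fu * c_li_perp * 1000 / pp$mw        # unbound, uM
      for (e in c("CYP3A4", "CYP3A5")) {
        terms <- inhibition_terms(iu_uM, inter, e)
        ri[[e]] <- terms[["ri_factor"]]
        kobs_h[[e]] <- terms[["kobs"]]
      }
    }
    dy[length(y) - 1L] <- kdeg[["CYP3A4"]] * (1 - e_frac[["CYP3A4"]]) -
      kobs_h[["CYP3A4"]] * e_frac[["CYP3A4"]]
    dy[length(y)] <- kdeg[["CYP3A5"]] * (1 - e_frac[["CYP3A5"]]) -
      kobs_h[["CYP3A5"]] * e_frac[["CYP3A5"]]
    for (i in seq_len(nc)) {
      p_i <- pars[[i]]
      off <- (i - 1L) * N_STATES_PER_COMPOUND
      dep <- y[[off + 1L]]; liv <- y[[off + 2L]]
      cen <- y[[off + 3L]]; per <- y[[off + 4L]]
      c_li <- liv / vli
      c_c <- cen / p_i$vc
      clint <- p_i$clint
      if (i == vic_i) {
        clint[["CYP3A4"]] <- clint[["CYP3A4"]] * ri[["CYP3A4"]] * e_frac[["CYP3A4"]]
        clint[["CYP3A5"]] <- clint[["CYP3A5"]] * ri[["CYP3A5"]] * e_frac[["CYP3A5"]]
      }
      elim_flux <- p_i$fu * sum(clint) * c_li
      inf_rate <- 0
      for (w in infusions) if (w$ci == i)
        inf_rate <- inf_rate + sum(w$rate * (t >= w$start & t < w$end))
      dy[off + 1L] <- -p_i$ka * dep
      dy[off + 2L] <- p_i$ka * dep + qh * (c_c - c_li) - elim_flux
      dy[off + 3L] <- qh * (c_li - c_c) + inf_rate +
        (if (p_i$q_periph > 0) p_i$q_periph * (per / p_i$v_periph - c_c) else 0)
      dy[off + 4L] <- if (p_i$q_periph > 0)
        p_i$q_periph * (c_c - per / p_i$v_periph) else 0
      dy[off + 5L] <- elim_flux
    }
    list(dy)
  }

  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                        events = if (!is.null(ev)) list(data = ev))
  if (attr(sol, "istate")[1L] < 0)
    stop_cypddi("ODE solver failed; last accepted time ",
                max(sol[, "time"], na.rm = TRUE), class = "cypddi_solver_error")
  tt <- sol[, "time"]
  conc <- sapply(seq_len(nc), function(i)
    sol[, paste0(cnames[i], ".cen")] / pars[[i]]$vc * 1000)
  conc <- matrix(conc, ncol = nc, dimnames = list(NULL, cnames))  # ng/mL plasma
  if (min(conc) < -1e-9 * max(abs(conc)))
    stop_cypddi("negative concentrations beyond tolerance",
                class = "cypddi_solver_error")
  conc[conc < 0] <- 0
  bp <- vapply(compounds, `[[`, numeric(1L), "bp_ratio")
  conc_blood <- sweep(conc, 2L, bp, `*`)
  administered <- sapply(seq_len(nc), function(i) {
    tot <- rep(0, length(tt))
    for (reg in regimens) {
      if (match(reg$compound, cnames) != i) next
      if (reg$route == "oral") {
        amt <- compounds[[i]]$fa * reg$dose_mg
        # doses at t = 0 sit in the initial state; later doses are solver
        # events, applied after the output row at the event time is written
        for (d in reg$times_h) tot <- tot + amt * (if (d == 0) tt >= d else tt > d)
      } else {
        for (k in seq_along(reg$times_h)) {
          st <- reg$times_h[k]; en <- st + reg$infusion_duration_h
          rate <- reg$dose_mg / reg$infusion_duration_h
          tot <- tot + rate * pmin(pmax(tt - st, 0), en - st)
        }
      }
    }
    tot
  })
  administered <- matrix(administered, ncol = nc, dimnames = list(NULL, cnames))
  structure(list(time_h = tt, conc = conc, conc_blood = conc_blood,
                 amounts = sol[, state_names[seq_len(nc * N_STATES_PER_COMPOUND)],
                               drop = FALSE],
                 enzyme = sol[, c("E.CYP3A4", "E.CYP3A5"), drop = FALSE],
                 administered = administered,
                 compounds = compounds, regimens = regimens, phys = phys,
                 interaction = interaction),
            class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %d compound(s), t = 0..%g h (%d points)%s\n",
              ncol(x$conc), max(x$time_h), length(x$time_h),
              if (!is.null(x$interaction))
                sprintf(", interaction %s -> %s [%s]",
                        x$interaction$perpetrator, x$interaction$victim,
                        x$interaction$mode) else ""))
  for (nm in colnames(x$conc)) {
    m <- pk_metrics(x, nm)
    cat(sprintf("  %s: Cmax %.4g ng/mL at %.2f h, AUC(0-%g) %.4g ng/mL.h\n",
                nm, m$cmax, m$tmax, max(x$time_h), m$auc))
  }
  invisible(x)
}

#' @export
plot.pbpk_sim <- function(x, compound = colnames(x$conc), blood = FALSE, ...) {
  mat <- if (blood) x$conc_blood else x$conc
  mat <- mat[, compound, drop = FALSE]
  graphics::matplot(x$time_h, mat, type = "l", lty = 1,
                    xlab = "time (h)",
                    ylab = sprintf("%s concentration (ng/mL)",
                                   if (blood) "blood" else "plasma"), ...)
  graphics::legend("topright", legend = compound, lty = 1,
                   col = seq_along(compound), bty = "n")
  invisible(x)
}

#' Tidy concentration profile table
#'
#' @param sim a `pbpk_sim`.
#' @param compound compound name(s); default all.
#' @param blood report whole-blood instead of plasma concentrations.
#' @return data.frame `time_h`, `compound`, `conc_ng_per_mL`.
#' @export
profile_table <- function(sim, compound = colnames(sim$conc), blood = FALSE) {
  mat <- if (blood) sim$conc_blood else sim$conc
  do.call(rbind, lapply(compound, function(nm)
    data.frame(time_h = sim$time_h, compound = nm,
               conc_ng_per_mL = mat[, nm])))
}

#' Maximum mass-balance residual of a simulation
#'
#' For each compound, |amount in system + eliminated - administered| over the
#' whole output grid, as a fraction of the total administered amount. Should
#' be within solver tolerance of zero.
#'
#' @param sim a `pbpk_sim`.
#' @return named numeric, one relative residual per compound.
#' @export
mass_balance_residual <- function(sim) {
  nc <- ncol(sim$conc)
  res <- vapply(seq_len(nc), function(i) {
    cols <- (i - 1L) * N_STATES_PER_COMPOUND + seq_len(N_STATES_PER_COMPOUND)
    in_system <- rowSums(sim$amounts[, cols, drop = FALSE])
    tot <- max(sim$administered[, i])
    if (tot == 0) return(0)
    max(abs(in_system - sim$administered[, i])) / tot
  }, numeric(1L))
  stats::setNames(res, colnames(sim$conc))
}

#' Summary pharmacokinetic metrics from a simulated profile
#'
#' Cmax and Tmax are read from the output grid; AUC is the trapezoid over the
#' grid inside the window, with no extrapolation beyond it.
#'
#' @param sim a `pbpk_sim`.
#' @param compound compound name.
#' @param window `c(start, end)` in h; default the whole simulated span.
#' @param blood use whole-blood concentrations (e.g. tacrolimus exposure).
#' @return object of class `pk_metrics`: `cmax` (ng/mL), `tmax` (h), `auc`
#'   (ng/mL.h) and `auc_window`.
#' @export
pk_metrics <- function(sim, compound, window = NULL, blood = FALSE) {
  mat <- if (blood) sim$conc_blood else sim$conc
  if (!compound %in% colnames(mat)) stop_cypddi("unknown compound: ", compound)
  if (is.null(window)) window <- range(sim$time_h)
  sel <- sim$time_h >= window[1L] & sim$time_h <= window[2L]
  if (!any(sel)) stop_cypddi("window outside the simulated span")
  tt <- sim$time_h[sel]; cc <- mat[sel, compound]
  i <- which.max(cc)
  structure(list(cmax = cc[i], tmax = tt[i], auc = trapz_auc(tt, cc),
                 auc_window = window, compound = compound,
                 matrix = if (blood) "blood" else "plasma"),
            class = "pk_metrics")
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("%s (%s): Cmax %.4g ng/mL, Tmax %.3g h, AUC(%g-%g h) %.4g ng/mL.h\n",
              x$compound, x$matrix, x$cmax, x$tmax,
              x$auc_window[1L], x$auc_window[2L], x$auc))
  invisible(x)
}
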