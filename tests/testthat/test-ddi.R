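# Interaction arithmetic, enzyme turnover and scenario plumbing. The heavier
# simulation-based properties (monotonicity, static-oracle agreement,
# calibration) live in test-acceptance.R.

test_that("inhibition terms reduce to the textbook special cases", {
  spec <- szb_spec()
  expect_equal(inhibition_terms(0, spec, "CYP3A4"),
               c(ri_factor = 1, kobs = 0))
  expect_equal(inhibition_terms(2.03, spec, "CYP3A4")[["ri_factor"]], 0.5)
  expect_equal(inhibition_terms(0.69, spec, "CYP3A4")[["kobs"]], 30 * 0.37)
  expect_equal(inhibition_terms(0.5, spec, "CYP3A5")[["kobs"]], 30 * 0.009)
  # an enzyme without an entry is untouched
  sza <- sza_spec()
  expect_equal(inhibition_terms(10, sza, "CYP3A5"),
               c(ri_factor = 1, kobs = 0))
  expect_error(inhibition_terms(-1, spec, "CYP3A4"), ">= 0")
})

test_that("mode/parameter mismatches are configuration errors", {
  expect_error(interaction_spec(cyp3a4 = list(KI = 1, kinact = 0.1),
                                mode = "RI_only"),
               "requires ki", class = "cypddi_config_error")
  expect_error(interaction_spec(cyp3a4 = list(ki = 1), mode = "TDI_only"),
               class = "cypddi_config_error")
  expect_error(interaction_spec(mode = "RI_only"), "at least one enzyme",
               class = "cypddi_config_error")
  expect_error(interaction_spec(cyp3a4 = list(ki = -2), mode = "RI_only"),
               "positive", class = "cypddi_config_error")
})

test_that("enzyme turnover has the analytic steady state and relaxation", {
  expect_equal(enzyme_turnover_rhs(0.0193 / (0.0193 + 0.5), 0.0193, 0.5), 0,
               tolerance = 1e-15)
  expect_equal(enzyme_turnover_rhs(1, 0.0193, 0), 0)
  # trajectory under a constant inhibition step matches the linear-ODE solution
  kdeg <- 0.0193; kobs <- 0.3
  f <- function(t) {
    ess <- kdeg / (kdeg + kobs)
    ess + (1 - ess) * exp(-(kdeg + kobs) * t)
  }
  traj <- deSolve::lsoda(c(E = 1), seq(0, 48, 0.5),
                         function(t, y, p) list(enzyme_turnover_rhs(y, kdeg, kobs)),
                         NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(traj[, "E"]), f(traj[, "time"]), tolerance = 1e-6)
})

test_that("static AUCR oracle collapses correctly at its boundaries", {
  gen <- genotype_scenario("expresser", fm_cyp3a4 = 0.45, fm_cyp3a5 = 0.48,
                           fm_other = 0.07)
  expect_equal(static_aucr_oracle(0, szb_spec(), gen), 1)
  only_other <- genotype_scenario("expresser", fm_cyp3a4 = 0, fm_cyp3a5 = 0,
                                  fm_other = 1)
  expect_equal(static_aucr_oracle(50, szb_spec(), only_other), 1)
  expect_gt(static_aucr_oracle(0.1, szb_spec(), gen), 1)
})

test_that("genotype scenarios enforce their fm and abundance invariants", {
  expect_error(genotype_scenario("non_expresser", cyp3a5_abundance_scalar = 0.5),
               "non-expresser")
  expect_error(genotype_scenario("non_expresser", fm_cyp3a4 = 0.8,
                                 fm_cyp3a5 = 0.1, fm_other = 0.1),
               "fm_cyp3a5")
  expect_error(genotype_scenario("expresser", fm_cyp3a4 = 0.5, fm_cyp3a5 = 0.4,
                                 fm_other = 0.3), "sum to 1")
})

test_that("scenario tabulation reports AUCR and percent increase per scenario", {
  res <- reported_ddi_results()
  tab <- scenario_table(res)
  expect_equal(nrow(tab), 16L)
  expect_equal(tab$aucr, tab$auc_inhibited / tab$auc_control)
  expect_equal(tab$percent_increase, (tab$aucr - 1) * 100)
  # the three headline multiple-dose percent increases
  pick <- function(g, i) tab$percent_increase[tab$genotype == g & tab$inhibitor == i &
                                              tab$regimen == "multiple" &
                                              tab$mode %in% c("RI_and_TDI", "TDI_only")]
  expect_equal(round_half_up(max(pick("non_expresser", "SZB")), 0), 57)
  expect_equal(round_half_up(max(pick("expresser", "SZB")), 0), 23)
  expect_equal(round_half_up(max(pick("non_expresser", "SZA")), 0), 16)
  # duplicates rejected; empty input allowed
  expect_error(scenario_table(c(res, res[1])), "duplicate")
  expect_equal(nrow(scenario_table(list())), 0L)
})

test_that("run_ddi with a zero perpetrator dose reproduces the control arm", {
  cal_victim <- tacrolimus_params()
  gen <- genotype_scenario("expresser")
  r <- run_ddi(cal_victim, szb_params(), szb_spec(), gen, "single",
               perp_dose_mg = 0, dt = 0.1)
  expect_equal(r$aucr, 1, tolerance = 1e-6)
})

test_that("the scenario grid emits the full 24-cell layout with gaps for SZA RI cases", {
  # a pre-assembled victim/scenario bundle stands in for a full calibration
  stub <- list(victim = tacrolimus_params(),
               scenarios = list(
                 non_expresser = genotype_scenario("non_expresser",
                                                   fm_cyp3a4 = 0.86, fm_cyp3a5 = 0,
                                                   fm_other = 0.14),
                 expresser = genotype_scenario("expresser", fm_cyp3a4 = 0.45,
                                               fm_cyp3a5 = 0.48, fm_other = 0.07)))
  tab <- run_scenario_grid(stub, default_perpetrators(), dt = 1)
  expect_equal(nrow(tab), 24L)
  expect_equal(sum(is.na(tab$aucr)), 8L)          # SZA RI_only and RI_and_TDI
  expect_true(all(is.na(tab$aucr[tab$inhibitor == "SZA" & tab$mode != "TDI_only"])))
  expect_true(all(tab$aucr[!is.na(tab$aucr)] >= 1 - 1e-9))
  wide <- build_table2(tab)
  expect_equal(nrow(wide), 8L)
  expect_true(all(wide$RI_only[wide$inhibitor == "SZA"] == "—"))
})
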