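test_that("microsomal clearance scales to whole-liver L/h by unit arithmetic", {
  phys <- physiology_params()
  cp <- compound_params("x", mw = 400, fu_plasma = 0.1, bp_ratio = 1, fa = 1,
                        ka = 1, vss = 1, clint_hlm = 50,
                        enzyme_fractions = c(CYP3A4 = 1, CYP3A5 = 0, other = 0))
  cl <- scale_clearance(cp, phys)
  expect_equal(unname(cl[["CYP3A4"]]), 50 * 40 * 1650 * 60 / 1e6)  # 198 L/h
  expect_equal(unname(cl[["CYP3A5"]]), 0)
  # independent brute-force conversion for the SZB value
  szb <- szb_params()
  szb$enzyme_fractions <- c(CYP3A4 = 1, CYP3A5 = 0, other = 0)
  by_hand <- 4.5 * 1e-6 * 60 * 40 * 1650       # uL/min/mg -> L/h, x MPPGL x liver
  expect_equal(unname(scale_clearance(szb, phys)[["CYP3A4"]]), by_hand)
})

test_that("well-stirred clearance has the right limits and closed form", {
  phys <- physiology_params()
  cp <- compound_params("x", mw = 400, fu_plasma = 0.2, bp_ratio = 0.8, fa = 1,
                        ka = 1, vss = 1, clint_hlm = 1)
  expect_equal(hepatic_clearance(0, cp, phys), 0)
  expect_equal(hepatic_clearance(1e12, cp, phys), phys$hepatic_blood_flow,
               tolerance = 1e-9)
  fub <- 0.2 / 0.8
  expect_equal(hepatic_clearance(100, cp, phys),
               90 * fub * 100 / (90 + fub * 100))
})

test_that("mass balance holds to solver tolerance across dosing designs", {
  sim <- simulate_pk(sza_params(), dose_regimen("SZA", 33.6), duration_h = 48)
  expect_lt(max(mass_balance_residual(sim)), 1e-6)
  multi <- simulate_pk(szb_params(),
                       dose_regimen("SZB", 5.4, seq(0, 60, by = 12)),
                       duration_h = 96)
  expect_lt(max(mass_balance_residual(multi)), 1e-6)
})

test_that("the uninhibited model is dose-proportional", {
  s1 <- simulate_pk(szb_params(), dose_regimen("SZB", 10.8), duration_h = 48)
  s2 <- simulate_pk(szb_params(), dose_regimen("SZB", 21.6), duration_h = 48)
  m1 <- pk_metrics(s1, "SZB"); m2 <- pk_metrics(s2, "SZB")
  expect_equal(m2$cmax / m1$cmax, 2, tolerance = 1e-6)
  expect_equal(m2$auc / m1$auc, 2, tolerance = 1e-6)
})

test_that("oral AUC matches the analytic F x dose / clearance closed form", {
  # in this liver-entry model the oral plasma AUC over (0, inf) is exactly
  # fa * dose / (fu * CLint,total), independent of flow and volumes
  cp <- compound_params("y", mw = 400, fu_plasma = 0.1, bp_ratio = 1, fa = 0.8,
                        ka = 1.5, vss = 0.8, clint_hlm = 120,
                        enzyme_fractions = c(CYP3A4 = 1, CYP3A5 = 0, other = 0))
  clint <- sum(scale_clearance(cp, physiology_params()))
  sim <- simulate_pk(cp, dose_regimen("y", 10), duration_h = 200)
  auc <- pk_metrics(sim, "y")$auc                      # ng/mL.h == ug/L.h
  expect_equal(auc, 0.8 * 10 * 1000 / (0.1 * clint), tolerance = 5e-3)
})

test_that("PK metrics reproduce closed-form profiles on mock grids", {
  tt <- seq(0, 10, by = 0.05)
  const <- mock_sim(tt, rep(3, length(tt)))
  m <- pk_metrics(const, "x")
  expect_equal(m$auc, 30)
  expect_equal(m$cmax, 3)
  tri <- mock_sim(tt, pmax(0, 5 - abs(tt - 5)))        # triangle, area 25
  m2 <- pk_metrics(tri, "x", window = c(0, 10))
  expect_equal(m2$auc, 25)
  expect_equal(m2$tmax, 5)
  expect_equal(pk_metrics(tri, "x", blood = TRUE)$cmax, 10)  # B:P = 2
  expect_error(pk_metrics(tri, "x", window = c(50, 60)), "window")
  expect_error(pk_metrics(tri, "zz"), "unknown compound")
})

test_that("fold error is symmetric, >= 1, and matches reported table cells", {
  expect_equal(round_half_up(fold_error(126.88, 111.37), 2), 1.14)
  expect_equal(round_half_up(fold_error(271.74, 242.97), 2), 1.12)
  expect_equal(fold_error(7, 7), 1)
  set.seed(4)
  a <- runif(20, 0.1, 10); b <- runif(20, 0.1, 10)
  expect_equal(fold_error(a, b), fold_error(b, a))
  expect_true(all(fold_error(a, b) >= 1))
  expect_error(fold_error(-1, 2), "positive")
})

test_that("simulated perpetrator Cmax lands within 2-fold of the reference predictions", {
  sza <- simulate_pk(sza_params(), dose_regimen("SZA", 33.6), duration_h = 48)
  expect_lt(fold_error(pk_metrics(sza, "SZA")$cmax, 126.88), 2)
  szb <- simulate_pk(szb_params(), dose_regimen("SZB", 10.8), duration_h = 48)
  expect_lt(fold_error(pk_metrics(szb, "SZB")$cmax, 66.70), 2)
})

test_that("config round trip: packaged YAML equals the built-in parameter sets", {
  path <- system.file("extdata", "szb.yaml", package = "cypddi")
  expect_true(nzchar(path))
  cfg <- read_compound_config(path)
  expect_equal(cfg, szb_params())
})
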