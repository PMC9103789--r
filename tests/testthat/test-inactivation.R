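test_that("kobs is the negated log-linear decay slope with closed-form cases", {
  tt <- c(0, 5, 10, 20, 30)
  rec <- expand.grid(substrate_conc_uM = 200, inhibitor_conc_uM = c(0, 1),
                     preincubation_min = tt, replicate = 1,
                     KEEP.OUT.ATTRS = FALSE)
  rec$response <- ifelse(rec$inhibitor_conc_uM == 0, 1,
                         exp(-0.03 * rec$preincubation_min))
  ds <- assay_dataset(rec, "tdi", normalized = TRUE)
  expect_equal(fit_kobs(ds, 1), 0.03, tolerance = 1e-12)
  expect_equal(fit_kobs(ds, 0, control_correct = FALSE), 0)
  # nonpositive activity breaks the log transform
  rec$response[rec$inhibitor_conc_uM == 1 & rec$preincubation_min == 30] <- 0
  ds_bad <- assay_dataset(rec, "tdi", normalized = TRUE)
  expect_error(fit_kobs(ds_bad, 1), "log")
})

test_that("kobs at the half-saturation concentration equals kinact/2", {
  ds <- generate_tdi_dataset(KI = 0.43, kinact = 0.044,
                             inhibitor_uM = c(0, 0.1, 0.43, 1, 2), cv = 0)
  nds <- normalize_to_control(ds)
  expect_lt(abs(fit_kobs(nds, 0.43) - 0.022), 1e-6)
})

test_that("control-slope subtraction removes NADPH-independent activity loss", {
  ds <- generate_tdi_dataset(KI = 0.43, kinact = 0.044, control_loss = 0.005,
                             cv = 0)
  nds <- normalize_to_control(ds)
  # with correction the true kobs is recovered; without it the loss leaks in
  expect_equal(fit_kobs(nds, 2), 0.044 * 2 / 2.43, tolerance = 1e-9)
  expect_equal(fit_kobs(nds, 2, control_correct = FALSE),
               0.044 * 2 / 2.43 + 0.005, tolerance = 1e-9)
})

test_that("noiseless kobs values give exact (kinact, KI) and efficiencies", {
  mk <- function(kinact, KI, conc) setNames(kinact * conc / (KI + conc), conc)
  f <- fit_inactivation(mk(0.37, 0.69, c(0.5, 1, 2, 4, 8)))
  expect_lt(abs(f$kinact - 0.37) / 0.37, 1e-6)
  expect_lt(abs(f$KI - 0.69) / 0.69, 1e-6)
  expect_equal(round_half_up(f$efficiency, 1), 536.2)
  f2 <- fit_inactivation(mk(0.009, 0.5, c(2, 4, 8, 16)))
  expect_equal(f2$efficiency, 18, tolerance = 1e-6)
  # Kitz-Wilson cross-check agrees on noiseless data
  expect_equal(unname(f$kitz_wilson[["kinact"]]), 0.37, tolerance = 1e-6)
  expect_equal(unname(f$kitz_wilson[["KI"]]), 0.69, tolerance = 1e-6)
})

test_that("all-zero kobs values cannot be fitted", {
  expect_error(fit_inactivation(setNames(rep(0, 5), c(0.5, 1, 2, 4, 8))),
               "no inactivation", class = "cypddi_fit_error")
  expect_error(fit_inactivation(setNames(c(0.01, 0.02), c(1, 2))), ">= 4")
})

test_that("random noiseless truths are recovered through the full TDI pipeline", {
  set.seed(31)
  for (i in 1:8) {
    KI <- exp(runif(1, log(0.2), log(20)))
    kinact <- exp(runif(1, log(0.01), log(0.4)))
    ds <- generate_tdi_dataset(KI = KI, kinact = kinact,
                               inhibitor_uM = c(0, KI * c(0.25, 0.5, 1, 2, 4)),
                               cv = 0)
    f <- fit_tdi(ds)
    expect_lt(abs(f$KI - KI) / KI, 1e-6)
    expect_lt(abs(f$kinact - kinact) / kinact, 1e-6)
  }
})

test_that("fitted kobs is nondecreasing in concentration and below kinact", {
  ds <- generate_tdi_dataset(KI = 0.43, kinact = 0.044, cv = 0)
  nds <- normalize_to_control(ds)
  conc <- sort(setdiff(unique(nds$inhibitor_conc_uM), 0))
  kobs <- vapply(conc, function(ci) fit_kobs(nds, ci), numeric(1))
  expect_true(all(diff(kobs) >= -1e-12))
  expect_true(all(kobs <= 0.044 + 1e-12))
})

test_that("efficiency reproduces the reported kinact/KI potency values", {
  expect_equal(round_half_up(efficiency(0.044, 0.43), 2), 102.33)
  expect_equal(round_half_up(efficiency(0.029, 15.625), 3), 1.856)
  expect_equal(round_half_up(efficiency(0.024, 15.38), 2), 1.56)
  expect_error(efficiency(0, 1), "positive")
  expect_error(efficiency(0.1, -2), "positive")
})
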