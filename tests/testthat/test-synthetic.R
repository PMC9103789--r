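test_that("generators are pure functions of their seed", {
  a <- generate_dixon_dataset(5.82, cv = 0.1, seed = 99)
  b <- generate_dixon_dataset(5.82, cv = 0.1, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_dixon_dataset(5.82, cv = 0.1, seed = 100)
  expect_false(identical(a$response, c$response))
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_tdi_dataset(0.43, 0.044, cv = 0.2, seed = 5))
  expect_identical(runif(1), before)
})

test_that("generated datasets pass validation for every assay kind", {
  expect_s3_class(validate_assay_dataset(generate_dixon_dataset(2, cv = 0.1, seed = 1)),
                  "assay_dataset")
  expect_s3_class(validate_assay_dataset(generate_tdi_dataset(0.5, 0.05, cv = 0.1, seed = 1)),
                  "assay_dataset")
  expect_s3_class(validate_assay_dataset(generate_ic50_dataset(1, cv = 0.1, seed = 1)),
                  "assay_dataset")
})

test_that("noiseless responses equal the generating model exactly", {
  ds <- generate_dixon_dataset(5.82, cv = 0)
  v <- 100 * ds$substrate_conc_uM /
    (1.2 * (1 + ds$inhibitor_conc_uM / 5.82) + ds$substrate_conc_uM)
  expect_identical(ds$response, v)
  td <- generate_tdi_dataset(0.43, 0.044, cv = 0)
  expect_true(all(td$response[td$preincubation_min == 0] == 1))
})

test_that("generate -> fit closes on the truth at zero noise for all kinds", {
  set.seed(17)
  ki <- exp(runif(1, log(0.5), log(50)))
  expect_lt(abs(fit_dixon(generate_dixon_dataset(ki, cv = 0))$ki - ki) / ki, 1e-6)
  ic <- exp(runif(1, log(0.1), log(10)))
  dsic <- generate_ic50_dataset(ic, inhibitor_uM = ic * c(0, 0.1, 0.25, 0.5, 1, 2, 4, 10),
                                cv = 0)
  expect_lt(abs(fit_ic50(dsic)$ic50 - ic) / ic, 1e-6)
  f <- fit_tdi(generate_tdi_dataset(0.43, 0.044, cv = 0))
  expect_equal(round_half_up(f$efficiency, 2), 102.33)
})

test_that("lognormal noise has roughly the requested CV and unit mean", {
  ds <- generate_ic50_dataset(1e6, inhibitor_uM = c(0, rep(1, 1)), replicates = 2000,
                              cv = 0.1, seed = 8)
  x <- ds$response  # flat curve at 1, pure noise
  expect_equal(mean(x), 1, tolerance = 0.02)
  expect_equal(sd(x) / mean(x), 0.1, tolerance = 0.15)
})

test_that("sampled observations wrap the simulated profile with positive noise", {
  sim <- simulate_pk(szb_params(), dose_regimen("SZB", 10.8), duration_h = 24)
  obs0 <- generate_pk_observations(sim, "SZB", cv = 0, seed = 2)
  pred <- approx(sim$time_h, sim$conc[, "SZB"], xout = obs0$time_h)$y
  expect_equal(obs0$conc_ng_per_mL, pred)
  expect_true(all(fold_error(pred, obs0$conc_ng_per_mL + 1e-12) >= 1))
  obs1 <- generate_pk_observations(sim, "SZB", cv = 0.1, seed = 2)
  obs2 <- generate_pk_observations(sim, "SZB", cv = 0.1, seed = 2)
  expect_identical(obs1, obs2)
  expect_true(all(fold_error(pred, obs1$conc_ng_per_mL) >= 1))
})
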