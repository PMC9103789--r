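test_that("CSV read/write round trip preserves every field bit-exactly", {
  ds <- generate_dixon_dataset(5.82, cv = 0.05, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(ds, path)
  back <- read_assay_csv(path, "dixon")
  for (col in names(as.data.frame(ds)))
    expect_identical(back[[col]], ds[[col]], label = col)
  # sidecar metadata restored
  expect_identical(attr(back, "probe"), "tacrolimus")
  expect_identical(attr(back, "protein_conc"), 0.2)
})

test_that("a small well-formed CSV yields a dataset of matching size", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("substrate_conc_uM,inhibitor_conc_uM,preincubation_min,replicate,response",
               "200,0,0,1,1.0", "200,1,0,1,0.6", "200,2,0,1,0.4",
               "200,4,0,1,0.25", "200,8,0,1,0.12", "200,16,0,1,0.05"),
             path)
  ds <- read_assay_csv(path, "ic50", normalized = TRUE)
  expect_s3_class(ds, "assay_dataset")
  expect_equal(nrow(ds), 6L)
})

test_that("malformed and invalid CSV input is rejected with row context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("substrate_conc_uM,inhibitor_conc_uM,preincubation_min,replicate,response",
               "200,0,0,1,1.0", "200,xx,0,1,0.6"), path)
  expect_error(read_assay_csv(path, "ic50"), "row.*2", class = "cypddi_parse_error")
  writeLines(c("substrate_conc_uM,inhibitor_conc_uM,preincubation_min,replicate,response",
               "200,0,0,1,1.0", "200,1,0,1,"), path)
  expect_error(read_assay_csv(path, "ic50"), "missing", class = "cypddi_parse_error")
  writeLines(c("substrate_conc_uM,inhibitor_conc_uM,preincubation_min,replicate,response",
               "200,-1,0,1,1.0", "200,1,0,1,0.4"), path)
  expect_error(read_assay_csv(path, "ic50"), "negative",
               class = "cypddi_validation_error")
})

test_that("design invariants are enforced per assay kind", {
  rec <- expand.grid(substrate_conc_uM = c(0.5, 1), inhibitor_conc_uM = c(0, 1, 2),
                     preincubation_min = 0, replicate = 1, KEEP.OUT.ATTRS = FALSE)
  rec$response <- 1
  expect_error(assay_dataset(rec, "dixon"), "3 distinct substrate",
               class = "cypddi_validation_error")
  rec2 <- expand.grid(substrate_conc_uM = 200, inhibitor_conc_uM = c(1, 2),
                      preincubation_min = c(0, 5, 10, 20), replicate = 1,
                      KEEP.OUT.ATTRS = FALSE)
  rec2$response <- 1
  expect_error(assay_dataset(rec2, "tdi"), "control series",
               class = "cypddi_validation_error")
})

test_that("dilution correction is the aliquot ratio at the activity stage only", {
  d <- dilution_spec(20, 200)
  expect_equal(applied_inhibitor_conc(2.0, d, "activity"), 0.2)
  expect_equal(applied_inhibitor_conc(16, d, "preincubation"), 16)
  expect_equal(applied_inhibitor_conc(0, d, "activity"), 0)
  # linear in the nominal concentration
  nom <- c(0.1, 1, 7, 30)
  expect_equal(applied_inhibitor_conc(3 * nom, d, "activity"),
               3 * applied_inhibitor_conc(nom, d, "activity"))
  expect_error(dilution_spec(200, 20), class = "cypddi_validation_error")
})

test_that("control normalization rescales to unit control mean and is idempotent", {
  rec <- expand.grid(substrate_conc_uM = 200, inhibitor_conc_uM = c(0, 1, 2, 4, 8),
                     preincubation_min = 0, replicate = 1:2, KEEP.OUT.ATTRS = FALSE)
  rec$response <- ifelse(rec$inhibitor_conc_uM == 0, 50, 25)
  ds <- assay_dataset(rec, "ic50")
  nd <- normalize_to_control(ds)
  expect_equal(mean(nd$response[nd$inhibitor_conc_uM == 0]), 1.0)
  expect_equal(nd$response[nd$inhibitor_conc_uM == 1][1], 0.5)
  expect_true(attr(nd, "normalized"))
  nd2 <- normalize_to_control(nd)
  expect_equal(nd2$response, nd$response, tolerance = 1e-12)
  # noiseless TDI generator: control activity at t = 0, I = 0 is exactly 1
  td <- generate_tdi_dataset(KI = 0.43, kinact = 0.044, cv = 0)
  ntd <- normalize_to_control(td)
  expect_identical(unique(ntd$response[ntd$inhibitor_conc_uM == 0 &
                                       ntd$preincubation_min == 0]), 1)
  # missing control errors
  rec3 <- rec[rec$inhibitor_conc_uM > 0, ]
  expect_error(normalize_to_control(assay_dataset(rec3, "ic50")), "control")
})
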