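# In vitro incubation datasets: construction, validation, CSV input/output,
# control normalization and the two-step dilution bookkeeping used by
# time-dependent inhibition (TDI) assays.

ASSAY_KINDS <- c("ic50", "dixon", "tdi")
ENZYME_SOURCES <- c("pooled_HLM", "CYP3A4_via_3A5_star3star3",
                    "CYP3A5_via_star1star3_plus_CYP3cide")
ASSAY_COLUMNS <- c("substrate_conc_uM", "inhibitor_conc_uM",
                   "preincubation_min", "replicate", "response")
TDI_PREINC_TIMES <- c(0, 5, 10, 20, 30)

#' Construct an in vitro incubation dataset
#'
#' Bundles velocity records from a microsomal incubation experiment with the
#' assay metadata (enzyme source, probe substrate, protein concentration and
#' assay kind) and validates the design invariants for that kind.
#'
#' @param records data.frame with columns `substrate_conc_uM`,
#'   `inhibitor_conc_uM`, `preincubation_min`, `replicate` (positive integer)
#'   and `response` (metabolite formation rate in pmol/min/mg protein, or
#'   normalized activity as a fraction of control).
#' @param assay_kind one of `"ic50"`, `"dixon"`, `"tdi"`.
#' @param enzyme_source microsomal system: `"pooled_HLM"`,
#'   `"CYP3A4_via_3A5_star3star3"` (CYP3A5 *3/*3 genotyped HLM, CYP3A4 activity)
#'   or `"CYP3A5_via_star1star3_plus_CYP3cide"` (*1/*3 HLM with the selective
#'   CYP3A4 inactivator CYP3cide, isolating CYP3A5).
#' @param probe probe reaction identifier, e.g.
#'   `"testosterone_6b_hydroxylation"` or `"tacrolimus"`.
#' @param protein_conc microsomal protein concentration, mg/mL.
#' @param normalized logical; `TRUE` when `response` is a fraction of control
#'   activity rather than a raw rate.
#' @param temperature_C incubation temperature, metadata only (never used in
#'   any computation).
#' @return an object of class `assay_dataset`: the records data.frame with the
#'   metadata stored as attributes.
#' @seealso [read_assay_csv()], [normalize_to_control()]
#' @export
assay_dataset <- function(records, assay_kind,
                          enzyme_source = "pooled_HLM",
                          probe = "testosterone_6b_hydroxylation",
                          protein_conc = 0.5,
                          normalized = FALSE,
                          temperature_C = 37) {
  assay_kind <- match.arg(assay_kind, ASSAY_KINDS)
  enzyme_source <- match.arg(enzyme_source, ENZYME_SOURCES)
  if (!is.data.frame(records))
    stop_cypddi("records must be a data.frame", class = "cypddi_validation_error")
  missing_cols <- setdiff(ASSAY_COLUMNS, names(records))
  if (length(missing_cols))
    stop_cypddi("records is missing column(s): ", paste(missing_cols, collapse = ", "),
                class = "cypddi_validation_error")
  records <- records[ASSAY_COLUMNS]
  if (is.numeric(records$replicate) &&
      all(records$replicate == round(records$replicate), na.rm = TRUE))
    records$replicate <- as.integer(records$replicate)
  ds <- structure(records,
                  class = c("assay_dataset", "data.frame"),
                  assay_kind = assay_kind,
                  enzyme_source = enzyme_source,
                  probe = probe,
                  protein_conc = protein_conc,
                  normalized = isTRUE(normalized),
                  temperature_C = temperature_C)
  validate_assay_dataset(ds)
}

#' Validate the invariants of an incubation dataset
#'
#' Checks per-record invariants (non-negative concentrations and responses,
#' positive integer replicates) and the per-kind design invariants: a Dixon
#' dataset needs at least 3 distinct substrate levels and at least 3 distinct
#' inhibitor levels including 0; a TDI dataset needs at least 4 preincubation
#' times including 0 and an inhibitor-free control series.
#'
#' @param ds an `assay_dataset`.
#' @return `ds`, invisibly unchanged, on success; otherwise a validation error
#'   naming the violated invariant.
#' @export
validate_assay_dataset <- function(ds) {
  kind <- attr(ds, "assay_kind")
  fail <- function(...) stop_cypddi(..., class = "cypddi_validation_error")
  if (nrow(ds) == 0L) fail("dataset is empty")
  num_cols <- c("substrate_conc_uM", "inhibitor_conc_uM", "preincubation_min", "response")
  for (col in num_cols) {
    if (!is.numeric(ds[[col]])) fail("column ", col, " is not numeric")
    if (anyNA(ds[[col]]))
      fail("missing value in column ", col, " at row(s) ",
           paste(which(is.na(ds[[col]])), collapse = ", "))
    if (any(ds[[col]] < 0))
      fail("negative value in column ", col, " at row(s) ",
           paste(which(ds[[col]] < 0), collapse = ", "))
  }
  rep_ok <- is.numeric(ds$replicate) && !anyNA(ds$replicate) &&
    all(ds$replicate >= 1 & ds$replicate == round(ds$replicate))
  if (!rep_ok) fail("replicate must be a positive integer")
  if (kind == "dixon") {
    if (length(unique(ds$substrate_conc_uM)) < 3L)
      fail("dixon dataset needs >= 3 distinct substrate levels")
    ilev <- unique(ds$inhibitor_conc_uM)
    if (length(ilev) < 3L || !any(ilev == 0))
      fail("dixon dataset needs >= 3 distinct inhibitor levels including 0")
  }
  if (kind == "tdi") {
    tlev <- unique(ds$preincubation_min)
    if (!all(tlev %in% TDI_PREINC_TIMES))
      fail("tdi preincubation times must lie in {",
           paste(TDI_PREINC_TIMES, collapse = ","), "} min")
    if (length(tlev) < 4L || !any(tlev == 0))
      fail("tdi dataset needs >= 4 preincubation times including 0")
    if (!any(ds$inhibitor_conc_uM == 0))
      fail("tdi dataset needs an inhibitor_conc = 0 control series")
  }
  invisible(ds)
}

#' Read an incubation dataset from CSV
#'
#' CSV dialect: comma-separated, period decimal, UTF-8, one header line with
#' the exact column names `substrate_conc_uM, inhibitor_conc_uM,
#' preincubation_min, replicate, response`. A sidecar JSON file
#' `<path>.meta.json`, if present, supplies the dataset metadata (fields of
#' [assay_dataset()]); otherwise metadata defaults apply.
#'
#' @param path path to the CSV file.
#' @param assay_kind one of `"ic50"`, `"dixon"`, `"tdi"`.
#' @param ... metadata overrides passed to [assay_dataset()].
#' @return a validated `assay_dataset`.
#' @export
read_assay_csv <- function(path, assay_kind, ...) {
  if (!file.exists(path)) stop_cypddi("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(ASSAY_COLUMNS, names(raw))
  if (length(missing_cols))
    stop_cypddi("CSV header is missing column(s): ",
                paste(missing_cols, collapse = ", "),
                class = "cypddi_parse_error")
  parse_col <- function(col) {
    x <- raw[[col]]
    blank <- is.na(x) | !nzchar(trimws(x))
    if (any(blank))
      stop_cypddi("missing value in column ", col, " at row(s) ",
                  paste(which(blank), collapse = ", "),
                  class = "cypddi_parse_error")
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out))
      stop_cypddi("malformed numeric cell in column ", col, " at row(s) ",
                  paste(which(is.na(out)), collapse = ", "),
                  class = "cypddi_parse_error")
    out
  }
  records <- data.frame(lapply(setNames(ASSAY_COLUMNS, ASSAY_COLUMNS), parse_col))
  meta <- list(...)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar) && !length(meta)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- meta[intersect(names(meta),
                           c("enzyme_source", "probe", "protein_conc",
                             "normalized", "temperature_C"))]
  }
  do.call(assay_dataset, c(list(records = records, assay_kind = assay_kind), meta))
}

#' Write an incubation dataset to CSV
#'
#' Inverse of [read_assay_csv()]: numbers are written with 17 significant
#' digits so that a read/write/read round trip reproduces every field
#' bit-exactly. Metadata goes to a `<path>.meta.json` sidecar.
#'
#' @param ds an `assay_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(ds, path) {
  validate_assay_dataset(ds)
  fmt <- vapply(as.data.frame(ds), function(col) sprintf("%.17g", col),
                character(nrow(ds)))
  fmt <- matrix(fmt, nrow = nrow(ds),
                dimnames = list(NULL, ASSAY_COLUMNS))
  utils::write.csv(as.data.frame(fmt), path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(assay_kind = attr(ds, "assay_kind"),
               enzyme_source = attr(ds, "enzyme_source"),
               probe = attr(ds, "probe"),
               protein_conc = attr(ds, "protein_conc"),
               normalized = attr(ds, "normalized"),
               temperature_C = attr(ds, "temperature_C"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Two-step dilution specification
#'
#' In the two-step TDI protocol an aliquot of the preincubation mixture is
#' transferred into a larger activity-assay volume (e.g. 20 uL into a final
#' 200 uL, a 10-fold dilution), so the inhibitor concentration during the
#' activity read is the nominal preincubation concentration divided by the
#' dilution factor.
#'
#' @param aliquot_volume_uL aliquot volume transferred, uL.
#' @param final_volume_uL final activity-incubation volume, uL.
#' @return object of class `dilution_spec`.
#' @export
dilution_spec <- function(aliquot_volume_uL = 20, final_volume_uL = 200) {
  if (!(aliquot_volume_uL > 0 && final_volume_uL > aliquot_volume_uL))
    stop_cypddi("need 0 < aliquot_volume_uL < final_volume_uL",
                class = "cypddi_validation_error")
  structure(list(aliquot_volume_uL = aliquot_volume_uL,
                 final_volume_uL = final_volume_uL,
                 factor = final_volume_uL / aliquot_volume_uL),
            class = "dilution_spec")
}

#' Inhibitor concentration applied at an assay stage
#'
#' @param nominal nominal (preincubation-stage) inhibitor concentration, uM.
#' @param dilution a [dilution_spec()].
#' @param stage `"preincubation"` (returns the nominal concentration) or
#'   `"activity"` (returns the carried-over concentration,
#'   nominal x aliquot/final).
#' @return concentration in uM. Linear in `nominal`.
#' @export
applied_inhibitor_conc <- function(nominal, dilution = dilution_spec(),
                                   stage = c("preincubation", "activity")) {
  stage <- match.arg(stage)
  if (any(nominal < 0)) stop_cypddi("nominal concentration must be >= 0")
  if (stage == "preincubation") nominal
  else nominal * dilution$aliquot_volume_uL / dilution$final_volume_uL
}

#' Normalize responses to the control group
#'
#' Rescales responses so that the mean response of the control group equals 1
#' (fraction of control activity). The control group is the zero-inhibitor
#' records, additionally restricted to zero preincubation time for TDI
#' datasets. Idempotent: applying it twice is the identity.
#'
#' @param ds an `assay_dataset`.
#' @return the dataset with rescaled responses, `normalized` metadata set to
#'   `TRUE` and the original units recorded in the `original_units` attribute.
#' @export
normalize_to_control <- function(ds) {
  validate_assay_dataset(ds)
  kind <- attr(ds, "assay_kind")
  ctrl <- ds$inhibitor_conc_uM == 0
  if (kind == "tdi") ctrl <- ctrl & ds$preincubation_min == 0
  if (!any(ctrl))
    stop_cypddi("no control records (inhibitor 0",
                if (kind == "tdi") ", preincubation 0", ")")
  ctrl_mean <- mean(ds$response[ctrl])
  if (!(ctrl_mean > 0)) stop_cypddi("control mean response is not positive")
  out <- ds
  out$response <- ds$response / ctrl_mean
  attr(out, "normalized") <- TRUE
  if (is.null(attr(ds, "original_units")))
    attr(out, "original_units") <- if (isTRUE(attr(ds, "normalized")))
      "fraction_of_control" else "pmol/min/mg"
  out
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf("<assay_dataset: %s> %d records | source %s | probe %s | %s\n",
              attr(x, "assay_kind"), nrow(x), attr(x, "enzyme_source"),
              attr(x, "probe"),
              if (isTRUE(attr(x, "normalized"))) "normalized" else "raw rates"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
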