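# Report builders mirroring the shape of the validation tables: a
# predicted-vs-observed PK parameter table with fold errors, and the DDI
# scenario grid with control/inhibited AUC pairs and AUC ratios.

#' Predicted-versus-observed PK parameter table
#'
#' One row per parameter (Cmax, Tmax, AUC) and compound, with predicted and
#' observed values and the fold error max(pre, obs)/min(pre, obs). Display
#' values are rounded half-up to 2 decimals; the returned data.frame keeps
#' full precision in the `fold_error` column.
#'
#' @param predicted,observed named lists (one element per compound) of
#'   `pk_metrics` objects or named vectors with elements `cmax`, `tmax`,
#'   `auc`. Compound names must match; when both sides are `pk_metrics`,
#'   their AUC windows must agree.
#' @return data.frame with columns `compound`, `parameter`, `predicted`,
#'   `observed`, `fold_error`, `fold_error_display`.
#' @export
build_table1 <- function(predicted, observed) {
  if (!setequal(names(predicted), names(observed)))
    stop_cypddi("predicted and observed must cover the same compounds")
  as_vec <- function(x) {
    if (inherits(x, "pk_metrics")) c(cmax = x$cmax, tmax = x$tmax, auc = x$auc)
    else x[c("cmax", "tmax", "auc")]
  }
  rows <- lapply(names(predicted), function(nm) {
    p <- predicted[[nm]]; o <- observed[[nm]]
    if (inherits(p, "pk_metrics") && inherits(o, "pk_metrics") &&
        !isTRUE(all.equal(p$auc_window, o$auc_window)))
      stop_cypddi("AUC windows disagree for ", nm, ": predicted ",
                  paste(p$auc_window, collapse = "-"), " h vs observed ",
                  paste(o$auc_window, collapse = "-"), " h")
    pv <- as_vec(p); ov <- as_vec(o)
    fe <- fold_error(pv, ov)
    data.frame(compound = nm,
               parameter = c("Cmax (ng/mL)", "Tmax (h)", "AUC (ng/mL.h)"),
               predicted = unname(pv), observed = unname(ov),
               fold_error = unname(fe),
               fold_error_display = round_half_up(unname(fe), 2))
  })
  do.call(rbind, rows)
}

#' DDI scenario grid in validation-table layout
#'
#' Reshapes a [scenario_table()] data.frame into one row per genotype x
#' inhibitor x regimen with one column per inhibition case, each cell the
#' string `"control/inhibited AUCR"` (AUCs and AUCR rounded half-up to 2
#' decimals). Undefined cells (NA AUCs) are rendered as an em-dash, or as an
#' empty string with `dash = ""` for CSV output.
#'
#' @param tab data.frame from [scenario_table()] or [run_scenario_grid()].
#' @param dash string used for undefined cells (default em-dash).
#' @return data.frame with columns `genotype`, `inhibitor`, `regimen` and one
#'   column per inhibition mode present.
#' @export
build_table2 <- function(tab, dash = "—") {
  if (nrow(tab) == 0L)
    return(data.frame(genotype = character(), inhibitor = character(),
                      regimen = character()))
  cell <- function(r) {
    if (is.na(r$auc_control) || is.na(r$auc_inhibited)) return(dash)
    sprintf("%.2f/%.2f %.2f", round_half_up(r$auc_control, 2),
            round_half_up(r$auc_inhibited, 2), round_half_up(r$aucr, 2))
  }
  keys <- unique(tab[c("genotype", "inhibitor", "regimen")])
  modes <- intersect(DDI_MODES, unique(tab$mode))
  out <- keys
  for (m in modes) out[[m]] <- vapply(seq_len(nrow(keys)), function(i) {
    r <- tab[tab$genotype == keys$genotype[i] & tab$inhibitor == keys$inhibitor[i] &
             tab$regimen == keys$regimen[i] & tab$mode == m, , drop = FALSE]
    if (nrow(r) == 0L) dash else cell(r[1L, ])
  }, character(1L))
  rownames(out) <- NULL
  out
}
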