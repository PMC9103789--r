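# Shared fixtures built in code.

# Published control/inhibited whole-blood AUC pairs (ng/mL.h) of the victim
# across genotype x inhibitor x regimen x inhibition-case scenarios, used as
# worked-example inputs for the tabulation arithmetic.
reported_ddi_aucs <- function() {
  rbind(
    data.frame(genotype = "non_expresser", inhibitor = "SZA",
               regimen = c("single", "multiple"), mode = "TDI_only",
               auc_control = 118.07, auc_inhibited = c(118.17, 136.76)),
    data.frame(genotype = "non_expresser", inhibitor = "SZB",
               regimen = rep(c("single", "multiple"), each = 3),
               mode = rep(c("RI_only", "TDI_only", "RI_and_TDI"), 2),
               auc_control = 118.07,
               auc_inhibited = c(128.33, 124.60, 135.01,
                                 148.65, 173.14, 185.61)),
    data.frame(genotype = "expresser", inhibitor = "SZA",
               regimen = c("single", "multiple"), mode = "TDI_only",
               auc_control = 62.50, auc_inhibited = c(62.54, 62.66)),
    data.frame(genotype = "expresser", inhibitor = "SZB",
               regimen = rep(c("single", "multiple"), each = 3),
               mode = rep(c("RI_only", "TDI_only", "RI_and_TDI"), 2),
               auc_control = 62.50,
               auc_inhibited = c(69.83, 64.72, 72.12, 70.68, 70.60, 76.68)))
}

reported_ddi_results <- function() {
  tab <- reported_ddi_aucs()
  lapply(seq_len(nrow(tab)), function(i)
    ddi_result(tab$auc_control[i], tab$auc_inhibited[i],
               inhibitor = tab$inhibitor[i], regimen = tab$regimen[i],
               genotype = tab$genotype[i], mode = tab$mode[i]))
}

# A flat (inhibition-free) Dixon dataset: velocities follow plain
# Michaelis-Menten, independent of inhibitor concentration.
flat_dixon_dataset <- function(vmax = 100, km = 1.2) {
  design <- expand.grid(substrate_conc_uM = c(0.25, 0.5, 1, 2),
                        inhibitor_conc_uM = c(0, 1, 2, 4),
                        replicate = 1:3, KEEP.OUT.ATTRS = FALSE)
  design$response <- vmax * design$substrate_conc_uM /
    (km + design$substrate_conc_uM)
  design$preincubation_min <- 0
  assay_dataset(design, "dixon", probe = "tacrolimus", protein_conc = 0.2)
}

# Minimal stand-in for a pbpk_sim carrying a hand-built profile, for testing
# grid-based PK metric extraction against closed forms.
mock_sim <- function(time_h, conc, name = "x", bp = 2) {
  mat <- matrix(conc, ncol = 1, dimnames = list(NULL, name))
  structure(list(time_h = time_h, conc = mat, conc_blood = mat * bp),
            class = "pbpk_sim")
}

default_scenarios <- function() {
  list(genotype_scenario("non_expresser"), genotype_scenario("expresser"))
}
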