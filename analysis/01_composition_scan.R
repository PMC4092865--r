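#!/usr/bin/env Rscript

# Composition scans: percent inhibition of pAKT and pERK as a function of
# the HER3/HER2 co-expression ratio, for trastuzumab, pertuzumab and their
# combination at 100 nM each with 1 nM HRG (HER2 total 50 nM, HER3 floored
# at 5 nM, readout 60 min post-stimulation).

suppressPackageStartupMessages(library(erbbcombo))

dir.create("results", showWarnings = FALSE)
params <- kinetic_parameters()
base <- model_config(her2_total = 50, ratio = 0.5)
grid <- default_ratio_grid()

scans <- list()
for (lab in c("trastuzumab", "pertuzumab", "combination")) {
  sc <- composition_scan(treatment_scenario(lab), grid, base, params)
  write_scan_csv(sc, file.path("results", paste0("scan_", lab, ".csv")))
  scans[[lab]] <- sc
}

at <- function(sc, r, col) sc[[col]][which.min(abs(sc$ratio - r))]

cat("Composition dependence of drug inhibition (readout 60 min):\n")
cat(sprintf(
  " - trastuzumab pERK inhibition falls from %.0f%% at r = 0.01 to %.0f%%\n",
  scans$trastuzumab$perk_inhibition[1],
  scans$trastuzumab$perk_inhibition[nrow(scans$trastuzumab)]))
cat(sprintf(
  "   at r = 2: it blocks HER2 homodimerisation, which dominates only at\n"))
cat(sprintf(
  "   HER2 overexpression; its pAKT inhibition stays near zero (%.1f%% at r = 0.5).\n",
  at(scans$trastuzumab, 0.5, "pakt_inhibition")))
cat(sprintf(
  " - pertuzumab pERK inhibition rises from %.0f%% to %.0f%% over r in [0.1, 1]\n",
  at(scans$pertuzumab, 0.1, "perk_inhibition"),
  at(scans$pertuzumab, 1, "perk_inhibition")))
cat(sprintf(
  "   and its pAKT inhibition exceeds %.0f%% throughout: it blocks the\n",
  min(scans$pertuzumab$pakt_inhibition)))
cat("   ligand-driven heterodimer that feeds both branches.\n")
cat(sprintf(
  " - the combination inhibits pERK at every composition (%.0f%% at r = 0.1,\n",
  at(scans$combination, 0.1, "perk_inhibition")))
cat(sprintf(
  "   %.0f%% at r = 0.5, %.0f%% at r = 1) - composition-independent, unlike\n",
  at(scans$combination, 0.5, "perk_inhibition"),
  at(scans$combination, 1, "perk_inhibition")))
cat("   either monotherapy.\n")
cat("Tables written to results/scan_<scenario>.csv\n")
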