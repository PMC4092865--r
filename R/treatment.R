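#' Antibody dimerisation-blocking rules
#'
#' The rule set describing which homo-/heterodimerisation events
#' trastuzumab and pertuzumab block, depending on ligand presence.
#' Trastuzumab (domain IV binder) blocks ligand-independent HER2
#' homodimerisation but not ligand-driven HER3/HER2 heterodimerisation;
#' pertuzumab (domain II binder) blocks ligand-driven heterodimerisation
#' but not homodimerisation. The p95HER2 row is returned for completeness
#' but marked out of model (ectodomain shedding is not simulated).
#'
#' @return data.frame with columns drug, receptor1, receptor2, ligand,
#'   blocked ("yes", "no" or "no/minor") and in_model.
#' @export
dimerisation_rules <- function() {
  data.frame(
    drug = c("Trastuzumab", "Trastuzumab", "Trastuzumab", "Trastuzumab",
             "Pertuzumab", "Pertuzumab", "Pertuzumab"),
    receptor1 = c("HER2", "HER2", "p95HER2", "HER2",
                  "HER2", "HER2", "HER2"),
    receptor2 = c("HER3", "HER3", "", "HER2", "HER3", "HER3", "HER2"),
    ligand = c("yes", "no", "no", "no", "yes", "no", "no"),
    blocked = c("no/minor", "yes", "yes", "yes", "yes", "no/minor", "no"),
    in_model = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Treatment scenarios
#'
#' Standard scenarios at the reference doses: 100 nM of each antibody
#' and 1 nM HRG.
#'
#' @param label one of "control", "trastuzumab", "pertuzumab",
#'   "combination".
#' @param tr_dose,pr_dose,hrg_dose dose overrides (nM).
#' @export
treatment_scenario <- function(label = c("control", "trastuzumab",
                                         "pertuzumab", "combination"),
                               tr_dose = NULL, pr_dose = NULL,
                               hrg_dose = 1) {
  label <- match.arg(label)
  tr <- switch(label, control = 0, trastuzumab = 100, pertuzumab = 0,
               combination = 100)
  pr <- switch(label, control = 0, trastuzumab = 0, pertuzumab = 100,
               combination = 100)
  if (!is.null(tr_dose)) tr <- tr_dose
  if (!is.null(pr_dose)) pr <- pr_dose
  if (tr < 0 || pr < 0 || hrg_dose < 0) stop("doses must be non-negative")
  if (label == "control" && (tr > 0 || pr > 0)) {
    stop("control scenario must have zero drug doses")
  }
  structure(list(label = label, tr_dose = tr, pr_dose = pr,
                 hrg_dose = hrg_dose), class = "treatment_scenario")
}

#' Apply a treatment scenario to a drug-free network
#'
#' Rebuilds the network with the scenario's antibody doses, adding the
#' drug-binding reactions, the cooperative ternary complex and the
#' rule-conformant dimerisation reactions of drug-bound HER2.
#'
#' @param network a network built by [build_network()] without drugs (or
#'   with zero doses).
#' @param scenario a [treatment_scenario()].
#' @param params kinetic parameter set used for the rebuild.
#' @export
apply_treatment <- function(network, scenario,
                            params = kinetic_parameters()) {
  config <- attr(network, "config")
  if (is.null(config)) stop("network carries no model config")
  if (config$tr_dose > 0 || config$pr_dose > 0) {
    stop("apply_treatment expects a drug-free network")
  }
  if (scenario$tr_dose < 0 || scenario$pr_dose < 0) {
    stop("doses must be non-negative")
  }
  cfg <- model_config(her2_total = config$her2_total,
                      her3_total = config$her3_total,
                      hrg_dose = scenario$hrg_dose,
                      tr_dose = scenario$tr_dose,
                      pr_dose = scenario$pr_dose,
                      readout = config$readout)
  build_network(cfg, params)
}

#' Percent inhibition of pAKT and pERK
#'
#' inhibition = 100 * (1 - treated / control) per signal; negative values
#' indicate signal enhancement by the treatment.
#'
#' @param treated,control `signal_readout` objects.
#' @return an `inhibition_result` with fields pAKT and pERK (percent) and
#'   the underlying readouts.
#' @export
percent_inhibition <- function(treated, control) {
  if (!is.finite(control$pAKT) || !is.finite(control$pERK) ||
      control$pAKT <= 0 || control$pERK <= 0) {
    stop("control signal must be positive for both pAKT and pERK")
  }
  structure(list(
    pAKT = 100 * (1 - treated$pAKT / control$pAKT),
    pERK = 100 * (1 - treated$pERK / control$pERK),
    treated = treated, control = control),
    class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("inhibition: pAKT %.1f%%, pERK %.1f%%\n", x$pAKT, x$pERK))
  invisible(x)
}

#' Inhibition of a scenario relative to its drug-free control
#'
#' Runs the control and the treated condition under identical protocol and
#' returns the percent inhibition.
#'
#' @param scenario a [treatment_scenario()].
#' @param base a [model_config()] giving receptor totals and readout
#'   policy (its doses are overridden).
#' @param params kinetic parameter set.
#' @param ... passed to [simulate_scenario()].
#' @export
scenario_inhibition <- function(scenario, base,
                                params = kinetic_parameters(), ...) {
  ctrl_cfg <- model_config(her2_total = base$her2_total,
                           her3_total = base$her3_total,
                           hrg_dose = scenario$hrg_dose,
                           readout = base$readout)
  trt_cfg <- model_config(her2_total = base$her2_total,
                          her3_total = base$her3_total,
                          hrg_dose = scenario$hrg_dose,
                          tr_dose = scenario$tr_dose,
                          pr_dose = scenario$pr_dose,
                          readout = base$readout)
  ctrl <- simulate_scenario(ctrl_cfg, params, ...)$readout
  trt <- simulate_scenario(trt_cfg, params, ...)$readout
  percent_inhibition(trt, ctrl)
}

#' Default log-spaced HER3/HER2 ratio grid
#'
#' @param n number of points.
#' @param lo,hi grid range.
#' @export
default_ratio_grid <- function(n = 30, lo = 0.01, hi = 2) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Composition scan: inhibition versus HER3/HER2 ratio
#'
#' For every ratio r on the grid, HER3 total is r times the HER2 total of
#' the base config, floored at 5 nM (the minimum HER3 concentration of the
#' scan design), and one drug-free control plus one treated simulation are
#' run.
#'
#' @param scenario a [treatment_scenario()].
#' @param ratio_grid strictly increasing ratios within [0.01, 2].
#' @param base a [model_config()] supplying HER2 total and readout policy.
#' @param params kinetic parameter set.
#' @param her3_floor minimum HER3 total (nM).
#' @param ... passed to [simulate_scenario()].
#' @return a `composition_scan` data.frame with columns ratio,
#'   pakt_inhibition, perk_inhibition (percent).
#' @export
composition_scan <- function(scenario, ratio_grid = default_ratio_grid(),
                             base = model_config(her2_total = 50,
                                                 ratio = 0.5),
                             params = kinetic_parameters(),
                             her3_floor = 5, ...) {
  if (any(diff(ratio_grid) <= 0)) {
    stop("ratio grid must be strictly increasing")
  }
  if (min(ratio_grid) < 0.01 || max(ratio_grid) > 2) {
    stop("ratio grid must lie within [0.01, 2]")
  }
  rows <- lapply(ratio_grid, function(r) {
    cfg <- model_config(her2_total = base$her2_total,
                        her3_total = max(r * base$her2_total, her3_floor),
                        hrg_dose = scenario$hrg_dose,
                        readout = base$readout)
    inh <- tryCatch(
      scenario_inhibition(scenario, cfg, params, ...),
      error = function(e) {
        stop("composition scan failed at ratio ", signif(r, 4), ": ",
             conditionMessage(e))
      })
    data.frame(ratio = r, pakt_inhibition = inh$pAKT,
               perk_inhibition = inh$pERK)
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario$label
  class(out) <- c("composition_scan", "data.frame")
  out
}

#' Cell-line presets for receptor composition
#'
#' HER3/HER2 co-expression presets: SKOV3 xenograft under treatment
#' (HER3 up-regulated, r = 0.5), untreated SKOV3 (HER2 overexpression,
#' r < 0.1), MCF7 (equimolar, lower HER2 total) and the HER2-transfected
#' MCF7-HER2-18 line (r = 0.1). HER3 totals are floored at 5 nM.
#'
#' @param name preset name.
#' @return a [model_config()].
#' @export
cell_line_preset <- function(name) {
  presets <- list(
    SKOV3_treated = list(ratio = 0.5, her2 = 50),
    SKOV3_untreated = list(ratio = 0.05, her2 = 50),
    MCF7 = list(ratio = 1.0, her2 = 30),
    MCF7_HER2_18 = list(ratio = 0.1, her2 = 50))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  model_config(her2_total = p$her2,
               her3_total = max(p$ratio * p$her2, 5))
}

#' Compare simulated with reference inhibition
#'
#' Side-by-side table of simulated and reference percent inhibition, per
#' scenario and signal, with absolute differences and a within-error flag
#' (difference not exceeding the reference SD). No fitting is performed.
#'
#' @param sim named list: scenario -> `inhibition_result`.
#' @param ref a `reference_inhibition` object (see
#'   [generate_reference_inhibition()]).
#' @export
compare_to_reference <- function(sim, ref) {
  if (!length(ref$scenarios)) stop("reference inhibition set is empty")
  if (!setequal(names(sim), names(ref$scenarios))) {
    stop("scenario mismatch between simulation (",
         paste(names(sim), collapse = ", "), ") and reference (",
         paste(names(ref$scenarios), collapse = ", "), ")")
  }
  rows <- list()
  for (sc in names(ref$scenarios)) {
    for (sig in c("pAKT", "pERK")) {
      s <- sim[[sc]][[sig]]
      r <- ref$scenarios[[sc]][[sig]]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, signal = sig,
        simulated = s, reference = r$mean, reference_sd = r$sd,
        abs_difference = abs(s - r$mean),
        within_error = abs(s - r$mean) <= r$sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.composition_scan <- function(x, ...) {
  cat("composition scan (", attr(x, "scenario"), "): ",
      nrow(x), " ratios in [", signif(min(x$ratio), 3), ", ",
      signif(max(x$ratio), 3), "]\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
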