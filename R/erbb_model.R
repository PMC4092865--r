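#' Model configuration for the HER2/HER3 signalling system
#'
#' Totals are in nM. Either `her3_total` or `ratio` (HER3/HER2) must be
#' given; if `ratio` is given, HER3 total is `ratio * her2_total`.
#'
#' @param her2_total total HER2 receptor (nM).
#' @param her3_total total HER3 receptor (nM).
#' @param ratio HER3/HER2 abundance ratio (dimensionless).
#' @param hrg_dose heregulin dose (nM); clamped boundary concentration.
#' @param tr_dose trastuzumab dose (nM).
#' @param pr_dose pertuzumab dose (nM).
#' @param readout readout policy: time in minutes (default 60, a
#'   quasi-steady-state point for the default parameter set) or
#'   `list(type = "steady_state")`.
#' @return a `model_config` list.
#' @export
model_config <- function(her2_total, her3_total = NULL, ratio = NULL,
                         hrg_dose = 1, tr_dose = 0, pr_dose = 0,
                         readout = 60) {
  if (is.null(her3_total)) {
    if (is.null(ratio)) stop("give her3_total or ratio")
    her3_total <- ratio * her2_total
  } else if (is.null(ratio)) {
    ratio <- if (her2_total > 0) her3_total / her2_total else NA_real_
  }
  vals <- c(her2_total = her2_total, her3_total = her3_total,
            hrg_dose = hrg_dose, tr_dose = tr_dose, pr_dose = pr_dose)
  if (any(vals < 0)) {
    stop("negative value in model config: ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  structure(list(her2_total = her2_total, her3_total = her3_total,
                 ratio = ratio, hrg_dose = hrg_dose, tr_dose = tr_dose,
                 pr_dose = pr_dose, readout = readout),
            class = "model_config")
}

#' Kinetic parameter set
#'
#' Loads the rate-constant and protein-total set from a structured JSON
#' file, so the parameterisation can be swapped without code change.
#' Association constants are in 1/(nM min), first-order constants in
#' 1/min, totals in nM; `coop_ternary` is the dimensionless cooperativity
#' factor scaling the association rate of the second antibody onto a
#' HER2 molecule that already carries the other one.
#'
#' @param path JSON file; default is the parameter set shipped with the
#'   package.
#' @return named numeric vector of parameters.
#' @export
kinetic_parameters <- function(path = system.file("extdata",
                                                  "kinetic_params.json",
                                                  package = "erbbcombo")) {
  raw <- jsonlite::fromJSON(path)
  p <- unlist(raw)
  if (any(p < 0)) {
    stop("negative parameter in ", path, ": ",
         paste(names(p)[p < 0], collapse = ", "))
  }
  if (p[["coop_ternary"]] <= 0) stop("coop_ternary must be > 0")
  p
}

# species name constants for the receptor layer
.SP <- list(
  HRG = "HRG", HER3 = "HER3", HER2 = "HER2",
  HER3HRG = "HER3:HRG",
  HD = "HER3:HRG:HER2", pHD = "pHER3:HRG:HER2",
  HDT = "HER3:HRG:HER2:Tr", pHDT = "pHER3:HRG:HER2:Tr",
  HH = "(HER2)2", pHH = "p(HER2)2",
  HHP = "(HER2)2:Pr", pHHP = "p(HER2)2:Pr",
  HHPP = "(HER2:Pr)2", pHHPP = "p(HER2:Pr)2",
  TR = "Tr", PR = "Pr",
  H2T = "HER2:Tr", H2P = "HER2:Pr", H2TP = "HER2:Tr:Pr")

# downstream cascade species
.DOWNSTREAM <- c("SOS", "RAS", "aRAS", "RAF", "aRAF", "MEK", "MEKp", "pMEK",
                 "ERK", "ERKp", "pERK", "PI3K", "aPI3K", "PTEN",
                 "AKT", "pAKT")

required_params <- function(with_tr, with_pr) {
  base <- c("kon_hrg", "koff_hrg", "kon_het", "koff_het", "kon_hom",
            "koff_hom", "k_phos", "k_dephos",
            "kon_sos", "koff_sos", "k_sos_ras",
            "k_ras_het", "k_ras_deact",
            "k_raf_act", "k_raf_deact", "k_mek_act", "k_mek_deact",
            "k_erk_act", "k_erk_deact", "k_pi3k_act", "k_pten",
            "k_akt_act", "k_akt_deact",
            "ras_total", "raf_total", "mek_total", "erk_total",
            "pi3k_total", "akt_total", "pten_total", "sos_total")
  if (with_tr) base <- c(base, "kon_tr", "koff_tr")
  if (with_pr) base <- c(base, "kon_pr", "koff_pr")
  if (with_tr && with_pr) base <- c(base, "coop_ternary")
  base
}

#' Build the HER2/HER3 reaction network
#'
#' Constructs the full mass-action network: HRG binding to HER3,
#' ligand-dependent HER3:HRG + HER2 heterodimerisation, ligand-independent
#' HER2 homodimerisation, dimer (de)phosphorylation, antibody binding
#' (only for drugs with positive dose), and the downstream cascade in
#' which phospho-heterodimers activate both the PI3K/AKT and the
#' Ras/RAF/MEK/ERK branch while phospho-homodimers activate only the ERK
#' branch. Dimerisation-blocking follows the antibody rule set (see
#' [dimerisation_rules()]): Tr-bound HER2 is excluded from
#' homodimerisation but still heterodimerises with HER3:HRG; Pr-bound
#' HER2 is excluded from ligand-dependent heterodimerisation but still
#' homodimerises; doubly-bound HER2 takes part in no dimerisation.
#' Ligand-independent HER3/HER2 heterodimers are not modelled.
#'
#' HRG is a clamped boundary species (an extracellular bath at the dosed
#' concentration), so it belongs to no conservation group; HER2, HER3, Tr,
#' Pr and every downstream protein are conserved moieties.
#'
#' @param config a [model_config()].
#' @param params a [kinetic_parameters()] vector.
#' @return a [reaction_network()].
#' @export
build_network <- function(config, params) {
  with_tr <- config$tr_dose > 0
  with_pr <- config$pr_dose > 0
  need <- required_params(with_tr, with_pr)
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("kinetic parameter set is missing: ", paste(miss, collapse = ", "))
  }
  s <- .SP
  species <- c(s$HRG, s$HER3, s$HER2, s$HER3HRG, s$HD, s$pHD, s$HH, s$pHH)
  if (with_tr) species <- c(species, s$TR, s$H2T, s$HDT, s$pHDT)
  if (with_pr) species <- c(species, s$PR, s$H2P, s$HHP, s$pHHP,
                            s$HHPP, s$pHHPP)
  if (with_tr && with_pr) species <- c(species, s$H2TP)
  species <- c(species, .DOWNSTREAM)

  rx <- list()
  add <- function(name, reactants, products, rate) {
    rx[[length(rx) + 1L]] <<- reaction(name, reactants, products, rate)
  }
  rev2 <- function(name, reactants, products, kon, koff) {
    add(name, reactants, products, kon)
    add(paste0(name, "_rev"), products, reactants, koff)
  }

  # receptor layer
  rev2("hrg_binding", c(HRG = 1, HER3 = 1), c("HER3:HRG" = 1),
       "kon_hrg", "koff_hrg")
  rev2("heterodimerisation", c("HER3:HRG" = 1, HER2 = 1),
       c("HER3:HRG:HER2" = 1), "kon_het", "koff_het")
  rev2("homodimerisation", c(HER2 = 2), c("(HER2)2" = 1),
       "kon_hom", "koff_hom")
  rev2("het_phosphorylation", c("HER3:HRG:HER2" = 1),
       c("pHER3:HRG:HER2" = 1), "k_phos", "k_dephos")
  rev2("hom_phosphorylation", c("(HER2)2" = 1), c("p(HER2)2" = 1),
       "k_phos", "k_dephos")

  if (with_tr) {
    rev2("tr_binding", c(Tr = 1, HER2 = 1), c("HER2:Tr" = 1),
         "kon_tr", "koff_tr")
    # trastuzumab does not block ligand-dependent heterodimerisation
    rev2("heterodimerisation_tr", c("HER3:HRG" = 1, "HER2:Tr" = 1),
         c("HER3:HRG:HER2:Tr" = 1), "kon_het", "koff_het")
    rev2("het_tr_phosphorylation", c("HER3:HRG:HER2:Tr" = 1),
         c("pHER3:HRG:HER2:Tr" = 1), "k_phos", "k_dephos")
  }
  if (with_pr) {
    rev2("pr_binding", c(Pr = 1, HER2 = 1), c("HER2:Pr" = 1),
         "kon_pr", "koff_pr")
    # pertuzumab does not block HER2 homodimerisation
    rev2("homodimerisation_pr", c(HER2 = 1, "HER2:Pr" = 1),
         c("(HER2)2:Pr" = 1), "kon_hom", "koff_hom")
    rev2("homodimerisation_prpr", c("HER2:Pr" = 2), c("(HER2:Pr)2" = 1),
         "kon_hom", "koff_hom")
    rev2("hom_pr_phosphorylation", c("(HER2)2:Pr" = 1),
         c("p(HER2)2:Pr" = 1), "k_phos", "k_dephos")
    rev2("hom_prpr_phosphorylation", c("(HER2:Pr)2" = 1),
         c("p(HER2:Pr)2" = 1), "k_phos", "k_dephos")
  }
  if (with_tr && with_pr) {
    # cooperative ternary complex; blocked for all dimerisation
    rev2("ternary_pr_join", c(Pr = 1, "HER2:Tr" = 1), c("HER2:Tr:Pr" = 1),
         "kon_pr_coop", "koff_pr")
    rev2("ternary_tr_join", c(Tr = 1, "HER2:Pr" = 1), c("HER2:Tr:Pr" = 1),
         "kon_tr_coop", "koff_tr")
  }

  # downstream: phospho-heterodimers feed both branches directly (HER3
  # carries multiple adapter/p85 docking sites); phospho-homodimers feed
  # only the ERK branch, and only through HER2's single Grb2 docking site,
  # modelled as recruitment of a limited SOS adapter pool
  het_p <- intersect(c(s$pHD, s$pHDT), species)
  hom_p <- intersect(c(s$pHH, s$pHHP, s$pHHPP), species)
  sos_cplx <- character()
  for (d in het_p) {
    add(paste0("ras_act_", d), stats::setNames(c(1, 1), c(d, "RAS")),
        stats::setNames(c(1, 1), c(d, "aRAS")), "k_ras_het")
    add(paste0("pi3k_act_", d), stats::setNames(c(1, 1), c(d, "PI3K")),
        stats::setNames(c(1, 1), c(d, "aPI3K")), "k_pi3k_act")
  }
  for (d in hom_p) {
    cx <- paste0(d, ":SOS")
    sos_cplx <- c(sos_cplx, cx)
    rev2(paste0("sos_recruit_", d),
         stats::setNames(c(1, 1), c(d, "SOS")),
         stats::setNames(1, cx), "kon_sos", "koff_sos")
    add(paste0("ras_act_", d), stats::setNames(c(1, 1), c(cx, "RAS")),
        stats::setNames(c(1, 1), c(cx, "aRAS")), "k_sos_ras")
  }
  species <- append(species, sos_cplx, after = match("SOS", species))
  add("ras_deact", c(aRAS = 1), c(RAS = 1), "k_ras_deact")
  add("raf_act", c(aRAS = 1, RAF = 1), c(aRAS = 1, aRAF = 1), "k_raf_act")
  add("raf_deact", c(aRAF = 1), c(RAF = 1), "k_raf_deact")
  # distributive dual phosphorylation of MEK
  add("mek_act1", c(aRAF = 1, MEK = 1), c(aRAF = 1, MEKp = 1), "k_mek_act")
  add("mek_act2", c(aRAF = 1, MEKp = 1), c(aRAF = 1, pMEK = 1), "k_mek_act")
  add("mek_deact2", c(pMEK = 1), c(MEKp = 1), "k_mek_deact")
  add("mek_deact1", c(MEKp = 1), c(MEK = 1), "k_mek_deact")
  # distributive dual phosphorylation of ERK
  add("erk_act1", c(pMEK = 1, ERK = 1), c(pMEK = 1, ERKp = 1), "k_erk_act")
  add("erk_act2", c(pMEK = 1, ERKp = 1), c(pMEK = 1, pERK = 1), "k_erk_act")
  add("erk_deact2", c(pERK = 1), c(ERKp = 1), "k_erk_deact")
  add("erk_deact1", c(ERKp = 1), c(ERK = 1), "k_erk_deact")
  add("pi3k_deact", c(PTEN = 1, aPI3K = 1), c(PTEN = 1, PI3K = 1), "k_pten")
  add("akt_act", c(aPI3K = 1, AKT = 1), c(aPI3K = 1, pAKT = 1), "k_akt_act")
  add("akt_deact", c(pAKT = 1), c(AKT = 1), "k_akt_deact")

  # conservation groups (HRG is a boundary bath, not conserved)
  grp <- function(...) {
    v <- c(...)
    v[names(v) %in% species]
  }
  conservation <- list(
    HER2 = grp(stats::setNames(
      c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 1),
      c(s$HER2, s$H2T, s$H2P, s$H2TP, s$HD, s$pHD, s$HH, s$pHH,
        s$HHP, s$pHHP, s$HHPP, s$pHHPP, s$HDT)),
      stats::setNames(1, s$pHDT),
      stats::setNames(rep(2, length(sos_cplx)), sos_cplx)),
    HER3 = grp(stats::setNames(
      c(1, 1, 1, 1, 1, 1),
      c(s$HER3, s$HER3HRG, s$HD, s$pHD, s$HDT, s$pHDT))),
    SOS = grp(c(SOS = 1),
              stats::setNames(rep(1, length(sos_cplx)), sos_cplx)),
    RAS = c(RAS = 1, aRAS = 1), RAF = c(RAF = 1, aRAF = 1),
    MEK = c(MEK = 1, MEKp = 1, pMEK = 1), ERK = c(ERK = 1, ERKp = 1, pERK = 1),
    PI3K = c(PI3K = 1, aPI3K = 1), PTEN = c(PTEN = 1),
    AKT = c(AKT = 1, pAKT = 1))
  if (with_tr) {
    conservation$Tr <- grp(stats::setNames(
      c(1, 1, 1, 1, 1), c(s$TR, s$H2T, s$H2TP, s$HDT, s$pHDT)))
  }
  if (with_pr) {
    conservation$Pr <- grp(
      stats::setNames(
        c(1, 1, 1, 1, 1, 2, 2),
        c(s$PR, s$H2P, s$H2TP, s$HHP, s$pHHP, s$HHPP, s$pHHPP)),
      stats::setNames(1, paste0(s$pHHP, ":SOS")),
      stats::setNames(2, paste0(s$pHHPP, ":SOS")))
  }
  conservation <- Filter(length, conservation)

  use <- params[intersect(names(params), c(required_params(TRUE, TRUE)))]
  use <- use[!is.na(use)]
  if (with_tr && with_pr) {
    use <- c(use,
             kon_pr_coop = unname(params[["kon_pr"]] *
                                    params[["coop_ternary"]]),
             kon_tr_coop = unname(params[["kon_tr"]] *
                                    params[["coop_ternary"]]))
  }
  net <- reaction_network(species, rx, use, boundary = s$HRG,
                          conservation = conservation)
  attr(net, "config") <- config
  net
}

#' Initial state for a model configuration
#'
#' All receptor pools start monomeric and unphosphorylated; downstream
#' proteins start in their inactive form at the totals given in the
#' parameter set.
#'
#' @inheritParams build_network
#' @param network the network built from `config`.
#' @param hrg override for the clamped HRG concentration (used for the
#'   drug pre-incubation stage); defaults to the configured dose.
#' @export
initial_state <- function(network, config, params, hrg = NULL) {
  y <- stats::setNames(rep(0, length(network$species)), network$species)
  y["HRG"] <- if (is.null(hrg)) config$hrg_dose else hrg
  y["HER3"] <- config$her3_total
  y["HER2"] <- config$her2_total
  if ("Tr" %in% names(y)) y["Tr"] <- config$tr_dose
  if ("Pr" %in% names(y)) y["Pr"] <- config$pr_dose
  y["SOS"] <- params[["sos_total"]]
  y["RAS"] <- params[["ras_total"]]
  y["RAF"] <- params[["raf_total"]]
  y["MEK"] <- params[["mek_total"]]
  y["ERK"] <- params[["erk_total"]]
  y["PI3K"] <- params[["pi3k_total"]]
  y["PTEN"] <- params[["pten_total"]]
  y["AKT"] <- params[["akt_total"]]
  y
}

#' Simulate one treatment condition end to end
#'
#' Mimics the experimental protocol: antibodies are pre-incubated with the
#' cells for `pre_time` minutes without ligand (drug-receptor binding and
#' ligand-independent homodimerisation equilibrate), then HRG is added at
#' t = 0 and the system is integrated to `horizon` minutes. The signal
#' readout is taken according to the config's readout policy (default
#' 60 min post-stimulation).
#'
#' @inheritParams build_network
#' @param preincubate pre-equilibrate drug binding before HRG addition.
#' @param pre_time pre-incubation duration (min).
#' @param horizon post-stimulation horizon (min).
#' @param dt output grid spacing (min).
#' @return list with the post-stimulation `trajectory` and the
#'   `signal_readout`.
#' @export
simulate_scenario <- function(config, params = kinetic_parameters(),
                              preincubate = TRUE, pre_time = 20,
                              horizon = NULL, dt = 1) {
  net <- build_network(config, params)
  if (is.null(horizon)) {
    horizon <- if (is.numeric(config$readout)) {
      max(60, config$readout)
    } else 600
  }
  y0 <- initial_state(net, config, params, hrg = 0)
  if (preincubate && pre_time > 0) {
    pre <- simulate(net, y0, seq(0, pre_time, by = min(dt, pre_time)))
    y0 <- pre$conc[nrow(pre$conc), ]
  }
  y0["HRG"] <- config$hrg_dose
  traj <- simulate(net, y0, seq(0, horizon, by = dt))
  list(trajectory = traj, readout = readout(traj, config$readout))
}
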