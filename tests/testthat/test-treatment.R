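test_that("dimerisation rule table reproduces the seven-row rule set", {
  rules <- dimerisation_rules()
  expect_equal(nrow(rules), 7)
  q <- function(drug, r2, ligand) {
    rules$blocked[rules$drug == drug & rules$receptor2 == r2 &
                    rules$ligand == ligand]
  }
  expect_equal(q("Trastuzumab", "HER3", "yes"), "no/minor")
  expect_equal(q("Trastuzumab", "HER3", "no"), "yes")
  expect_equal(q("Trastuzumab", "HER2", "no"), "yes")
  expect_equal(q("Pertuzumab", "HER3", "yes"), "yes")
  expect_equal(q("Pertuzumab", "HER3", "no"), "no/minor")
  expect_equal(q("Pertuzumab", "HER2", "no"), "no")
  # the ectodomain-shedding row is carried but flagged out of model
  expect_false(rules$in_model[rules$receptor1 == "p95HER2"])
})

test_that("treatment scenarios carry the reference doses", {
  expect_equal(treatment_scenario("control")$tr_dose, 0)
  expect_equal(treatment_scenario("trastuzumab")$tr_dose, 100)
  expect_equal(treatment_scenario("combination")$pr_dose, 100)
  expect_equal(treatment_scenario("pertuzumab")$hrg_dose, 1)
  expect_error(treatment_scenario("trastuzumab", tr_dose = -1),
               "non-negative")
})

test_that("apply_treatment rebuilds the drug-extended network", {
  p <- default_params()
  net0 <- build_network(skov3(), p)
  net <- apply_treatment(net0, treatment_scenario("combination"), p)
  expect_true(all(c("HER2:Tr", "HER2:Pr", "HER2:Tr:Pr") %in% net$species))
  # control leaves the network structurally unchanged
  netc <- apply_treatment(net0, treatment_scenario("control"), p)
  expect_identical(netc$species, net0$species)
  expect_identical(length(netc$reactions), length(net0$reactions))
  expect_error(apply_treatment(net, treatment_scenario("control"), p),
               "drug-free")
})

test_that("percent inhibition arithmetic and error handling", {
  mk <- function(akt, erk) {
    structure(list(pAKT = akt, pERK = erk, time = 60),
              class = "signal_readout")
  }
  same <- percent_inhibition(mk(10, 20), mk(10, 20))
  expect_equal(same$pAKT, 0)
  expect_equal(same$pERK, 0)
  half <- percent_inhibition(mk(10, 10), mk(10, 20))
  expect_equal(half$pERK, 50)
  boosted <- percent_inhibition(mk(15, 20), mk(10, 20))
  expect_equal(boosted$pAKT, -50)
  expect_error(percent_inhibition(mk(1, 1), mk(0, 1)), "positive")
})

test_that("saturating monotherapies with HER3 absent act through pERK only", {
  p <- default_params()
  base <- model_config(her2_total = 50, her3_total = 0, hrg_dose = 1,
                       readout = list(type = "steady_state"))
  run <- function(tr, pr) {
    cfg <- model_config(her2_total = 50, her3_total = 0, hrg_dose = 1,
                        tr_dose = tr, pr_dose = pr,
                        readout = list(type = "steady_state"))
    simulate_scenario(cfg, p, horizon = 2000, dt = 10)$readout
  }
  ctrl <- run(0, 0)
  tr <- run(1000, 0)
  pr <- run(0, 1000)
  # trastuzumab suppresses homodimer-driven pERK almost completely
  expect_lt(tr$pERK / ctrl$pERK, 0.02)
  # pertuzumab leaves homodimer-driven pERK essentially unchanged
  expect_equal(pr$pERK, ctrl$pERK, tolerance = 0.02)
})

test_that("composition scan validates its grid and control scans are zero", {
  p <- default_params()
  expect_error(composition_scan(treatment_scenario("control"),
                                c(0.5, 0.4), skov3(), p), "increasing")
  expect_error(composition_scan(treatment_scenario("control"),
                                c(0.001, 0.5), skov3(), p), "within")
  grid <- c(0.05, 0.5, 1.5)
  sc <- composition_scan(treatment_scenario("control"), grid, skov3(), p)
  expect_equal(sc$pakt_inhibition, rep(0, 3))
  expect_equal(sc$perk_inhibition, rep(0, 3))
  expect_equal(sc$ratio, grid)
})

test_that("cell-line presets encode the assumed receptor compositions", {
  expect_equal(cell_line_preset("MCF7")$ratio, 1.0)
  expect_equal(cell_line_preset("MCF7_HER2_18")$ratio, 0.1)
  expect_equal(cell_line_preset("SKOV3_treated")$ratio, 0.5)
  expect_lt(cell_line_preset("SKOV3_untreated")$her3_total /
              cell_line_preset("SKOV3_untreated")$her2_total, 0.11)
  expect_lt(cell_line_preset("MCF7")$her2_total,
            cell_line_preset("SKOV3_treated")$her2_total)
  expect_error(cell_line_preset("HELA"), "valid presets")
})

test_that("compare_to_reference tabulates differences without fitting", {
  inh <- function(akt, erk) {
    structure(list(pAKT = akt, pERK = erk), class = "inhibition_result")
  }
  ref <- generate_reference_inhibition(
    list(trastuzumab = list(pAKT = 5, pERK = 55)), sds = 0, seed = 1)
  # sd 0 returns means exactly
  expect_equal(ref$scenarios$trastuzumab$pERK$mean, 55)
  tab <- compare_to_reference(list(trastuzumab = inh(5, 55)), ref)
  expect_equal(tab$abs_difference, c(0, 0))
  ref5 <- generate_reference_inhibition(
    list(trastuzumab = list(pAKT = 5, pERK = 55)), sds = 5, seed = 1)
  ref5$scenarios$trastuzumab$pERK$mean <- 55  # pin for arithmetic check
  tab5 <- compare_to_reference(list(trastuzumab = inh(5, 60)), ref5)
  erk_row <- tab5[tab5$signal == "pERK", ]
  expect_equal(erk_row$abs_difference, 5)
  expect_true(erk_row$within_error)
  expect_error(
    compare_to_reference(list(pertuzumab = inh(1, 1)), ref), "mismatch")
  expect_error(
    compare_to_reference(list(), structure(list(scenarios = list()),
                                           class = "reference_inhibition")),
    "empty")
})

test_that("unit ternary cooperativity factorises combination occupancy", {
  p <- default_params()
  p["coop_ternary"] <- 1
  p["kon_hom"] <- 0  # isolated receptor: no dimerisation
  p["kon_het"] <- 0
  # drugs in large excess over receptor so free-drug depletion is negligible
  run <- function(tr, pr) {
    cfg <- model_config(her2_total = 1, her3_total = 0, hrg_dose = 0,
                        tr_dose = tr, pr_dose = pr,
                        readout = list(type = "steady_state"))
    simulate_scenario(cfg, p, horizon = 4000, dt = 20)$readout$state
  }
  st_t <- run(500, 0)
  st_p <- run(0, 500)
  st_c <- run(500, 500)
  theta_t <- st_t[["HER2:Tr"]]
  theta_p <- st_p[["HER2:Pr"]]
  expect_equal(st_c[["HER2:Tr:Pr"]], theta_t * theta_p, tolerance = 1e-3)
})
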