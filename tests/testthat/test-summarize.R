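test_that("mitochondrial ATP share reproduces the published worked example", {
  # inputs are the published light-period ATP synthesis rates for CAM
  expect_equal(round(mito_atp_share(37.86, 68.59), 1), 35.6)
  expect_equal(mito_atp_share(5, 5), 50)
  expect_equal(mito_atp_share(0, 3), 0)
  expect_error(mito_atp_share(0, 0), "zero")
  expect_error(mito_atp_share(-1, 2), "non-negative")
})

test_that("percent change reproduces the published worked example", {
  # photon cost of CAM cycling relative to C3
  expect_equal(round(percent_change(199.40, 209.04), 1), 4.8)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(10, 5), -50)
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("an all-zero flux solution summarizes to all-zero fields", {
  m <- apply_scenario(
    build_toy_leaf(toy_config(maintenance_atp_light = 0,
                              maintenance_atp_dark = 0,
                              maintenance_nadph_light = 0,
                              maintenance_nadph_dark = 0, phloem_export = 0)),
    scenario_spec("CAM_idling", phloem_export = 0))
  es <- energetics_summary(pfba(m), m)
  expect_true(all(as.numeric(es[1, ]) == 0, na.rm = TRUE))
})

test_that("summaries refuse non-optimal solutions", {
  bad <- minimize_photons(chain_model(demand = 1, converter_ub = 0.4))
  expect_error(energetics_summary(bad, chain_model()), "optimal")
  expect_error(carbon_closure(bad, chain_model()), "optimal")
})

test_that("toy CAM summary shows nocturnal malate and daytime starch storage", {
  x <- scenario_solution("CAM")
  es <- energetics_summary(x$solution, x$model)
  expect_gt(es$starch_accumulation, 0)
  expect_lt(es$malate_accumulation, 0)
  expect_gt(es$pepc_dark, 0)
  expect_gt(es$malate_decarboxylation_light, 0)
  expect_gt(es$glycolysis_dark, 0)
  expect_gt(es$gluconeogenesis_light, 0)
  # nocturnal PEPC fixation equals daytime decarboxylation in steady state
  expect_equal(es$pepc_dark, es$malate_decarboxylation_light, tolerance = 1e-6)
  # ATP production fields account for the synthase stoichiometry
  v <- coef(x$solution)
  expect_equal(es$atp_mito_dark, 2.5 * v[["MITO_ETC_m2"]], tolerance = 1e-9)
  expect_equal(es$atp_light_reactions, v[["PLASTID_ATP_SYNTH_p1"]],
               tolerance = 1e-9)
})

test_that("accumulation signs across scenarios match the published pattern", {
  starch <- vapply(c("C3", "CAM", "CAM_cycling", "CAM_idling"), function(sc) {
    x <- scenario_solution(sc)
    energetics_summary(x$solution, x$model)$starch_accumulation
  }, numeric(1))
  malate <- vapply(c("C3", "CAM", "CAM_cycling", "CAM_idling"), function(sc) {
    x <- scenario_solution(sc)
    energetics_summary(x$solution, x$model)$malate_accumulation
  }, numeric(1))
  expect_true(all(starch > 0))
  expect_true(all(malate[c("CAM", "CAM_cycling", "CAM_idling")] <= 0))
  expect_lt(starch[["C3"]], starch[["CAM_cycling"]])
  expect_lt(starch[["CAM_cycling"]], starch[["CAM"]])
  expect_lt(starch[["C3"]], starch[["CAM_idling"]])
  expect_lt(starch[["CAM_idling"]], starch[["CAM"]])
})

test_that("CAM idling closes the carbon books: starch carbon equals malate carbon", {
  x <- scenario_solution("CAM_idling")
  cc <- carbon_closure(x$solution, x$model)
  expect_lt(abs(cc$net_external_light), 1e-6)
  expect_lt(abs(cc$net_external_dark), 1e-6)
  tc <- stats::setNames(cc$transfer_carbon$carbon_flux,
                        cc$transfer_carbon$reaction_id)
  # 6 carbons per starch glucose unit vs 4 per malate
  v <- coef(x$solution)
  expect_equal(unname(tc[["STARCH_p_dielTransfer"]]),
               6 * v[["STARCH_p_dielTransfer"]], tolerance = 1e-9)
  expect_equal(6 * abs(v[["STARCH_p_dielTransfer"]]),
               4 * abs(v[["MAL_v_dielTransfer"]]), tolerance = 1e-6)
  # no other carbon crosses the phase boundary
  other <- setdiff(names(tc), c("STARCH_p_dielTransfer", "MAL_v_dielTransfer",
                                "O2_c_dielTransfer"))
  expect_true(all(abs(tc[other]) < 1e-6))
})

test_that("C3 carbon audit: net CO2 uptake equals phloem carbon export", {
  x <- scenario_solution("C3")
  v <- coef(x$solution)
  co2_in <- v[["EX_CO2_e1"]] + v[["EX_CO2_e2"]]
  phloem_c <- 12 * (v[["EX_PHLOEM_SUC_e1"]] + v[["EX_PHLOEM_SUC_e2"]])
  expect_equal(co2_in, phloem_c, tolerance = 1e-6)
  cc <- carbon_closure(x$solution, x$model)
  expect_lt(abs(cc$net_external_total), 1e-6)
})

test_that("energetics tables line scenarios up side by side", {
  sols <- lapply(c(C3 = "C3", CAM = "CAM"), function(sc) scenario_solution(sc)$solution)
  mods <- lapply(c(C3 = "C3", CAM = "CAM"), function(sc) scenario_solution(sc)$model)
  tab <- energetics_table(sols, mods)
  expect_equal(colnames(tab), c("C3", "CAM"))
  expect_true("photon_demand" %in% rownames(tab))
  expect_lt(tab["photon_demand", "C3"], tab["photon_demand", "CAM"])
})
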