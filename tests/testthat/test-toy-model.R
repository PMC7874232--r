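test_that("every internal toy reaction conserves carbon", {
  m <- toy()
  imb <- reaction_carbon_imbalance(m)
  boundary <- grepl("^EX_", m$reactions$id)
  expect_true(all(abs(imb[!boundary]) < 1e-12))
  # and the boundary reactions move exactly their species' carbon
  expect_equal(unname(imb[["EX_CO2_e1"]]), 1)
  expect_equal(unname(imb[["EX_PHLOEM_SUC_e1"]]), -12)
})

test_that("the toy model is feasible under all four canonical scenarios", {
  for (sc in c("C3", "CAM", "CAM_cycling", "CAM_idling")) {
    x <- scenario_solution(sc)
    expect_equal(x$solution$status, "optimal")
    expect_lt(mass_balance_residual(x$solution, x$model), 1e-6)
  }
})

test_that("with no demands at all the photon optimum is zero", {
  cfg <- toy_config(maintenance_atp_light = 0, maintenance_atp_dark = 0,
                    maintenance_nadph_light = 0, maintenance_nadph_dark = 0,
                    phloem_export = 0)
  m <- build_toy_leaf(cfg)
  spec <- scenario_spec("CAM_idling", phloem_export = 0)
  sol <- minimize_photons(apply_scenario(m, spec))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-9)
})

test_that("invalid toy configurations are rejected", {
  expect_error(toy_config(photons_per_atp = 0), "> 0")
  expect_error(toy_config(maintenance_atp_dark = -1), ">= 0")
  expect_error(toy_config(photoresp_co2_release = 1.2), "electron")
})

test_that("randomized variants are reproducible and feasible", {
  v1 <- randomized_variants(n = 2, seed = 42)
  v2 <- randomized_variants(n = 2, seed = 42)
  expect_equal(v1[[1]]$toy_config, v2[[1]]$toy_config)
  expect_equal(v1[[2]]$toy_config, v2[[2]]$toy_config)
  # jitter actually moved the parameters
  expect_false(isTRUE(all.equal(v1[[1]]$toy_config$photons_per_atp,
                                toy_config()$photons_per_atp)))
  # feasibility was checked at build time for all four scenarios; spot-check one
  sol <- pfba(apply_scenario(v1[[1]], scenario_spec("CAM")))
  expect_equal(sol$status, "optimal")
})

test_that("energetic costs act monotonically on the solutions", {
  base_cam <- scenario_solution("CAM")$solution$objective_value
  dearer <- build_toy_leaf(toy_config(tonoplast_atp_per_malate = 1.0))
  dear_cam <- minimize_photons(apply_scenario(dearer,
                                              scenario_spec("CAM")))$objective_value
  # doubling the tonoplast pump cost makes CAM strictly more expensive
  expect_gt(dear_cam, base_cam + 1e-6)

  base_tca <- coef(scenario_solution("C3")$solution)[["SDH_FUM_m2"]]
  hungry <- build_toy_leaf(toy_config(maintenance_atp_dark = 4))
  hungry_tca <- coef(pfba(apply_scenario(hungry,
                                         scenario_spec("C3"))))[["SDH_FUM_m2"]]
  # doubling the dark maintenance ATP drain pulls more flux through the TCA cycle
  expect_gt(hungry_tca, base_tca + 1e-6)
})

test_that("scenario physiology emerges from the default toy", {
  c3 <- scenario_solution("C3")
  cam <- scenario_solution("CAM")
  cyc <- scenario_solution("CAM_cycling")
  idl <- scenario_solution("CAM_idling")
  vc3 <- coef(c3$solution); vcam <- coef(cam$solution)
  vcyc <- coef(cyc$solution); vidl <- coef(idl$solution)

  # (a) C3: no nocturnal PEPC, negligible malate transfer
  expect_equal(unname(vc3[["PEPC_c2"]]), 0, tolerance = 1e-6)
  expect_lt(abs(vc3[["MAL_v_dielTransfer"]]), 1e-6)

  # (b) CAM cycling: nocturnal PEPC and malate storage; more daytime starch
  expect_gt(vcyc[["PEPC_c2"]], 1e-3)
  expect_lt(vcyc[["MAL_v_dielTransfer"]], -1e-3)  # dark-to-light transfer
  expect_gt(vcyc[["STARCH_p_dielTransfer"]], vc3[["STARCH_p_dielTransfer"]] + 1e-3)

  # (c) CAM: all uptake nocturnal; largest starch and malate transfers
  expect_equal(unname(vcam[["EX_CO2_e1"]]), 0, tolerance = 1e-9)
  expect_gt(vcam[["EX_CO2_e2"]], 1e-3)
  expect_gt(vcam[["STARCH_p_dielTransfer"]],
            max(vc3[["STARCH_p_dielTransfer"]], vcyc[["STARCH_p_dielTransfer"]],
                vidl[["STARCH_p_dielTransfer"]]))
  expect_gt(abs(vcam[["MAL_v_dielTransfer"]]),
            max(abs(vc3[["MAL_v_dielTransfer"]]), abs(vcyc[["MAL_v_dielTransfer"]]),
                abs(vidl[["MAL_v_dielTransfer"]])))

  # (d) CAM idling: closed to carbon, photons still needed for maintenance
  expect_gt(idl$solution$objective_value, 1)
  expect_equal(unname(vidl[["EX_CO2_e1"]]), 0, tolerance = 1e-9)
  expect_equal(unname(vidl[["EX_CO2_e2"]]), 0, tolerance = 1e-9)

  # photon-demand ordering across modes
  expect_lt(c3$solution$objective_value, cyc$solution$objective_value)
  expect_lt(cyc$solution$objective_value, cam$solution$objective_value)
  expect_lt(idl$solution$objective_value, c3$solution$objective_value)
})
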