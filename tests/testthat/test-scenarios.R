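test_that("the four canonical scenario columns carry the published constraints", {
  c3 <- scenario_spec("C3")
  expect_equal(c3$phloem_export, 0.259)
  expect_equal(c3$co2_light, "unconstrained")
  expect_equal(c3$ratio_light, 3)
  expect_equal(c3$ratio_dark, 3)

  cam <- scenario_spec("CAM")
  expect_equal(cam$co2_light, 0)
  expect_equal(cam$o2_light, 0)
  expect_equal(cam$co2_dark, "unconstrained")
  expect_equal(cam$ratio_light, 5.15)
  expect_equal(cam$ratio_dark, 3)

  cyc <- scenario_spec("CAM_cycling")
  expect_equal(cyc$co2_dark, 0)
  expect_equal(cyc$o2_dark, 0)
  expect_equal(cyc$ratio_light, 3)
  expect_equal(cyc$ratio_dark, 5.15)

  idl <- scenario_spec("CAM_idling")
  expect_equal(idl$phloem_export, 0)
  expect_equal(idl$co2_light, 0)
  expect_equal(idl$co2_dark, 0)
  expect_equal(idl$ratio_light, 5.15)
  expect_equal(idl$ratio_dark, 5.15)

  expect_error(scenario_spec("C4"), "unknown scenario")
})

test_that("applying a scenario sets the stated bounds and phloem equality", {
  m <- apply_scenario(toy(), scenario_spec("CAM"))
  expect_equal(unname(reaction_bounds(m, "EX_CO2_e1")), c(0, 0))
  expect_equal(unname(reaction_bounds(m, "EX_O2_e1")), c(0, 0))
  expect_equal(unname(reaction_bounds(m, "EX_CO2_e2")), c(-1000, 1000))
  # 3:1 light:dark phloem split, fixed as equalities
  expect_equal(unname(reaction_bounds(m, "EX_PHLOEM_SUC_e1")),
               rep(0.75 * 0.259, 2))
  expect_equal(unname(reaction_bounds(m, "EX_PHLOEM_SUC_e2")),
               rep(0.25 * 0.259, 2))
})

test_that("every optimal solution satisfies the ratio coupling in both phases", {
  for (sc in c("C3", "CAM", "CAM_cycling", "CAM_idling")) {
    x <- scenario_solution(sc)
    spec <- scenario_spec(sc)
    v <- coef(x$solution)
    expect_lt(abs(v[["RBC_CARB_p1"]] - spec$ratio_light * v[["RBC_OXY_p1"]]), 1e-6)
    expect_lt(abs(v[["RBC_CARB_p2"]] - spec$ratio_dark * v[["RBC_OXY_p2"]]), 1e-6)
  }
})

test_that("scenario application is idempotent", {
  spec <- scenario_spec("CAM")
  m1 <- apply_scenario(toy(), spec)
  m2 <- apply_scenario(m1, spec)
  expect_identical(m2$reactions, m1$reactions)
  expect_equal(stoich_matrix(m2), stoich_matrix(m1))
  # and swapping scenarios on an already-constrained model works
  m3 <- apply_scenario(m1, scenario_spec("C3"))
  s3 <- minimize_photons(m3)
  s3_fresh <- minimize_photons(apply_scenario(toy(), scenario_spec("C3")))
  expect_equal(s3$objective_value, s3_fresh$objective_value, tolerance = 1e-9)
})

test_that("added scenario constraints cannot lower the photon optimum", {
  # same ratios; closing the dark exchanges only tightens the feasible set
  open_spec <- scenario_spec("C3")
  closed_spec <- scenario_spec("C3", co2_dark = 0, o2_dark = 0)
  open_opt <- minimize_photons(apply_scenario(toy(), open_spec))$objective_value
  closed_opt <- minimize_photons(apply_scenario(toy(), closed_spec))$objective_value
  expect_gte(closed_opt, open_opt - 1e-9)
})

test_that("storage restrictions close the excluded diel transfers", {
  m <- apply_scenario(toy(), scenario_spec("CAM", storage = "sucrose_only"))
  expect_equal(unname(reaction_bounds(m, "STARCH_p_dielTransfer")), c(0, 0))
  expect_equal(unname(reaction_bounds(m, "FRU_v_dielTransfer")), c(0, 0))
  expect_equal(unname(reaction_bounds(m, "SUC_v_dielTransfer")), c(-1000, 1000))
  # each sole-storage variant still solves, and the storage flows through
  # the permitted pool
  for (st in c("starch_only", "sucrose_only", "fructan_only")) {
    sol <- pfba(apply_scenario(toy(), scenario_spec("CAM", storage = st)))
    expect_equal(sol$status, "optimal")
  }
})

test_that("decarboxylation route restrictions zero disjoint reaction sets", {
  m_pk <- restrict_decarboxylation(toy(), "PEPCK_only")
  m_me <- restrict_decarboxylation(toy(), "ME_only")
  zeroed <- function(m) m$reactions$id[m$reactions$lb == 0 & m$reactions$ub == 0]
  z_pk <- setdiff(zeroed(m_pk), zeroed(toy()))
  z_me <- setdiff(zeroed(m_me), zeroed(toy()))
  expect_setequal(z_pk, c("NADP_ME_c1", "NADP_ME_c2"))
  expect_setequal(z_me, c("PEPCK_c1", "PEPCK_c2"))
  expect_length(intersect(z_pk, z_me), 0)
  # identity route leaves the model untouched
  expect_identical(restrict_decarboxylation(toy(), "any"), toy())
  # both restricted routes remain solvable under CAM
  for (rt in c("PEPCK_only", "ME_only")) {
    sol <- pfba(apply_scenario(toy(), scenario_spec("CAM", decarb_route = rt)))
    expect_equal(sol$status, "optimal")
  }
})
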