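test_that("oxygen diel transfer is added once, idempotently", {
  m <- remove_reactions(toy(), "O2_c_dielTransfer")
  m2 <- add_oxygen_diel_transfer(m)
  expect_true(has_reaction(m2, "OXYGEN_MOLECULE_e_dielTransfer"))
  s <- m2$stoich[["OXYGEN_MOLECULE_e_dielTransfer"]]
  expect_equal(unname(s[c("O2_c1", "O2_c2")]), c(-1, 1))
  expect_equal(unname(reaction_bounds(m2, "OXYGEN_MOLECULE_e_dielTransfer")),
               c(-1000, 1000))
  # already present (either id form): reported as skipped, nothing added
  m3 <- add_oxygen_diel_transfer(m2)
  expect_equal(attr(m3, "prep_note"), "skipped_already_present")
  expect_equal(nrow(m3$reactions), nrow(m2$reactions))
  expect_equal(attr(add_oxygen_diel_transfer(toy()), "prep_note"),
               "skipped_already_present")
})

test_that("oxygen transfer restores CAM feasibility on a model lacking it", {
  m <- remove_reactions(toy(), "O2_c_dielTransfer")
  cam <- apply_scenario(m, scenario_spec("CAM"))
  expect_false(minimize_photons(cam)$status == "optimal")
  cam_fixed <- apply_scenario(add_oxygen_diel_transfer(m), scenario_spec("CAM"))
  expect_equal(minimize_photons(cam_fixed)$status, "optimal")
})

test_that("strict ops error on models lacking the required species", {
  m <- toy()  # no proton bookkeeping by design
  expect_error(enable_vacuolar_proton_accumulation(m), "proton")
  expect_error(add_proton_leaks(m), "proton")
  m_no_o2 <- remove_reactions(m, c("EX_O2_e1", "EX_O2_e2", "O2_c_dielTransfer"))
  expect_error(add_oxygen_diel_transfer(m_no_o2), "[oO]2")
})

test_that("proton corrections act on a synthetic genome-scale fragment", {
  frag <- synthetic_core_fragment()

  f1 <- enable_vacuolar_proton_accumulation(frag)
  expect_true(has_reaction(f1, "PROTON_v_dielTransfer"))
  expect_equal(attr(enable_vacuolar_proton_accumulation(f1), "prep_note"),
               "skipped_already_present")

  f2 <- block_free_proton_flow(frag)
  expect_equal(unname(reaction_bounds(f2, "unlProtHYPO_c1")), c(0, 0))
  expect_equal(unname(reaction_bounds(f2, "unlProtHYPO_c2")), c(0, 0))
  expect_identical(reaction_bounds(block_free_proton_flow(f2), "unlProtHYPO_c1"),
                   reaction_bounds(f2, "unlProtHYPO_c1"))

  f3 <- set_ims_proton_transport_reversible(frag)
  expect_equal(unname(reaction_bounds(f3, "H_ic1")), c(-1000, 1000))
  expect_equal(unname(reaction_bounds(f3, "H_ic2")), c(-1000, 1000))

  f4 <- add_proton_leaks(frag)
  for (rid in c("H_vc1", "H_vc2", "H_ec1", "H_ec2")) {
    expect_true(has_reaction(f4, rid))
    expect_equal(unname(reaction_bounds(f4, rid)), c(0, 1000))
  }
  expect_equal(nrow(add_proton_leaks(f4)$reactions), nrow(f4$reactions))

  f5 <- fix_mannose_hexokinase_compartment(frag)
  s <- f5$stoich[["HEXOKINASE_RXN_MANNOSE_c1"]]
  comp <- f5$metabolites$compartment[match(names(s), f5$metabolites$id)]
  expect_true(all(comp == "c"))
  expect_true("MANNOSE_c1" %in% names(s))
})

test_that("the correction bundle is idempotent and leaves other stoichiometry intact", {
  frag <- synthetic_core_fragment()
  r1 <- apply_core_modifications(frag)
  expect_setequal(names(r1$report$notes),
                  c("oxygen_diel_transfer", "vacuolar_proton_accumulation",
                    "block_free_proton_flow", "ims_proton_transport_reversible",
                    "proton_leaks", "mannose_hexokinase_compartment"))
  expect_true(length(r1$report$applied) >= 5)

  r2 <- apply_core_modifications(r1$model)
  expect_identical(r2$model$reactions, r1$model$reactions)
  expect_identical(r2$model$stoich, r1$model$stoich)
  expect_length(setdiff(r2$report$applied,
                        c("block_free_proton_flow",
                          "ims_proton_transport_reversible")), 0)

  # only the mannose hexokinase stoichiometry may change
  pre <- frag$stoich[setdiff(names(frag$stoich), "HEXOKINASE_RXN_MANNOSE_c1")]
  post <- r1$model$stoich[names(pre)]
  expect_identical(post, pre)

  # bundle on the toy: everything skips, model unchanged, solutions identical
  t1 <- apply_core_modifications(toy())
  expect_length(t1$report$applied, 0)
  before <- minimize_photons(apply_scenario(toy(), scenario_spec("C3")))
  after <- minimize_photons(apply_scenario(t1$model, scenario_spec("C3")))
  expect_equal(after$objective_value, before$objective_value, tolerance = 1e-9)
})

test_that("proton leak fluxes can never be negative by construction", {
  frag <- apply_core_modifications(synthetic_core_fragment())$model
  for (rid in c("H_vc1", "H_vc2", "H_ec1", "H_ec2"))
    expect_gte(reaction_bounds(frag, rid)[["lb"]], 0)
})
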