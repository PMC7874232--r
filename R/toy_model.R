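#' Configuration of the synthetic diel leaf model
#'
#' The toy leaf is a lumped two-phase network (one reaction per pathway
#' segment) that carries every semantic role the analysis pipeline relies on:
#' photon-driven ATP/NADPH supply, RuBisCO carboxylase/oxygenase with a
#' photorespiratory CO2 release, diel starch (plus optional vacuolar sucrose
#' and fructan) storage, PEPC and vacuolar malate storage behind an
#' ATP-dependent tonoplast pump, PEPCK and malic-enzyme decarboxylation
#' routes, glycolysis/gluconeogenesis, a TCA lump ending in succinate
#' dehydrogenase, an NADH-dehydrogenase-fronted mitochondrial ETC, plastidial
#' and cytosolic G6PDH (OPPP), sucrose synthesis with phloem export, and fixed
#' per-phase maintenance drains. Every metabolite carries a carbon count and
#' every internal reaction is carbon balanced, so carbon bookkeeping is exact.
#'
#' Units: fluxes umol m-2 s-1; cost parameters are dimensionless
#' stoichiometric ratios.
#'
#' @param photons_per_atp photons per ATP at the plastidial ATP synthase
#'   (cyclic electron flow lump), default 3.
#' @param photons_per_nadph photons per NADPH at linear electron flow
#'   (releases 0.5 O2 from water splitting), default 4.
#' @param atp_per_co2_cbb,nadph_per_co2_cbb Calvin-Benson cost per CO2 fixed,
#'   defaults 3 and 2.
#' @param photoresp_co2_release CO2 released per RuBisCO oxygenation,
#'   default 0.5; must lie in (0, 1). The NADPH cost of the oxygenation lump
#'   is derived as `2 - 2 * photoresp_co2_release` so that the lump conserves
#'   electrons — in the fully closed CAM-idling scenario any redox imbalance
#'   would make the O2 books unclosable.
#' @param atp_per_oxygenation ATP cost of photorespiratory recovery per
#'   oxygenation, default 1.
#' @param tonoplast_atp_per_malate ATP cost of pumping one malate into the
#'   vacuole, default 0.5.
#' @param sugar_storage_atp ATP cost of vacuolar sucrose/fructan storage per
#'   hexose pair, default 0.5.
#' @param po_ratio_nadh ATP per NADH at the mitochondrial ETC, default 2.5.
#' @param maintenance_atp_light,maintenance_atp_dark,maintenance_nadph_light,maintenance_nadph_dark
#'   fixed maintenance drains (umol m-2 s-1), defaults 2, 2, 0.5, 0.5.
#' @param phloem_export default phloem export rate, 0.259 umol sucrose
#'   m-2 s-1 (the standard C3 leaf value used by the scenarios).
#' @param seed optional integer recorded for randomized variants.
#' @return a `toy_config` list, validated.
#' @export
toy_config <- function(photons_per_atp = 3, photons_per_nadph = 4,
                       atp_per_co2_cbb = 3, nadph_per_co2_cbb = 2,
                       photoresp_co2_release = 0.5,
                       atp_per_oxygenation = 1,
                       tonoplast_atp_per_malate = 0.5,
                       sugar_storage_atp = 0.5,
                       po_ratio_nadh = 2.5,
                       maintenance_atp_light = 2, maintenance_atp_dark = 2,
                       maintenance_nadph_light = 0.5,
                       maintenance_nadph_dark = 0.5,
                       phloem_export = 0.259, seed = NULL) {
  cfg <- list(photons_per_atp = photons_per_atp,
              photons_per_nadph = photons_per_nadph,
              atp_per_co2_cbb = atp_per_co2_cbb,
              nadph_per_co2_cbb = nadph_per_co2_cbb,
              photoresp_co2_release = photoresp_co2_release,
              atp_per_oxygenation = atp_per_oxygenation,
              nadph_per_oxygenation = 2 - 2 * photoresp_co2_release,
              tonoplast_atp_per_malate = tonoplast_atp_per_malate,
              sugar_storage_atp = sugar_storage_atp,
              po_ratio_nadh = po_ratio_nadh,
              maintenance_atp_light = maintenance_atp_light,
              maintenance_atp_dark = maintenance_atp_dark,
              maintenance_nadph_light = maintenance_nadph_light,
              maintenance_nadph_dark = maintenance_nadph_dark,
              phloem_export = phloem_export, seed = seed)
  costs <- cfg[c("photons_per_atp", "photons_per_nadph", "atp_per_co2_cbb",
                 "nadph_per_co2_cbb", "photoresp_co2_release",
                 "atp_per_oxygenation", "tonoplast_atp_per_malate",
                 "sugar_storage_atp", "po_ratio_nadh")]
  if (any(unlist(costs) <= 0)) stop("all cost parameters must be > 0")
  if (photoresp_co2_release >= 1)
    stop("photoresp_co2_release must be < 1 (electron balance of the lump)")
  maint <- cfg[c("maintenance_atp_light", "maintenance_atp_dark",
                 "maintenance_nadph_light", "maintenance_nadph_dark")]
  if (any(unlist(maint) < 0)) stop("maintenance drains must be >= 0")
  if (cfg$phloem_export < 0) stop("phloem_export must be >= 0")
  class(cfg) <- "toy_config"
  cfg
}

# metabolite template: id stem, compartment, carbon count
toy_metabolite_table <- function() {
  m <- rbind(
    c("PHOTON_p", "p", 0), c("CO2_c", "c", 1), c("O2_c", "c", 0),
    c("ATP_c", "c", 0), c("NADPH_c", "c", 0), c("NADH_c", "c", 0),
    c("TP_c", "c", 3), c("PGA_c", "c", 3), c("PEP_c", "c", 3),
    c("PYR_c", "c", 3), c("OAA_c", "c", 4), c("MAL_c", "c", 4),
    c("MAL_v", "v", 4), c("G6P_c", "c", 6), c("R5P_c", "c", 5),
    c("ACCOA_m", "m", 2), c("SUCC_m", "m", 4), c("STARCH_p", "p", 6),
    c("SUC_c", "c", 12), c("SUC_v", "v", 12), c("FRU_v", "v", 12))
  data.frame(stem = m[, 1], compartment = m[, 2],
             carbon = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

# one phase worth of reactions; s is the id suffix ("1" light, "2" dark),
# light=TRUE adds the photon-driven reactions
toy_phase_reactions <- function(cfg, s, light) {
  M <- function(stem) paste0(stem, s)
  r <- list()
  add <- function(id, stoich, lb, ub, name = id)
    r[[length(r) + 1]] <<- list(id = paste0(id, s), stoich = stoich,
                                lb = lb, ub = ub, name = name)
  if (light) {
    add("EX_PHOTON_p", stats::setNames(1, M("PHOTON_p")), 0, 1000,
        "photon uptake")
    add("PLASTID_ATP_SYNTH_p",
        stats::setNames(c(-cfg$photons_per_atp, 1), c(M("PHOTON_p"), M("ATP_c"))),
        0, 1000, "plastidial ATP synthase (cyclic electron flow lump)")
    add("LIGHT_NADPH_p",
        stats::setNames(c(-cfg$photons_per_nadph, 1, 0.5),
                        c(M("PHOTON_p"), M("NADPH_c"), M("O2_c"))),
        0, 1000, "linear electron flow: NADPH + O2 from water splitting")
  }
  add("EX_CO2_e", stats::setNames(1, M("CO2_c")), -1000, 1000, "CO2 exchange")
  add("EX_O2_e", stats::setNames(1, M("O2_c")), -1000, 1000, "O2 exchange")
  add("RBC_CARB_p",
      stats::setNames(c(-1, -cfg$atp_per_co2_cbb, -cfg$nadph_per_co2_cbb, 1 / 3),
                      c(M("CO2_c"), M("ATP_c"), M("NADPH_c"), M("TP_c"))),
      0, 1000, "RuBisCO carboxylase (Calvin-Benson lump)")
  add("RBC_OXY_p",
      stats::setNames(c(-1, -cfg$photoresp_co2_release / 3,
                        -cfg$atp_per_oxygenation, -cfg$nadph_per_oxygenation,
                        cfg$photoresp_co2_release),
                      c(M("O2_c"), M("TP_c"), M("ATP_c"), M("NADPH_c"),
                        M("CO2_c"))),
      0, 1000, "RuBisCO oxygenase + photorespiratory recovery lump")
  add("GAPDH_PGK_c",
      stats::setNames(c(-1, -1, -1, 1),
                      c(M("PGA_c"), M("ATP_c"), M("NADH_c"), M("TP_c"))),
      -1000, 1000, "3-PGA <-> triose-P (reverse = glycolytic ATP/NADH yield)")
  add("ENO_c", stats::setNames(c(-1, 1), c(M("PGA_c"), M("PEP_c"))),
      -1000, 1000, "3-PGA <-> PEP (glycolysis/gluconeogenesis marker)")
  add("PK_c", stats::setNames(c(-1, 1, 1), c(M("PEP_c"), M("PYR_c"), M("ATP_c"))),
      0, 1000, "pyruvate kinase")
  add("PPDK_c", stats::setNames(c(-1, -2, 1), c(M("PYR_c"), M("ATP_c"), M("PEP_c"))),
      0, 1000, "pyruvate orthophosphate dikinase")
  add("PEPC_c", stats::setNames(c(-1, -1, 1), c(M("PEP_c"), M("CO2_c"), M("OAA_c"))),
      0, 1000, "PEP carboxylase")
  add("MDH_c", stats::setNames(c(-1, -1, 1), c(M("OAA_c"), M("NADH_c"), M("MAL_c"))),
      -1000, 1000, "malate dehydrogenase")
  add("PEPCK_c", stats::setNames(c(-1, -1, 1, 1),
                                 c(M("OAA_c"), M("ATP_c"), M("PEP_c"), M("CO2_c"))),
      0, 1000, "PEP carboxykinase")
  add("NADP_ME_c", stats::setNames(c(-1, 1, 1, 1),
                                   c(M("MAL_c"), M("PYR_c"), M("CO2_c"), M("NADPH_c"))),
      0, 1000, "NADP-malic enzyme")
  add("TONOPLAST_MAL_PUMP_v",
      stats::setNames(c(-1, -cfg$tonoplast_atp_per_malate, 1),
                      c(M("MAL_c"), M("ATP_c"), M("MAL_v"))),
      0, 1000, "ATP-dependent tonoplast malate import")
  add("MAL_v_RELEASE_v", stats::setNames(c(-1, 1), c(M("MAL_v"), M("MAL_c"))),
      0, 1000, "vacuolar malate release")
  add("PDH_m", stats::setNames(c(-1, 1, 1, 1),
                               c(M("PYR_c"), M("ACCOA_m"), M("CO2_c"), M("NADH_c"))),
      0, 1000, "pyruvate dehydrogenase")
  add("TCA_CS_SCS_m",
      stats::setNames(c(-1, -1, 1, 2, 2, 1),
                      c(M("ACCOA_m"), M("OAA_c"), M("SUCC_m"), M("CO2_c"),
                        M("NADH_c"), M("ATP_c"))),
      0, 1000, "TCA citrate -> succinate lump (incl. substrate-level ATP)")
  add("SDH_FUM_m", stats::setNames(c(-1, 1, 1),
                                   c(M("SUCC_m"), M("MAL_c"), M("NADH_c"))),
      0, 1000, "succinate dehydrogenase + fumarase lump")
  add("MITO_ETC_m",
      stats::setNames(c(-1, -0.5, cfg$po_ratio_nadh),
                      c(M("NADH_c"), M("O2_c"), M("ATP_c"))),
      0, 1000, "NADH dehydrogenase-fronted mitochondrial ETC + ATP synthase")
  add("FBP_ALD_c", stats::setNames(c(-2, 1), c(M("TP_c"), M("G6P_c"))),
      0, 1000, "aldolase + FBPase (gluconeogenic)")
  add("PFK_c", stats::setNames(c(-1, -1, 2), c(M("G6P_c"), M("ATP_c"), M("TP_c"))),
      0, 1000, "phosphofructokinase + aldolase (glycolytic)")
  add("STARCH_SYNTH_p", stats::setNames(c(-1, -1, 1),
                                        c(M("G6P_c"), M("ATP_c"), M("STARCH_p"))),
      0, 1000, "starch synthesis (per glucose unit)")
  add("STARCH_DEG_p", stats::setNames(c(-1, 1), c(M("STARCH_p"), M("G6P_c"))),
      0, 1000, "phosphorolytic starch degradation")
  add("SPS_c", stats::setNames(c(-2, -1, 1), c(M("G6P_c"), M("ATP_c"), M("SUC_c"))),
      0, 1000, "sucrose phosphate synthase lump")
  add("INV_HXK_c", stats::setNames(c(-1, -2, 2), c(M("SUC_c"), M("ATP_c"), M("G6P_c"))),
      0, 1000, "invertase + hexokinase lump")
  add("EX_PHLOEM_SUC_e", stats::setNames(-1, M("SUC_c")), 0, 1000,
      "sucrose export to phloem")
  add("G6PDH_p", stats::setNames(c(-1, 1, 1, 2),
                                 c(M("G6P_c"), M("R5P_c"), M("CO2_c"), M("NADPH_c"))),
      0, 1000, "plastidial G6P dehydrogenase (oxidative OPPP lump)")
  add("G6PDH_c", stats::setNames(c(-1, 1, 1, 2),
                                 c(M("G6P_c"), M("R5P_c"), M("CO2_c"), M("NADPH_c"))),
      0, 1000, "cytosolic G6P dehydrogenase (oxidative OPPP lump)")
  add("NONOX_PPP_c", stats::setNames(c(-6, 5), c(M("R5P_c"), M("G6P_c"))),
      0, 1000, "non-oxidative pentose phosphate recombination")
  maint_atp <- if (s == "1") cfg$maintenance_atp_light else cfg$maintenance_atp_dark
  maint_nadph <- if (s == "1") cfg$maintenance_nadph_light else cfg$maintenance_nadph_dark
  add("MAINT_ATP_c", stats::setNames(-1, M("ATP_c")), maint_atp, maint_atp,
      "maintenance ATP drain")
  add("MAINT_NADPH_c", stats::setNames(c(-1, -0.5), c(M("NADPH_c"), M("O2_c"))),
      maint_nadph, maint_nadph, "maintenance NADPH oxidation drain")
  add("VAC_SUC_PUMP_v",
      stats::setNames(c(-1, -cfg$sugar_storage_atp, 1),
                      c(M("SUC_c"), M("ATP_c"), M("SUC_v"))),
      0, 1000, "vacuolar sucrose import")
  add("VAC_SUC_RELEASE_v", stats::setNames(c(-1, 1), c(M("SUC_v"), M("SUC_c"))),
      0, 1000, "vacuolar sucrose release")
  add("FRUCTAN_SYNTH_v",
      stats::setNames(c(-1, -cfg$sugar_storage_atp, 1),
                      c(M("SUC_c"), M("ATP_c"), M("FRU_v"))),
      0, 1000, "fructan synthesis (per sucrose equivalent)")
  add("FRUCTAN_DEG_v", stats::setNames(c(-1, 1), c(M("FRU_v"), M("SUC_c"))),
      0, 1000, "fructan degradation")
  r
}

#' Build the synthetic diel leaf model
#'
#' Instantiates the lumped leaf network in both phases (id suffix `"1"` =
#' light, `"2"` = dark, matching the diel id convention of genome-scale leaf
#' models), adds the diel transfer reactions for O2, starch, vacuolar malate,
#' vacuolar sucrose and fructan, and wires the full role map. All internal
#' reactions are carbon balanced by construction.
#'
#' @param cfg a [toy_config()].
#' @param check when `TRUE`, verify by solving that the model is feasible
#'   under all four canonical scenarios (slower; used by
#'   [randomized_variants()]).
#' @return a [diel_model()] carrying every required role.
#' @export
build_toy_leaf <- function(cfg = toy_config(), check = FALSE) {
  stopifnot(inherits(cfg, "toy_config"))
  tmpl <- toy_metabolite_table()
  phase_of <- c("1" = "light", "2" = "dark")
  mets <- do.call(rbind, lapply(c("1", "2"), function(s) {
    data.frame(id = paste0(tmpl$stem, s), name = tmpl$stem,
               compartment = tmpl$compartment,
               phase = phase_of[[s]], carbon = tmpl$carbon,
               stringsAsFactors = FALSE)
  }))
  # photons exist only in the light phase
  mets <- mets[mets$id != "PHOTON_p2", , drop = FALSE]

  rl <- c(toy_phase_reactions(cfg, "1", light = TRUE),
          toy_phase_reactions(cfg, "2", light = FALSE))
  transfer <- function(id, stem)
    list(id = id, stoich = stats::setNames(c(-1, 1), paste0(stem, c("1", "2"))),
         lb = -1000, ub = 1000, name = paste(stem, "diel transfer"))
  rl <- c(rl, list(
    transfer("O2_c_dielTransfer", "O2_c"),
    transfer("STARCH_p_dielTransfer", "STARCH_p"),
    transfer("MAL_v_dielTransfer", "MAL_v"),
    transfer("SUC_v_dielTransfer", "SUC_v"),
    transfer("FRU_v_dielTransfer", "FRU_v")))

  ids <- vapply(rl, `[[`, "", "id")
  rxns <- data.frame(id = ids,
                     name = vapply(rl, `[[`, "", "name"),
                     phase = NA_character_,
                     lb = vapply(rl, `[[`, 0, "lb"),
                     ub = vapply(rl, `[[`, 0, "ub"),
                     stringsAsFactors = FALSE)
  stoich <- stats::setNames(lapply(rl, `[[`, "stoich"), ids)
  met_phase <- stats::setNames(mets$phase, mets$id)
  rxns$phase <- vapply(seq_along(ids), function(i) {
    ph <- unique(met_phase[names(stoich[[i]])])
    if (length(ph) == 1L) ph else "transfer"
  }, "")

  role_map <- list(
    photon_uptake_light = "EX_PHOTON_p1",
    co2_exchange_light = "EX_CO2_e1", co2_exchange_dark = "EX_CO2_e2",
    o2_exchange_light = "EX_O2_e1", o2_exchange_dark = "EX_O2_e2",
    phloem_export = c("EX_PHLOEM_SUC_e1", "EX_PHLOEM_SUC_e2"),
    rubisco_carboxylase_light = "RBC_CARB_p1",
    rubisco_oxygenase_light = "RBC_OXY_p1",
    rubisco_carboxylase_dark = "RBC_CARB_p2",
    rubisco_oxygenase_dark = "RBC_OXY_p2",
    pepc_light = "PEPC_c1", pepc_dark = "PEPC_c2",
    pepck = c("PEPCK_c1", "PEPCK_c2"),
    malic_enzyme = c("NADP_ME_c1", "NADP_ME_c2"),
    sdh_light = "SDH_FUM_m1", sdh_dark = "SDH_FUM_m2",
    nadh_dehydrogenase_light = "MITO_ETC_m1",
    nadh_dehydrogenase_dark = "MITO_ETC_m2",
    atp_synthase_plastid_light = "PLASTID_ATP_SYNTH_p1",
    light_reactions_nadph = "LIGHT_NADPH_p1",
    atp_synthase_mito_light = "MITO_ETC_m1",
    atp_synthase_mito_dark = "MITO_ETC_m2",
    g6pdh_plastid_light = "G6PDH_p1", g6pdh_plastid_dark = "G6PDH_p2",
    g6pdh_cytosol_light = "G6PDH_c1", g6pdh_cytosol_dark = "G6PDH_c2",
    glycolysis_3pga_to_pep_light = "ENO_c1",
    glycolysis_3pga_to_pep_dark = "ENO_c2",
    starch_transfer = "STARCH_p_dielTransfer",
    malate_transfer = "MAL_v_dielTransfer",
    sucrose_transfer = "SUC_v_dielTransfer",
    fructan_transfer = "FRU_v_dielTransfer",
    maintenance_atp_light = "MAINT_ATP_c1",
    maintenance_atp_dark = "MAINT_ATP_c2",
    maintenance_nadph_light = "MAINT_NADPH_c1",
    maintenance_nadph_dark = "MAINT_NADPH_c2")

  model <- diel_model(mets, rxns, stoich, role_map, id = "toy_diel_leaf")
  model$toy_config <- cfg
  assert_roles(model)
  if (check) {
    for (sc in c("C3", "CAM", "CAM_cycling", "CAM_idling")) {
      sol <- minimize_photons(apply_scenario(model, scenario_spec(
        sc, phloem_export = if (sc == "CAM_idling") 0 else cfg$phloem_export)))
      if (sol$status != "optimal")
        stop("toy model infeasible under scenario ", sc)
    }
  }
  model
}

#' Randomized parameter variants of the toy leaf
#'
#' Draws `n` models with all cost and maintenance parameters jittered
#' uniformly by +/- 20 percent (seeded, reproducible). Draws whose model is
#' not feasible under all four canonical scenarios are rejected and redrawn.
#'
#' @param cfg base [toy_config()].
#' @param n number of variants.
#' @param seed integer seed.
#' @param max_retry rejection cap per variant; exceeding it is an error that
#'   names the offending parameter draw.
#' @return list of `n` [diel_model()] objects.
#' @export
randomized_variants <- function(cfg = toy_config(), n = 1, seed = 1,
                                max_retry = 20) {
  stopifnot(n >= 1)
  # energetic costs and demands only: the redox-stoichiometric ratios
  # (NADPH per CO2, CO2 per oxygenation) are chemistry, not costs, and
  # perturbing them would break electron conservation in closed scenarios
  jitter_fields <- c("photons_per_atp", "photons_per_nadph", "atp_per_co2_cbb",
                     "atp_per_oxygenation", "tonoplast_atp_per_malate",
                     "sugar_storage_atp", "po_ratio_nadh",
                     "maintenance_atp_light", "maintenance_atp_dark",
                     "maintenance_nadph_light", "maintenance_nadph_dark")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cfg_i <- cfg
      fac <- stats::runif(length(jitter_fields), 0.8, 1.2)
      for (k in seq_along(jitter_fields))
        cfg_i[[jitter_fields[k]]] <- cfg[[jitter_fields[k]]] * fac[k]
      cfg_i$seed <- seed
      model <- tryCatch(build_toy_leaf(cfg_i, check = TRUE),
                        error = function(e) e)
      if (!inherits(model, "error")) {
        out[[i]] <- model
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("variant ", i, " still infeasible after ", max_retry,
           " redraws; last parameter draw: ",
           paste(sprintf("%s=%.3g", jitter_fields,
                         unlist(cfg_i[jitter_fields])), collapse = ", "))
  }
  out
}
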