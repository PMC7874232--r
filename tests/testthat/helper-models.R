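# Hand-built miniature models with closed-form optima, used as independent
# oracles for the optimizer stack. All are diel only in form (everything in
# the light phase) -- the optimizer does not care.

mini_model <- function(mets, rxns, role_map = list(), id = "mini") {
  met_df <- data.frame(id = mets, name = mets, compartment = "c",
                       phase = "light", carbon = NA_real_,
                       stringsAsFactors = FALSE)
  rxn_df <- data.frame(id = names(rxns),
                       name = names(rxns), phase = "light",
                       lb = vapply(rxns, function(r) r$lb, 0),
                       ub = vapply(rxns, function(r) r$ub, 0),
                       stringsAsFactors = FALSE)
  stoich <- lapply(rxns, function(r) r$s)
  diel_model(met_df, rxn_df, stoich, role_map, id = id)
}

# photon -> ATP chain; exporting one unit of product costs 2 ATP,
# so the photon optimum is exactly 2 * demand
chain_model <- function(demand = 1, converter_ub = 1000) {
  mini_model(
    mets = c("PH", "ATP", "PREC", "P"),
    rxns = list(
      EX_PH = list(s = c(PH = 1), lb = 0, ub = 1000),
      CONV = list(s = c(PH = -1, ATP = 1), lb = 0, ub = 1000),
      MAKE = list(s = c(ATP = -2, PREC = 1), lb = 0, ub = converter_ub),
      FIN = list(s = c(PREC = -1, P = 1), lb = 0, ub = 1000),
      EXPORT = list(s = c(P = -1), lb = demand, ub = demand)),
    role_map = list(photon_uptake_light = "EX_PH"),
    id = "chain")
}

# two stoichiometrically identical routes carrying a fixed total demand
two_route_model <- function(demand = 1) {
  mini_model(
    mets = c("PH", "ATP", "P"),
    rxns = list(
      EX_PH = list(s = c(PH = 1), lb = 0, ub = 1000),
      CONV = list(s = c(PH = -1, ATP = 1), lb = 0, ub = 1000),
      ROUTE_A = list(s = c(ATP = -1, P = 1), lb = 0, ub = 1000),
      ROUTE_B = list(s = c(ATP = -1, P = 1), lb = 0, ub = 1000),
      EXPORT = list(s = c(P = -1), lb = demand, ub = demand)),
    role_map = list(photon_uptake_light = "EX_PH"),
    id = "two_route")
}

# chain model plus a closed 2-reaction futile loop disconnected from demand
futile_loop_model <- function(demand = 1) {
  m <- chain_model(demand)
  m$metabolites <- rbind(m$metabolites,
    data.frame(id = c("LA", "LB"), name = c("LA", "LB"), compartment = "c",
               phase = "light", carbon = NA_real_, stringsAsFactors = FALSE))
  m <- add_reaction(m, "LOOP_FWD", c(LA = -1, LB = 1), -1000, 1000)
  m <- add_reaction(m, "LOOP_BACK", c(LB = -1, LA = 1), -1000, 1000)
  m
}

# random small network (<= 12 reactions): several parallel energy routes with
# random photon costs feeding a fixed product demand; the photon optimum has
# the closed form demand * min(cost)
random_route_model <- function(seed) {
  set.seed(seed)
  k <- sample(2:5, 1)
  costs <- round(stats::runif(k, 0.5, 5), 3)
  demand <- round(stats::runif(1, 0.5, 2), 3)
  rxns <- list(
    EX_PH = list(s = c(PH = 1), lb = 0, ub = 1000),
    CONV = list(s = c(PH = -1, ATP = 1), lb = 0, ub = 1000))
  for (i in seq_len(k))
    rxns[[paste0("ROUTE_", i)]] <-
      list(s = stats::setNames(c(-costs[i], 1), c("ATP", "P")), lb = 0, ub = 1000)
  rxns$EXPORT <- list(s = c(P = -1), lb = demand, ub = demand)
  m <- mini_model(c("PH", "ATP", "P"), rxns,
                  role_map = list(photon_uptake_light = "EX_PH"),
                  id = paste0("random_", seed))
  attr(m, "closed_form_optimum") <- demand * min(costs)
  m
}

# a synthetic miniature with the reaction/species ids the core-model
# corrections look for (labelled synthetic: it stands in for a genome-scale
# diel leaf model that is not redistributable here)
synthetic_core_fragment <- function() {
  mets <- c("OXYGEN_MOLECULE_e1", "OXYGEN_MOLECULE_e2",
            "PROTON_v1", "PROTON_v2", "PROTON_c1", "PROTON_c2",
            "PROTON_e1", "PROTON_e2",
            "MANNOSE_p1", "MANNOSE_6P_c1", "ATP_c1")
  comp <- c("e", "e", "v", "v", "c", "c", "e", "e", "p", "c", "c")
  phase <- ifelse(endsWith(mets, "1"), "light", "dark")
  met_df <- data.frame(id = mets, name = mets, compartment = comp,
                       phase = phase, carbon = NA_real_,
                       stringsAsFactors = FALSE)
  rxns <- list(
    EX_O2_1 = list(s = c(OXYGEN_MOLECULE_e1 = 1), lb = -1000, ub = 1000),
    EX_O2_2 = list(s = c(OXYGEN_MOLECULE_e2 = 1), lb = -1000, ub = 1000),
    unlProtHYPO_c1 = list(s = c(PROTON_c1 = 1), lb = -1000, ub = 1000),
    unlProtHYPO_c2 = list(s = c(PROTON_c2 = 1), lb = -1000, ub = 1000),
    H_ic1 = list(s = c(PROTON_c1 = -1), lb = 0, ub = 1000),
    H_ic2 = list(s = c(PROTON_c2 = -1), lb = 0, ub = 1000),
    HEXOKINASE_RXN_MANNOSE_c1 = list(
      s = c(MANNOSE_p1 = -1, ATP_c1 = -1, MANNOSE_6P_c1 = 1), lb = 0, ub = 1000))
  rxn_df <- data.frame(id = names(rxns), name = names(rxns),
                       phase = ifelse(endsWith(names(rxns), "1"), "light", "dark"),
                       lb = vapply(rxns, function(r) r$lb, 0),
                       ub = vapply(rxns, function(r) r$ub, 0),
                       stringsAsFactors = FALSE)
  diel_model(met_df, rxn_df, lapply(rxns, function(r) r$s),
             role_map = list(o2_exchange_light = "EX_O2_1",
                             o2_exchange_dark = "EX_O2_2"),
             id = "synthetic_core_fragment")
}

# cached default toy model: building it is cheap but many tests want one
toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_leaf()
    cache
  }
})

scenario_solution <- local({
  cache <- list()
  # pFBA solution + constrained model for a canonical scenario, memoized
  function(name) {
    if (is.null(cache[[name]])) {
      ms <- apply_scenario(toy(), scenario_spec(name))
      cache[[name]] <<- list(model = ms, solution = pfba(ms))
    }
    cache[[name]]
  }
})
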