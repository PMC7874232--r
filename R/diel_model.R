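#' Semantic reaction roles of a diel leaf model
#'
#' The pipeline never addresses reactions by raw id: scenarios, the optimizer
#' and the reporting layer all go through a role map that names the reactions
#' with a defined physiological meaning (gas exchanges, RuBisCO isoforms per
#' phase, the diel storage transfers, maintenance drains, ...). A role may
#' resolve to several reaction ids (isozymes, compartments, phases).
#'
#' `required_roles()` lists the roles every usable model must carry;
#' `optional_roles()` lists roles that enrich reporting when present
#' (for example the vacuolar proton transfer, which genome-scale models
#' carry but the synthetic toy leaf deliberately omits).
#'
#' @return character vector of role names.
#' @export
required_roles <- function() {
  c("photon_uptake_light",
    "co2_exchange_light", "co2_exchange_dark",
    "o2_exchange_light", "o2_exchange_dark",
    "phloem_export",
    "rubisco_carboxylase_light", "rubisco_oxygenase_light",
    "rubisco_carboxylase_dark", "rubisco_oxygenase_dark",
    "pepc_light", "pepc_dark",
    "pepck", "malic_enzyme",
    "sdh_dark",
    "nadh_dehydrogenase_light", "nadh_dehydrogenase_dark",
    "atp_synthase_plastid_light",
    "atp_synthase_mito_light", "atp_synthase_mito_dark",
    "g6pdh_plastid_light", "g6pdh_plastid_dark",
    "g6pdh_cytosol_light", "g6pdh_cytosol_dark",
    "glycolysis_3pga_to_pep_light", "glycolysis_3pga_to_pep_dark",
    "starch_transfer", "malate_transfer",
    "maintenance_atp_light", "maintenance_atp_dark",
    "maintenance_nadph_light", "maintenance_nadph_dark")
}

#' @rdname required_roles
#' @export
optional_roles <- function() {
  c("proton_transfer", "light_reactions_nadph", "sdh_light",
    "sucrose_transfer", "fructan_transfer")
}

#' Two-phase (diel) stoichiometric model
#'
#' A diel model duplicates a leaf metabolic network into a light phase and a
#' dark phase; "transfer" reactions connect the two phases so a metabolite can
#' accumulate in one phase and be consumed in the other (starch by day, malate
#' by night). The container is deliberately plain: two data frames, a
#' stoichiometry list and the role map.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `phase` (one of `"light"`, `"dark"`, `"shared"`) and `carbon`
#'   (non-negative integer carbon count, `NA` when unknown).
#' @param reactions data.frame with columns `id`, `name`, `phase` (one of
#'   `"light"`, `"dark"`, `"transfer"`), `lb`, `ub` (flux bounds in
#'   umol m-2 s-1).
#' @param stoich named list, one entry per reaction id, each a named numeric
#'   vector of signed coefficients keyed by metabolite id.
#' @param role_map named list mapping role names to character vectors of
#'   reaction ids.
#' @param id model identifier string.
#'
#' @return object of class `diel_model`.
#' @export
diel_model <- function(metabolites, reactions, stoich, role_map = list(),
                       id = "diel_model") {
  m <- structure(list(id = id,
                      metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
                      reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
                      stoich = stoich, role_map = role_map),
                 class = "diel_model")
  validate_diel_model(m)
  m
}

#' Validate a diel model's internal consistency
#'
#' Checks id uniqueness, bound ordering, alignment of the stoichiometry list
#' with the reaction table, that every stoichiometric entry references an
#' existing metabolite, carbon counts are non-negative, and that every role in
#' the role map resolves to existing reaction ids.
#'
#' @param model a [diel_model()].
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_diel_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  needed_m <- c("id", "name", "compartment", "phase", "carbon")
  needed_r <- c("id", "name", "phase", "lb", "ub")
  if (!all(needed_m %in% names(met)))
    stop("metabolite table must have columns: ", paste(needed_m, collapse = ", "))
  if (!all(needed_r %in% names(rxn)))
    stop("reaction table must have columns: ", paste(needed_r, collapse = ", "))
  if (anyDuplicated(met$id)) stop("duplicate metabolite id: ",
                                  met$id[duplicated(met$id)][1])
  if (anyDuplicated(rxn$id)) stop("duplicate reaction id: ",
                                  rxn$id[duplicated(rxn$id)][1])
  if (any(rxn$lb > rxn$ub + 1e-12))
    stop("lower bound exceeds upper bound for reaction ",
         rxn$id[which(rxn$lb > rxn$ub + 1e-12)[1]])
  if (!setequal(names(model$stoich), rxn$id) ||
      length(model$stoich) != nrow(rxn))
    stop("stoichiometry list must have exactly one entry per reaction id")
  bad_carbon <- !is.na(met$carbon) & met$carbon < 0
  if (any(bad_carbon)) stop("negative carbon count for metabolite ",
                            met$id[bad_carbon][1])
  all_mets <- unlist(lapply(model$stoich, names), use.names = FALSE)
  unknown <- setdiff(unique(all_mets), met$id)
  if (length(unknown))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  for (role in names(model$role_map)) {
    miss <- setdiff(model$role_map[[role]], rxn$id)
    if (length(miss))
      stop("role '", role, "' maps to missing reaction id(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(model)
}

#' Assert that a model resolves all required roles
#' @param model a [diel_model()].
#' @param roles role names to require; defaults to [required_roles()].
#' @return the model, invisibly.
#' @export
assert_roles <- function(model, roles = required_roles()) {
  miss <- setdiff(roles, names(model$role_map))
  if (length(miss))
    stop("model is missing required role(s): ", paste(miss, collapse = ", "))
  invisible(model)
}

#' Look up the reaction ids carrying a semantic role
#' @param model a [diel_model()].
#' @param role role name.
#' @param strict error when the role is absent (default); otherwise return
#'   `character(0)`.
#' @return character vector of reaction ids.
#' @export
role_reactions <- function(model, role, strict = TRUE) {
  ids <- model$role_map[[role]]
  if (is.null(ids)) {
    if (strict) stop("unresolved role: ", role)
    return(character(0))
  }
  ids
}

#' Stoichiometric matrix of a diel model
#' @param model a [diel_model()].
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$stoich[[rxns[j]]]
    if (length(s)) S[names(s), j] <- s
  }
  S
}

#' @export
print.diel_model <- function(x, ...) {
  rp <- table(factor(x$reactions$phase, levels = c("light", "dark", "transfer")))
  cat("Diel stoichiometric model '", x$id, "'\n", sep = "")
  cat(sprintf("  %d metabolites, %d reactions (light %d, dark %d, transfer %d)\n",
              nrow(x$metabolites), nrow(x$reactions), rp[["light"]],
              rp[["dark"]], rp[["transfer"]]))
  req <- required_roles()
  cat(sprintf("  roles: %d mapped (%d of %d required present)\n",
              length(x$role_map), sum(req %in% names(x$role_map)), length(req)))
  invisible(x)
}

has_reaction <- function(model, id) id %in% model$reactions$id

#' Add a reaction to a diel model
#' @param model a [diel_model()].
#' @param id new reaction id (must not exist).
#' @param stoich named numeric vector of coefficients (metabolite ids).
#' @param lb,ub flux bounds.
#' @param name display name; defaults to the id.
#' @param phase `"light"`, `"dark"` or `"transfer"`; inferred from the phases
#'   of the participating metabolites when `NULL`.
#' @return the modified model.
#' @export
add_reaction <- function(model, id, stoich, lb, ub, name = id, phase = NULL) {
  if (has_reaction(model, id)) stop("reaction id already present: ", id)
  unknown <- setdiff(names(stoich), model$metabolites$id)
  if (length(unknown)) stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  if (is.null(phase)) {
    ph <- unique(model$metabolites$phase[match(names(stoich), model$metabolites$id)])
    ph <- setdiff(ph, "shared")
    phase <- if (length(ph) == 1L) ph else "transfer"
  }
  model$reactions <- rbind(model$reactions,
    data.frame(id = id, name = name, phase = phase, lb = lb, ub = ub,
               stringsAsFactors = FALSE))
  model$stoich[[id]] <- stoich
  model
}

#' Remove reactions from a diel model
#' @param model a [diel_model()].
#' @param ids reaction ids to drop; ids not present are ignored.
#' @return the modified model (role map entries are pruned accordingly).
#' @export
remove_reactions <- function(model, ids) {
  keep <- !model$reactions$id %in% ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoich <- model$stoich[model$reactions$id]
  model$role_map <- lapply(model$role_map, setdiff, y = ids)
  model$role_map <- model$role_map[vapply(model$role_map, length, 1L) > 0]
  model
}

#' Set flux bounds on one or more reactions
#' @param model a [diel_model()].
#' @param ids reaction ids.
#' @param lb,ub new bounds, recycled across `ids`; `NA` leaves a bound as-is.
#' @param strict error when an id is absent (default); otherwise skip it.
#' @return the modified model.
#' @export
set_bounds <- function(model, ids, lb = NA, ub = NA, strict = TRUE) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    if (strict) stop("unknown reaction id(s): ",
                     paste(ids[is.na(idx)], collapse = ", "))
    ids <- ids[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  sel <- !is.na(lb); model$reactions$lb[idx[sel]] <- lb[sel]
  sel <- !is.na(ub); model$reactions$ub[idx[sel]] <- ub[sel]
  if (any(model$reactions$lb[idx] > model$reactions$ub[idx] + 1e-12))
    stop("infeasible bound combination (lower > upper) on ",
         paste(ids[model$reactions$lb[idx] > model$reactions$ub[idx] + 1e-12],
               collapse = ", "))
  model
}

reaction_bounds <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", id)
  c(lb = model$reactions$lb[i], ub = model$reactions$ub[i])
}

# carbon imbalance of each reaction: sum(coef * carbon_count). Internal
# reactions balance to 0; boundary reactions (exchanges, phloem) show the
# signed carbon flow across the system boundary per unit flux. NA when a
# participating metabolite has no carbon annotation.
reaction_carbon_imbalance <- function(model) {
  carbon <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  vapply(model$reactions$id, function(rid) {
    s <- model$stoich[[rid]]
    if (!length(s)) return(0)
    sum(s * carbon[names(s)])
  }, numeric(1))
}
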