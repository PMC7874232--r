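#' Energetics and accumulation summary of a flux solution
#'
#' Reduces a flux solution to the standard reporting quantities: photon
#' demand, ATP/NADPH production by the photosynthetic light reactions,
#' mitochondrial ATP production per phase, diel starch and malate
#' accumulation, and the pathway aggregates used for the continuum figures
#' (glycolysis read as the 3-PGA to PEP flux, TCA cycle as succinate
#' dehydrogenase, mitochondrial ETC as NADH dehydrogenase, OPPP as the sum of
#' plastidial and cytosolic G6P dehydrogenases, Calvin-Benson as RuBisCO
#' carboxylase).
#'
#' Sign convention: a diel-transfer flux is positive when carrying
#' light-to-dark, i.e. positive accumulation means net build-up during the
#' light period. Negative malate accumulation therefore reads as nocturnal
#' malate storage, the CAM signature.
#'
#' ATP production is reported as reaction flux times the stoichiometric
#' coefficient of the ATP species produced by the role reaction (detected by
#' metabolite id; falls back to the raw flux when no ATP species is
#' identifiable, which is correct for synthases producing one ATP per unit
#' flux).
#'
#' @param solution an optimal `flux_solution`.
#' @param model the [diel_model()] it was solved on.
#' @return one-row data.frame of class `energetics_summary`, all fields in
#'   umol m-2 s-1.
#' @export
energetics_summary <- function(solution, model) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal")
    stop("energetics summary requires an optimal solution (status: ",
         solution$status, ")")
  v <- solution$fluxes
  flux_of <- function(role, phase = NULL) {
    ids <- role_reactions(model, role)
    if (!is.null(phase)) {
      ph <- model$reactions$phase[match(ids, model$reactions$id)]
      ids <- ids[ph == phase]
    }
    sum(v[ids])
  }
  atp_production <- function(role) {
    ids <- role_reactions(model, role)
    sum(vapply(ids, function(id) {
      s <- model$stoich[[id]]
      atp <- s[grepl("^ATP([_0-9]|$)", names(s), ignore.case = TRUE) & s > 0]
      coefficient <- if (length(atp)) max(atp) else 1
      v[[id]] * coefficient
    }, numeric(1)))
  }
  out <- data.frame(
    photon_demand = flux_of("photon_uptake_light"),
    atp_light_reactions = atp_production("atp_synthase_plastid_light"),
    nadph_light_reactions = if ("light_reactions_nadph" %in% names(model$role_map))
      flux_of("light_reactions_nadph") else NA_real_,
    atp_mito_light = atp_production("atp_synthase_mito_light"),
    atp_mito_dark = atp_production("atp_synthase_mito_dark"),
    atp_plastid_synthase_light = flux_of("atp_synthase_plastid_light"),
    starch_accumulation = flux_of("starch_transfer"),
    malate_accumulation = flux_of("malate_transfer"),
    glycolysis_dark = max(flux_of("glycolysis_3pga_to_pep_dark"), 0),
    gluconeogenesis_light = max(-flux_of("glycolysis_3pga_to_pep_light"), 0),
    pepc_dark = flux_of("pepc_dark"),
    malate_decarboxylation_light = flux_of("pepck", phase = "light") +
      flux_of("malic_enzyme", phase = "light"),
    tca_dark = flux_of("sdh_dark"),
    mito_etc_dark = flux_of("nadh_dehydrogenase_dark"),
    oppp_dark = flux_of("g6pdh_plastid_dark") + flux_of("g6pdh_cytosol_dark"),
    rubisco_carb_light = flux_of("rubisco_carboxylase_light"),
    rubisco_oxy_light = flux_of("rubisco_oxygenase_light"),
    stringsAsFactors = FALSE)
  # clamp solver noise in the report (raw fluxes stay untouched)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) ifelse(!is.na(x) & abs(x) < 1e-7, 0, x))
  class(out) <- c("energetics_summary", "data.frame")
  out
}

#' Share of light-period ATP synthesis carried by the mitochondrion
#'
#' @param atp_mito_light mitochondrial ATP synthesis in the light
#'   (umol m-2 s-1).
#' @param atp_plastid_light plastidial ATP synthesis in the light.
#' @return percentage, `100 * mito / (mito + plastid)`.
#' @examples
#' mito_atp_share(37.86, 68.59) # 35.6
#' @export
mito_atp_share <- function(atp_mito_light, atp_plastid_light) {
  if (atp_mito_light < 0 || atp_plastid_light < 0)
    stop("ATP synthesis rates must be non-negative")
  total <- atp_mito_light + atp_plastid_light
  if (total == 0) stop("both ATP synthesis rates are zero")
  100 * atp_mito_light / total
}

#' Relative change in percent
#' @param reference baseline value (non-zero).
#' @param value new value.
#' @return `100 * (value - reference) / reference`.
#' @examples
#' percent_change(199.40, 209.04) # +4.8
#' @export
percent_change <- function(reference, value) {
  if (reference == 0) stop("reference must be non-zero")
  100 * (value - reference) / reference
}

#' Carbon bookkeeping of a flux solution
#'
#' Audits carbon conservation: the net carbon crossing the system boundary in
#' each phase (computed from the per-reaction carbon imbalance, so it needs
#' no role annotations) and the carbon carried light-to-dark by each diel
#' transfer reaction. In a fully closed system (CAM idling) the net external
#' carbon is zero and the light-period starch carbon equals the dark-period
#' malate carbon.
#'
#' @param solution an optimal `flux_solution`.
#' @param model the [diel_model()], with carbon counts for every metabolite
#'   that crosses the boundary or a phase transfer.
#' @return list with `net_external_light`, `net_external_dark`,
#'   `net_external_total` (umol C m-2 s-1; positive = import) and
#'   `transfer_carbon`, a data.frame of the carbon flux (light to dark
#'   positive) of each transfer reaction.
#' @export
carbon_closure <- function(solution, model) {
  stopifnot(inherits(solution, "flux_solution"))
  if (solution$status != "optimal")
    stop("carbon closure requires an optimal solution")
  v <- solution$fluxes
  imb <- reaction_carbon_imbalance(model)
  boundary <- !is.na(imb) & abs(imb) > 1e-9
  if (anyNA(imb[abs(v[names(imb)]) > 1e-9]))
    stop("carbon count missing for metabolites of an active reaction")
  phase <- model$reactions$phase
  # a reaction creating carbon from nothing (positive imbalance) imports it
  net <- function(ph) sum(imb[boundary & phase == ph] * v[names(imb)[boundary & phase == ph]])
  transfers <- model$reactions$id[phase == "transfer"]
  carbon <- stats::setNames(model$metabolites$carbon, model$metabolites$id)
  tc <- vapply(transfers, function(rid) {
    s <- model$stoich[[rid]]
    prod <- s[s > 0]
    if (anyNA(carbon[names(prod)])) return(NA_real_)
    sum(prod * carbon[names(prod)]) * v[[rid]]
  }, numeric(1))
  list(net_external_light = net("light"),
       net_external_dark = net("dark"),
       net_external_total = net("light") + net("dark"),
       transfer_carbon = data.frame(reaction_id = transfers,
                                    carbon_flux = unname(tc),
                                    stringsAsFactors = FALSE))
}

#' Side-by-side energetics table for several scenarios
#'
#' @param solutions named list of optimal `flux_solution` objects (names
#'   become the column labels).
#' @param model the [diel_model()] the solutions were computed on, or a list
#'   of models parallel to `solutions` (scenario application modifies the
#'   model, so pass the constrained models).
#' @return data.frame, rows = summary quantities, columns = scenario labels.
#' @export
energetics_table <- function(solutions, model) {
  stopifnot(length(solutions) >= 1, !is.null(names(solutions)))
  models <- if (inherits(model, "diel_model"))
    rep(list(model), length(solutions)) else model
  cols <- lapply(seq_along(solutions), function(i) {
    s <- energetics_summary(solutions[[i]], models[[i]])
    stats::setNames(as.numeric(s[1, ]), names(s))
  })
  out <- as.data.frame(cols, col.names = names(solutions))
  rownames(out) <- names(cols[[1]])
  out
}
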