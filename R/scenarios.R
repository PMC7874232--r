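#' Constraint scenario for a photosynthetic mode
#'
#' Encodes one column of the canonical constraint table for the four
#' photosynthetic modes. Gas-exchange entries are either `"unconstrained"`
#' (encoded as +/- 1000 umol m-2 s-1) or a fixed value (closed stomata = 0).
#' The carboxylase:oxygenase ratio `r` is enforced per phase as the linear
#' coupling `v_carb - r * v_oxy = 0`.
#'
#' Canonical columns:
#' \describe{
#'   \item{C3}{phloem 0.259; all exchanges unconstrained; ratios 3:1 / 3:1.}
#'   \item{CAM}{phloem 0.259; light CO2 and O2 closed; dark unconstrained;
#'     ratios 5.15:1 light, 3:1 dark.}
#'   \item{CAM_cycling}{phloem 0.259; light unconstrained; dark CO2 and O2
#'     closed; ratios 3:1 light, 5.15:1 dark.}
#'   \item{CAM_idling}{phloem 0; all exchanges closed; ratios 5.15:1 / 5.15:1.}
#' }
#'
#' @param name one of `"C3"`, `"CAM"`, `"CAM_cycling"`, `"CAM_idling"`,
#'   `"custom"`.
#' @param phloem_export phloem export rate (umol m-2 s-1); overrides the
#'   canonical value when given.
#' @param co2_light,co2_dark,o2_light,o2_dark `"unconstrained"` or a fixed
#'   non-negative numeric magnitude (0 closes the exchange).
#' @param ratio_light,ratio_dark carboxylase:oxygenase ratio (> 0).
#' @param decarb_route `"any"`, `"PEPCK_only"` or `"ME_only"`.
#' @param storage `"any"`, `"starch_only"`, `"sucrose_only"` or
#'   `"fructan_only"`.
#' @param maintenance optional list with entries `atp_light`, `atp_dark`,
#'   `nadph_light`, `nadph_dark`; when `NULL` the model's preset maintenance
#'   bounds are kept.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("C3", "CAM", "CAM_cycling", "CAM_idling",
                                   "custom"),
                          phloem_export = NULL,
                          co2_light = NULL, co2_dark = NULL,
                          o2_light = NULL, o2_dark = NULL,
                          ratio_light = NULL, ratio_dark = NULL,
                          decarb_route = "any", storage = "any",
                          maintenance = NULL) {
  if (!is.character(name) || !name[1] %in%
        c("C3", "CAM", "CAM_cycling", "CAM_idling", "custom"))
    stop("unknown scenario name: ", name[1],
         " (expected C3, CAM, CAM_cycling, CAM_idling or custom)")
  name <- name[1]
  defaults <- switch(name,
    C3 = list(phloem = 0.259, co2l = "unconstrained", co2d = "unconstrained",
              o2l = "unconstrained", o2d = "unconstrained", rl = 3, rd = 3),
    CAM = list(phloem = 0.259, co2l = 0, co2d = "unconstrained",
               o2l = 0, o2d = "unconstrained", rl = 5.15, rd = 3),
    CAM_cycling = list(phloem = 0.259, co2l = "unconstrained", co2d = 0,
                       o2l = "unconstrained", o2d = 0, rl = 3, rd = 5.15),
    CAM_idling = list(phloem = 0, co2l = 0, co2d = 0, o2l = 0, o2d = 0,
                      rl = 5.15, rd = 5.15),
    custom = list(phloem = 0.259, co2l = "unconstrained", co2d = "unconstrained",
                  o2l = "unconstrained", o2d = "unconstrained", rl = 3, rd = 3))
  spec <- list(name = name,
               phloem_export = if (is.null(phloem_export)) defaults$phloem else phloem_export,
               co2_light = if (is.null(co2_light)) defaults$co2l else co2_light,
               co2_dark = if (is.null(co2_dark)) defaults$co2d else co2_dark,
               o2_light = if (is.null(o2_light)) defaults$o2l else o2_light,
               o2_dark = if (is.null(o2_dark)) defaults$o2d else o2_dark,
               ratio_light = if (is.null(ratio_light)) defaults$rl else ratio_light,
               ratio_dark = if (is.null(ratio_dark)) defaults$rd else ratio_dark,
               decarb_route = match.arg(decarb_route,
                                        c("any", "PEPCK_only", "ME_only")),
               storage = match.arg(storage, c("any", "starch_only",
                                              "sucrose_only", "fructan_only")),
               maintenance = maintenance)
  if (spec$phloem_export < 0) stop("phloem_export must be >= 0")
  if (spec$ratio_light <= 0 || spec$ratio_dark <= 0)
    stop("carboxylase:oxygenase ratios must be > 0")
  for (f in c("co2_light", "co2_dark", "o2_light", "o2_dark")) {
    v <- spec[[f]]
    if (!(identical(v, "unconstrained") || (is.numeric(v) && v >= 0)))
      stop(f, " must be \"unconstrained\" or a non-negative magnitude")
  }
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  fmt <- function(v) if (identical(v, "unconstrained")) v else sprintf("%g", v)
  cat("Scenario '", x$name, "'\n", sep = "")
  cat(sprintf("  phloem export: %g umol m-2 s-1\n", x$phloem_export))
  cat(sprintf("  CO2 exchange light/dark: %s / %s\n",
              fmt(x$co2_light), fmt(x$co2_dark)))
  cat(sprintf("  O2 exchange light/dark:  %s / %s\n",
              fmt(x$o2_light), fmt(x$o2_dark)))
  cat(sprintf("  carboxylase:oxygenase ratio light/dark: %g / %g\n",
              x$ratio_light, x$ratio_dark))
  if (x$decarb_route != "any")
    cat("  decarboxylation route:", x$decarb_route, "\n")
  if (x$storage != "any") cat("  storage:", x$storage, "\n")
  invisible(x)
}

ratio_pseudo_ids <- c(light = "RATIO_COUPLING_light", dark = "RATIO_COUPLING_dark")

# drop any previously installed ratio-coupling pseudo-species so that
# applying a scenario is idempotent and scenarios can be swapped
strip_ratio_coupling <- function(model) {
  ids <- intersect(ratio_pseudo_ids, model$metabolites$id)
  if (!length(ids)) return(model)
  model$metabolites <- model$metabolites[!model$metabolites$id %in% ids, , drop = FALSE]
  model$stoich <- lapply(model$stoich, function(s) s[!names(s) %in% ids])
  model
}

# install v_carb - r * v_oxy = 0 as a balanced pseudo-species row:
# each carboxylase reaction produces 1 unit, each oxygenase consumes r units.
add_ratio_coupling <- function(model, phase, r) {
  pid <- ratio_pseudo_ids[[phase]]
  carb <- role_reactions(model, paste0("rubisco_carboxylase_", phase))
  oxy <- role_reactions(model, paste0("rubisco_oxygenase_", phase))
  model$metabolites <- rbind(model$metabolites,
    data.frame(id = pid, name = paste("RuBisCO ratio coupling,", phase),
               compartment = "constraint", phase = "shared", carbon = 0,
               stringsAsFactors = FALSE))
  for (id in carb) model$stoich[[id]][pid] <- 1
  for (id in oxy) model$stoich[[id]][pid] <- -r
  model
}

apply_exchange_bound <- function(model, role, value) {
  ids <- role_reactions(model, role)
  if (identical(value, "unconstrained"))
    set_bounds(model, ids, lb = -1000, ub = 1000)
  else
    set_bounds(model, ids, lb = -abs(value), ub = abs(value))
}

#' Apply a constraint scenario to a diel model
#'
#' Bound changes: phloem export is fixed as an equality (split across the
#' per-phase export reactions by `phloem_split`); closed gas exchanges get
#' bounds (0, 0) and unconstrained ones (-1000, 1000); optional maintenance
#' drains are fixed; route/storage restrictions zero the excluded
#' decarboxylation or storage-transfer reactions. The per-phase
#' carboxylase:oxygenase coupling is installed as a balanced pseudo-species
#' row, so the constrained model remains a pure `S v = 0` system. The ratio
#' row is installed in both phases even where RuBisCO is expected to carry no
#' flux (the constraint is then vacuously satisfied at 0). Applying a
#' scenario twice equals applying it once.
#'
#' @param model a [diel_model()] resolving the constrained roles.
#' @param spec a [scenario_spec()].
#' @param phloem_split fraction of the phloem export assigned to each phase;
#'   must sum to 1. The default 3:1 light:dark split follows the diel leaf
#'   modeling convention. Ignored when the model has a single export
#'   reaction.
#' @return the constrained model.
#' @export
apply_scenario <- function(model, spec, phloem_split = c(light = 0.75, dark = 0.25)) {
  stopifnot(inherits(model, "diel_model"), inherits(spec, "scenario_spec"))
  if (abs(sum(phloem_split) - 1) > 1e-9) stop("phloem_split must sum to 1")

  phl <- role_reactions(model, "phloem_export")
  if (length(phl) == 1L) {
    model <- set_bounds(model, phl, lb = spec$phloem_export, ub = spec$phloem_export)
  } else {
    phase <- model$reactions$phase[match(phl, model$reactions$id)]
    for (k in seq_along(phl)) {
      share <- spec$phloem_export *
        switch(phase[k], light = phloem_split[["light"]],
               dark = phloem_split[["dark"]], 1 / length(phl))
      model <- set_bounds(model, phl[k], lb = share, ub = share)
    }
  }

  model <- apply_exchange_bound(model, "co2_exchange_light", spec$co2_light)
  model <- apply_exchange_bound(model, "co2_exchange_dark", spec$co2_dark)
  model <- apply_exchange_bound(model, "o2_exchange_light", spec$o2_light)
  model <- apply_exchange_bound(model, "o2_exchange_dark", spec$o2_dark)

  model <- strip_ratio_coupling(model)
  model <- add_ratio_coupling(model, "light", spec$ratio_light)
  model <- add_ratio_coupling(model, "dark", spec$ratio_dark)

  if (!is.null(spec$maintenance)) {
    mt <- spec$maintenance
    pairs <- list(atp_light = "maintenance_atp_light",
                  atp_dark = "maintenance_atp_dark",
                  nadph_light = "maintenance_nadph_light",
                  nadph_dark = "maintenance_nadph_dark")
    for (f in names(pairs)) {
      if (!is.null(mt[[f]]))
        model <- set_bounds(model, role_reactions(model, pairs[[f]]),
                            lb = mt[[f]], ub = mt[[f]])
    }
  }

  model <- restrict_decarboxylation(model, spec$decarb_route)
  model <- restrict_storage(model, spec$storage)
  validate_diel_model(model)
  model$scenario <- spec$name
  model
}

#' Restrict the daytime malate decarboxylation route
#'
#' `PEPCK_only` zeroes all malic-enzyme reactions; `ME_only` zeroes all PEP
#' carboxykinase reactions (both phases); `any` leaves the model unchanged.
#'
#' @param model a [diel_model()].
#' @param route `"any"`, `"PEPCK_only"` or `"ME_only"`.
#' @return the modified model.
#' @export
restrict_decarboxylation <- function(model, route = c("any", "PEPCK_only", "ME_only")) {
  route <- match.arg(route)
  if (route == "any") return(model)
  blocked <- switch(route, PEPCK_only = "malic_enzyme", ME_only = "pepck")
  set_bounds(model, role_reactions(model, blocked), lb = 0, ub = 0)
}

#' Restrict the diel carbohydrate storage compound
#'
#' Forces a sole storage compound by closing the diel transfer reactions of
#' the excluded compounds (a storage pool that cannot cross the phase
#' boundary cannot act as diel storage). Transfers whose role is absent from
#' the model are skipped.
#'
#' @param model a [diel_model()].
#' @param storage `"any"`, `"starch_only"`, `"sucrose_only"` or
#'   `"fructan_only"`.
#' @return the modified model.
#' @export
restrict_storage <- function(model, storage = c("any", "starch_only",
                                                "sucrose_only", "fructan_only")) {
  storage <- match.arg(storage)
  if (storage == "any") return(model)
  all_roles <- c(starch_only = "starch_transfer",
                 sucrose_only = "sucrose_transfer",
                 fructan_only = "fructan_transfer")
  excluded <- setdiff(all_roles, all_roles[[storage]])
  for (role in excluded) {
    ids <- role_reactions(model, role, strict = FALSE)
    if (length(ids)) model <- set_bounds(model, ids, lb = 0, ub = 0)
  }
  model
}
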