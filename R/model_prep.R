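#' Core-model corrections for diel gas and proton accounting
#'
#' Genome-scale diel leaf models need a handful of structural corrections
#' before the four photosynthetic-mode scenarios are all solvable: oxygen
#' from daytime water splitting must be storable across the phase boundary
#' (otherwise closing the light-period O2 exchange is infeasible), vacuolar
#' acidification is modeled by letting protons accumulate in the vacuole
#' rather than by fixing a vacuolar pH, free proton exchange with the cytosol
#' is blocked so that pH homeostasis is meaningful, proton transport into the
#' mitochondrial intermembrane space is made reversible, explicit
#' down-gradient proton leaks are added, and a known compartmentation error
#' in the cytosolic mannose hexokinase reaction is corrected.
#'
#' Each correction is idempotent. When called directly, an op whose required
#' species are absent errors (`strict = TRUE`); [apply_core_modifications()]
#' runs them with `strict = FALSE` so the same code path serves both
#' genome-scale inputs and the synthetic toy leaf, recording skips in the
#' report.
#'
#' @name model_prep
NULL

# species of a single-metabolite exchange reaction carrying `role`
exchange_species <- function(model, role, strict) {
  ids <- role_reactions(model, role, strict = strict)
  if (!length(ids)) return(NA_character_)
  s <- model$stoich[[ids[1]]]
  names(s)[which.max(abs(s))]
}

# does any transfer reaction already move `sp_light` to `sp_dark`?
find_transfer <- function(model, sp_light, sp_dark) {
  tr <- model$reactions$id[model$reactions$phase == "transfer"]
  hit <- vapply(tr, function(rid) {
    s <- model$stoich[[rid]]
    all(c(sp_light, sp_dark) %in% names(s)) &&
      s[[sp_light]] * s[[sp_dark]] < 0
  }, TRUE)
  tr[hit]
}

#' @rdname model_prep
#' @param model a [diel_model()].
#' @param strict error when required species are absent (default); otherwise
#'   skip with a note.
#' @return the modified model, with a `prep_note` attribute describing what
#'   happened (`"applied"`, `"skipped_already_present"` or a skip reason).
#' @export
add_oxygen_diel_transfer <- function(model, strict = TRUE) {
  o2l <- exchange_species(model, "o2_exchange_light", strict)
  o2d <- exchange_species(model, "o2_exchange_dark", strict)
  if (is.na(o2l) || is.na(o2d)) {
    if (strict) stop("cannot locate the extracellular O2 species in both phases")
    attr(model, "prep_note") <- "skipped: O2 exchange roles unresolved"
    return(model)
  }
  existing <- find_transfer(model, o2l, o2d)
  if (length(existing)) {
    attr(model, "prep_note") <- "skipped_already_present"
    return(model)
  }
  model <- add_reaction(model, "OXYGEN_MOLECULE_e_dielTransfer",
                        stats::setNames(c(-1, 1), c(o2l, o2d)),
                        lb = -1000, ub = 1000,
                        name = "oxygen diel transfer", phase = "transfer")
  attr(model, "prep_note") <- "applied"
  model
}

#' @rdname model_prep
#' @param proton_vacuole_stem id stem of the vacuolar proton species (the
#'   phase suffixes are appended).
#' @export
enable_vacuolar_proton_accumulation <- function(model, strict = TRUE,
                                                proton_vacuole_stem = "PROTON_v") {
  spl <- paste0(proton_vacuole_stem, "1")
  spd <- paste0(proton_vacuole_stem, "2")
  if (!all(c(spl, spd) %in% model$metabolites$id)) {
    if (strict) stop("vacuolar proton species not found in both phases (",
                     spl, ", ", spd, ")")
    attr(model, "prep_note") <- "skipped: no vacuolar proton species"
    return(model)
  }
  rid <- paste0(proton_vacuole_stem, "_dielTransfer")
  if (has_reaction(model, rid)) {
    model <- set_bounds(model, rid, lb = -1000, ub = 1000)
    attr(model, "prep_note") <- "skipped_already_present"
    return(model)
  }
  model <- add_reaction(model, rid, stats::setNames(c(-1, 1), c(spl, spd)),
                        lb = -1000, ub = 1000,
                        name = "vacuolar proton accumulation", phase = "transfer")
  attr(model, "prep_note") <- "applied"
  model
}

#' @rdname model_prep
#' @export
block_free_proton_flow <- function(model) {
  ids <- c("unlProtHYPO_c1", "unlProtHYPO_c2")
  present <- ids[ids %in% model$reactions$id]
  if (length(present)) model <- set_bounds(model, present, lb = 0, ub = 0)
  attr(model, "prep_note") <- if (length(present))
    paste("applied to", paste(present, collapse = ", ")) else
      "skipped: unlProtHYPO reactions absent"
  model
}

#' @rdname model_prep
#' @export
set_ims_proton_transport_reversible <- function(model) {
  ids <- c("H_ic1", "H_ic2")
  present <- ids[ids %in% model$reactions$id]
  if (length(present)) model <- set_bounds(model, present, lb = -1000)
  attr(model, "prep_note") <- if (length(present))
    paste("applied to", paste(present, collapse = ", ")) else
      "skipped: H_ic reactions absent"
  model
}

#' @rdname model_prep
#' @export
add_proton_leaks <- function(model, strict = TRUE) {
  leaks <- list(H_vc1 = c("PROTON_v1", "PROTON_c1"),
                H_vc2 = c("PROTON_v2", "PROTON_c2"),
                H_ec1 = c("PROTON_e1", "PROTON_c1"),
                H_ec2 = c("PROTON_e2", "PROTON_c2"))
  added <- character(0); skipped <- character(0)
  for (rid in names(leaks)) {
    from <- leaks[[rid]][1]; to <- leaks[[rid]][2]
    if (has_reaction(model, rid)) { skipped <- c(skipped, rid); next }
    if (!all(c(from, to) %in% model$metabolites$id)) {
      if (strict) stop("proton species missing for leak ", rid,
                       " (", from, " -> ", to, ")")
      skipped <- c(skipped, rid)
      next
    }
    model <- add_reaction(model, rid, stats::setNames(c(-1, 1), c(from, to)),
                          lb = 0, ub = 1000,
                          name = paste("proton leak", from, "->", to))
    added <- c(added, rid)
  }
  attr(model, "prep_note") <- if (length(added))
    paste("added", paste(added, collapse = ", ")) else
      "skipped: no leak added"
  model
}

#' @rdname model_prep
#' @export
fix_mannose_hexokinase_compartment <- function(model) {
  targets <- model$reactions$id[startsWith(model$reactions$id,
                                           "HEXOKINASE_RXN_MANNOSE_c")]
  if (!length(targets)) {
    attr(model, "prep_note") <- "skipped: reaction absent"
    return(model)
  }
  remapped <- character(0)
  for (rid in targets) {
    s <- model$stoich[[rid]]
    comp <- model$metabolites$compartment[match(names(s), model$metabolites$id)]
    wrong <- names(s)[comp != "c"]
    for (sp in wrong) {
      # derive the cytosolic counterpart id: swap the compartment tag
      cyt <- sub("_[a-z]([12])$", "_c\\1", sp)
      if (identical(cyt, sp)) next
      if (!cyt %in% model$metabolites$id) {
        row <- model$metabolites[model$metabolites$id == sp, , drop = FALSE]
        row$id <- cyt; row$compartment <- "c"
        model$metabolites <- rbind(model$metabolites, row)
      }
      coefficient <- s[[sp]]
      s <- s[names(s) != sp]
      s[cyt] <- coefficient + (if (cyt %in% names(s)) s[[cyt]] else 0)
      remapped <- c(remapped, sp)
    }
    model$stoich[[rid]] <- s
  }
  attr(model, "prep_note") <- if (length(remapped))
    paste("remapped", paste(remapped, collapse = ", "), "to cytosol") else
      "skipped: already cytosolic"
  model
}

#' Apply all core-model corrections in order
#'
#' Runs the six corrections of [model_prep] in their canonical, fixed order
#' with `strict = FALSE`, collecting a report. Applying the bundle twice
#' leaves the model unchanged.
#'
#' @param model a [diel_model()].
#' @return list with `model` (corrected) and `report` (a
#'   `modification_report`: per-correction status plus `applied` /
#'   `skipped` name vectors).
#' @export
apply_core_modifications <- function(model) {
  steps <- list(
    oxygen_diel_transfer = function(m) add_oxygen_diel_transfer(m, strict = FALSE),
    vacuolar_proton_accumulation = function(m)
      enable_vacuolar_proton_accumulation(m, strict = FALSE),
    block_free_proton_flow = block_free_proton_flow,
    ims_proton_transport_reversible = set_ims_proton_transport_reversible,
    proton_leaks = function(m) add_proton_leaks(m, strict = FALSE),
    mannose_hexokinase_compartment = fix_mannose_hexokinase_compartment)
  notes <- character(length(steps))
  names(notes) <- names(steps)
  for (nm in names(steps)) {
    model <- steps[[nm]](model)
    notes[nm] <- attr(model, "prep_note") %||% "applied"
    attr(model, "prep_note") <- NULL
  }
  applied <- names(notes)[startsWith(notes, "applied") | startsWith(notes, "added") |
                            startsWith(notes, "remapped")]
  report <- structure(list(applied = applied,
                           skipped = setdiff(names(notes), applied),
                           notes = as.list(notes)),
                      class = "modification_report")
  validate_diel_model(model)
  list(model = model, report = report)
}

#' @export
print.modification_report <- function(x, ...) {
  cat("Core-model corrections\n")
  for (nm in names(x$notes))
    cat(sprintf("  %-34s %s\n", nm, x$notes[[nm]]))
  invisible(x)
}

#' @rdname apply_core_modifications
#' @param report a `modification_report`.
#' @param path output JSON file.
#' @export
write_modification_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
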