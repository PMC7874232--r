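#' Role-map configuration
#'
#' A role configuration names the reactions carrying each semantic role (see
#' [required_roles()]) and states the diel id-suffix convention. Stored as
#' YAML with top-level keys `light_suffix`, `dark_suffix`, `transfer_tag` and
#' `roles` (role name -> reaction id or list of ids).
#'
#' The suffix convention defaults to `"1"` = light and `"2"` = dark (matching
#' paired ids like `H_ic1` / `H_ic2`); it is configurable because the diel
#' convention does not itself state which index is light, and
#' [read_diel_sbml()] validates the choice against the phase of the
#' photon-uptake reaction.
#'
#' @param roles named list mapping role names to reaction id vectors.
#' @param light_suffix,dark_suffix id suffixes marking the two phases.
#' @param transfer_tag substring marking diel transfer reactions.
#' @return object of class `role_config`.
#' @export
role_config <- function(roles, light_suffix = "1", dark_suffix = "2",
                        transfer_tag = "dielTransfer") {
  stopifnot(is.list(roles), length(names(roles)) == length(roles))
  structure(list(roles = lapply(roles, as.character),
                 light_suffix = light_suffix, dark_suffix = dark_suffix,
                 transfer_tag = transfer_tag),
            class = "role_config")
}

#' @rdname role_config
#' @param path YAML file path.
#' @export
read_role_config <- function(path) {
  y <- yaml::read_yaml(path)
  role_config(y$roles,
              light_suffix = y$light_suffix %||% "1",
              dark_suffix = y$dark_suffix %||% "2",
              transfer_tag = y$transfer_tag %||% "dielTransfer")
}

#' @rdname role_config
#' @param cfg a `role_config` to serialize.
#' @export
write_role_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "role_config"))
  yaml::write_yaml(list(light_suffix = cfg$light_suffix,
                        dark_suffix = cfg$dark_suffix,
                        transfer_tag = cfg$transfer_tag,
                        roles = cfg$roles), path)
  invisible(path)
}

#' Extract a model's role map as a role configuration
#' @param model a [diel_model()].
#' @inheritParams role_config
#' @return a `role_config`.
#' @export
as_role_config <- function(model, light_suffix = "1", dark_suffix = "2") {
  role_config(model$role_map, light_suffix = light_suffix,
              dark_suffix = dark_suffix)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_phase_from_id <- function(ids, light_suffix, dark_suffix) {
  phase <- rep("shared", length(ids))
  phase[endsWith(ids, dark_suffix)] <- "dark"
  phase[endsWith(ids, light_suffix)] <- "light"
  phase
}

# namespaced attributes arrive as "fbc:lowerFluxBound" or plain; take either
attr_any <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(names(a) == name | endsWith(names(a), paste0(":", name)))
  if (length(hit)) a[[hit[1]]] else NA_character_
}

local_find <- function(node, tag)
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", tag))

carbon_from_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  m <- regmatches(formula, regexec("C([0-9]*)([A-Z]|$)", formula))[[1]]
  if (!length(m)) return(NA_real_)
  if (m[2] == "") 1 else as.numeric(m[2])
}

#' Read a diel stoichiometric model from SBML
#'
#' Accepts SBML Level 3 with FBC flux bounds (bound parameters referenced per
#' reaction) as well as the older Level 2 convention of `LOWER_BOUND` /
#' `UPPER_BOUND` kinetic-law parameters. Infinite bounds are clamped to
#' +/- 1000 umol m-2 s-1 so all LP solvers see finite boxes. Metabolite
#' carbon counts are taken from FBC chemical formulas when present.
#'
#' Phases are inferred from the configured id-suffix convention; the
#' configuration is validated by requiring that the photon-uptake role
#' resolves to a light-phase reaction (if it resolves to the dark phase the
#' suffixes are almost certainly swapped, and the error says so).
#'
#' @param path SBML file.
#' @param role_cfg a [role_config()] (or path to its YAML form).
#' @param required roles that must resolve; defaults to [required_roles()].
#' @return a [diel_model()].
#' @export
read_diel_sbml <- function(path, role_cfg, required = required_roles()) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  if (is.character(role_cfg)) role_cfg <- read_role_config(role_cfg)
  stopifnot(inherits(role_cfg, "role_config"))
  doc <- xml2::read_xml(path)

  params <- local_find(doc, "parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp <- local_find(doc, "species")
  mids <- xml2::xml_attr(sp, "id")
  mets <- data.frame(
    id = mids,
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), mids,
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    phase = infer_phase_from_id(mids, role_cfg$light_suffix, role_cfg$dark_suffix),
    carbon = vapply(sp, function(s) carbon_from_formula(attr_any(s, "chemicalFormula")),
                    numeric(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(mets$id))
    stop("duplicate species id: ", mets$id[duplicated(mets$id)][1])

  rx <- local_find(doc, "reaction")
  if (!length(rx)) stop("no reactions found; is this an SBML model?")
  rids <- xml2::xml_attr(rx, "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1])

  clamp <- function(x) max(min(x, 1000), -1000)
  stoich <- vector("list", length(rx))
  lb <- ub <- numeric(length(rx))
  for (i in seq_along(rx)) {
    node <- rx[[i]]
    refs <- function(tag, sign) {
      lst <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(lst)) return(numeric(0))
      coefs <- as.numeric(xml2::xml_attr(lst, "stoichiometry"))
      coefs[is.na(coefs)] <- 1
      stats::setNames(sign * coefs, xml2::xml_attr(lst, "species"))
    }
    s <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    # merge duplicated species references
    if (anyDuplicated(names(s))) {
      s <- tapply(s, names(s), sum)
      s <- stats::setNames(as.numeric(s), names(s))
    }
    stoich[[i]] <- s

    lo <- attr_any(node, "lowerFluxBound")
    hi <- attr_any(node, "upperFluxBound")
    if (!is.na(lo) && !is.na(hi)) {
      lb[i] <- pval[[lo]]; ub[i] <- pval[[hi]]
    } else {
      kl <- xml2::xml_find_all(node, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter' or ",
        "local-name()='localParameter']"))
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      lo <- kv[match("LOWER_BOUND", kid)]
      hi <- kv[match("UPPER_BOUND", kid)]
      rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
      lb[i] <- if (!is.na(lo)) lo else if (rev) -1000 else 0
      ub[i] <- if (!is.na(hi)) hi else 1000
    }
    lb[i] <- clamp(lb[i]); ub[i] <- clamp(ub[i])
  }

  met_phase <- stats::setNames(mets$phase, mets$id)
  phase <- vapply(seq_along(rx), function(i) {
    if (grepl(role_cfg$transfer_tag, rids[i], fixed = TRUE)) return("transfer")
    ph <- setdiff(unique(met_phase[names(stoich[[i]])]), "shared")
    if (length(ph) == 1L) ph else if (length(ph) == 0L) "shared" else "transfer"
  }, "")

  rxns <- data.frame(
    id = rids,
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), rids,
                  xml2::xml_attr(rx, "name")),
    phase = phase, lb = lb, ub = ub, stringsAsFactors = FALSE)

  mid <- xml2::xml_attr(local_find(doc, "model")[[1]], "id")
  model <- diel_model(mets, rxns, stats::setNames(stoich, rids),
                      role_map = role_cfg$roles,
                      id = if (is.na(mid)) "diel_model" else mid)
  miss <- setdiff(required, names(model$role_map))
  if (length(miss))
    stop("role configuration is missing required role(s): ",
         paste(miss, collapse = ", "))

  ph_ids <- role_reactions(model, "photon_uptake_light")
  ph_phase <- model$reactions$phase[match(ph_ids, model$reactions$id)]
  if (any(ph_phase == "dark"))
    stop("photon uptake resolves to the dark phase; the light/dark id ",
         "suffixes in the role configuration are probably swapped")
  model
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a diel model to SBML (Level 3 + FBC)
#'
#' Bounds are emitted as shared FBC bound parameters; carbon counts as FBC
#' chemical formulas (`C<n>`). The role map is not part of SBML; serialize it
#' separately with [write_role_config()].
#'
#' @param model a [diel_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diel_sbml <- function(model, path) {
  validate_diel_model(model)
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  bvals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bid <- stats::setNames(paste0("bnd_", seq_along(bvals)), fmt(bvals))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w(paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'))
  w('  <model id="%s" fbc:strict="true">', xml_escape(model$id))
  w('    <listOfCompartments>')
  for (cmp in unique(model$metabolites$compartment))
    w('      <compartment id="%s" constant="true"/>', xml_escape(cmp))
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    formula <- if (!is.na(m$carbon)) sprintf(' fbc:chemicalFormula="C%d"', as.integer(m$carbon)) else ""
    w(paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false"%s/>'),
      xml_escape(m$id), xml_escape(m$name), xml_escape(m$compartment), formula)
  }
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  for (k in seq_along(bvals))
    w('      <parameter id="%s" value="%s" constant="true"/>',
      bid[[k]], fmt(bvals[k]))
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- model$stoich[[r$id]]
    s <- s[s != 0]
    w(paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_escape(r$id), xml_escape(r$name),
      if (r$lb < 0) "true" else "false",
      bid[[fmt(r$lb)]], bid[[fmt(r$ub)]])
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      w('        <listOfReactants>')
      for (j in seq_along(reac))
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(names(reac)[j]), fmt(-reac[j]))
      w('        </listOfReactants>')
    }
    if (length(prod)) {
      w('        <listOfProducts>')
      for (j in seq_along(prod))
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          xml_escape(names(prod)[j]), fmt(prod[j]))
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
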