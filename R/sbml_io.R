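## ---------------------------------------------------------------------------
## SBML Level 3 import/export, built directly on xml2.
##
## Scope: species (boundaryCondition marks buffered pools), mass-action and
## Michaelis-Menten kinetic laws, hierarchical pathway structure via the SBML
## 'groups' package, and stimulus events. Entity paths are carried in SBML
## 'name' attributes (SBML ids cannot contain '/'); ids are sanitized paths.
## Kinetic laws are recognized through their canonical local parameters
## (Kf/Kb for mass action, Km/kcat plus one modifier for Michaelis-Menten);
## any other rate law raises an error naming the reaction.
## ---------------------------------------------------------------------------

SBML_CORE_NS   <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
MATHML_NS      <- "http://www.w3.org/1998/Math/MathML"

sbml_ns <- c(s = SBML_CORE_NS, g = SBML_GROUPS_NS, m = MATHML_NS)

## path -> legal SId, collision-free within one document
make_sid_map <- function(paths) {
  ids <- gsub("[^A-Za-z0-9_]", "_", paths)
  ids <- ifelse(grepl("^[0-9]", ids), paste0("x", ids), ids)
  ids <- ifelse(ids == "", "x", ids)
  while (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- paste0(ids[dup], "_", seq_len(sum(dup)))
  }
  names(ids) <- paths
  ids
}

mathml_ci <- function(parent, sym) {
  xml2::xml_add_child(parent, "ci", sym)
}

## <apply><op/>args...</apply>
mathml_apply <- function(parent, op) {
  ap <- xml2::xml_add_child(parent, "apply")
  xml2::xml_add_child(ap, op)
  ap
}

mathml_cn <- function(parent, value) {
  xml2::xml_add_child(parent, "cn", fmt_num(value))
}

## product Kconst * prod(species^stoich) under 'parent'
mathml_mass_action_term <- function(parent, kname, specs, stoich) {
  times <- mathml_apply(parent, "times")
  mathml_ci(times, kname)
  for (i in seq_along(specs)) {
    if (stoich[[i]] == 1) {
      mathml_ci(times, specs[[i]])
    } else {
      pw <- mathml_apply(times, "power")
      mathml_ci(pw, specs[[i]])
      mathml_cn(pw, stoich[[i]])
    }
  }
  invisible(times)
}

add_math <- function(parent) {
  m <- xml2::xml_add_child(parent, "math")
  xml2::xml_set_attr(m, "xmlns", MATHML_NS)
  m
}

#' Export a model as SBML Level 3
#'
#' Buffered pools become boundary-condition species; pathway grouping is
#' written with the SBML groups package; time-series stimuli, when supplied,
#' become SBML events assigning species concentrations at their trigger
#' times. Dose clamps are represented as boundary species (the buffered
#' flag), and multi-stimulus combinations are not exported.
#'
#' @param model a `ReactionModel`
#' @param dest destination file path
#' @param stimuli optional `StimulusSchedule` (see [stimulus_schedule()]);
#'   only `conc`/`concInit` assignments are exportable as events
#' @return `dest`, invisibly
#' @export
export_sbml <- function(model, dest, stimuli = NULL) {
  doc <- xml2::xml_new_root("sbml",
                            xmlns = SBML_CORE_NS,
                            "xmlns:groups" = SBML_GROUPS_NS,
                            level = "3", version = "1",
                            "groups:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             name = model$name,
                             substanceUnits = "millimole",
                             timeUnits = "second", volumeUnits = "litre")

  comp_ids <- make_sid_map(names(model$compartments))
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cm in model$compartments)
    xml2::xml_add_child(loc, "compartment", id = comp_ids[[cm$name]],
                        name = cm$name, size = fmt_num(cm$volume),
                        spatialDimensions = "3", constant = "true")

  ent_paths <- all_entity_paths(model)
  sid <- make_sid_map(c(ent_paths, paste0("grp:", model$groups)))

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (p in model$pools)
    xml2::xml_add_child(los, "species", id = sid[[p$path]], name = p$path,
                        compartment = comp_ids[[p$compartment]],
                        initialConcentration = fmt_num(p$concInit),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (p$buffered) "true" else "false",
                        constant = "false")

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rx <- xml2::xml_add_child(lor, "reaction", id = sid[[r$path]],
                              name = r$path,
                              reversible = if (r$Kb > 0) "true" else "false")
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (i in seq_along(r$substrates))
      xml2::xml_add_child(lre, "speciesReference",
                          species = sid[[names(r$substrates)[[i]]]],
                          stoichiometry = fmt_num(r$substrates[[i]]),
                          constant = "true")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (i in seq_along(r$products))
      xml2::xml_add_child(lpr, "speciesReference",
                          species = sid[[names(r$products)[[i]]]],
                          stoichiometry = fmt_num(r$products[[i]]),
                          constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- add_math(kl)
    minus <- mathml_apply(math, "minus")
    mathml_mass_action_term(minus, "Kf", sid[names(r$substrates)], r$substrates)
    mathml_mass_action_term(minus, "Kb", sid[names(r$products)], r$products)
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "Kf", value = fmt_num(r$Kf))
    xml2::xml_add_child(lp, "localParameter", id = "Kb", value = fmt_num(r$Kb))
  }
  for (e in model$enzymes) {
    rx <- xml2::xml_add_child(lor, "reaction", id = sid[[e$path]],
                              name = e$path, reversible = "false")
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    xml2::xml_add_child(lre, "speciesReference", species = sid[[e$substrate]],
                        stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference", species = sid[[e$product]],
                        stoichiometry = "1", constant = "true")
    lmo <- xml2::xml_add_child(rx, "listOfModifiers")
    xml2::xml_add_child(lmo, "modifierSpeciesReference",
                        species = sid[[e$enzymePool]])
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- add_math(kl)
    dv <- mathml_apply(math, "divide")
    num <- mathml_apply(dv, "times")
    mathml_ci(num, "kcat")
    mathml_ci(num, sid[[e$enzymePool]])
    mathml_ci(num, sid[[e$substrate]])
    den <- mathml_apply(dv, "plus")
    mathml_ci(den, "Km")
    mathml_ci(den, sid[[e$substrate]])
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "Km", value = fmt_num(e$Km))
    xml2::xml_add_child(lp, "localParameter", id = "kcat", value = fmt_num(e$kcat))
  }

  if (length(model$groups)) {
    log_ <- xml2::xml_add_child(mdl, "groups:listOfGroups")
    for (gpath in model$groups) {
      g <- xml2::xml_add_child(log_, "groups:group",
                               "groups:id" = sid[[paste0("grp:", gpath)]],
                               "groups:name" = gpath,
                               "groups:kind" = "collection")
      members <- ent_paths[vapply(ent_paths, path_parent, "") == gpath]
      if (length(members)) {
        lm <- xml2::xml_add_child(g, "groups:listOfMembers")
        for (mpath in members)
          xml2::xml_add_child(lm, "groups:member",
                              "groups:idRef" = sid[[mpath]])
      }
    }
  }

  if (!is.null(stimuli)) {
    ev <- stimuli$events
    ev <- ev[vapply(ev, function(x) x$field %in% c("conc", "concInit"), TRUE)]
    if (length(ev)) {
      loe <- xml2::xml_add_child(mdl, "listOfEvents")
      for (k in seq_along(ev)) {
        e <- ev[[k]]
        evn <- xml2::xml_add_child(loe, "event", id = sprintf("stim_%d", k),
                                   useValuesFromTriggerTime = "true")
        trg <- xml2::xml_add_child(evn, "trigger", initialValue = "false",
                                   persistent = "true")
        math <- add_math(trg)
        geq <- mathml_apply(math, "geq")
        tsym <- xml2::xml_add_child(geq, "csymbol", "t",
                                    encoding = "text",
                                    definitionURL = "http://www.sbml.org/sbml/symbols/time")
        mathml_cn(geq, e$time)
        loea <- xml2::xml_add_child(evn, "listOfEventAssignments")
        ea <- xml2::xml_add_child(loea, "eventAssignment",
                                  variable = sid[[e$entity]])
        math2 <- add_math(ea)
        mathml_cn(math2, e$value)
      }
    }
  }

  xml2::write_xml(doc, dest)
  invisible(dest)
}

attr_or <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

local_param_values <- function(kl) {
  lp <- xml2::xml_find_all(kl, ".//s:localParameter | .//s:parameter", sbml_ns)
  vals <- as.numeric(xml2::xml_attr(lp, "value"))
  names(vals) <- xml2::xml_attr(lp, "id")
  vals
}

## species name looks like a rooted path -> use it, else flat under root
sbml_path_of <- function(node) {
  nm <- xml2::xml_attr(node, "name")
  if (!is.na(nm) && path_is_valid(nm)) nm
  else paste0("/", xml2::xml_attr(node, "id"))
}

#' Read a model from an SBML Level 3 file
#'
#' @param path file path
#' @return a `ReactionModel` (not yet validated; see [load_model()])
#' @export
read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_expsim("SBML parse failure in '%s': %s",
                                                  path, conditionMessage(e)))
  mdl <- xml2::xml_find_first(doc, "//s:model", sbml_ns)
  if (inherits(mdl, "xml_missing"))
    stop_expsim("'%s': no <model> element found (is this SBML?)", path)

  model <- new_reaction_model(attr_or(mdl, "name", attr_or(mdl, "id", "model")))

  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", sbml_ns)
  comp_name_by_id <- character(0)
  for (cn in comp_nodes) {
    nm <- attr_or(cn, "name", xml2::xml_attr(cn, "id"))
    comp_name_by_id[[xml2::xml_attr(cn, "id")]] <- nm
    size <- as.numeric(attr_or(cn, "size", "1"))
    model <- add_compartment(model, nm, if (is.finite(size)) size else 1)
  }
  if (length(comp_nodes) == 0L) model <- add_compartment(model, "cell")

  grp_nodes <- xml2::xml_find_all(mdl, ".//g:listOfGroups/g:group", sbml_ns)
  grp_paths <- character(0)
  for (gn in grp_nodes) {
    gname <- xml2::xml_attr(gn, "name", ns = sbml_ns["g"])
    if (is.na(gname)) gname <- xml2::xml_attr(gn, "name")
    if (!is.na(gname) && path_is_valid(gname)) grp_paths <- c(grp_paths, gname)
  }
  ## declare parents before children
  for (g in grp_paths[order(nchar(grp_paths))]) model <- add_group(model, g)

  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", sbml_ns)
  path_by_sid <- character(0)
  for (sn in sp_nodes) {
    spath <- sbml_path_of(sn)
    path_by_sid[[xml2::xml_attr(sn, "id")]] <- spath
    cid <- xml2::xml_attr(sn, "compartment")
    conc <- as.numeric(attr_or(sn, "initialConcentration", "0"))
    if (!is.finite(conc)) conc <- 0
    model <- add_pool(model, spath, concInit = conc,
                      buffered = identical(attr_or(sn, "boundaryCondition"), "true"),
                      compartment = comp_name_by_id[[cid]])
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", sbml_ns)
  for (rn in rx_nodes) {
    rid <- xml2::xml_attr(rn, "id")
    rpath <- sbml_path_of(rn)
    refs <- function(xp) {
      srefs <- xml2::xml_find_all(rn, xp, sbml_ns)
      if (length(srefs) == 0L) return(numeric(0))
      v <- as.numeric(xml2::xml_attr(srefs, "stoichiometry"))
      v[is.na(v)] <- 1
      names(v) <- path_by_sid[xml2::xml_attr(srefs, "species")]
      v
    }
    subs <- refs(".//s:listOfReactants/s:speciesReference")
    prods <- refs(".//s:listOfProducts/s:speciesReference")
    mods <- xml2::xml_find_all(rn, ".//s:listOfModifiers/s:modifierSpeciesReference", sbml_ns)
    kl <- xml2::xml_find_first(rn, ".//s:kineticLaw", sbml_ns)
    if (inherits(kl, "xml_missing"))
      stop_expsim("unsupported kinetic law in reaction '%s': no kineticLaw element", rid)
    pv <- local_param_values(kl)
    if (all(c("Kf", "Kb") %in% names(pv)) && length(mods) == 0L) {
      if (length(subs) < 1L || length(prods) < 1L)
        stop_expsim("unsupported kinetic law in reaction '%s': mass action needs reactants and products", rid)
      model <- add_reaction(model, rpath, substrates = subs, products = prods,
                            Kf = pv[["Kf"]], Kb = pv[["Kb"]])
    } else if (all(c("Km", "kcat") %in% names(pv)) && length(mods) == 1L &&
               length(subs) == 1L && length(prods) == 1L) {
      model <- add_enzyme(model, rpath,
                          enzymePool = path_by_sid[[xml2::xml_attr(mods, "species")]],
                          substrate = names(subs), product = names(prods),
                          Km = pv[["Km"]], kcat = pv[["kcat"]])
    } else {
      stop_expsim("unsupported kinetic law in reaction '%s': expected mass action (local Kf/Kb) or Michaelis-Menten (local Km/kcat with one modifier)", rid)
    }
  }

  ## adopt orphan parents as groups for foreign files without groups markup
  for (ent in all_entity_paths(model)) {
    par <- path_parent(ent)
    while (par != "/" && !(par %in% model$groups)) {
      model <- add_group(model, par)
      par <- path_parent(par)
    }
  }
  model$groups <- sort(model$groups)
  model
}

#' Structural conformance check for an SBML Level 3 document
#'
#' Verifies the document skeleton an SBML L3 consumer relies on: correct
#' root element and namespace, level/version attributes, a model element,
#' and id/compartment/constancy attributes on every species, compartment
#' and reaction. Returns diagnostics; empty means conformant.
#'
#' @param path file path to an SBML document
#' @return character vector of diagnostics (empty iff structurally valid)
#' @export
validate_sbml_structure <- function(path) {
  diags <- character(0)
  note <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) e)
  if (inherits(doc, "error"))
    return(sprintf("XML parse failure: %s", conditionMessage(doc)))
  root <- xml2::xml_name(doc)
  if (root != "sbml") note("root element is <%s>, expected <sbml>", root)
  if (!identical(xml2::xml_ns(doc)[["d1"]], SBML_CORE_NS))
    note("default namespace is not SBML Level 3 core")
  if (!identical(xml2::xml_attr(doc, "level"), "3")) note("level attribute is not 3")
  if (is.na(xml2::xml_attr(doc, "version"))) note("missing version attribute")
  mdl <- xml2::xml_find_first(doc, "//s:model", sbml_ns)
  if (inherits(mdl, "xml_missing")) { note("no <model> element"); return(diags) }
  for (sn in xml2::xml_find_all(mdl, ".//s:species", sbml_ns)) {
    for (a in c("id", "compartment", "constant", "boundaryCondition",
                "hasOnlySubstanceUnits"))
      if (is.na(xml2::xml_attr(sn, a)))
        note("species '%s': missing required attribute '%s'",
             attr_or(sn, "id", "?"), a)
  }
  for (cn in xml2::xml_find_all(mdl, ".//s:compartment", sbml_ns))
    for (a in c("id", "constant"))
      if (is.na(xml2::xml_attr(cn, a)))
        note("compartment '%s': missing required attribute '%s'",
             attr_or(cn, "id", "?"), a)
  for (rn in xml2::xml_find_all(mdl, ".//s:reaction", sbml_ns)) {
    for (a in c("id", "reversible"))
      if (is.na(xml2::xml_attr(rn, a)))
        note("reaction '%s': missing required attribute '%s'",
             attr_or(rn, "id", "?"), a)
    for (sr in xml2::xml_find_all(rn, ".//s:speciesReference", sbml_ns))
      if (is.na(xml2::xml_attr(sr, "species")))
        note("reaction '%s': speciesReference without species", attr_or(rn, "id", "?"))
  }
  diags
}
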