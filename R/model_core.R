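#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Hierarchical reaction-network model: constructors, path addressing,
## validation. Canonical units throughout: millimolar, seconds, litres, mV.
## ---------------------------------------------------------------------------

#' Create an empty reaction model
#'
#' A `ReactionModel` is a hierarchical container of pathway groups holding
#' molecular pools, mass-action reactions and Michaelis-Menten enzymes.
#' Every entity is addressed by a rooted, '/'-separated, case-sensitive path
#' (e.g. `/cell/MAPK/MAPK_p`); the parent path of an entity must be a
#' declared group (or the root `/`).
#'
#' @param name model name (informational)
#' @return an object of class `ReactionModel`
#' @export
new_reaction_model <- function(name = "model") {
  structure(
    list(
      name         = name,
      compartments = list(),  # name -> list(name, volume)
      groups       = character(0),  # group paths, root "/" implicit
      pools        = list(),  # path -> list(path, compartment, concInit, buffered)
      reactions    = list(),  # path -> list(path, substrates, products, Kf, Kb)
      enzymes      = list(),  # path -> list(path, enzymePool, substrate, product, Km, kcat)
      hh           = NULL,    # optional Hodgkin-Huxley parameter block
      solver       = "ode_stiff"
    ),
    class = "ReactionModel"
  )
}

#' @export
print.ReactionModel <- function(x, ...) {
  cat(sprintf(
    "ReactionModel '%s': %d pools, %d reactions, %d enzymes, %d groups, %d compartments\n",
    x$name, length(x$pools), length(x$reactions), length(x$enzymes),
    length(x$groups), length(x$compartments)))
  if (!is.null(x$hh)) cat("  carries Hodgkin-Huxley parameter block (solver 'hh')\n")
  invisible(x)
}

path_parent <- function(path) {
  p <- sub("/[^/]*$", "", path)
  if (!nzchar(p)) "/" else p
}

path_is_valid <- function(path) {
  is.character(path) && length(path) == 1L && nzchar(path) &&
    startsWith(path, "/") && !endsWith(path, "/") && !grepl("//", path) &&
    !grepl("[\t\n]", path)
}

all_entity_paths <- function(model) {
  c(names(model$pools), names(model$reactions), names(model$enzymes))
}

stop_expsim <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Add a compartment
#' @param model a `ReactionModel`
#' @param name compartment identifier, unique within the model
#' @param volume compartment volume in litres, strictly positive
#' @export
add_compartment <- function(model, name, volume = 1e-15) {
  stopifnot(inherits(model, "ReactionModel"))
  if (!is.null(model$compartments[[name]]))
    stop_expsim("compartment '%s' already defined", name)
  if (!is.finite(volume) || volume <= 0)
    stop_expsim("compartment '%s': volume must be > 0", name)
  model$compartments[[name]] <- list(name = name, volume = volume)
  model
}

#' Add a pathway group
#' @param model a `ReactionModel`
#' @param path rooted group path, e.g. `/cell/MAPK`
#' @export
add_group <- function(model, path) {
  stopifnot(inherits(model, "ReactionModel"))
  if (!path_is_valid(path)) stop_expsim("invalid group path '%s'", path)
  if (path %in% model$groups) stop_expsim("group '%s' already defined", path)
  model$groups <- c(model$groups, path)
  model
}

#' Add a molecular pool
#'
#' @param model a `ReactionModel`
#' @param path rooted entity path
#' @param concInit initial concentration, millimolar, non-negative
#' @param buffered if `TRUE` the pool is clamped at `concInit` during
#'   integration (an experimental buffer)
#' @param compartment name of a declared compartment
#' @export
add_pool <- function(model, path, concInit, buffered = FALSE,
                     compartment = NULL) {
  stopifnot(inherits(model, "ReactionModel"))
  if (!path_is_valid(path)) stop_expsim("invalid pool path '%s'", path)
  if (path %in% all_entity_paths(model))
    stop_expsim("path '%s' already in use", path)
  if (!is.finite(concInit) || concInit < 0)
    stop_expsim("pool '%s': concInit must be >= 0", path)
  if (is.null(compartment)) {
    if (length(model$compartments) == 0L)
      model <- add_compartment(model, "cell")
    compartment <- names(model$compartments)[[1L]]
  }
  model$pools[[path]] <- list(path = path, compartment = compartment,
                              concInit = concInit, buffered = isTRUE(buffered))
  model
}

#' Add a mass-action reaction
#'
#' Flux is `Kf * prod([sub]^stoich) - Kb * prod([prod]^stoich)` in mM/s.
#'
#' @param model a `ReactionModel`
#' @param path rooted entity path
#' @param substrates named numeric vector, pool path -> stoichiometry (>= 1)
#' @param products named numeric vector, pool path -> stoichiometry (>= 1)
#' @param Kf,Kb forward/backward rate constants (per-second scaled by
#'   per-millimolar to the power sum(stoich) - 1), non-negative
#' @export
add_reaction <- function(model, path, substrates, products, Kf, Kb = 0) {
  stopifnot(inherits(model, "ReactionModel"))
  if (!path_is_valid(path)) stop_expsim("invalid reaction path '%s'", path)
  if (path %in% all_entity_paths(model))
    stop_expsim("path '%s' already in use", path)
  if (length(substrates) < 1L || length(products) < 1L)
    stop_expsim("reaction '%s': needs at least one substrate and one product", path)
  if (is.null(names(substrates)) || is.null(names(products)))
    stop_expsim("reaction '%s': substrates/products must be named by pool path", path)
  if (any(substrates < 1) || any(products < 1))
    stop_expsim("reaction '%s': stoichiometries must be >= 1", path)
  if (!is.finite(Kf) || Kf < 0 || !is.finite(Kb) || Kb < 0)
    stop_expsim("reaction '%s': Kf and Kb must be >= 0", path)
  model$reactions[[path]] <- list(path = path,
                                  substrates = substrates, products = products,
                                  Kf = Kf, Kb = Kb)
  model
}

#' Add a Michaelis-Menten enzyme
#'
#' Rate obeys `v = kcat * [E] * [S] / (Km + [S])`; the enzyme pool is not
#' consumed, the substrate is converted to the product at rate `v`.
#'
#' @param model a `ReactionModel`
#' @param path rooted entity path
#' @param enzymePool,substrate,product pool paths
#' @param Km Michaelis constant, millimolar, strictly positive
#' @param kcat catalytic constant, per second, non-negative
#' @export
add_enzyme <- function(model, path, enzymePool, substrate, product, Km, kcat) {
  stopifnot(inherits(model, "ReactionModel"))
  if (!path_is_valid(path)) stop_expsim("invalid enzyme path '%s'", path)
  if (path %in% all_entity_paths(model))
    stop_expsim("path '%s' already in use", path)
  if (!is.finite(Km) || Km <= 0) stop_expsim("enzyme '%s': Km must be > 0", path)
  if (!is.finite(kcat) || kcat < 0) stop_expsim("enzyme '%s': kcat must be >= 0", path)
  model$enzymes[[path]] <- list(path = path, enzymePool = enzymePool,
                                substrate = substrate, product = product,
                                Km = Km, kcat = kcat)
  model
}

reaction_participants <- function(rec) {
  if (!is.null(rec$enzymePool)) {
    c(rec$enzymePool, rec$substrate, rec$product)
  } else {
    c(names(rec$substrates), names(rec$products))
  }
}

#' Resolve path selectors against a model
#'
#' A selector matching a group returns every entity in the group's subtree
#' (pools, reactions and enzymes under it); a selector matching a leaf entity
#' returns that entity. The result is the union over selectors with
#' duplicates removed. Matching is exact, case-sensitive, no wildcards.
#'
#' @param model a `ReactionModel`
#' @param selectors character vector of rooted paths
#' @return character vector of entity paths (sorted)
#' @export
resolve_paths <- function(model, selectors) {
  stopifnot(inherits(model, "ReactionModel"), is.character(selectors) || length(selectors) == 0L)
  ents <- all_entity_paths(model)
  out <- character(0)
  for (sel in selectors) {
    if (sel == "/" ) {
      out <- c(out, ents)
    } else if (sel %in% model$groups) {
      pref <- paste0(sel, "/")
      out <- c(out, ents[startsWith(ents, pref)])
    } else if (sel %in% ents) {
      out <- c(out, sel)
    } else {
      stop_expsim("selector '%s' matches no group or entity in the model", sel)
    }
  }
  sort(unique(out))
}

#' Validate a reaction model
#'
#' Checks every structural invariant and returns a character vector of
#' diagnostics, empty when the model is valid. Diagnostics, not exceptions:
#' a broken model can be inspected.
#'
#' @param model a `ReactionModel`
#' @return character vector of diagnostics (empty iff valid)
#' @export
validate_model <- function(model) {
  diags <- character(0)
  note <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))
  ents <- all_entity_paths(model)
  if (anyDuplicated(ents))
    for (d in unique(ents[duplicated(ents)]))
      note("path '%s': duplicate entity path", d)
  for (cm in model$compartments)
    if (!is.finite(cm$volume) || cm$volume <= 0)
      note("compartment '%s': volume must be > 0", cm$name)
  known_groups <- c("/", model$groups)
  for (g in model$groups) {
    if (!path_is_valid(g)) note("group '%s': invalid path", g)
    else if (!(path_parent(g) %in% known_groups))
      note("group '%s': parent '%s' is not a declared group", g, path_parent(g))
  }
  for (p in model$pools) {
    if (!is.finite(p$concInit) || p$concInit < 0)
      note("pool '%s': concInit must be >= 0", p$path)
    if (!(p$compartment %in% names(model$compartments)))
      note("pool '%s': unknown compartment '%s'", p$path, p$compartment)
    if (!(path_parent(p$path) %in% known_groups))
      note("pool '%s': parent '%s' is not a declared group", p$path, path_parent(p$path))
  }
  pool_paths <- names(model$pools)
  for (r in model$reactions) {
    if (r$Kf < 0 || r$Kb < 0) note("reaction '%s': negative rate constant", r$path)
    if (length(r$substrates) < 1L || length(r$products) < 1L)
      note("reaction '%s': needs >= 1 substrate and >= 1 product", r$path)
    for (q in reaction_participants(r))
      if (!(q %in% pool_paths))
        note("reaction '%s': participant '%s' does not resolve to a pool", r$path, q)
    if (!(path_parent(r$path) %in% known_groups))
      note("reaction '%s': parent is not a declared group", r$path)
  }
  for (e in model$enzymes) {
    if (!is.finite(e$Km) || e$Km <= 0) note("enzyme '%s': Km must be > 0", e$path)
    if (e$kcat < 0) note("enzyme '%s': negative kcat", e$path)
    for (q in reaction_participants(e))
      if (!(q %in% pool_paths))
        note("enzyme '%s': participant '%s' does not resolve to a pool", e$path, q)
    if (!(path_parent(e$path) %in% known_groups))
      note("enzyme '%s': parent is not a declared group", e$path)
  }
  diags
}

#' Load a model from file
#'
#' @param source path to a model file
#' @param format `"native"` (the line-oriented text dialect) or `"sbml"`;
#'   `"auto"` guesses from the extension (`.xml`/`.sbml` are SBML)
#' @return a validated `ReactionModel`
#' @export
load_model <- function(source, format = c("auto", "native", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop_expsim("model file '%s' does not exist", source)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(source))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "native"
  }
  model <- switch(format,
                  native = read_native_model(source),
                  sbml   = read_sbml_model(source))
  diags <- validate_model(model)
  if (length(diags))
    stop_expsim("model '%s' failed validation:\n  %s", source,
                paste(diags, collapse = "\n  "))
  model
}

#' Save a model to file
#'
#' @param model a `ReactionModel`
#' @param dest destination file path
#' @param format `"native"` or `"sbml"`
#' @param stimuli optional `StimulusSchedule` exported as SBML events
#' @export
save_model <- function(model, dest, format = c("native", "sbml"),
                       stimuli = NULL) {
  format <- match.arg(format)
  switch(format,
         native = write_native_model(model, dest),
         sbml   = export_sbml(model, dest, stimuli = stimuli))
  invisible(dest)
}
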