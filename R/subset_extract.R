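## ---------------------------------------------------------------------------
## Experiment-specific sub-model extraction: pathway selection, deletions,
## dangling-reaction detection, condition overrides, experiment<->model
## renaming.
## ---------------------------------------------------------------------------

OVERRIDE_FIELDS <- c("concInit", "buffered", "Kf", "Kb", "Km", "kcat", "volume")

#' Build a subset specification
#'
#' Describes how to carve the experiment-relevant sub-model out of a larger
#' composite model: which pathway groups (or single entities) to include,
#' which entities to delete from that selection, which parameters to
#' override so the model matches experimental conditions, and how
#' experiment-domain entity names map to model paths.
#'
#' @param includePaths character vector of path selectors (groups or leaves)
#' @param deletePaths character vector of entity or group paths to remove
#'   from the included set (a group path deletes its whole subtree)
#' @param parameterOverrides list of `list(path, field, value)` with field in
#'   `r paste(OVERRIDE_FIELDS, collapse=", ")`
#' @param entityMap named list: experiment name -> character vector of model
#'   pool paths (several paths are summed at readout time, e.g. isoforms)
#' @return an object of class `SubsetSpec`
#' @export
subset_spec <- function(includePaths = "/", deletePaths = character(0),
                        parameterOverrides = list(),
                        entityMap = list()) {
  for (ov in parameterOverrides) {
    if (!all(c("path", "field", "value") %in% names(ov)))
      stop_expsim("parameter override needs path, field and value")
    if (!(ov$field %in% OVERRIDE_FIELDS))
      stop_expsim("override field '%s' not in {%s}", ov$field,
                  paste(OVERRIDE_FIELDS, collapse = ", "))
  }
  structure(list(includePaths = includePaths,
                 deletePaths = deletePaths,
                 parameterOverrides = parameterOverrides,
                 entityMap = entityMap),
            class = "SubsetSpec")
}

#' Find dangling reactions and enzymes
#'
#' A reaction or enzyme is dangling when at least one of its participants
#' (substrate, product, or enzyme pool) does not resolve to a pool present
#' in the model — the typical aftermath of deleting molecules during
#' sub-model extraction.
#'
#' @param model a `ReactionModel`
#' @return an object of class `DanglingReport`: list of entries, each
#'   `list(path, missing)`; empty when every participant resolves
#' @export
find_dangling <- function(model) {
  pool_paths <- names(model$pools)
  entries <- list()
  for (rec in c(model$reactions, model$enzymes)) {
    missing <- setdiff(unique(reaction_participants(rec)), pool_paths)
    if (length(missing))
      entries[[length(entries) + 1L]] <- list(path = rec$path, missing = missing)
  }
  structure(list(entries = entries), class = "DanglingReport")
}

#' @export
print.DanglingReport <- function(x, ...) {
  if (length(x$entries) == 0L) {
    cat("DanglingReport: clean (no dangling reactions or enzymes)\n")
  } else {
    cat(sprintf("DanglingReport: %d dangling entr%s\n", length(x$entries),
                if (length(x$entries) == 1L) "y" else "ies"))
    for (e in x$entries)
      cat(sprintf("  %s: missing %s\n", e$path, paste(e$missing, collapse = ", ")))
  }
  invisible(x)
}

#' Apply condition overrides to a model
#'
#' Sets entity fields to match experimental conditions, e.g. buffering a
#' molecule at a known concentration or zeroing a rate to represent an
#' inhibitor. Setting `buffered = TRUE` freezes the pool at its (possibly
#' overridden) `concInit` for the whole integration.
#'
#' @param model a `ReactionModel`
#' @param overrides list of `list(path, field, value)`
#' @return the modified model
#' @export
apply_condition <- function(model, overrides) {
  for (ov in overrides) {
    path <- ov$path; field <- ov$field; value <- ov$value
    if (!(field %in% OVERRIDE_FIELDS))
      stop_expsim("override on '%s': unknown field '%s'", path, field)
    if (field == "buffered") value <- as.logical(value)
    else value <- as.numeric(value)
    if (field %in% c("concInit", "Km", "volume", "Kf", "Kb", "kcat") &&
        (!is.finite(value) || value < 0))
      stop_expsim("override on '%s': %s must be a non-negative number", path, field)
    if (field == "Km" && value <= 0)
      stop_expsim("override on '%s': Km must be > 0", path)
    if (field == "volume" && value <= 0)
      stop_expsim("override on '%s': volume must be > 0", path)

    if (!is.null(model$pools[[path]])) {
      if (!(field %in% c("concInit", "buffered")))
        stop_expsim("override on pool '%s': field '%s' does not apply", path, field)
      model$pools[[path]][[field]] <- value
    } else if (!is.null(model$reactions[[path]])) {
      if (!(field %in% c("Kf", "Kb")))
        stop_expsim("override on reaction '%s': field '%s' does not apply", path, field)
      model$reactions[[path]][[field]] <- value
    } else if (!is.null(model$enzymes[[path]])) {
      if (!(field %in% c("Km", "kcat")))
        stop_expsim("override on enzyme '%s': field '%s' does not apply", path, field)
      model$enzymes[[path]][[field]] <- value
    } else if (!is.null(model$compartments[[sub("^/", "", path)]]) ||
               !is.null(model$compartments[[path]])) {
      nm <- if (!is.null(model$compartments[[path]])) path else sub("^/", "", path)
      if (field != "volume")
        stop_expsim("override on compartment '%s': field '%s' does not apply", nm, field)
      model$compartments[[nm]]$volume <- value
    } else {
      stop_expsim("override target '%s' does not exist in the model", path)
    }
  }
  model
}

keep_entities <- function(model, keep) {
  model$pools     <- model$pools[intersect(names(model$pools), keep)]
  model$reactions <- model$reactions[intersect(names(model$reactions), keep)]
  model$enzymes   <- model$enzymes[intersect(names(model$enzymes), keep)]
  ## retain a group iff it (still) lies on the path of some kept entity
  used <- character(0)
  for (ent in all_entity_paths(model)) {
    par <- path_parent(ent)
    while (par != "/") { used <- c(used, par); par <- path_parent(par) }
  }
  model$groups <- sort(intersect(model$groups, unique(used)))
  model
}

#' Extract the experiment-specific sub-model
#'
#' Resolves the include selectors, removes the deletions (a group path in
#' `deletePaths` deletes its subtree), detects reactions left dangling by
#' the deletions, and applies the parameter overrides to the surviving
#' entities. Under `policy = "strict"` (the default) any dangling reaction
#' is an error carrying the `DanglingReport`; under `policy = "prune"`
#' dangling reactions are removed, reported, and logged as warnings —
#' silent pruning would hide modelling errors.
#'
#' @param model a `ReactionModel`
#' @param spec a `SubsetSpec`
#' @param policy `"strict"` or `"prune"`
#' @return `list(model = extracted ReactionModel, dangling = DanglingReport,
#'   entityMap = re-targeted map)`
#' @export
extract_subset <- function(model, spec, policy = c("strict", "prune")) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "ReactionModel"), inherits(spec, "SubsetSpec"))

  included <- resolve_paths(model, spec$includePaths)

  deletions <- character(0)
  for (dp in spec$deletePaths) {
    hits <- tryCatch(resolve_paths(model, dp), error = function(e) NULL)
    if (is.null(hits))
      stop_expsim("deletePaths entry '%s' matches nothing in the model", dp)
    if (!all(hits %in% included))
      stop_expsim("deletePaths entry '%s' lies outside the included subset", dp)
    deletions <- c(deletions, hits)
  }
  deletions <- unique(deletions)

  sub <- keep_entities(model, setdiff(included, deletions))
  report <- find_dangling(sub)

  if (length(report$entries)) {
    if (policy == "strict") {
      msg <- paste(vapply(report$entries, function(e)
        sprintf("%s (missing %s)", e$path, paste(e$missing, collapse = ", ")),
        ""), collapse = "; ")
      cond <- structure(
        class = c("expsim_dangling_error", "error", "condition"),
        list(message = sprintf(
          "extraction left %d dangling reaction(s): %s [use policy='prune' to drop them]",
          length(report$entries), msg),
          call = NULL, report = report))
      stop(cond)
    }
    pruned <- vapply(report$entries, `[[`, "", "path")
    for (p in pruned)
      warning(sprintf("pruning dangling reaction '%s'", p), call. = FALSE)
    sub <- keep_entities(sub, setdiff(all_entity_paths(sub), pruned))
  }

  if (length(spec$parameterOverrides))
    sub <- apply_condition(sub, spec$parameterOverrides)

  emap <- spec$entityMap
  for (nm in names(emap)) {
    unresolved <- setdiff(emap[[nm]], names(sub$pools))
    if (length(unresolved))
      stop_expsim("entityMap '%s' -> %s: not present in the extracted model",
                  nm, paste(unresolved, collapse = ", "))
  }

  list(model = sub, dangling = report, entityMap = emap)
}
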