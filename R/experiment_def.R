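## ---------------------------------------------------------------------------
## Structured experiment definitions: five tab-separated blocks
## (ExperimentMetadata, ExperimentContext, Stimuli, Readouts, ModelMapping)
## covering the three chemical experiment classes plus electrical
## time-series (current clamp). A JSON mirror of the same schema is
## accepted and emitted. The dialect is documented in
## inst/extdata/experiment-format.md.
## ---------------------------------------------------------------------------

EXPT_TYPES   <- c("TimeSeries", "DoseResponse", "MultiStimulus")
EXPT_SOURCES <- c("paperReference", "inHouse", "database")
NORMALIZATIONS <- c("absolute", "foldChange", "percentOfMax")
STIM_FIELDS  <- c("conc", "concInit", "buffered", "current")
READ_FIELDS  <- c("conc", "Vm")
SOLVERS      <- c("ode_stiff", "ode_nonstiff", "hh")
BLOCK_NAMES  <- c("ExperimentMetadata", "ExperimentContext", "Stimuli",
                  "Readouts", "ModelMapping")
DEFAULT_SCORE_FORMULA <- "sqrt(mean(((expt-sim)/range)^2))"

#' Construct an experiment document
#'
#' Usually produced by [parse_experiment_tsv()] or the fixture generators;
#' direct construction is for programmatic experiment building.
#'
#' @param exptType `"TimeSeries"`, `"DoseResponse"` or `"MultiStimulus"`
#' @param metadata list: transcriber, organization, exptSource, citationId,
#'   authors, journal
#' @param context list: species, cellType, preparation, temperature, pH, notes
#' @param stimuli list of stimulus entries `list(entityName, field, unit,
#'   timeUnit, points)`; points is a data.frame with canonical-unit columns
#'   (`time`,`value`) for time series or (`dose`) for dose-response
#' @param readouts list of readout entries `list(entityName, field, unit,
#'   timeUnit, normalization, points)`; points columns (`coord`,`value`,
#'   `stderr`) — coord is time (s), dose (mM) or a combination label
#' @param modelMap list: refModel, solver, weight, scoringFormula, subset
#'   (a [subset_spec()]), plus simulation controls tEnd, dtOut, settle, tMax
#' @param combinations named list of settings lists (MultiStimulus only)
#' @param experimentId identifier used in reports
#' @return an object of class `ExperimentDoc`
#' @export
experiment_doc <- function(exptType, metadata = list(), context = list(),
                           stimuli = list(), readouts = list(),
                           modelMap = list(), combinations = NULL,
                           experimentId = "experiment") {
  if (!(exptType %in% EXPT_TYPES))
    stop_expsim("exptType must be one of %s", paste(EXPT_TYPES, collapse = ", "))
  doc <- structure(list(exptType = exptType, experimentId = experimentId,
                        metadata = metadata, context = context,
                        stimuli = stimuli, readouts = readouts,
                        combinations = combinations, modelMap = modelMap),
                   class = "ExperimentDoc")
  probs <- validate_experiment(doc)
  if (length(probs))
    stop_expsim("invalid experiment document:\n  %s",
                paste(probs, collapse = "\n  "))
  doc
}

#' @export
print.ExperimentDoc <- function(x, ...) {
  cat(sprintf("ExperimentDoc '%s' (%s): %d stimul%s, %d readout entr%s\n",
              x$experimentId, x$exptType,
              length(x$stimuli), if (length(x$stimuli) == 1L) "us" else "i",
              length(x$readouts), if (length(x$readouts) == 1L) "y" else "ies"))
  invisible(x)
}

## ---- parsing --------------------------------------------------------------

expt_err <- function(lineno, field, fmt, ...) {
  stop_expsim("experiment file line %d, %s: %s", lineno, field, sprintf(fmt, ...))
}

num_field <- function(x, lineno, field) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) expt_err(lineno, field, "expected a number, got '%s'", x)
  v
}

check_unit <- function(unit, lineno, field, kinds) {
  if (!(unit %in% names(UNIT_TABLE)))
    expt_err(lineno, field, "unknown unit '%s'", unit)
  if (!(unit_kind(unit) %in% kinds))
    expt_err(lineno, field, "unit '%s' is a %s unit; expected %s",
             unit, unit_kind(unit), paste(kinds, collapse = " or "))
  unit
}

#' Parse an experiment definition
#'
#' Reads the five-block tab-separated format, range-checks every field,
#' converts all quantities to the canonical unit frame (mM, s, mV, uA), and
#' returns a validated `ExperimentDoc`. `.json` files are parsed through
#' the JSON mirror of the schema.
#'
#' @param source file path
#' @return an `ExperimentDoc`
#' @export
parse_experiment_tsv <- function(source) {
  if (!file.exists(source)) stop_expsim("experiment file '%s' does not exist", source)
  if (tolower(tools::file_ext(source)) == "json")
    return(parse_experiment_json(source))
  lines <- readLines(source, encoding = "UTF-8")

  ## split into blocks keyed by header keyword in column 1
  blocks <- list(); current <- NULL
  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    if (!nzchar(trimws(raw)) || startsWith(trimws(raw), "#")) next
    f <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    if (f[[1]] %in% BLOCK_NAMES) {
      current <- f[[1]]
      if (!is.null(blocks[[current]]))
        expt_err(i, "block", "duplicate block '%s'", current)
      blocks[[current]] <- list()
    } else {
      if (is.null(current))
        expt_err(i, f[[1]], "content before any block header")
      blocks[[current]][[length(blocks[[current]]) + 1L]] <-
        list(lineno = i, fields = f)
    }
  }
  for (b in BLOCK_NAMES)
    if (is.null(blocks[[b]]))
      stop_expsim("experiment file '%s': missing mandatory block '%s'", source, b)

  kv <- function(block) {
    out <- list()
    for (row in blocks[[block]]) {
      f <- row$fields
      out[[f[[1]]]] <- list(value = if (length(f) > 1L) f[[2]] else "",
                            lineno = row$lineno, fields = f)
    }
    out
  }
  get_str <- function(tbl, key, default = "") {
    if (is.null(tbl[[key]])) default else tbl[[key]]$value
  }

  ## -- metadata --
  md <- kv("ExperimentMetadata")
  exptType <- get_str(md, "exptType")
  if (!(exptType %in% EXPT_TYPES))
    expt_err(if (is.null(md$exptType)) 0L else md$exptType$lineno, "exptType",
             "must be one of %s", paste(EXPT_TYPES, collapse = ", "))
  exptSource <- get_str(md, "exptSource", "inHouse")
  if (!(exptSource %in% EXPT_SOURCES))
    expt_err(md$exptSource$lineno, "exptSource", "must be one of %s",
             paste(EXPT_SOURCES, collapse = ", "))
  citationId <- get_str(md, "citationId")
  if (exptSource == "paperReference" && !nzchar(citationId))
    expt_err(if (is.null(md$citationId)) md$exptSource$lineno else md$citationId$lineno,
             "citationId", "required when exptSource is paperReference")
  metadata <- list(transcriber = get_str(md, "transcriber"),
                   organization = get_str(md, "organization"),
                   exptSource = exptSource, citationId = citationId,
                   authors = get_str(md, "authors"),
                   journal = get_str(md, "journal"))

  ## -- context --
  cx <- kv("ExperimentContext")
  temperature <- NA_real_
  if (!is.null(cx$temperature) && nzchar(cx$temperature$value)) {
    temperature <- num_field(cx$temperature$value, cx$temperature$lineno, "temperature")
    if (temperature < 0 || temperature > 60)
      expt_err(cx$temperature$lineno, "temperature", "must lie in [0, 60] degrees C")
  }
  pH <- NA_real_
  if (!is.null(cx$pH) && nzchar(cx$pH$value)) {
    pH <- num_field(cx$pH$value, cx$pH$lineno, "pH")
    if (pH < 0 || pH > 14) expt_err(cx$pH$lineno, "pH", "must lie in [0, 14]")
  }
  context <- list(species = get_str(cx, "species"),
                  cellType = get_str(cx, "cellType"),
                  preparation = get_str(cx, "preparation"),
                  temperature = temperature, pH = pH,
                  notes = get_str(cx, "notes"))

  ## -- stimuli --
  stimuli <- list(); combinations <- NULL; settle <- NA_real_
  cur_stim <- NULL; cur_comb <- NULL
  flush_stim <- function() {
    if (!is.null(cur_stim)) stimuli[[length(stimuli) + 1L]] <<- cur_stim
    cur_stim <<- NULL
  }
  for (row in blocks$Stimuli) {
    f <- row$fields; ln <- row$lineno
    switch(f[[1]],
      stimulus = {
        flush_stim()
        if (length(f) < 4L) expt_err(ln, "stimulus", "needs entity, field, unit")
        field <- f[[3]]
        if (!(field %in% STIM_FIELDS))
          expt_err(ln, "stimulus field", "must be one of %s",
                   paste(STIM_FIELDS, collapse = ", "))
        kinds <- if (field == "current") "current" else
                 if (field == "buffered") c("concentration", "dimensionless") else "concentration"
        unit <- check_unit(f[[4]], ln, "stimulus unit", kinds)
        timeUnit <- if (length(f) >= 5L && nzchar(f[[5]]))
          check_unit(f[[5]], ln, "stimulus time unit", "time") else "s"
        cur_stim <- list(entityName = f[[2]], field = field, unit = unit,
                         timeUnit = timeUnit,
                         points = data.frame(time = numeric(0), value = numeric(0)))
        if (exptType == "DoseResponse")
          cur_stim$points <- data.frame(dose = numeric(0))
      },
      point = {
        if (is.null(cur_stim)) expt_err(ln, "point", "no preceding stimulus line")
        if (exptType == "DoseResponse") {
          d <- to_canonical(num_field(f[[2]], ln, "dose"), cur_stim$unit)
          if (d < 0) expt_err(ln, "dose", "must be >= 0")
          cur_stim$points <- rbind(cur_stim$points, data.frame(dose = d))
        } else {
          if (length(f) < 3L) expt_err(ln, "point", "needs time and value")
          tv <- to_canonical(num_field(f[[2]], ln, "time"), cur_stim$timeUnit)
          vv <- num_field(f[[3]], ln, "value")
          if (cur_stim$field != "buffered") vv <- to_canonical(vv, cur_stim$unit)
          if (cur_stim$field %in% c("conc", "concInit") && vv < 0)
            expt_err(ln, "value", "concentration must be >= 0")
          if (nrow(cur_stim$points) && tv <= max(cur_stim$points$time))
            expt_err(ln, "time", "stimulus times must be strictly increasing")
          cur_stim$points <- rbind(cur_stim$points, data.frame(time = tv, value = vv))
        }
      },
      combination = {
        if (exptType != "MultiStimulus")
          expt_err(ln, "combination", "only allowed in MultiStimulus experiments")
        if (is.null(combinations)) combinations <- list()
        cur_comb <- f[[2]]
        if (cur_comb %in% names(combinations))
          expt_err(ln, "combination", "duplicate label '%s'", cur_comb)
        combinations[[cur_comb]] <- list()
      },
      setting = {
        if (is.null(cur_comb)) expt_err(ln, "setting", "no preceding combination line")
        if (length(f) < 5L) expt_err(ln, "setting", "needs entity, field, value, unit")
        sf <- f[[3]]
        if (!(sf %in% c(STIM_FIELDS, "Kf", "Kb", "Km", "kcat")))
          expt_err(ln, "setting field", "unsupported field '%s'", sf)
        val <- num_field(f[[4]], ln, "setting value")
        if (sf %in% c("conc", "concInit")) {
          check_unit(f[[5]], ln, "setting unit", "concentration")
          val <- to_canonical(val, f[[5]])
          if (val < 0) expt_err(ln, "setting value", "concentration must be >= 0")
        }
        combinations[[cur_comb]][[length(combinations[[cur_comb]]) + 1L]] <-
          list(entity = f[[2]], field = sf, value = val, unit = f[[5]])
      },
      settle = {
        tu <- if (length(f) >= 3L && nzchar(f[[3]]))
          check_unit(f[[3]], ln, "settle unit", "time") else "s"
        settle <- to_canonical(num_field(f[[2]], ln, "settle"), tu)
      },
      expt_err(ln, f[[1]], "unknown Stimuli record")
    )
  }
  flush_stim()

  ## -- readouts --
  readouts <- list(); cur_read <- NULL
  flush_read <- function() {
    if (!is.null(cur_read)) readouts[[length(readouts) + 1L]] <<- cur_read
    cur_read <<- NULL
  }
  for (row in blocks$Readouts) {
    f <- row$fields; ln <- row$lineno
    switch(f[[1]],
      readout = {
        flush_read()
        if (length(f) < 4L) expt_err(ln, "readout", "needs entity, field, unit")
        rf <- f[[3]]
        if (!(rf %in% READ_FIELDS))
          expt_err(ln, "readout field", "must be one of %s",
                   paste(READ_FIELDS, collapse = ", "))
        unit <- check_unit(f[[4]], ln, "readout unit",
                           if (rf == "Vm") "voltage" else c("concentration", "dimensionless"))
        norm <- if (length(f) >= 5L && nzchar(f[[5]])) f[[5]] else "absolute"
        if (!(norm %in% NORMALIZATIONS))
          expt_err(ln, "normalization", "must be one of %s",
                   paste(NORMALIZATIONS, collapse = ", "))
        timeUnit <- if (length(f) >= 6L && nzchar(f[[6]]))
          check_unit(f[[6]], ln, "readout time unit", "time") else "s"
        cur_read <- list(entityName = f[[2]], field = rf, unit = unit,
                         normalization = norm, timeUnit = timeUnit,
                         points = if (exptType == "MultiStimulus")
                           data.frame(coord = character(0), value = numeric(0),
                                      stderr = numeric(0), stringsAsFactors = FALSE)
                         else data.frame(coord = numeric(0), value = numeric(0),
                                         stderr = numeric(0)))
      },
      point = {
        if (is.null(cur_read)) expt_err(ln, "point", "no preceding readout line")
        if (length(f) < 3L) expt_err(ln, "point", "needs coordinate and value")
        vv <- to_canonical(num_field(f[[3]], ln, "value"), cur_read$unit)
        se <- NA_real_
        if (length(f) >= 4L && nzchar(f[[4]])) {
          se <- to_canonical(num_field(f[[4]], ln, "stderr"), cur_read$unit)
          if (se < 0) expt_err(ln, "stderr", "must be >= 0")
        }
        if (exptType == "MultiStimulus") {
          cur_read$points <- rbind(cur_read$points,
                                   data.frame(coord = f[[2]], value = vv, stderr = se,
                                              stringsAsFactors = FALSE))
        } else {
          cu <- if (exptType == "DoseResponse") {
            if (length(stimuli)) stimuli[[1L]]$unit else "mM"
          } else cur_read$timeUnit
          cv <- to_canonical(num_field(f[[2]], ln, "coordinate"), cu)
          if (nrow(cur_read$points) && cv <= max(cur_read$points$coord))
            expt_err(ln, "coordinate", "readout coordinates must be strictly increasing")
          cur_read$points <- rbind(cur_read$points,
                                   data.frame(coord = cv, value = vv, stderr = se))
        }
      },
      expt_err(ln, f[[1]], "unknown Readouts record")
    )
  }
  flush_read()

  ## -- model mapping --
  mm_rows <- blocks$ModelMapping
  includePaths <- character(0); deletePaths <- character(0)
  overrides <- list(); entityMap <- list()
  mmkv <- list()
  for (row in mm_rows) {
    f <- row$fields; ln <- row$lineno
    switch(f[[1]],
      includePath = includePaths <- c(includePaths, f[[2]]),
      deletePath  = deletePaths <- c(deletePaths, f[[2]]),
      override = {
        if (length(f) < 4L) expt_err(ln, "override", "needs path, field, value")
        if (!(f[[3]] %in% OVERRIDE_FIELDS))
          expt_err(ln, "override field", "must be one of %s",
                   paste(OVERRIDE_FIELDS, collapse = ", "))
        val <- if (f[[3]] == "buffered") as.logical(as.numeric(f[[4]])) else
          num_field(f[[4]], ln, "override value")
        overrides[[length(overrides) + 1L]] <-
          list(path = f[[2]], field = f[[3]], value = val)
      },
      map = {
        if (length(f) < 3L) expt_err(ln, "map", "needs experiment name and model path(s)")
        entityMap[[f[[2]]]] <- f[-(1:2)]
      },
      mmkv[[f[[1]]]] <- list(value = f[[2]], lineno = ln)
    )
  }
  mget_ <- function(key, default = NA_character_)
    if (is.null(mmkv[[key]])) default else mmkv[[key]]$value
  solver <- mget_("solver", "ode_stiff")
  if (!(solver %in% SOLVERS))
    expt_err(mmkv$solver$lineno, "solver", "must be one of %s",
             paste(SOLVERS, collapse = ", "))
  weight <- if (is.null(mmkv$weight)) 1 else
    num_field(mmkv$weight$value, mmkv$weight$lineno, "weight")
  if (weight < 0) expt_err(mmkv$weight$lineno, "weight", "must be >= 0")
  formula <- mget_("scoringFormula", DEFAULT_SCORE_FORMULA)
  tryCatch(parse_score_formula(formula), error = function(e)
    expt_err(if (is.null(mmkv$scoringFormula)) 0L else mmkv$scoringFormula$lineno,
             "scoringFormula", "%s", conditionMessage(e)))
  numopt <- function(key, default) {
    if (is.null(mmkv[[key]])) default
    else num_field(mmkv[[key]]$value, mmkv[[key]]$lineno, key)
  }
  modelMap <- list(
    refModel = mget_("refModel", ""),
    solver = solver, weight = weight, scoringFormula = formula,
    subset = subset_spec(includePaths = if (length(includePaths)) includePaths else "/",
                         deletePaths = deletePaths,
                         parameterOverrides = overrides,
                         entityMap = entityMap),
    tEnd = numopt("tEnd", NA_real_), dtOut = numopt("dtOut", NA_real_),
    settle = if (!is.na(settle)) settle else numopt("settle", NA_real_),
    tMax = numopt("tMax", 1e5), tol = numopt("tol", 1e-6))

  doc <- structure(list(
    exptType = exptType,
    experimentId = get_str(md, "experimentId",
                           tools::file_path_sans_ext(basename(source))),
    metadata = metadata, context = context, stimuli = stimuli,
    readouts = readouts, combinations = combinations, modelMap = modelMap),
    class = "ExperimentDoc")
  ## doc-internal invariants that parsing alone cannot catch
  probs <- validate_experiment(doc)
  if (length(probs))
    stop_expsim("experiment file '%s' is invalid:\n  %s", source,
                paste(probs, collapse = "\n  "))
  doc
}

#' @rdname parse_experiment_tsv
#' @export
parse_experiment <- parse_experiment_tsv

## ---- writing --------------------------------------------------------------

#' Write an experiment document
#'
#' Emits the five-block tab-separated dialect (or the JSON mirror when
#' `dest` ends in `.json`). Values are converted from the canonical frame
#' back to each entry's declared unit; `parse_experiment_tsv(write(doc))`
#' reproduces the document field-for-field.
#'
#' @param doc an `ExperimentDoc`
#' @param dest destination file path
#' @export
write_experiment_tsv <- function(doc, dest) {
  stopifnot(inherits(doc, "ExperimentDoc"))
  if (tolower(tools::file_ext(dest)) == "json")
    return(write_experiment_json(doc, dest))
  L <- character(0)
  add <- function(...) L <<- c(L, paste(..., sep = "\t"))
  add("# expsim experiment v1")
  add("ExperimentMetadata")
  add("exptType", doc$exptType)
  add("experimentId", doc$experimentId)
  for (k in c("transcriber", "organization", "exptSource", "citationId",
              "authors", "journal"))
    add(k, if (is.null(doc$metadata[[k]])) "" else doc$metadata[[k]])
  add("")
  add("ExperimentContext")
  for (k in c("species", "cellType", "preparation", "notes"))
    add(k, if (is.null(doc$context[[k]])) "" else doc$context[[k]])
  add("temperature", if (is.na(doc$context$temperature)) "" else fmt_num(doc$context$temperature))
  add("pH", if (is.na(doc$context$pH)) "" else fmt_num(doc$context$pH))
  add("")
  add("Stimuli")
  for (s in doc$stimuli) {
    add("stimulus", s$entityName, s$field, s$unit, s$timeUnit)
    if (doc$exptType == "DoseResponse") {
      for (i in seq_len(nrow(s$points)))
        add("point", fmt_num(from_canonical(s$points$dose[[i]], s$unit)))
    } else {
      for (i in seq_len(nrow(s$points))) {
        v <- s$points$value[[i]]
        if (s$field != "buffered") v <- from_canonical(v, s$unit)
        add("point", fmt_num(from_canonical(s$points$time[[i]], s$timeUnit)),
            fmt_num(v))
      }
    }
  }
  if (!is.null(doc$combinations) && doc$exptType == "MultiStimulus") {
    for (lab in names(doc$combinations)) {
      add("combination", lab)
      for (st in doc$combinations[[lab]]) {
        v <- st$value
        if (st$field %in% c("conc", "concInit")) v <- from_canonical(v, st$unit)
        add("setting", st$entity, st$field, fmt_num(v), st$unit)
      }
    }
  }
  if (doc$exptType == "MultiStimulus" && !is.null(doc$modelMap$settle) &&
      !is.na(doc$modelMap$settle))
    add("settle", fmt_num(doc$modelMap$settle), "s")
  add("")
  add("Readouts")
  for (r in doc$readouts) {
    add("readout", r$entityName, r$field, r$unit, r$normalization, r$timeUnit)
    for (i in seq_len(nrow(r$points))) {
      se <- r$points$stderr[[i]]
      coord <- r$points$coord[[i]]
      if (doc$exptType == "TimeSeries") coord <- fmt_num(from_canonical(coord, r$timeUnit))
      else if (doc$exptType == "DoseResponse")
        coord <- fmt_num(from_canonical(coord, doc$stimuli[[1L]]$unit))
      add("point", coord, fmt_num(from_canonical(r$points$value[[i]], r$unit)),
          if (is.na(se)) "" else fmt_num(from_canonical(se, r$unit)))
    }
  }
  add("")
  add("ModelMapping")
  mm <- doc$modelMap
  add("refModel", mm$refModel)
  add("solver", mm$solver)
  add("weight", fmt_num(mm$weight))
  add("scoringFormula", mm$scoringFormula)
  for (p in mm$subset$includePaths) add("includePath", p)
  for (p in mm$subset$deletePaths) add("deletePath", p)
  for (ov in mm$subset$parameterOverrides)
    add("override", ov$path, ov$field,
        if (is.logical(ov$value)) (if (ov$value) "1" else "0") else fmt_num(ov$value))
  for (nm in names(mm$subset$entityMap))
    add("map", nm, paste(mm$subset$entityMap[[nm]], collapse = "\t"))
  if (!is.na(mm$tEnd)) add("tEnd", fmt_num(mm$tEnd))
  if (!is.na(mm$dtOut)) add("dtOut", fmt_num(mm$dtOut))
  if (doc$exptType != "MultiStimulus" && !is.null(mm$settle) && !is.na(mm$settle))
    add("settle", fmt_num(mm$settle))
  if (!is.null(mm$tMax) && mm$tMax != 1e5) add("tMax", fmt_num(mm$tMax))
  writeLines(L, dest, useBytes = TRUE)
  invisible(dest)
}

## JSON mirror: the ExperimentDoc serialized field-for-field
#' @rdname write_experiment_tsv
#' @export
write_experiment_json <- function(doc, dest) {
  stopifnot(inherits(doc, "ExperimentDoc"))
  x <- unclass(doc)
  x$modelMap$subset <- unclass(x$modelMap$subset)
  jsonlite::write_json(x, dest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(dest)
}

#' @rdname parse_experiment_tsv
#' @export
parse_experiment_json <- function(source) {
  x <- jsonlite::read_json(source, simplifyVector = FALSE)
  num_col <- function(v) vapply(v, function(z)
    if (is.null(z)) NA_real_ else as.numeric(z), 0)
  chr_col <- function(v) vapply(v, function(z)
    if (is.null(z)) NA_character_ else as.character(z), "")
  scal_num <- function(z) if (is.null(z)) NA_real_ else as.numeric(z)
  scal_chr <- function(z) if (is.null(z)) "" else as.character(z)
  points_df <- function(pts, cols, chr_first = FALSE) {
    out <- lapply(seq_along(cols), function(j) {
      v <- pts[[cols[[j]]]]
      if (is.null(v)) v <- list()
      if (j == 1L && chr_first) chr_col(v) else num_col(v)
    })
    names(out) <- cols
    do.call(data.frame, c(out, stringsAsFactors = FALSE))
  }
  exptType <- scal_chr(x$exptType)
  multistim <- identical(exptType, "MultiStimulus")
  stim_cols <- if (identical(exptType, "DoseResponse")) "dose" else c("time", "value")
  stimuli <- lapply(x$stimuli, function(s) list(
    entityName = scal_chr(s$entityName), field = scal_chr(s$field),
    unit = scal_chr(s$unit), timeUnit = scal_chr(s$timeUnit),
    points = points_df(s$points, stim_cols)))
  readouts <- lapply(x$readouts, function(r) list(
    entityName = scal_chr(r$entityName), field = scal_chr(r$field),
    unit = scal_chr(r$unit), normalization = scal_chr(r$normalization),
    timeUnit = scal_chr(r$timeUnit),
    points = points_df(r$points, c("coord", "value", "stderr"),
                       chr_first = multistim)))
  combinations <- NULL
  if (!is.null(x$combinations) && length(x$combinations))
    combinations <- lapply(x$combinations, function(cb) lapply(cb, function(st)
      list(entity = scal_chr(st$entity), field = scal_chr(st$field),
           value = as.numeric(st$value), unit = scal_chr(st$unit))))
  sb <- x$modelMap$subset
  subset <- subset_spec(
    includePaths = if (length(sb$includePaths)) chr_col(sb$includePaths) else "/",
    deletePaths = if (length(sb$deletePaths)) chr_col(sb$deletePaths) else character(0),
    parameterOverrides = lapply(sb$parameterOverrides, function(ov)
      list(path = scal_chr(ov$path), field = scal_chr(ov$field),
           value = if (identical(scal_chr(ov$field), "buffered"))
             as.logical(ov$value) else as.numeric(ov$value))),
    entityMap = lapply(sb$entityMap, chr_col))
  modelMap <- list(
    refModel = scal_chr(x$modelMap$refModel),
    solver = scal_chr(x$modelMap$solver),
    weight = scal_num(x$modelMap$weight),
    scoringFormula = scal_chr(x$modelMap$scoringFormula),
    subset = subset,
    tEnd = scal_num(x$modelMap$tEnd), dtOut = scal_num(x$modelMap$dtOut),
    settle = scal_num(x$modelMap$settle), tMax = scal_num(x$modelMap$tMax),
    tol = scal_num(x$modelMap$tol))
  doc <- structure(list(
    exptType = exptType, experimentId = scal_chr(x$experimentId),
    metadata = lapply(x$metadata, scal_chr),
    context = list(species = scal_chr(x$context$species),
                   cellType = scal_chr(x$context$cellType),
                   preparation = scal_chr(x$context$preparation),
                   temperature = scal_num(x$context$temperature),
                   pH = scal_num(x$context$pH),
                   notes = scal_chr(x$context$notes)),
    stimuli = stimuli, readouts = readouts, combinations = combinations,
    modelMap = modelMap), class = "ExperimentDoc")
  probs <- validate_experiment(doc)
  if (length(probs))
    stop_expsim("experiment file '%s' is invalid:\n  %s", source,
                paste(probs, collapse = "\n  "))
  doc
}

## ---- validation -----------------------------------------------------------

#' Validate an experiment document
#'
#' Checks document-internal invariants and, when a model is supplied, that
#' every entity-map target resolves in the sub-model the document's subset
#' specification extracts.
#'
#' @param doc an `ExperimentDoc`
#' @param model optional `ReactionModel` to cross-validate against
#' @return character vector of diagnostics (empty iff valid)
#' @export
validate_experiment <- function(doc, model = NULL) {
  diags <- character(0)
  note <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))
  if (!(doc$exptType %in% EXPT_TYPES))
    note("exptType '%s' invalid", doc$exptType)
  if (!is.null(doc$metadata$exptSource)) {
    if (!(doc$metadata$exptSource %in% EXPT_SOURCES))
      note("exptSource '%s' invalid", doc$metadata$exptSource)
    else if (doc$metadata$exptSource == "paperReference" &&
             !nzchar(doc$metadata$citationId %||% ""))
      note("citationId required when exptSource is paperReference")
  }
  tmp <- doc$context$temperature
  if (!is.null(tmp) && !is.na(tmp) && (tmp < 0 || tmp > 60))
    note("temperature %g outside [0, 60]", tmp)
  ph <- doc$context$pH
  if (!is.null(ph) && !is.na(ph) && (ph < 0 || ph > 14))
    note("pH %g outside [0, 14]", ph)

  for (s in doc$stimuli) {
    if (doc$exptType == "DoseResponse") {
      if (any(duplicated(s$points$dose)))
        note("stimulus '%s': duplicate dose", s$entityName)
      if (is.unsorted(s$points$dose, strictly = TRUE) && nrow(s$points) > 1L)
        note("stimulus '%s': doses must be strictly increasing", s$entityName)
    } else if (nrow(s$points) > 1L && any(diff(s$points$time) <= 0)) {
      note("stimulus '%s': times must be strictly increasing", s$entityName)
    }
    if (s$field %in% c("conc", "concInit") && nrow(s$points) &&
        !is.null(s$points$value) && any(s$points$value < 0))
      note("stimulus '%s': negative concentration", s$entityName)
  }
  if (doc$exptType == "DoseResponse" && length(doc$stimuli) != 1L)
    note("DoseResponse requires exactly one stimulus entity, found %d",
         length(doc$stimuli))
  if (doc$exptType == "MultiStimulus" && is.null(doc$combinations))
    note("MultiStimulus requires named combinations")

  for (r in doc$readouts) {
    if (doc$exptType == "MultiStimulus") {
      if (any(duplicated(r$points$coord)))
        note("readout '%s': duplicate combination label", r$entityName)
      unknown <- setdiff(r$points$coord, names(doc$combinations))
      if (length(unknown))
        note("readout '%s': unknown combination label(s) %s", r$entityName,
             paste(unknown, collapse = ", "))
    } else {
      if (nrow(r$points) > 1L && any(diff(r$points$coord) <= 0))
        note("readout '%s': coordinates must be strictly increasing", r$entityName)
      if (doc$exptType == "DoseResponse" && length(doc$stimuli) == 1L) {
        doses <- doc$stimuli[[1L]]$points$dose
        if (nrow(r$points) && !isTRUE(all.equal(sort(r$points$coord), sort(doses))))
          note("readout '%s': coordinates must equal the stimulus doses", r$entityName)
      }
    }
    if (any(stats::na.omit(r$points$stderr) < 0))
      note("readout '%s': negative stderr", r$entityName)
  }
  if (!is.null(doc$modelMap$weight) && doc$modelMap$weight < 0)
    note("weight must be >= 0")
  if (!is.null(doc$modelMap$scoringFormula)) {
    ok <- tryCatch({ parse_score_formula(doc$modelMap$scoringFormula); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) note("scoringFormula does not parse: %s", ok)
  }

  if (!is.null(model)) {
    ext <- tryCatch(extract_subset(model, doc$modelMap$subset, policy = "prune"),
                    error = function(e) e)
    if (inherits(ext, "error")) {
      note("subset extraction fails: %s", conditionMessage(ext))
    } else {
      pool_paths <- names(ext$model$pools)
      emap <- doc$modelMap$subset$entityMap
      used <- unique(c(vapply(doc$stimuli, `[[`, "", "entityName"),
                       vapply(doc$readouts, `[[`, "", "entityName")))
      for (nm in used) {
        targets <- if (!is.null(emap[[nm]])) emap[[nm]] else nm
        if (doc$modelMap$solver == "hh") next  # electrical entities are not pools
        bad <- setdiff(targets, pool_paths)
        if (length(bad))
          note("entity '%s' maps to %s: absent from the extracted model",
               nm, paste(bad, collapse = ", "))
      }
    }
  }
  diags
}

`%||%` <- function(a, b) if (is.null(a)) b else a
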