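## ---------------------------------------------------------------------------
## Fixture generators: small models with known closed-form or qualitative
## behaviour, plus matching experiment documents whose readouts are the
## model's own simulated output (optionally with Gaussian noise). Every
## stage of the pipeline is testable from these with zero downloads.
## ---------------------------------------------------------------------------

#' Reversible-binding toy model
#'
#' `R + L <-> RL` in one pathway group `/binding`, with the equilibrium
#' isotherm known analytically: `RL_ss = Rtot * L / (Kd + L)` for clamped
#' ligand, `Kd = Kb / Kf`.
#'
#' @param Rtot total receptor, mM
#' @param Kf association rate, 1/(mM s)
#' @param Kb dissociation rate, 1/s
#' @return a `ReactionModel`; the dissociation constant is attached as
#'   attribute `Kd`
#' @export
make_binding_model <- function(Rtot = 1, Kf = 1, Kb = 1) {
  stopifnot(Rtot > 0, Kf > 0, Kb > 0)
  m <- new_reaction_model("binding")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/binding")
  m <- add_pool(m, "/binding/R", concInit = Rtot)
  m <- add_pool(m, "/binding/L", concInit = 0)
  m <- add_pool(m, "/binding/RL", concInit = 0)
  m <- add_reaction(m, "/binding/bind",
                    substrates = c("/binding/R" = 1, "/binding/L" = 1),
                    products = c("/binding/RL" = 1), Kf = Kf, Kb = Kb)
  attr(m, "Kd") <- Kb / Kf
  m
}

#' Kinase-cascade toy model
#'
#' A chain of `tiers` activation steps (Michaelis-Menten activation by the
#' tier above, first-order relaxation back) grouped as nested pathways
#' under `/core`, with two distinct input pathway groups (`/input_EGF`,
#' `/input_Ca`) converging on the top tier — the shape needed to exercise
#' subset selection.
#'
#' @param tiers number of cascade tiers, 1..4
#' @return a `ReactionModel`; the top-tier active pool path is attached as
#'   attribute `readout`
#' @export
make_cascade_model <- function(tiers = 3) {
  stopifnot(tiers >= 1, tiers <= 4)
  m <- new_reaction_model("cascade")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/core")
  m <- add_group(m, "/input_EGF")
  m <- add_group(m, "/input_Ca")
  m <- add_pool(m, "/input_EGF/EGF", concInit = 0)
  m <- add_pool(m, "/input_Ca/Ca", concInit = 0)
  for (i in seq_len(tiers)) {
    g <- sprintf("/core/tier%d", i)
    inact <- sprintf("%s/T%d", g, i)
    act <- sprintf("%s/T%d_a", g, i)
    m <- add_group(m, g)
    m <- add_pool(m, inact, concInit = 1)
    m <- add_pool(m, act, concInit = 0)
    if (i == 1L) {
      m <- add_enzyme(m, sprintf("%s/act_EGF", g), "/input_EGF/EGF",
                      inact, act, Km = 0.5, kcat = 1)
      m <- add_enzyme(m, sprintf("%s/act_Ca", g), "/input_Ca/Ca",
                      inact, act, Km = 0.5, kcat = 1)
    } else {
      m <- add_enzyme(m, sprintf("%s/act", g), sprintf("/core/tier%d/T%d_a", i - 1L, i - 1L),
                      inact, act, Km = 0.5, kcat = 1)
    }
    m <- add_reaction(m, sprintf("%s/relax", g),
                      substrates = stats::setNames(1, act),
                      products = stats::setNames(1, inact), Kf = 0.2, Kb = 0)
  }
  attr(m, "readout") <- sprintf("/core/tier%d/T%d_a", tiers, tiers)
  m
}

#' Bistable positive-feedback switch
#'
#' Two species (`X`, `Y`) in mutual Michaelis-Menten activation with
#' saturable (zero-order) dephosphorylation — a system with two stable
#' fixed points. The low state is globally attracting for small
#' perturbations; a suprathreshold transient input through `/input/Ca`
#' flips it to a sustained high state. Tetanus-like calcium pulse trains
#' are the intended stimulus.
#'
#' @return a `ReactionModel`; readout pool attached as attribute `readout`
#' @export
make_bistable_model <- function() {
  m <- new_reaction_model("bistable")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/switch")
  m <- add_group(m, "/input")
  m <- add_pool(m, "/switch/Xi", concInit = 1)
  m <- add_pool(m, "/switch/Xa", concInit = 0)
  m <- add_pool(m, "/switch/Yi", concInit = 1)
  m <- add_pool(m, "/switch/Ya", concInit = 0)
  m <- add_pool(m, "/switch/PX", concInit = 1, buffered = TRUE)
  m <- add_pool(m, "/switch/PY", concInit = 1, buffered = TRUE)
  m <- add_pool(m, "/input/Ca", concInit = 0)
  m <- add_enzyme(m, "/switch/actX", "/switch/Ya", "/switch/Xi", "/switch/Xa",
                  Km = 0.5, kcat = 1)
  m <- add_enzyme(m, "/switch/actY", "/switch/Xa", "/switch/Yi", "/switch/Ya",
                  Km = 0.5, kcat = 1)
  m <- add_enzyme(m, "/switch/deactX", "/switch/PX", "/switch/Xa", "/switch/Xi",
                  Km = 0.05, kcat = 0.2)
  m <- add_enzyme(m, "/switch/deactY", "/switch/PY", "/switch/Ya", "/switch/Yi",
                  Km = 0.05, kcat = 0.2)
  m <- add_enzyme(m, "/input/stim", "/input/Ca", "/switch/Xi", "/switch/Xa",
                  Km = 0.5, kcat = 1)
  attr(m, "readout") <- "/switch/Xa"
  m
}

#' Calcium pulse-train schedule for the bistable switch
#'
#' `n` square pulses of the given amplitude and width, separated by
#' `spacing` seconds (onset-to-onset) — the classic LTP-induction tetanus
#' pattern.
#'
#' @param amplitude pulse amplitude, mM
#' @param n number of pulses
#' @param spacing onset-to-onset separation, s
#' @param width pulse width, s
#' @param entity stimulated pool path
#' @return a `StimulusSchedule`
#' @export
make_pulse_train <- function(amplitude, n = 3, spacing = 600, width = 10,
                             entity = "/input/Ca") {
  ev <- list()
  for (k in seq_len(n)) {
    t0 <- (k - 1) * spacing
    ev[[length(ev) + 1L]] <- list(time = t0, entity = entity,
                                  field = "conc", value = amplitude)
    ev[[length(ev) + 1L]] <- list(time = t0 + width, entity = entity,
                                  field = "conc", value = 0)
  }
  stimulus_schedule(ev)
}

#' Default squid-axon Hodgkin-Huxley model
#'
#' A `ReactionModel` shell carrying the classic HH parameter block under
#' the `hh` solver tag, storable in the native model dialect.
#'
#' @return a `ReactionModel` with `$hh` set and `solver = "hh"`
#' @export
make_hh_model <- function() {
  m <- new_reaction_model("squid_axon")
  m <- add_compartment(m, "soma", volume = 1e-12)
  m$solver <- "hh"
  m$hh <- hh_compartment()
  m
}

#' Translation-initiation fixture: model plus experiment
#'
#' A binding step in which the 40S ribosomal subunit is applied to a
#' solution with a known amount of eIF4E-mRNA and formation of the 43S
#' complex is monitored over time. The model also carries an extraneous
#' side pathway (an IRES sequestering 40S) that the experiment's subset
#' specification deletes, exercising the extraction/deletion path.
#'
#' @param applied40S concentration of 40S applied at t = 0, mM
#' @return `list(model, doc)` — the `ReactionModel` and a matching
#'   self-consistent `ExperimentDoc`
#' @export
make_translation_fixture <- function(applied40S = 0.5) {
  m <- new_reaction_model("translation")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/translation")
  m <- add_group(m, "/side")
  m <- add_pool(m, "/translation/40S", concInit = 0)
  m <- add_pool(m, "/translation/eIF4E-mRNA", concInit = 0.5)
  m <- add_pool(m, "/translation/43S", concInit = 0)
  m <- add_reaction(m, "/translation/assoc",
                    substrates = c("/translation/40S" = 1,
                                   "/translation/eIF4E-mRNA" = 1),
                    products = c("/translation/43S" = 1), Kf = 1, Kb = 0.1)
  m <- add_pool(m, "/side/IRES", concInit = 0.3)
  m <- add_pool(m, "/side/40S_IRES", concInit = 0)
  m <- add_reaction(m, "/side/sequester",
                    substrates = c("/translation/40S" = 1, "/side/IRES" = 1),
                    products = c("/side/40S_IRES" = 1), Kf = 2, Kb = 0.05)
  doc <- make_experiment_fixture("TimeSeries", m,
                                 stimulusEntity = "40S",
                                 stimulusValue = applied40S,
                                 readoutEntity = "43S",
                                 includePaths = c("/translation", "/side"),
                                 deletePaths = "/side",
                                 entityMap = list(
                                   "40S" = "/translation/40S",
                                   "eIF4E-mRNA" = "/translation/eIF4E-mRNA",
                                   "43S" = "/translation/43S"),
                                 coords = seq(2, 32, by = 6),
                                 tEnd = 40, dtOut = 0.2,
                                 experimentId = "translation_ts")
  list(model = m, doc = doc)
}

fixture_metadata <- function() {
  list(transcriber = "fixture generator", organization = "expsim",
       exptSource = "inHouse", citationId = "", authors = "",
       journal = "")
}

fixture_context <- function(noise_sd, seed) {
  list(species = "synthetic", cellType = "synthetic",
       preparation = "in silico", temperature = 25, pH = 7.2,
       notes = sprintf("synthetic fixture; gaussian noise sd=%g; seed=%d",
                       noise_sd, seed))
}

#' Generate a valid experiment document of a given class
#'
#' The readouts are the model's own simulated output (through the same
#' extraction + simulation path the pipeline uses), plus optional Gaussian
#' noise of stated sd under a recorded seed — so a noise-free fixture
#' scores ~0 against its source model by construction.
#'
#' @param class `"TimeSeries"`, `"DoseResponse"`, `"MultiStimulus"` or
#'   `"CurrentClamp"` (an electrical time-series)
#' @param model source `ReactionModel`; defaults per class (binding model,
#'   cascade for MultiStimulus, squid axon for CurrentClamp)
#' @param noise_sd Gaussian noise sd added to readout values (canonical
#'   units); 0 for a noise-free fixture
#' @param seed RNG seed, recorded in the context notes
#' @param weight experiment weight for battery aggregation
#' @param stimulusEntity,stimulusValue,readoutEntity,entityMap,includePaths,deletePaths
#'   mapping controls (sensible defaults per class)
#' @param coords readout coordinates (times or doses; labels for
#'   MultiStimulus are the combination names)
#' @param tEnd,dtOut,settle,tMax simulation controls
#' @param experimentId identifier
#' @return an `ExperimentDoc`
#' @export
make_experiment_fixture <- function(class = c("TimeSeries", "DoseResponse",
                                              "MultiStimulus", "CurrentClamp"),
                                    model = NULL, noise_sd = 0, seed = 1L,
                                    weight = 1,
                                    stimulusEntity = NULL, stimulusValue = NULL,
                                    readoutEntity = NULL, entityMap = NULL,
                                    includePaths = NULL, deletePaths = character(0),
                                    coords = NULL, tEnd = NULL, dtOut = NULL,
                                    settle = NULL, tMax = 1e5,
                                    experimentId = NULL) {
  class <- match.arg(class)
  set.seed(seed)

  if (class == "CurrentClamp") {
    if (is.null(model)) model <- make_hh_model()
    if (is.null(tEnd)) tEnd <- 0.1
    if (is.null(dtOut)) dtOut <- 1e-4
    if (is.null(coords)) coords <- seq(0.005, 0.095, by = 0.005)
    if (is.null(stimulusValue)) stimulusValue <- 10  # uA/cm^2 step
    stim <- list(entityName = "electrode", field = "current", unit = "uA",
                 timeUnit = "s",
                 points = data.frame(time = c(0.02, 0.08),
                                     value = c(stimulusValue, 0)))
    sched <- stimulus_schedule(list(
      list(time = 0.02, entity = "electrode", field = "current",
           value = stimulusValue),
      list(time = 0.08, entity = "electrode", field = "current", value = 0)))
    sim <- run_current_clamp(model$hh, sched, tEnd = tEnd, dtOut = dtOut)
    vals <- stats::approx(sim$times, sim$trajectories$Vm, xout = coords)$y
    vals <- vals + stats::rnorm(length(vals), sd = noise_sd)
    return(experiment_doc(
      exptType = "TimeSeries",
      experimentId = experimentId %||% "hh_current_clamp",
      metadata = fixture_metadata(),
      context = fixture_context(noise_sd, seed),
      stimuli = list(stim),
      readouts = list(list(entityName = "Vm", field = "Vm", unit = "mV",
                           normalization = "absolute", timeUnit = "s",
                           points = data.frame(coord = coords, value = vals,
                                               stderr = NA_real_))),
      modelMap = list(refModel = "hh.model", solver = "hh", weight = weight,
                      scoringFormula = DEFAULT_SCORE_FORMULA,
                      subset = subset_spec("/"),
                      tEnd = tEnd, dtOut = dtOut, settle = NA_real_,
                      tMax = tMax, tol = 1e-6)))
  }

  if (is.null(model))
    model <- if (class == "MultiStimulus") make_cascade_model() else make_binding_model()

  defaults_binding <- !is.null(attr(model, "Kd"))
  Kd <- attr(model, "Kd") %||% 1
  if (is.null(stimulusEntity)) stimulusEntity <- if (defaults_binding) "L" else "EGF"
  if (is.null(readoutEntity))
    readoutEntity <- if (defaults_binding) "RL" else basename(attr(model, "readout"))
  if (is.null(entityMap)) {
    entityMap <- if (defaults_binding)
      list(R = "/binding/R", L = "/binding/L", RL = "/binding/RL")
    else stats::setNames(list("/input_EGF/EGF", "/input_Ca/Ca",
                              attr(model, "readout")),
                         c("EGF", "Ca", readoutEntity))
  }
  if (is.null(includePaths))
    includePaths <- if (defaults_binding) "/binding" else
      c("/core", "/input_EGF", "/input_Ca")

  subset <- subset_spec(includePaths = includePaths, deletePaths = deletePaths,
                        entityMap = entityMap)
  mm <- list(refModel = paste0(model$name, ".model"), solver = "ode_stiff",
             weight = weight, scoringFormula = DEFAULT_SCORE_FORMULA,
             subset = subset, tEnd = NA_real_, dtOut = NA_real_,
             settle = NA_real_, tMax = tMax, tol = 1e-6)

  stimuli <- list(); readout_points <- NULL; combinations <- NULL

  if (class == "TimeSeries") {
    if (is.null(stimulusValue)) stimulusValue <- 2 * Kd
    if (is.null(coords)) coords <- seq(1, 16, by = 3)
    if (is.null(tEnd)) tEnd <- max(coords) * 1.25
    if (is.null(dtOut)) dtOut <- tEnd / 200
    mm$tEnd <- tEnd; mm$dtOut <- dtOut
    if (!is.null(settle)) mm$settle <- settle
    stimuli <- list(list(entityName = stimulusEntity, field = "conc",
                         unit = "mM", timeUnit = "s",
                         points = data.frame(time = 0, value = stimulusValue)))
  } else if (class == "DoseResponse") {
    if (is.null(coords)) coords <- Kd * c(0.01, 0.1, 0.3, 1, 3, 10, 100)
    stimuli <- list(list(entityName = stimulusEntity, field = "conc",
                         unit = "mM", timeUnit = "s",
                         points = data.frame(dose = coords)))
  } else { # MultiStimulus
    if (is.null(settle)) settle <- 200
    mm$settle <- settle
    combinations <- list(
      control = list(),
      EGF = list(list(entity = "EGF", field = "conc", value = 1, unit = "mM")),
      Ca = list(list(entity = "Ca", field = "conc", value = 0.5, unit = "mM")),
      "EGF+Ca" = list(list(entity = "EGF", field = "conc", value = 1, unit = "mM"),
                      list(entity = "Ca", field = "conc", value = 0.5, unit = "mM")))
    coords <- names(combinations)
  }

  ## skeleton document; readout points are filled from the simulation
  skeleton <- structure(list(
    exptType = if (class == "MultiStimulus") "MultiStimulus" else class,
    experimentId = experimentId %||% tolower(paste0(model$name, "_", class)),
    metadata = fixture_metadata(),
    context = fixture_context(noise_sd, seed),
    stimuli = stimuli,
    readouts = list(list(entityName = readoutEntity, field = "conc",
                         unit = "mM", normalization = "absolute",
                         timeUnit = "s",
                         points = if (class == "MultiStimulus")
                           data.frame(coord = character(0), value = numeric(0),
                                      stderr = numeric(0), stringsAsFactors = FALSE)
                         else data.frame(coord = numeric(0), value = numeric(0),
                                         stderr = numeric(0)))),
    combinations = combinations,
    modelMap = mm), class = "ExperimentDoc")

  ext <- extract_subset(model, subset, policy = "strict")
  sim <- simulate_experiment(ext$model, skeleton, ext$entityMap)
  vals <- if (class == "MultiStimulus") {
    sim$trajectories[[readoutEntity]][match(coords, sim$labels)]
  } else {
    stats::approx(sim$times, sim$trajectories[[readoutEntity]], xout = coords)$y
  }
  vals <- vals + stats::rnorm(length(vals), sd = noise_sd)

  skeleton$readouts[[1L]]$points <-
    if (class == "MultiStimulus")
      data.frame(coord = coords, value = vals, stderr = NA_real_,
                 stringsAsFactors = FALSE)
    else data.frame(coord = coords, value = vals, stderr = NA_real_)

  experiment_doc(exptType = skeleton$exptType,
                 experimentId = skeleton$experimentId,
                 metadata = skeleton$metadata, context = skeleton$context,
                 stimuli = skeleton$stimuli, readouts = skeleton$readouts,
                 combinations = skeleton$combinations,
                 modelMap = skeleton$modelMap)
}

merge_models <- function(models, name = "composite") {
  out <- new_reaction_model(name)
  for (m in models) {
    for (cm in m$compartments)
      if (is.null(out$compartments[[cm$name]]))
        out <- add_compartment(out, cm$name, cm$volume)
    for (g in m$groups) if (!(g %in% out$groups)) out <- add_group(out, g)
    for (p in m$pools)
      out <- add_pool(out, p$path, p$concInit, p$buffered, p$compartment)
    for (r in m$reactions)
      out <- add_reaction(out, r$path, r$substrates, r$products, r$Kf, r$Kb)
    for (e in m$enzymes)
      out <- add_enzyme(out, e$path, e$enzymePool, e$substrate, e$product,
                        e$Km, e$kcat)
  }
  out
}

#' Write the complete fixture suite to a directory
#'
#' Emits the toy models (native dialect), one self-consistent experiment
#' file per experiment class, a composite model combining the chemical
#' pathways (binding, cascade, translation, bistable switch) under
#' disjoint groups, and a battery manifest running the chemical
#' experiments against the composite model.
#'
#' @param dir output directory (created if needed)
#' @param noise_sd Gaussian readout noise (0 = self-consistent fixtures)
#' @param seed RNG seed for the noise
#' @return named list of the paths written, invisibly
#' @export
make_fixture_suite <- function(dir, noise_sd = 0, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  w <- function(key, file) { paths[[key]] <<- file.path(dir, file); paths[[key]] }

  binding <- make_binding_model()
  cascade <- make_cascade_model()
  bist <- make_bistable_model()
  trans <- make_translation_fixture()
  hh <- make_hh_model()
  composite <- merge_models(list(binding, cascade, trans$model, bist))

  write_native_model(binding, w("binding_model", "binding.model"))
  write_native_model(cascade, w("cascade_model", "cascade.model"))
  write_native_model(bist, w("bistable_model", "bistable.model"))
  write_native_model(trans$model, w("translation_model", "translation.model"))
  write_native_model(hh, w("hh_model", "hh.model"))
  write_native_model(composite, w("composite_model", "composite.model"))
  export_sbml(binding, w("binding_sbml", "binding.sbml"))

  ts <- make_experiment_fixture("TimeSeries", binding, noise_sd = noise_sd,
                                seed = seed, experimentId = "binding_ts")
  dr <- make_experiment_fixture("DoseResponse", binding, noise_sd = noise_sd,
                                seed = seed + 1L, experimentId = "binding_dr")
  ms <- make_experiment_fixture("MultiStimulus", cascade, noise_sd = noise_sd,
                                seed = seed + 2L, experimentId = "cascade_ms")
  cc <- make_experiment_fixture("CurrentClamp", hh, noise_sd = noise_sd,
                                seed = seed + 3L, experimentId = "hh_cc")
  write_experiment_tsv(ts, w("binding_ts", "binding_ts.tsv"))
  write_experiment_tsv(dr, w("binding_dr", "binding_dr.tsv"))
  write_experiment_tsv(ms, w("cascade_ms", "cascade_ms.tsv"))
  write_experiment_tsv(trans$doc, w("translation_ts", "translation_ts.tsv"))
  write_experiment_tsv(cc, w("hh_cc", "hh_cc.tsv"))

  manifest <- w("manifest", "battery.tsv")
  writeLines(c("# battery manifest: experiment file <TAB> optional weight",
               "binding_ts.tsv\t1", "binding_dr.tsv\t1",
               "cascade_ms.tsv\t1", "translation_ts.tsv\t1"),
             manifest)
  invisible(paths)
}
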