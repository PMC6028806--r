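## ---------------------------------------------------------------------------
## Pipeline orchestration: run one experiment against a model, run a
## weighted battery, and locally optimize parameters against the battery
## score. Also the command-line front end (cli_main).
## ---------------------------------------------------------------------------

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_expsim("%s: %s", stage, conditionMessage(e))
  })
}

## readout name -> model pool paths (entity map with identity fallback)
build_readout_map <- function(doc, emap, model) {
  out <- list()
  for (r in doc$readouts) {
    nm <- r$entityName
    targets <- if (!is.null(emap[[nm]])) emap[[nm]] else nm
    bad <- setdiff(targets, names(model$pools))
    if (length(bad))
      stop_expsim("readout '%s' maps to %s: not a pool in the extracted model",
                  nm, paste(bad, collapse = ", "))
    out[[nm]] <- targets
  }
  out
}

map_entity <- function(name, emap, model, role) {
  targets <- if (!is.null(emap[[name]])) emap[[name]] else name
  bad <- setdiff(targets, names(model$pools))
  if (length(bad))
    stop_expsim("%s entity '%s' maps to %s: not a pool in the extracted model",
                role, name, paste(bad, collapse = ", "))
  targets
}

simulate_experiment <- function(model, doc, emap) {
  mm <- doc$modelMap
  if (mm$solver == "hh") {
    if (is.null(model$hh))
      stop_expsim("experiment requests the 'hh' solver but the model carries no Hodgkin-Huxley block")
    if (length(doc$stimuli) != 1L)
      stop_expsim("current-clamp experiments need exactly one current stimulus")
    s <- doc$stimuli[[1L]]
    if (s$field != "current")
      stop_expsim("hh solver requires a stimulus with field 'current'")
    events <- lapply(seq_len(nrow(s$points)), function(i)
      list(time = s$points$time[[i]], entity = s$entityName,
           field = "current", value = s$points$value[[i]]))
    tEnd <- mm$tEnd
    if (is.na(tEnd)) tEnd <- max(vapply(doc$readouts,
                                        function(r) max(r$points$coord), 0))
    dtOut <- mm$dtOut
    if (is.na(dtOut)) dtOut <- tEnd / 1000
    return(run_current_clamp(model$hh, stimulus_schedule(events),
                             tEnd = tEnd, dtOut = dtOut))
  }

  switch(doc$exptType,
    TimeSeries = {
      events <- list()
      for (s in doc$stimuli) {
        targets <- map_entity(s$entityName, emap, model, "stimulus")
        for (i in seq_len(nrow(s$points)))
          for (tg in targets)
            events[[length(events) + 1L]] <-
              list(time = s$points$time[[i]], entity = tg,
                   field = if (s$field == "concInit") "conc" else s$field,
                   value = s$points$value[[i]])
      }
      tEnd <- mm$tEnd
      if (is.na(tEnd))
        tEnd <- max(c(vapply(doc$readouts, function(r) max(r$points$coord), 0),
                      vapply(events, `[[`, 0, "time") * 1.0001 + 1e-9))
      dtOut <- mm$dtOut
      if (is.na(dtOut)) dtOut <- tEnd / 200
      run_time_series(model, stimulus_schedule(events),
                      build_readout_map(doc, emap, model),
                      tEnd = tEnd, dtOut = dtOut, settle = mm$settle,
                      solver = mm$solver)
    },
    DoseResponse = {
      s <- doc$stimuli[[1L]]
      target <- map_entity(s$entityName, emap, model, "dose")[[1L]]
      run_dose_response(model, target, s$points$dose,
                        build_readout_map(doc, emap, model),
                        tMax = mm$tMax, tol = mm$tol, solver = mm$solver)
    },
    MultiStimulus = {
      combos <- lapply(doc$combinations, function(cb)
        lapply(cb, function(st) {
          tg <- map_entity(st$entity, emap, model, "setting")
          list(entity = tg[[1L]], field = st$field, value = st$value)
        }))
      settle <- mm$settle
      if (is.null(settle) || is.na(settle))
        stop_expsim("MultiStimulus experiments must state a settle time")
      run_multi_stim(model, combos, build_readout_map(doc, emap, model),
                     settle = settle, solver = mm$solver)
    },
    stop_expsim("unknown experiment type '%s'", doc$exptType))
}

#' Run one experiment against one model
#'
#' The full pipeline: load the model, parse the experiment, extract and
#' condition the experiment-specific sub-model, simulate according to the
#' experiment class, and score simulation against readouts.
#'
#' @param modelFile model file (native dialect or SBML)
#' @param exptFile experiment definition (tsv or JSON mirror)
#' @param prune drop dangling reactions instead of failing (logged)
#' @param dumpSubset optional path: write the extracted sub-model as SBML
#' @param outDir optional directory for artifacts (comparison table and
#'   a comparison figure)
#' @param quiet suppress stage logging
#' @return a `ScoreResult` with the `SimOutput` attached as `$sim`
#' @export
run_single <- function(modelFile, exptFile, prune = FALSE, dumpSubset = NULL,
                       outDir = NULL, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else log_stage
  say("load", "model '%s'", modelFile)
  model <- stage_wrap("load", load_model(modelFile))
  say("parse", "experiment '%s'", exptFile)
  doc <- stage_wrap("parse", parse_experiment_tsv(exptFile))

  if (doc$modelMap$solver == "hh") {
    sub <- model; emap <- doc$modelMap$subset$entityMap
  } else {
    say("extract", "subset (%s policy)", if (prune) "prune" else "strict")
    ext <- stage_wrap("extract",
                      extract_subset(model, doc$modelMap$subset,
                                     policy = if (prune) "prune" else "strict"))
    sub <- ext$model; emap <- ext$entityMap
    if (!is.null(dumpSubset)) {
      say("extract", "writing extracted sub-model to '%s'", dumpSubset)
      export_sbml(sub, dumpSubset)
    }
  }

  say("simulate", "%s experiment '%s'", doc$exptType, doc$experimentId)
  sim <- stage_wrap("simulate", simulate_experiment(sub, doc, emap))
  say("score", "evaluating '%s'", doc$modelMap$scoringFormula)
  res <- stage_wrap("score", score_experiment(doc, sim))
  res$sim <- sim

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res$comparison,
                       file.path(outDir, paste0(doc$experimentId, "_comparison.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    plot_path <- file.path(outDir, paste0(doc$experimentId, "_comparison.pdf"))
    tryCatch({
      grDevices::pdf(plot_path, width = 6, height = 4)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_comparison(doc, res)
    }, error = function(e)
      warning(sprintf("could not draw comparison figure: %s",
                      conditionMessage(e)), call. = FALSE))
  }
  res
}

plot_comparison <- function(doc, res) {
  cmp <- res$comparison
  if (doc$exptType == "MultiStimulus") {
    h <- rbind(expt = cmp$expt, sim = cmp$sim)
    graphics::barplot(h, beside = TRUE, names.arg = cmp$coordinate,
                      legend.text = TRUE, ylab = "readout",
                      main = sprintf("%s (score %.4g)", doc$experimentId, res$score))
  } else {
    xlab <- if (doc$exptType == "DoseResponse") "dose (mM)" else "time (s)"
    graphics::plot(cmp$coordinate, cmp$expt, pch = 19, xlab = xlab,
                   ylab = "readout", log = if (doc$exptType == "DoseResponse" &&
                                               all(cmp$coordinate > 0)) "x" else "",
                   main = sprintf("%s (score %.4g)", doc$experimentId, res$score))
    graphics::lines(cmp$coordinate, cmp$sim, col = "firebrick", lwd = 2)
    graphics::legend("topleft", c("experiment", "simulation"), bty = "n",
                     pch = c(19, NA), lty = c(NA, 1),
                     col = c("black", "firebrick"))
  }
}

#' Read a battery manifest
#'
#' Tab-separated lines `experimentFile [weightOverride]`; '#' comments and
#' blank lines ignored. Relative experiment paths resolve against the
#' manifest's directory.
#'
#' @param manifest file path
#' @return data.frame with columns exptFile, weight (NA = use the
#'   experiment's own weight)
#' @export
read_battery_manifest <- function(manifest) {
  lines <- readLines(manifest, encoding = "UTF-8")
  base <- dirname(normalizePath(manifest))
  rows <- list()
  for (raw in lines) {
    if (!nzchar(trimws(raw)) || startsWith(trimws(raw), "#")) next
    f <- strsplit(raw, "\t", fixed = TRUE)[[1]]
    p <- f[[1]]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    w <- if (length(f) >= 2L && nzchar(f[[2]])) as.numeric(f[[2]]) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(exptFile = p, weight = w,
                                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop_expsim("battery manifest '%s' is empty", manifest)
  do.call(rbind, rows)
}

#' Run a battery of experiments against one model
#'
#' Experiments are independent (results do not depend on execution order or
#' on `jobs`); per-experiment failures are recorded in the report and do
#' not abort the battery.
#'
#' @param modelFile model file path
#' @param manifest battery manifest path (see [read_battery_manifest()]),
#'   or a data.frame of the same shape
#' @param jobs number of worker processes (forked; results identical for
#'   any value)
#' @param prune passed to [run_single()]
#' @param quiet suppress stage logging
#' @return list with `results` (data.frame: experiment, score, weight,
#'   status, message) and `global` (weighted mean score over successes)
#' @export
run_battery <- function(modelFile, manifest, jobs = 1, prune = FALSE,
                        quiet = TRUE) {
  entries <- if (is.data.frame(manifest)) manifest else
    read_battery_manifest(manifest)
  run_one <- function(i) {
    ef <- entries$exptFile[[i]]
    res <- tryCatch(run_single(modelFile, ef, prune = prune, quiet = quiet),
                    error = function(e) e)
    if (inherits(res, "error")) {
      list(experiment = basename(ef), score = NA_real_, weight = NA_real_,
           status = "error", message = conditionMessage(res), result = NULL)
    } else {
      w <- if (!is.na(entries$weight[[i]])) entries$weight[[i]] else res$weight
      res$weight <- w
      list(experiment = res$experimentId, score = res$score, weight = w,
           status = "ok", message = "", result = res)
    }
  }
  idx <- seq_len(nrow(entries))
  rows <- if (jobs > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = jobs, mc.preschedule = TRUE)
  } else {
    lapply(idx, run_one)
  }
  report <- do.call(rbind, lapply(rows, function(r)
    data.frame(experiment = r$experiment, score = r$score, weight = r$weight,
               status = r$status, message = r$message, stringsAsFactors = FALSE)))
  ok <- Filter(function(r) r$status == "ok", rows)
  global <- if (length(ok)) aggregate_battery(lapply(ok, `[[`, "result")) else NA_real_
  list(results = report, global = global)
}

#' Write a battery report
#'
#' Emits the per-experiment table as tab-separated text and a JSON summary.
#'
#' @param report return value of [run_battery()]
#' @param outDir output directory
#' @export
write_battery_report <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$results, file.path(outDir, "battery_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(global = report$global,
         experiments = report$results),
    file.path(outDir, "battery_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(outDir)
}

get_param_value <- function(model, path, field) {
  if (!is.null(model$pools[[path]])) return(model$pools[[path]][[field]])
  if (!is.null(model$reactions[[path]])) return(model$reactions[[path]][[field]])
  if (!is.null(model$enzymes[[path]])) return(model$enzymes[[path]][[field]])
  stop_expsim("parameter target '%s' not found in model", path)
}

#' Locally optimize model parameters against a battery score
#'
#' Derivative-free local minimization of the weighted battery score over
#' the listed parameters, within their bounds: Brent search for one free
#' parameter, Nelder-Mead on logit-transformed coordinates otherwise.
#' The returned model never scores worse than the input model.
#'
#' @param modelFile model file path
#' @param manifest battery manifest path or data.frame
#' @param paramList data.frame with columns path, field, lower, upper
#' @param maxiter iteration budget
#' @param seed integer seed (recorded; the optimizer itself is
#'   deterministic)
#' @param outModel optional path for the tuned model (native dialect)
#' @param quiet suppress logging
#' @return list: model (tuned `ReactionModel`), initialScore, finalScore,
#'   params (data.frame with initial and fitted values), trace
#'   (data.frame of evaluations), method
#' @export
optimize_parameters <- function(modelFile, manifest, paramList, maxiter = 200,
                                seed = 1, outModel = NULL, quiet = TRUE) {
  if (is.null(paramList) || nrow(paramList) == 0L)
    stop_expsim("paramList must name at least one parameter")
  for (cn in c("path", "field", "lower", "upper"))
    if (!(cn %in% names(paramList)))
      stop_expsim("paramList needs a '%s' column", cn)
  if (any(!is.finite(paramList$lower)) || any(!is.finite(paramList$upper)) ||
      any(paramList$upper <= paramList$lower))
    stop_expsim("parameter bounds must be finite with lower < upper")
  set.seed(seed)

  base <- load_model(modelFile)
  entries <- if (is.data.frame(manifest)) manifest else
    read_battery_manifest(manifest)

  tmp_model <- tempfile(fileext = ".model")
  on.exit(unlink(tmp_model), add = TRUE)
  trace <- list()

  objective <- function(theta) {
    m <- base
    ov <- lapply(seq_len(nrow(paramList)), function(i)
      list(path = paramList$path[[i]], field = paramList$field[[i]],
           value = theta[[i]]))
    m <- apply_condition(m, ov)
    write_native_model(m, tmp_model)
    rep <- run_battery(tmp_model, entries, quiet = TRUE)
    if (any(rep$results$status != "ok"))
      stop_expsim("battery failure during optimization: %s",
                  paste(rep$results$message[rep$results$status != "ok"],
                        collapse = "; "))
    trace[[length(trace) + 1L]] <<- c(theta, score = rep$global)
    rep$global
  }

  theta0 <- vapply(seq_len(nrow(paramList)), function(i)
    get_param_value(base, paramList$path[[i]], paramList$field[[i]]), 0)
  lo <- paramList$lower; hi <- paramList$upper
  theta0 <- pmin(pmax(theta0, lo + (hi - lo) * 1e-6), hi - (hi - lo) * 1e-6)
  f0 <- objective(theta0)

  if (nrow(paramList) == 1L) {
    method <- "Brent (bounded scalar search)"
    opt <- stats::optimize(function(x) objective(x),
                           interval = c(lo[[1L]], hi[[1L]]), tol = 1e-8)
    theta_hat <- opt$minimum; f_hat <- opt$objective
    ## polish: Brent can stall on flat shoulders; refine around the optimum
    w <- (hi[[1L]] - lo[[1L]]) * 0.02
    opt2 <- stats::optimize(function(x) objective(x),
                            interval = c(max(lo[[1L]], theta_hat - w),
                                         min(hi[[1L]], theta_hat + w)),
                            tol = 1e-10)
    if (opt2$objective < f_hat) { theta_hat <- opt2$minimum; f_hat <- opt2$objective }
  } else {
    method <- "Nelder-Mead on logit-transformed bounded coordinates"
    to_z <- function(x) stats::qlogis((x - lo) / (hi - lo))
    to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
    opt <- stats::optim(to_z(theta0), function(z) objective(to_x(z)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxiter, reltol = 1e-10))
    theta_hat <- to_x(opt$par); f_hat <- opt$value
  }

  if (f_hat > f0) { theta_hat <- theta0; f_hat <- f0 }  # never degrade

  trace_df <- as.data.frame(do.call(rbind, trace))
  names(trace_df) <- c(paste0(paramList$path, ":", paramList$field), "score")
  flat <- (max(trace_df$score) - min(trace_df$score)) < 1e-12
  if (flat)
    warning("parameter(s) appear unidentifiable: battery score flat to tolerance",
            call. = FALSE)

  tuned <- apply_condition(base, lapply(seq_len(nrow(paramList)), function(i)
    list(path = paramList$path[[i]], field = paramList$field[[i]],
         value = theta_hat[[i]])))
  if (!is.null(outModel)) write_native_model(tuned, outModel)
  if (!quiet)
    log_stage("optimize", "score %.6g -> %.6g (%s)", f0, f_hat, method)
  list(model = tuned, initialScore = f0, finalScore = f_hat,
       params = data.frame(path = paramList$path, field = paramList$field,
                           initial = vapply(seq_len(nrow(paramList)), function(i)
                             get_param_value(base, paramList$path[[i]],
                                             paramList$field[[i]]), 0),
                           fitted = theta_hat, stringsAsFactors = FALSE),
       trace = trace_df, method = method, seed = seed,
       unidentifiable = flat)
}

## ---- command line ---------------------------------------------------------

parse_cli_flags <- function(argv) {
  flags <- list(); positional <- character(0)
  i <- 1L
  bools <- c("--prune", "--quiet")
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (a %in% bools) { flags[[key]] <- TRUE; i <- i + 1L }
      else {
        if (i == length(argv)) stop_expsim("flag %s needs a value", a)
        flags[[key]] <- argv[[i + 1L]]; i <- i + 2L
      }
    } else { positional <- c(positional, a); i <- i + 1L }
  }
  ## config file: key=value lines mirroring the flags
  if (!is.null(flags$config)) {
    for (raw in readLines(flags$config)) {
      raw <- trimws(raw)
      if (!nzchar(raw) || startsWith(raw, "#")) next
      kv <- strsplit(raw, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[[1]])
      if (is.null(flags[[key]]))  # explicit flags win over config
        flags[[key]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  list(flags = flags, positional = positional)
}

read_param_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("path", "field", "lower", "upper"),
                          comment.char = "#", stringsAsFactors = FALSE)
  df
}

#' Command-line entry point
#'
#' Subcommands: `run --model M --expt E [--prune] [--dump-subset F]
#' [--out DIR]`; `battery --model M --manifest F [--jobs N] [--out DIR]`;
#' `optimize --model M --manifest F --params F [--seed N] [--maxiter N]
#' [--out DIR]`. A `--config FILE` of `key=value` lines mirrors any flag.
#' Invoked by the `inst/cli/expsim` script; callable in-process for tests.
#'
#' @param argv character vector of arguments (excluding the program name)
#' @return exit status, invisibly (0 on success)
#' @export
cli_main <- function(argv) {
  status <- tryCatch({
    if (length(argv) < 1L)
      stop_expsim("usage: expsim <run|battery|optimize> [flags]")
    cmd <- argv[[1L]]
    p <- parse_cli_flags(argv[-1L])
    fl <- p$flags
    quiet <- isTRUE(fl$quiet)
    need <- function(key) {
      if (is.null(fl[[key]])) stop_expsim("'%s' requires --%s", cmd, key)
      fl[[key]]
    }
    switch(cmd,
      run = {
        res <- run_single(need("model"), need("expt"),
                          prune = isTRUE(fl$prune),
                          dumpSubset = fl[["dump-subset"]],
                          outDir = fl$out, quiet = quiet)
        cat(sprintf("experiment\t%s\nscore\t%.10g\n", res$experimentId, res$score))
        0L
      },
      battery = {
        rep <- run_battery(need("model"), need("manifest"),
                           jobs = as.integer(fl$jobs %||% "1"),
                           prune = isTRUE(fl$prune), quiet = TRUE)
        if (!is.null(fl$out)) write_battery_report(rep, fl$out)
        utils::write.table(rep$results, stdout(), sep = "\t", quote = FALSE,
                           row.names = FALSE)
        cat(sprintf("global\t%.10g\n", rep$global))
        if (any(rep$results$status != "ok")) 2L else 0L
      },
      optimize = {
        fit <- optimize_parameters(need("model"), need("manifest"),
                                   read_param_file(need("params")),
                                   maxiter = as.integer(fl$maxiter %||% "200"),
                                   seed = as.integer(fl$seed %||% "1"),
                                   outModel = if (!is.null(fl$out)) {
                                     dir.create(fl$out, recursive = TRUE,
                                                showWarnings = FALSE)
                                     file.path(fl$out, "tuned.model")
                                   },
                                   quiet = quiet)
        if (!is.null(fl$out))
          utils::write.table(fit$trace, file.path(fl$out, "score_trace.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        cat(sprintf("initialScore\t%.10g\nfinalScore\t%.10g\n",
                    fit$initialScore, fit$finalScore))
        for (i in seq_len(nrow(fit$params)))
          cat(sprintf("param\t%s:%s\t%.10g\n", fit$params$path[[i]],
                      fit$params$field[[i]], fit$params$fitted[[i]]))
        0L
      },
      stop_expsim("unknown command '%s' (expected run, battery or optimize)", cmd)
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
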