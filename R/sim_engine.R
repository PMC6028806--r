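## ---------------------------------------------------------------------------
## Deterministic ODE engine for the chemical experiment classes.
## Mass-action + Michaelis-Menten kinetics compiled to a deSolve derivative
## function; stiff integration (lsoda) with rtol 1e-6, atol 1e-9 mM defaults.
## ---------------------------------------------------------------------------

#' Build a stimulus schedule
#'
#' @param events list of `list(time, entity, field, value)`; fields
#'   `conc` (set concentration now), `concInit` (synonym at t = 0),
#'   `buffered` (clamp/unclamp), `Kf`, `Kb`, `Km`, `kcat`, or `current`
#'   (HH injected current, uA/cm^2)
#' @return a `StimulusSchedule`, events sorted by time
#' @export
stimulus_schedule <- function(events = list()) {
  for (e in events) {
    if (!all(c("time", "entity", "field", "value") %in% names(e)))
      stop_expsim("stimulus event needs time, entity, field, value")
    if (!is.finite(e$time) || e$time < 0)
      stop_expsim("stimulus event: time must be >= 0")
  }
  ord <- order(vapply(events, `[[`, 0, "time"))
  structure(list(events = events[ord]), class = "StimulusSchedule")
}

#' Compile a model's kinetics into a derivative function
#'
#' The derivative of each non-buffered pool is the stoichiometry-weighted
#' sum of reaction fluxes, `flux = Kf * prod([sub]^stoich) -
#' Kb * prod([prod]^stoich)`, plus Michaelis-Menten enzyme terms
#' `v = kcat * [E] * [S] / (Km + [S])`. Buffered pools have derivative 0.
#'
#' @param model a valid `ReactionModel` with no dangling reactions
#' @return `list(state0, buffered, deriv, rate_of)`: initial state (mM,
#'   named by pool path), buffered mask, a deSolve-style derivative function
#'   `f(t, y, parms)`, and `rate_of(y)` returning the raw derivative vector
#' @export
compile_rates <- function(model) {
  dang <- find_dangling(model)
  if (length(dang$entries))
    stop_expsim("cannot compile rates: %d dangling reaction(s), first is '%s'",
                length(dang$entries), dang$entries[[1L]]$path)
  pool_paths <- names(model$pools)
  if (length(pool_paths) == 0L) stop_expsim("model has no pools")
  idx <- seq_along(pool_paths); names(idx) <- pool_paths

  state0 <- vapply(model$pools, `[[`, 0, "concInit")
  names(state0) <- pool_paths
  buffered <- vapply(model$pools, function(p) isTRUE(p$buffered), TRUE)
  names(buffered) <- pool_paths

  rxs <- lapply(model$reactions, function(r) list(
    si = idx[names(r$substrates)], sn = unname(r$substrates),
    pi = idx[names(r$products)],  pn = unname(r$products),
    Kf = r$Kf, Kb = r$Kb))
  enz <- lapply(model$enzymes, function(e) list(
    ei = idx[[e$enzymePool]], si = idx[[e$substrate]], pi = idx[[e$product]],
    Km = e$Km, kcat = e$kcat))

  rate_of <- function(y) {
    y <- pmax(y, 0)  # guard against tiny solver undershoot
    dy <- numeric(length(y))
    for (r in rxs) {
      flux <- r$Kf * prod(y[r$si] ^ r$sn) - r$Kb * prod(y[r$pi] ^ r$pn)
      dy[r$si] <- dy[r$si] - r$sn * flux
      dy[r$pi] <- dy[r$pi] + r$pn * flux
    }
    for (e in enz) {
      v <- e$kcat * y[[e$ei]] * y[[e$si]] / (e$Km + y[[e$si]])
      dy[[e$si]] <- dy[[e$si]] - v
      dy[[e$pi]] <- dy[[e$pi]] + v
    }
    dy[buffered] <- 0
    dy
  }

  list(state0 = state0, buffered = buffered,
       deriv = function(t, y, parms) list(rate_of(y)),
       rate_of = rate_of)
}

solver_method <- function(solver) {
  switch(solver, ode_nonstiff = "adams", "lsoda")
}

integrate_segment <- function(compiled, state, times, solver = "ode_stiff",
                              rtol = 1e-6, atol = 1e-9) {
  out <- deSolve::ode(y = state, times = times, func = compiled$deriv,
                      parms = NULL, method = solver_method(solver),
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[[1L]] < 0)
    stop_expsim("ODE solver failure near t = %g s", max(out[, 1L]))
  m <- unclass(out)[, -1L, drop = FALSE]
  neg <- m < 0
  if (any(neg)) {
    worst <- min(m[neg])
    if (-worst > atol * 10)
      stop_expsim("solver produced negative concentration %g mM", worst)
    warning(sprintf("clipping tiny negative concentrations (min %g) to 0", worst),
            call. = FALSE)
    m[neg] <- 0
  }
  m
}

## apply one stimulus event to (model, state); returns both updated
apply_event <- function(model, state, ev) {
  entity <- ev$entity; field <- ev$field; value <- ev$value
  if (field %in% c("conc", "concInit")) {
    if (is.null(model$pools[[entity]]))
      stop_expsim("stimulus targets unknown pool '%s'", entity)
    if (value < 0) stop_expsim("stimulus on '%s': concentration must be >= 0", entity)
    state[[entity]] <- value
    model$pools[[entity]]$concInit <- value
  } else if (field == "buffered") {
    if (is.null(model$pools[[entity]]))
      stop_expsim("stimulus targets unknown pool '%s'", entity)
    model$pools[[entity]]$buffered <- as.logical(value)
  } else if (field %in% c("Kf", "Kb", "Km", "kcat")) {
    model <- apply_condition(model, list(list(path = entity, field = field,
                                              value = value)))
  } else {
    stop_expsim("stimulus field '%s' not supported by the chemical engine", field)
  }
  list(model = model, state = state)
}

readout_series <- function(traj_matrix, readoutMap) {
  out <- list()
  for (nm in names(readoutMap)) {
    cols <- readoutMap[[nm]]
    missing <- setdiff(cols, colnames(traj_matrix))
    if (length(missing))
      stop_expsim("readout '%s': mapped pool(s) %s absent from simulation",
                  nm, paste(missing, collapse = ", "))
    out[[nm]] <- rowSums(traj_matrix[, cols, drop = FALSE])
  }
  out
}

new_sim_output <- function(times, trajectories, coordType,
                           labels = NULL, steadyStateReached = NA) {
  structure(list(times = times, trajectories = trajectories,
                 coordType = coordType, labels = labels,
                 steadyStateReached = steadyStateReached),
            class = "SimOutput")
}

#' @export
print.SimOutput <- function(x, ...) {
  cat(sprintf("SimOutput: %d %s points, readouts: %s\n",
              length(x$times), x$coordType,
              paste(names(x$trajectories), collapse = ", ")))
  invisible(x)
}

#' Run a time-series experiment
#'
#' Integration is restarted at every stimulus event: the state is taken at
#' the event time (left limit), the assignment applied instantaneously, and
#' integration continues. Output is sampled on the `dtOut` grid.
#'
#' @param model a `ReactionModel` (already extracted/conditioned)
#' @param schedule a `StimulusSchedule`
#' @param readoutMap named list: readout name -> pool paths (summed)
#' @param tEnd end time, s (must exceed the last event time)
#' @param dtOut output sampling interval, s
#' @param settle pre-equilibration before t = 0: `NA` (default) relaxes the
#'   model to steady state first, `0` starts from the declared initial
#'   concentrations, a positive number pre-integrates for that many seconds
#' @param solver `"ode_stiff"` or `"ode_nonstiff"`
#' @param rtol,atol solver tolerances
#' @return a `SimOutput` with time coordinates
#' @export
run_time_series <- function(model, schedule, readoutMap, tEnd, dtOut,
                            settle = NA, solver = "ode_stiff",
                            rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(schedule, "StimulusSchedule"))
  ev_times <- vapply(schedule$events, `[[`, 0, "time")
  if (length(ev_times) && tEnd <= max(ev_times))
    stop_expsim("tEnd (%g s) must exceed the last stimulus time (%g s)",
                tEnd, max(ev_times))
  compiled <- compile_rates(model)
  state <- compiled$state0

  if (is.na(settle) || settle > 0) {
    ss <- find_steady_state(model, tMax = if (is.na(settle)) 1e5 else settle,
                            solver = solver, rtol = rtol, atol = atol)
    state <- ss$state
    for (p in names(state)) model$pools[[p]]$concInit <- state[[p]]
  }

  grid <- seq(0, tEnd, by = dtOut)
  breaks <- sort(unique(c(0, ev_times, tEnd)))
  traj <- matrix(NA_real_, nrow = length(grid), ncol = length(state),
                 dimnames = list(NULL, names(state)))
  ## events at t=0 are applied before the first sample
  for (ev in schedule$events[ev_times == 0]) {
    upd <- apply_event(model, state, ev)
    model <- upd$model; state <- upd$state
    compiled <- compile_rates(model)
  }
  traj[1L, ] <- state
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[[k]]; t1 <- breaks[[k + 1L]]
    sample_idx <- which(grid > t0 & grid <= t1)
    seg_times <- sort(unique(c(t0, grid[sample_idx], t1)))
    if (length(seg_times) > 1L) {
      m <- integrate_segment(compiled, state, seg_times, solver, rtol, atol)
      state <- m[nrow(m), ]
      names(state) <- names(compiled$state0)
      if (length(sample_idx))
        traj[sample_idx, ] <- m[match(grid[sample_idx], seg_times), , drop = FALSE]
    }
    for (ev in schedule$events[ev_times == t1 & t1 > 0]) {
      upd <- apply_event(model, state, ev)
      model <- upd$model; state <- upd$state
      compiled <- compile_rates(model)
      if (t1 %in% grid) traj[which(grid == t1), ] <- state
    }
  }
  new_sim_output(grid, readout_series(traj, readoutMap), "time")
}

#' Integrate a model to steady state
#'
#' Steady state is declared when `max|dC/dt| / max(1, max|C|) < tol`,
#' evaluated on the compiled rate function. Integration proceeds in
#' geometrically growing spans until the criterion holds or `tMax` is hit.
#'
#' @param model a `ReactionModel`
#' @param tMax maximum simulated time, s
#' @param tol relative rate tolerance, 1/s
#' @param state optional starting state (defaults to the model's initials)
#' @param solver,rtol,atol solver controls
#' @return `list(state, reached, t)`
#' @export
find_steady_state <- function(model, tMax = 1e5, tol = 1e-6, state = NULL,
                              solver = "ode_stiff", rtol = 1e-6, atol = 1e-9) {
  stopifnot(tMax > 0)
  compiled <- compile_rates(model)
  if (is.null(state)) state <- compiled$state0
  is_steady <- function(y)
    max(abs(compiled$rate_of(y))) / max(1, max(abs(y))) < tol
  t_now <- 0
  if (is_steady(state)) return(list(state = state, reached = TRUE, t = 0))
  span <- max(tMax * 1e-4, 1e-3)
  while (t_now < tMax) {
    span <- min(span, tMax - t_now)
    m <- integrate_segment(compiled, state, c(0, span), solver, rtol, atol)
    state <- m[nrow(m), ]
    names(state) <- names(compiled$state0)
    t_now <- t_now + span
    if (is_steady(state)) return(list(state = state, reached = TRUE, t = t_now))
    span <- span * 2
  }
  list(state = state, reached = FALSE, t = t_now)
}

#' Run a dose-response experiment
#'
#' For each dose the model is reset to its initial conditions, the dose
#' entity is buffered (clamped) at the dose, the system is integrated to
#' steady state, and the readout recorded. A dose whose run does not reach
#' steady state before `tMax` is flagged and reported with a warning.
#'
#' @param model a `ReactionModel`
#' @param doseEntity pool path receiving the dose clamp
#' @param doses strictly increasing dose values, mM
#' @param readoutMap named list: readout name -> pool paths
#' @param tMax steady-state search horizon, s
#' @param tol steady-state tolerance
#' @param solver,rtol,atol solver controls
#' @return a `SimOutput` with dose coordinates and per-dose
#'   `steadyStateReached` flags
#' @export
run_dose_response <- function(model, doseEntity, doses, readoutMap,
                              tMax = 1e5, tol = 1e-6, solver = "ode_stiff",
                              rtol = 1e-6, atol = 1e-9) {
  if (length(doses) < 1L) stop_expsim("need at least one dose")
  if (any(diff(doses) <= 0)) stop_expsim("doses must be strictly increasing")
  if (is.null(model$pools[[doseEntity]]))
    stop_expsim("dose entity '%s' is not a pool in the model", doseEntity)
  traj <- matrix(NA_real_, nrow = length(doses), ncol = length(model$pools),
                 dimnames = list(NULL, names(model$pools)))
  reached <- logical(length(doses))
  for (i in seq_along(doses)) {
    m_i <- model
    m_i$pools[[doseEntity]]$concInit <- doses[[i]]
    m_i$pools[[doseEntity]]$buffered <- TRUE
    ss <- find_steady_state(m_i, tMax = tMax, tol = tol, solver = solver,
                            rtol = rtol, atol = atol)
    if (!ss$reached)
      warning(sprintf("dose %g: steady state not reached before tMax = %g s",
                      doses[[i]], tMax), call. = FALSE)
    reached[[i]] <- ss$reached
    traj[i, ] <- ss$state[colnames(traj)]
  }
  new_sim_output(doses, readout_series(traj, readoutMap), "dose",
                 steadyStateReached = reached)
}

#' Run a multi-stimulus (combination) experiment
#'
#' Each named combination resets the model, applies its settings at t = 0,
#' integrates for the settle duration, and records the readout — one bar
#' per combination, with no state carry-over between combinations.
#'
#' @param model a `ReactionModel`
#' @param combinations named list; each element is a list of
#'   `list(entity, field, value)` settings
#' @param readoutMap named list: readout name -> pool paths
#' @param settle integration time per combination, s
#' @param solver,rtol,atol solver controls
#' @return a `SimOutput` with label coordinates
#' @export
run_multi_stim <- function(model, combinations, readoutMap, settle,
                           solver = "ode_stiff", rtol = 1e-6, atol = 1e-9) {
  if (length(combinations) < 1L) stop_expsim("need at least one combination")
  if (is.null(names(combinations)) || any(!nzchar(names(combinations))))
    stop_expsim("combinations must be named")
  labels <- names(combinations)
  traj <- matrix(NA_real_, nrow = length(labels), ncol = length(model$pools),
                 dimnames = list(NULL, names(model$pools)))
  for (i in seq_along(combinations)) {
    m_i <- model
    state <- NULL
    for (s in combinations[[i]]) {
      upd <- apply_event(m_i, vapply(m_i$pools, `[[`, 0, "concInit"), s)
      m_i <- upd$model
    }
    compiled <- compile_rates(m_i)
    m <- integrate_segment(compiled, compiled$state0, c(0, settle),
                           solver, rtol, atol)
    final <- m[nrow(m), ]
    names(final) <- names(compiled$state0)
    traj[i, ] <- final[colnames(traj)]
  }
  new_sim_output(seq_along(labels), readout_series(traj, readoutMap),
                 "label", labels = labels)
}

#' Tidy table view of a simulation output
#'
#' @param x a `SimOutput`
#' @param ... unused
#' @return data.frame with columns coordinate, readout, value (plus label
#'   for multi-stimulus outputs)
#' @export
as.data.frame.SimOutput <- function(x, ...) {
  do.call(rbind, lapply(names(x$trajectories), function(nm) {
    data.frame(coordinate = x$times,
               label = if (!is.null(x$labels)) x$labels else NA_character_,
               readout = nm, value = x$trajectories[[nm]],
               stringsAsFactors = FALSE)
  }))
}
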