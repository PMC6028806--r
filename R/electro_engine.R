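## ---------------------------------------------------------------------------
## Minimal single-compartment Hodgkin-Huxley current-clamp simulator, so
## electrical time-series experiments run through the same pipeline as
## chemical ones. Classic squid-axon formulation; voltages in mV, time in
## ms internally (converted from the s-based schedule), currents uA/cm^2.
## ---------------------------------------------------------------------------

#' Construct a Hodgkin-Huxley compartment
#'
#' Defaults are the classic squid-axon parameter set; no temperature
#' correction is applied.
#'
#' @param Cm membrane capacitance, uF/cm^2
#' @param gNa,gK,gLeak maximal conductances, mS/cm^2
#' @param ENa,EK,ELeak reversal potentials, mV
#' @return named numeric vector of class `HHCompartment`
#' @export
hh_compartment <- function(Cm = 1, gNa = 120, gK = 36, gLeak = 0.3,
                           ENa = 50, EK = -77, ELeak = -54.387) {
  if (any(c(gNa, gK, gLeak) < 0)) stop_expsim("HH conductances must be >= 0")
  if (Cm <= 0) stop_expsim("HH capacitance must be > 0")
  structure(c(Cm = Cm, gNa = gNa, gK = gK, gLeak = gLeak,
              ENa = ENa, EK = EK, ELeak = ELeak),
            class = "HHCompartment")
}

## voltage-dependent gating rates, 1/ms; V in mV
## the 0/0 singularities at V = -40 and V = -55 are filled by their limits
hh_alpha_m <- function(V) ifelse(abs(V + 40) < 1e-7, 1,
                                 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10)))
hh_beta_m  <- function(V) 4 * exp(-(V + 65) / 18)
hh_alpha_h <- function(V) 0.07 * exp(-(V + 65) / 20)
hh_beta_h  <- function(V) 1 / (1 + exp(-(V + 35) / 10))
hh_alpha_n <- function(V) ifelse(abs(V + 55) < 1e-7, 0.1,
                                 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10)))
hh_beta_n  <- function(V) 0.125 * exp(-(V + 65) / 80)

hh_gate_inf <- function(a, b) a / (a + b)

## total steady-state membrane current at voltage V with zero injection
hh_steady_current <- function(V, p) {
  m <- hh_gate_inf(hh_alpha_m(V), hh_beta_m(V))
  h <- hh_gate_inf(hh_alpha_h(V), hh_beta_h(V))
  n <- hh_gate_inf(hh_alpha_n(V), hh_beta_n(V))
  p[["gNa"]] * m^3 * h * (V - p[["ENa"]]) +
    p[["gK"]] * n^4 * (V - p[["EK"]]) +
    p[["gLeak"]] * (V - p[["ELeak"]])
}

#' Resting potential of an HH compartment
#'
#' Root of the steady-state current equation on [-90, -40] mV.
#' @param comp an `HHCompartment`
#' @return resting potential, mV
#' @export
hh_resting_potential <- function(comp) {
  stats::uniroot(function(V) hh_steady_current(V, comp),
                 interval = c(-90, -40), tol = 1e-10)$root
}

#' Run a current-clamp simulation on an HH compartment
#'
#' The compartment starts at its resting potential with gating variables at
#' their voltage-dependent steady states. The current schedule (field
#' `current`, uA/cm^2) sets the injected current at each event time;
#' integration restarts at every event.
#'
#' @param comp an `HHCompartment`
#' @param currentSchedule a `StimulusSchedule` whose events carry
#'   `field = "current"`; the entity name is informational
#' @param tEnd end time, s
#' @param dtOut output sampling interval, s
#' @param rtol,atol solver tolerances
#' @return a `SimOutput` with a `Vm` trajectory (mV) plus gating variables
#' @export
run_current_clamp <- function(comp, currentSchedule, tEnd, dtOut,
                              rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(comp, "HHCompartment"),
            inherits(currentSchedule, "StimulusSchedule"))
  for (e in currentSchedule$events)
    if (e$field != "current")
      stop_expsim("HH engine only accepts 'current' stimuli, got '%s'", e$field)

  Vrest <- hh_resting_potential(comp)
  state <- c(Vm = Vrest,
             m = hh_gate_inf(hh_alpha_m(Vrest), hh_beta_m(Vrest)),
             h = hh_gate_inf(hh_alpha_h(Vrest), hh_beta_h(Vrest)),
             n = hh_gate_inf(hh_alpha_n(Vrest), hh_beta_n(Vrest)))
  p <- unclass(comp)

  deriv <- function(t, y, I_inj) {
    V <- y[[1]]; m <- y[[2]]; h <- y[[3]]; n <- y[[4]]
    I_ion <- p[["gNa"]] * m^3 * h * (V - p[["ENa"]]) +
      p[["gK"]] * n^4 * (V - p[["EK"]]) +
      p[["gLeak"]] * (V - p[["ELeak"]])
    list(c(
      (I_inj - I_ion) / p[["Cm"]],                     # dV/dt, mV/ms
      hh_alpha_m(V) * (1 - m) - hh_beta_m(V) * m,
      hh_alpha_h(V) * (1 - h) - hh_beta_h(V) * h,
      hh_alpha_n(V) * (1 - n) - hh_beta_n(V) * n
    ))
  }

  ## all times handled in ms internally
  ev_t <- vapply(currentSchedule$events, `[[`, 0, "time") * 1e3
  ev_v <- vapply(currentSchedule$events, `[[`, 0, "value")
  tEnd_ms <- tEnd * 1e3
  grid <- seq(0, tEnd_ms, by = dtOut * 1e3)
  breaks <- sort(unique(c(0, ev_t, tEnd_ms)))
  traj <- matrix(NA_real_, nrow = length(grid), ncol = 4,
                 dimnames = list(NULL, c("Vm", "m", "h", "n")))
  I_now <- 0
  for (k in which(ev_t == 0)) I_now <- ev_v[[k]]
  traj[1L, ] <- state
  for (k in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[[k]]; t1 <- breaks[[k + 1L]]
    sample_idx <- which(grid > t0 & grid <= t1)
    seg_times <- sort(unique(c(t0, grid[sample_idx], t1)))
    if (length(seg_times) > 1L) {
      out <- deSolve::ode(y = state, times = seg_times, func = deriv,
                          parms = I_now, method = "lsoda",
                          rtol = rtol, atol = atol)
      if (attr(out, "istate")[[1L]] < 0)
        stop_expsim("HH solver failure near t = %g ms", max(out[, 1L]))
      m <- unclass(out)[, -1L, drop = FALSE]
      state <- m[nrow(m), ]
      names(state) <- c("Vm", "m", "h", "n")
      if (length(sample_idx))
        traj[sample_idx, ] <- m[match(grid[sample_idx], seg_times), , drop = FALSE]
    }
    for (j in which(ev_t == t1 & t1 > 0)) I_now <- ev_v[[j]]
  }
  ## gating variables live in [0,1]; clip roundoff excursions
  traj[, 2:4] <- pmin(pmax(traj[, 2:4], 0), 1)
  new_sim_output(grid / 1e3,
                 list(Vm = traj[, "Vm"], m = traj[, "m"],
                      h = traj[, "h"], n = traj[, "n"]),
                 "time")
}

#' Count action potentials in a membrane-potential trace
#'
#' A spike is an upward crossing of the threshold followed by a local
#' maximum above it.
#'
#' @param times time grid, s
#' @param vm membrane potential, mV
#' @param threshold detection threshold, mV
#' @return integer spike count
#' @export
count_spikes <- function(times, vm, threshold = 0) {
  above <- vm > threshold
  sum(diff(as.integer(above)) == 1L)
}
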