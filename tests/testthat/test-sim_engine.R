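test_that("compile_rates reproduces the mass-action law by hand", {
  ## A <-> B with Kf=1, Kb=2 at (A=1, B=1): dA/dt = -1 + 2 = +1 mM/s
  m <- make_pair_model(Kf = 1, Kb = 2)
  cr <- compile_rates(m)
  dy <- cr$rate_of(c(1, 1))
  expect_equal(dy[[1]], 1)
  expect_equal(dy[[2]], -1)

  ## buffered pool: derivative exactly 0 at any state
  m2 <- apply_condition(m, list(list(path = "/g/A", field = "buffered",
                                     value = TRUE)))
  cr2 <- compile_rates(m2)
  for (st in list(c(1, 1), c(5, 0.1), c(0, 3)))
    expect_identical(compile_rates(m2)$rate_of(st)[[1]], 0)

  ## enzyme at [S] = Km runs at half saturation: v = kcat*E/2
  me <- new_reaction_model("enz")
  me <- add_compartment(me, "cell"); me <- add_group(me, "/g")
  me <- add_pool(me, "/g/E", 0.3); me <- add_pool(me, "/g/S", 0.5)
  me <- add_pool(me, "/g/P", 0)
  me <- add_enzyme(me, "/g/cat", "/g/E", "/g/S", "/g/P", Km = 0.5, kcat = 2)
  dy <- compile_rates(me)$rate_of(c(0.3, 0.5, 0))
  expect_equal(dy[[3]], 2 * 0.3 / 2)   # kcat*E/2
  expect_equal(dy[[2]], -2 * 0.3 / 2)

  ## dangling reaction refuses to compile
  mb <- make_binding_model(); mb$pools[["/binding/L"]] <- NULL
  expect_error(compile_rates(mb), "dangling")
})

test_that("exponential decay matches the closed form", {
  m <- make_decay_model(Kf = 0.1)
  out <- run_time_series(m, stimulus_schedule(), list(A = "/g/A"),
                         tEnd = 10, dtOut = 0.5, settle = 0)
  expect_equal(tail(out$trajectories$A, 1), exp(-1), tolerance = 1e-5)
  expect_equal(out$trajectories$A, exp(-0.1 * out$times), tolerance = 1e-5)
})

test_that("time-series events restart integration and leave fixed points alone", {
  m <- make_binding_model()
  sched <- stimulus_schedule(list(
    list(time = 0, entity = "/binding/L", field = "conc", value = 1),
    list(time = 10, entity = "/binding/L", field = "conc", value = 3),
    list(time = 20, entity = "/binding/L", field = "conc", value = 0.5)))
  out <- run_time_series(m, sched, list(L = "/binding/L", RL = "/binding/RL"),
                         tEnd = 30, dtOut = 1, settle = 0)
  ## the input pool shows each assignment at its event time
  expect_equal(out$trajectories$L[out$times == 10], 3)
  expect_equal(out$trajectories$L[out$times == 20], 0.5)

  ## empty schedule at a fixed point stays put
  mp <- make_pair_model(Kf = 1, Kb = 2)
  mp$pools[["/g/A"]]$concInit <- 2 / 3
  mp$pools[["/g/B"]]$concInit <- 1 / 3
  out2 <- run_time_series(mp, stimulus_schedule(), list(A = "/g/A", B = "/g/B"),
                          tEnd = 50, dtOut = 5, settle = 0)
  expect_equal(out2$trajectories$A, rep(2 / 3, length(out2$times)),
               tolerance = 1e-6)
})

test_that("simultaneous events on distinct entities commute", {
  m <- make_binding_model()
  ev1 <- list(time = 5, entity = "/binding/L", field = "conc", value = 2)
  ev2 <- list(time = 5, entity = "/binding/R", field = "conc", value = 0.25)
  rm_ <- list(L = "/binding/L", R = "/binding/R", RL = "/binding/RL")
  a <- run_time_series(m, stimulus_schedule(list(ev1, ev2)), rm_,
                       tEnd = 20, dtOut = 1, settle = 0)
  b <- run_time_series(m, stimulus_schedule(list(ev2, ev1)), rm_,
                       tEnd = 20, dtOut = 1, settle = 0)
  expect_identical(a, b)
})

test_that("runs are deterministic: identical inputs give identical outputs", {
  m <- make_cascade_model()
  sched <- stimulus_schedule(list(
    list(time = 0, entity = "/input_EGF/EGF", field = "conc", value = 1)))
  rm_ <- list(T3_a = "/core/tier3/T3_a")
  a <- run_time_series(m, sched, rm_, tEnd = 100, dtOut = 2, settle = 0)
  b <- run_time_series(m, sched, rm_, tEnd = 100, dtOut = 2, settle = 0)
  expect_identical(a, b)
})

test_that("find_steady_state honours detailed balance and flags divergence", {
  m <- make_pair_model(Kf = 1, Kb = 2)
  ss <- find_steady_state(m, tol = 1e-8)
  expect_true(ss$reached)
  expect_equal(ss$state[["/g/B"]] / ss$state[["/g/A"]], 1 / 2, tolerance = 1e-7)

  ## an isolated constant pool is steady immediately
  m2 <- new_reaction_model("const")
  m2 <- add_compartment(m2, "cell"); m2 <- add_group(m2, "/g")
  m2 <- add_pool(m2, "/g/X", 1)
  ss2 <- find_steady_state(m2)
  expect_true(ss2$reached); expect_equal(ss2$t, 0)

  ## zero-order production with no degradation never settles
  m3 <- new_reaction_model("grow")
  m3 <- add_compartment(m3, "cell"); m3 <- add_group(m3, "/g")
  m3 <- add_pool(m3, "/g/src", 1, buffered = TRUE)
  m3 <- add_pool(m3, "/g/X", 0)
  m3 <- add_reaction(m3, "/g/make", c("/g/src" = 1), c("/g/X" = 1),
                     Kf = 1, Kb = 0)
  ss3 <- find_steady_state(m3, tMax = 50)
  expect_false(ss3$reached)
})

test_that("dose-response reproduces the binding isotherm and is monotone", {
  m <- make_binding_model(Rtot = 1, Kf = 2, Kb = 1)   # Kd = 0.5
  Kd <- 0.5
  doses <- Kd * c(0.01, 0.1, 0.5, 1, 2, 10, 100)
  out <- run_dose_response(m, "/binding/L", doses, list(RL = "/binding/RL"))
  expect_true(all(out$steadyStateReached))
  iso <- 1 * doses / (Kd + doses)
  expect_equal(out$trajectories$RL, iso, tolerance = 1e-5)
  expect_true(all(diff(out$trajectories$RL) >= -1e-12))  # monotone isotherm
  expect_equal(out$trajectories$RL[4], 0.5, tolerance = 1e-5)  # dose = Kd

  ## dose 0 equals the unstimulated steady state
  out0 <- run_dose_response(m, "/binding/L", c(0, Kd), list(RL = "/binding/RL"))
  expect_equal(out0$trajectories$RL[1], 0, tolerance = 1e-8)
  expect_error(run_dose_response(m, "/binding/L", c(2, 1), list(RL = "/binding/RL")),
               "strictly increasing")
})

test_that("multi-stimulus combinations are independent and clamp-aware", {
  m <- make_cascade_model()
  rm_ <- list(T3_a = "/core/tier3/T3_a")
  combos <- list(
    control = list(),
    act = list(list(entity = "/input_EGF/EGF", field = "conc", value = 1)),
    act_dup = list(list(entity = "/input_EGF/EGF", field = "conc", value = 1)))
  out <- run_multi_stim(m, combos, rm_, settle = 200)
  v <- out$trajectories$T3_a
  names(v) <- out$labels
  expect_gt(v[["act"]], v[["control"]])        # activator beats control
  expect_equal(v[["act"]], v[["act_dup"]])     # duplicated combo identical

  ## buffering the readout pool pins the bar at the buffered value
  combos2 <- list(clamp = list(
    list(entity = "/core/tier3/T3_a", field = "conc", value = 0.42),
    list(entity = "/core/tier3/T3_a", field = "buffered", value = TRUE)))
  out2 <- run_multi_stim(m, combos2, rm_, settle = 100)
  expect_equal(out2$trajectories$T3_a[[1]], 0.42, tolerance = 1e-9)
})

test_that("moiety totals on closed fixtures are conserved along trajectories", {
  for (maker in list(make_binding_model,
                     function() make_translation_fixture()$model)) {
    m <- maker()
    W <- moiety_vectors(m)
    sched <- stimulus_schedule(list(
      list(time = 0, entity = names(m$pools)[[1]], field = "conc", value = 1.3)))
    rm_ <- stats::setNames(as.list(names(m$pools)), names(m$pools))
    out <- run_time_series(m, sched, rm_, tEnd = 30, dtOut = 0.5, settle = 0)
    traj <- do.call(cbind, out$trajectories[names(m$pools)])
    for (j in seq_len(ncol(W))) {
      tot <- as.vector(traj %*% W[, j])
      drift <- max(abs(tot - tot[1])) / max(1, abs(tot[1]))
      expect_lt(drift, 1e-6)
    }
  }
})

test_that("tidy table view covers every readout point", {
  m <- make_binding_model()
  out <- run_dose_response(m, "/binding/L", c(0.5, 1, 2),
                           list(RL = "/binding/RL"))
  df <- as.data.frame(out)
  expect_equal(nrow(df), 3L)
  expect_named(df, c("coordinate", "label", "readout", "value"))
})
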