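test_that("resting potential is the root of the steady-state current", {
  comp <- hh_compartment()
  Vr <- hh_resting_potential(comp)
  expect_lt(abs(expsim:::hh_steady_current(Vr, comp)), 1e-8)
  out <- run_current_clamp(comp, stimulus_schedule(), tEnd = 0.1, dtOut = 1e-4)
  expect_lt(max(abs(out$trajectories$Vm - Vr)), 0.5)
})

test_that("suprathreshold steps spike, subthreshold steps do not", {
  comp <- hh_compartment()
  run_step <- function(amp) run_current_clamp(
    comp, stimulus_schedule(list(list(time = 0.01, entity = "e",
                                      field = "current", value = amp))),
    tEnd = 0.15, dtOut = 1e-4)
  supra <- run_step(10)
  expect_gte(count_spikes(supra$times, supra$trajectories$Vm), 1L)
  expect_gt(max(supra$trajectories$Vm), 0)
  sub <- run_step(0.5)
  expect_equal(count_spikes(sub$times, sub$trajectories$Vm), 0L)
  expect_lt(max(sub$trajectories$Vm), 0)
})

test_that("gating variables stay within [0,1] and spike count grows with amplitude", {
  comp <- hh_compartment()
  amps <- c(1, 2, 3, 5, 10, 20)
  counts <- integer(length(amps))
  for (i in seq_along(amps)) {
    out <- run_current_clamp(
      comp, stimulus_schedule(list(list(time = 0.005, entity = "e",
                                        field = "current", value = amps[i]))),
      tEnd = 0.2, dtOut = 1e-4)
    for (g in c("m", "h", "n")) {
      expect_gte(min(out$trajectories[[g]]), 0)
      expect_lte(max(out$trajectories[[g]]), 1)
    }
    counts[i] <- count_spikes(out$times, out$trajectories$Vm)
  }
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0L)
  expect_gte(counts[length(counts)], 1L)
})

test_that("electrical experiments run through the identical pipeline path", {
  res <- run_single(fixture_paths$hh_model, fixture_paths$hh_cc, quiet = TRUE)
  expect_s3_class(res, "ScoreResult")
  expect_lt(res$score, 1e-6)
  ## hh model round-trips through the native dialect
  m <- load_model(fixture_paths$hh_model)
  expect_identical(m$solver, "hh")
  expect_s3_class(m$hh, "HHCompartment")
  f <- tempfile(fileext = ".model")
  write_native_model(m, f)
  m2 <- load_model(f)
  expect_equal(unclass(m2$hh), unclass(m$hh), tolerance = 0)
  unlink(f)
  ## chemical solver on an hh experiment is rejected coherently
  expect_error(run_single(fixture_paths$binding_model, fixture_paths$hh_cc,
                          quiet = TRUE),
               "Hodgkin-Huxley")
})
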