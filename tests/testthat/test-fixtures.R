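test_that("generated models and experiments validate cleanly", {
  for (mk in list(make_binding_model, make_cascade_model, make_bistable_model,
                  function() make_translation_fixture()$model))
    expect_length(validate_model(mk()), 0L)
  comp <- load_model(fixture_paths$composite_model)
  expect_length(validate_model(comp), 0L)
  for (k in c("binding_ts", "binding_dr", "cascade_ms", "translation_ts"))
    expect_length(validate_experiment(parse_experiment_tsv(fixture_paths[[k]]),
                                      comp), 0L)
})

test_that("binding model carries the analytic dissociation constant", {
  m <- make_binding_model(Rtot = 2, Kf = 4, Kb = 1)
  expect_equal(attr(m, "Kd"), 0.25)
  ## saturation limit: very large clamped dose drives RL towards Rtot
  out <- run_dose_response(m, "/binding/L", c(0.25, 250),
                           list(RL = "/binding/RL"))
  expect_equal(out$trajectories$RL[1], 1, tolerance = 1e-4)     # half at Kd
  expect_equal(out$trajectories$RL[2], 2, tolerance = 1e-2)     # near Rtot
})

test_that("cascade construction matches the requested tier count", {
  m <- make_cascade_model(3)
  expect_setequal(m$groups, c("/core", "/core/tier1", "/core/tier2",
                              "/core/tier3", "/input_EGF", "/input_Ca"))
  ## selecting core + one input excludes the other input's pools
  sel <- resolve_paths(m, c("/core", "/input_EGF"))
  expect_false("/input_Ca/Ca" %in% sel)
  expect_true("/input_EGF/EGF" %in% sel)
  ## zero input settles at a basal, low top-tier activity
  ss <- find_steady_state(m)
  expect_true(ss$reached)
  expect_lt(ss$state[["/core/tier3/T3_a"]], 1e-6)
  expect_error(make_cascade_model(7))
})

test_that("noise-free fixtures self-score ~0; noisy ones do not; regeneration is deterministic", {
  doc0 <- make_experiment_fixture("TimeSeries", make_binding_model(),
                                  noise_sd = 0, seed = 3)
  f <- tempfile(fileext = ".tsv"); write_experiment_tsv(doc0, f)
  res <- run_single(fixture_paths$binding_model, f, quiet = TRUE)
  expect_lt(res$score, 1e-6)
  unlink(f)

  docN <- make_experiment_fixture("TimeSeries", make_binding_model(),
                                  noise_sd = 0.05, seed = 3)
  fN <- tempfile(fileext = ".tsv"); write_experiment_tsv(docN, fN)
  resN <- run_single(fixture_paths$binding_model, fN, quiet = TRUE)
  expect_gt(resN$score, 1e-4)
  unlink(fN)

  ## identical seed -> identical document (and file)
  a <- make_experiment_fixture("DoseResponse", make_binding_model(),
                               noise_sd = 0.02, seed = 11)
  b <- make_experiment_fixture("DoseResponse", make_binding_model(),
                               noise_sd = 0.02, seed = 11)
  expect_identical(a, b)
  fa <- tempfile(); fb <- tempfile()
  write_experiment_tsv(a, fa); write_experiment_tsv(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))
})

test_that("translation fixture exercises extraction and scores ~0", {
  tf <- make_translation_fixture()
  ext <- extract_subset(tf$model, tf$doc$modelMap$subset, "strict")
  expect_length(ext$dangling$entries, 0L)
  expect_false(any(grepl("^/side", names(ext$model$pools))))
  f <- tempfile(fileext = ".tsv")
  write_experiment_tsv(tf$doc, f)
  mfile <- tempfile(fileext = ".model")
  write_native_model(tf$model, mfile)
  expect_lt(run_single(mfile, f, quiet = TRUE)$score, 1e-6)
  unlink(c(f, mfile))
})

test_that("bistable switch: quiescent, suprathreshold and tiny-pulse behaviour", {
  bm <- make_bistable_model()
  rm_ <- list(Xa = "/switch/Xa")
  quiet_run <- function(...) suppressWarnings(run_time_series(...))
  nostim <- quiet_run(bm, stimulus_schedule(), rm_, tEnd = 3000, dtOut = 50,
                      settle = 0)
  expect_lt(max(nostim$trajectories$Xa), 0.05)
  tr <- quiet_run(bm, make_pulse_train(1, n = 3, spacing = 600, width = 10),
                  rm_, tEnd = 1200 + 3600 + 400, dtOut = 50, settle = 0)
  after <- tr$trajectories$Xa[tr$times >= 1400]
  expect_gt(min(after), 0.5)    # sustained high state for > 3600 s
  tiny <- quiet_run(bm, make_pulse_train(1e-3, n = 3, spacing = 600, width = 10),
                    rm_, tEnd = 3000, dtOut = 50, settle = 0)
  expect_lt(max(tiny$trajectories$Xa), 0.05)
})
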