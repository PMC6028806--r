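test_that("native fixture loads with counts preserved", {
  m <- load_model(fixture_paths$binding_model)
  expect_s3_class(m, "ReactionModel")
  expect_length(m$pools, 3L)
  expect_length(m$reactions, 1L)
  expect_equal(m$groups, "/binding")
})

test_that("native write/read round trip is structurally identical", {
  for (mf in c(fixture_paths$binding_model, fixture_paths$cascade_model,
               fixture_paths$translation_model, fixture_paths$bistable_model,
               fixture_paths$hh_model)) {
    m <- load_model(mf)
    f <- tempfile(fileext = ".model")
    write_native_model(m, f)
    m2 <- load_model(f)
    expect_equal(m2, m, tolerance = 0)
    unlink(f)
  }
})

test_that("resolve_paths returns subtrees, leaves, unions and errors", {
  m <- load_model(fixture_paths$composite_model)
  sub <- resolve_paths(m, "/binding")
  expect_setequal(sub, c("/binding/R", "/binding/L", "/binding/RL",
                         "/binding/bind"))
  expect_equal(resolve_paths(m, "/binding/R"), "/binding/R")
  expect_equal(resolve_paths(m, character(0)), character(0))
  expect_error(resolve_paths(m, "/cell/NoSuchPathway"), "NoSuchPathway")
  ## root selector returns every entity
  expect_setequal(resolve_paths(m, "/"), c(names(m$pools), names(m$reactions),
                                           names(m$enzymes)))
  ## monotone: adding a selector never shrinks the result
  for (extra in c("/core", "/switch", "/binding/L")) {
    expect_true(all(sub %in% resolve_paths(m, c("/binding", extra))))
  }
})

test_that("nested group selection picks up the full subtree", {
  m <- make_cascade_model(3)
  core <- resolve_paths(m, "/core")
  expect_true("/core/tier3/T3_a" %in% core)
  expect_true("/core/tier1/act_EGF" %in% core)
  expect_false("/input_EGF/EGF" %in% core)
  tier2 <- resolve_paths(m, "/core/tier2")
  expect_setequal(tier2, c("/core/tier2/T2", "/core/tier2/T2_a",
                           "/core/tier2/act", "/core/tier2/relax"))
})

test_that("validate_model flags injected faults and passes clean fixtures", {
  for (mf in c(fixture_paths$binding_model, fixture_paths$composite_model))
    expect_length(validate_model(load_model(mf)), 0L)

  base <- make_binding_model()
  ## fault injection: each single mutation must yield >= 1 diagnostic
  faults <- list(
    function(m) { m$pools[["/binding/L"]] <- NULL; m },          # dangling rx
    function(m) { m$pools[["/binding/R"]]$concInit <- -1; m },   # negative conc
    function(m) { m$reactions[["/binding/bind"]]$Kf <- -2; m },  # negative rate
    function(m) { m$compartments$cell$volume <- 0; m },          # zero volume
    function(m) { m$pools[["/binding/R"]]$compartment <- "nope"; m },
    function(m) { m$groups <- character(0); m }                  # orphan parent
  )
  for (f in faults) expect_gte(length(validate_model(f(base))), 1L)
})

test_that("constructors reject invalid entities", {
  m <- make_binding_model()
  expect_error(add_pool(m, "/binding/R", 1), "already in use")
  expect_error(add_pool(m, "no-slash", 1), "invalid pool path")
  expect_error(add_pool(m, "/binding/X", -0.5), "concInit")
  expect_error(add_reaction(m, "/binding/r2", c("/binding/R" = 1),
                            c("/binding/RL" = 1), Kf = -1), "Kf and Kb")
  expect_error(add_reaction(m, "/binding/r2", numeric(0),
                            c("/binding/RL" = 1), Kf = 1),
               "at least one substrate")
  expect_error(add_enzyme(m, "/binding/e", "/binding/R", "/binding/L",
                          "/binding/RL", Km = 0, kcat = 1), "Km")
})

test_that("model printing summarises contents", {
  expect_output(print(make_binding_model()), "3 pools, 1 reactions")
})
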