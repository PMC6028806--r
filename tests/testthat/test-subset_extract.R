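brute_force_dangling <- function(model) {
  pools <- names(model$pools)
  hits <- list()
  for (rec in c(model$reactions, model$enzymes)) {
    parts <- if (!is.null(rec$enzymePool))
      c(rec$enzymePool, rec$substrate, rec$product)
    else c(names(rec$substrates), names(rec$products))
    miss <- setdiff(unique(parts), pools)
    if (length(miss)) hits[[rec$path]] <- sort(miss)
  }
  hits
}

test_that("extraction keeps selected-minus-deleted entities", {
  m <- load_model(fixture_paths$composite_model)
  spec <- subset_spec(includePaths = c("/translation", "/side"),
                      deletePaths = "/side")
  ext <- extract_subset(m, spec, policy = "strict")
  expect_setequal(names(ext$model$pools),
                  c("/translation/40S", "/translation/eIF4E-mRNA",
                    "/translation/43S"))
  expect_setequal(names(ext$model$reactions), "/translation/assoc")
  expect_length(ext$dangling$entries, 0L)
  ## entity count arithmetic: |extracted| = |includes| - |deletions|
  inc <- resolve_paths(m, spec$includePaths)
  del <- resolve_paths(m, "/side")
  expect_length(all_paths <- c(names(ext$model$pools),
                               names(ext$model$reactions),
                               names(ext$model$enzymes)),
                length(inc) - length(del))
})

test_that("strict policy errors on dangling, prune removes and reports", {
  m <- make_binding_model()
  spec <- subset_spec(includePaths = "/binding", deletePaths = "/binding/L")
  expect_error(extract_subset(m, spec, policy = "strict"), "dangling")
  err <- tryCatch(extract_subset(m, spec, policy = "strict"), error = identity)
  expect_s3_class(err$report, "DanglingReport")
  expect_equal(err$report$entries[[1L]]$missing, "/binding/L")

  ext <- suppressWarnings(extract_subset(m, spec, policy = "prune"))
  expect_length(ext$model$reactions, 0L)
  expect_length(ext$dangling$entries, 1L)
  expect_warning(extract_subset(m, spec, policy = "prune"), "pruning")
})

test_that("identity extraction and idempotence", {
  m <- load_model(fixture_paths$composite_model)
  spec <- subset_spec(includePaths = "/")
  once <- extract_subset(m, spec, "strict")$model
  expect_setequal(names(once$pools), names(m$pools))
  expect_setequal(names(once$reactions), names(m$reactions))
  twice <- extract_subset(once, spec, "strict")$model
  expect_equal(twice, once, tolerance = 0)

  spec2 <- subset_spec(includePaths = c("/core", "/input_EGF", "/input_Ca"))
  e1 <- extract_subset(m, spec2, "strict")$model
  e2 <- extract_subset(e1, spec2, "strict")$model
  expect_equal(e2, e1, tolerance = 0)
})

test_that("deleting eIF4E-mRNA under strict raises a dangling error", {
  tf <- make_translation_fixture()
  spec <- subset_spec(includePaths = c("/translation", "/side"),
                      deletePaths = c("/side", "/translation/eIF4E-mRNA"))
  expect_error(extract_subset(tf$model, spec, "strict"),
               "dangling")
})

test_that("find_dangling matches the brute-force participant scan (50 randomized runs)", {
  for (trial in 1:50) {
    m <- random_model(1000 + trial)
    ents <- names(m$pools)
    set.seed(2000 + trial)
    kill <- sample(ents, sample(0:min(3, length(ents) - 1L), 1))
    m$pools[kill] <- NULL
    rep <- find_dangling(m)
    got <- lapply(rep$entries, `[[`, "missing")
    names(got) <- vapply(rep$entries, `[[`, "", "path")
    expect_identical(canon_dangling(got), canon_dangling(brute_force_dangling(m)))
  }
})

test_that("apply_condition sets fields, rejects bad values, and buffering clamps", {
  m <- make_binding_model()
  m2 <- apply_condition(m, list(
    list(path = "/binding/L", field = "concInit", value = 0.7),
    list(path = "/binding/L", field = "buffered", value = TRUE)))
  expect_equal(m2$pools[["/binding/L"]]$concInit, 0.7)
  out <- run_time_series(m2, stimulus_schedule(), list(L = "/binding/L"),
                         tEnd = 5, dtOut = 0.5, settle = 0)
  expect_true(all(out$trajectories$L == 0.7))

  ## Kf = 0 kills the forward flux entirely
  m3 <- apply_condition(m, list(list(path = "/binding/bind", field = "Kf",
                                     value = 0)))
  cr <- compile_rates(m3)
  expect_equal(cr$rate_of(c(1, 1, 0))[[3]], 0)

  expect_error(apply_condition(m, list(list(path = "/binding/L",
                                            field = "concInit", value = -1))),
               "non-negative")
  expect_error(apply_condition(m, list(list(path = "/binding/L",
                                            field = "flux", value = 1))),
               "unknown field")
  expect_error(apply_condition(m, list(list(path = "/binding/ghost",
                                            field = "concInit", value = 1))),
               "does not exist")
  expect_error(apply_condition(m, list(list(path = "/binding/L",
                                            field = "Kf", value = 1))),
               "does not apply")
})

test_that("overrides on disjoint entities commute", {
  m <- make_cascade_model()
  ov1 <- list(path = "/core/tier1/T1", field = "concInit", value = 2)
  ov2 <- list(path = "/core/tier2/relax", field = "Kf", value = 0.05)
  ov3 <- list(path = "/core/tier3/act", field = "kcat", value = 0.4)
  a <- apply_condition(apply_condition(apply_condition(m, list(ov1)), list(ov2)), list(ov3))
  b <- apply_condition(apply_condition(apply_condition(m, list(ov3)), list(ov1)), list(ov2))
  expect_equal(a, b, tolerance = 0)
})

test_that("subset spec validates override fields and entity map targets", {
  expect_error(subset_spec(parameterOverrides =
                             list(list(path = "/x", field = "banana", value = 1))),
               "banana")
  m <- make_binding_model()
  spec <- subset_spec(includePaths = "/binding",
                      entityMap = list(X = "/binding/ghost"))
  expect_error(extract_subset(m, spec, "strict"), "ghost")
})
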