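test_that("bundled time-series fixture parses with expected shape", {
  doc <- parse_experiment_tsv(fixture_paths$binding_ts)
  expect_s3_class(doc, "ExperimentDoc")
  expect_identical(doc$exptType, "TimeSeries")
  expect_length(doc$stimuli, 1L)
  expect_equal(nrow(doc$stimuli[[1L]]$points), 1L)
  expect_equal(nrow(doc$readouts[[1L]]$points), 6L)
  expect_identical(doc$modelMap$solver, "ode_stiff")
})

test_that("unit conversion to the canonical frame", {
  expect_equal(to_canonical(0.1, "mM"), 0.1)     # identity
  expect_equal(to_canonical(100, "uM"), 0.1)     # 100 uM = 0.1 mM
  expect_equal(to_canonical(2, "min"), 120)
  expect_equal(to_canonical(1.5, "nA"), 0.0015)
  expect_error(to_canonical(1, "furlongs"), "unknown unit")
  ## invertible to 12 significant digits over all units
  set.seed(42)
  for (u in c("M", "mM", "uM", "nM", "pM", "s", "ms", "min", "h",
              "mV", "pA", "nA", "uA")) {
    x <- stats::runif(20, 1e-6, 1e3)
    expect_equal(from_canonical(to_canonical(x, u), u), x, tolerance = 1e-12)
  }
})

test_that("missing mandatory block is an error citing the block", {
  doc <- readLines(fixture_paths$binding_ts)
  drop_block <- function(lines, name) {
    out <- character(0); skipping <- FALSE
    for (l in lines) {
      key <- strsplit(l, "\t")[[1]][1]
      if (identical(key, name)) { skipping <- TRUE; next }
      if (skipping && key %in% c("ExperimentMetadata", "ExperimentContext",
                                 "Stimuli", "Readouts", "ModelMapping"))
        skipping <- FALSE
      if (!skipping) out <- c(out, l)
    }
    out
  }
  f <- tempfile(fileext = ".tsv")
  writeLines(drop_block(doc, "Readouts"), f)
  expect_error(parse_experiment_tsv(f), "Readouts")
  unlink(f)
})

test_that("parse errors carry line numbers and field names", {
  lines <- readLines(fixture_paths$binding_ts)
  ## corrupt the stimulus unit
  bad <- sub("\tmM\ts$", "\tparsecs\ts", lines)
  f <- tempfile(fileext = ".tsv")
  writeLines(bad, f)
  expect_error(parse_experiment_tsv(f), "line [0-9]+.*unit")
  unlink(f)
})

test_that("non-increasing times and bad ranges are rejected", {
  doc <- parse_experiment_tsv(fixture_paths$binding_ts)
  d2 <- doc
  d2$readouts[[1L]]$points$coord <- rev(d2$readouts[[1L]]$points$coord)
  expect_gte(length(validate_experiment(d2)), 1L)
  d3 <- doc
  d3$context$pH <- 19
  expect_match(validate_experiment(d3), "pH", all = FALSE)
  d4 <- doc
  d4$metadata$exptSource <- "paperReference"
  d4$metadata$citationId <- ""
  expect_match(validate_experiment(d4), "citationId", all = FALSE)
})

test_that("duplicate doses are flagged", {
  doc <- parse_experiment_tsv(fixture_paths$binding_dr)
  doc$stimuli[[1L]]$points$dose[2] <- doc$stimuli[[1L]]$points$dose[1]
  doc$readouts[[1L]]$points$coord[2] <- doc$readouts[[1L]]$points$coord[1]
  expect_match(validate_experiment(doc), "duplicate dose", all = FALSE)
})

test_that("fixtures cross-validate cleanly against their models", {
  comp <- load_model(fixture_paths$composite_model)
  for (k in c("binding_ts", "binding_dr", "cascade_ms", "translation_ts")) {
    doc <- parse_experiment_tsv(fixture_paths[[k]])
    expect_length(validate_experiment(doc, comp), 0L)
  }
  ## mapping to an absent pool yields a diagnostic
  doc <- parse_experiment_tsv(fixture_paths$binding_ts)
  doc$modelMap$subset$entityMap$RL <- "/binding/missing_pool"
  expect_gte(length(validate_experiment(doc, comp)), 1L)
})

test_that("tsv and json round trips are identities on the class fixtures", {
  for (k in c("binding_ts", "binding_dr", "cascade_ms", "translation_ts",
              "hh_cc")) {
    doc <- parse_experiment_tsv(fixture_paths[[k]])
    ft <- tempfile(fileext = ".tsv"); fj <- tempfile(fileext = ".json")
    write_experiment_tsv(doc, ft)
    expect_doc_equal(parse_experiment_tsv(ft), doc)
    write_experiment_json(doc, fj)
    expect_doc_equal(parse_experiment_json(fj), doc)
    unlink(c(ft, fj))
  }
})

test_that("stderr column and blank optional context fields survive a round trip", {
  doc <- random_experiment_doc(7)
  doc$readouts[[1L]]$points$stderr <- abs(doc$readouts[[1L]]$points$value) / 10 + 1e-4
  doc$context$species <- ""; doc$context$notes <- ""
  f <- tempfile(fileext = ".tsv")
  write_experiment_tsv(doc, f)
  txt <- readLines(f)
  expect_true(any(grepl("^species\t?$", txt)))   # blank, not omitted
  doc2 <- parse_experiment_tsv(f)
  expect_doc_equal(doc2, doc)
  expect_equal(doc2$readouts[[1L]]$points$stderr,
               doc$readouts[[1L]]$points$stderr, tolerance = 1e-12)
  unlink(f)
})

test_that("randomized documents survive write/parse in both formats", {
  for (seed in 1:25) {
    doc <- random_experiment_doc(seed)
    ft <- tempfile(fileext = ".tsv")
    write_experiment_tsv(doc, ft)
    expect_doc_equal(parse_experiment_tsv(ft), doc)
    unlink(ft)
  }
  for (seed in 26:40) {
    doc <- random_experiment_doc(seed)
    fj <- tempfile(fileext = ".json")
    write_experiment_json(doc, fj)
    expect_doc_equal(parse_experiment_json(fj), doc)
    unlink(fj)
  }
})
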