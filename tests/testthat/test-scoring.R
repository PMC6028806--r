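test_that("default formula matches hand evaluation", {
  expect_equal(evaluate_score(NULL, c(1, 3), c(1, 3)), 0)
  ## expt=[1,3], sim=[1,1]: range=2, sqrt(((0)^2+(2/2)^2)/2) = 1/sqrt(2)
  expect_equal(evaluate_score(NULL, c(1, 3), c(1, 1)), 1 / sqrt(2))
  ## sem-weighted mean absolute error
  expect_equal(evaluate_score("mean(abs(expt-sim)/sem)", c(1, 3), c(0, 1),
                              sem = c(1, 2)), 1)
})

test_that("scoring grammar evaluates whitelisted expressions only", {
  env_ok <- function(f) evaluate_score(f, c(1, 2, 4), c(1, 2, 3))
  expect_equal(env_ok("max(abs(expt-sim))"), 1)
  expect_equal(env_ok("sum((expt-sim)^2)"), 1)
  expect_equal(env_ok("min(expt)"), 1)
  expect_equal(env_ok("mean(expt > sim)"), 1 / 3)
  expect_equal(env_ok("2e-1 + 0"), 0.2)
  expect_error(env_ok("system('ls')"), "unknown function|unexpected character")
  expect_error(env_ok("pi"), "unbound name")
  expect_error(env_ok("mean(expt"), "expected")
  expect_error(env_ok("expt @ sim"), "unexpected character")
  expect_error(parse_score_formula("log(expt)")(list(expt = 1)),
               "unknown function")
})

test_that("default score is scale invariant and permutation symmetric", {
  set.seed(11)
  for (i in 1:20) {
    e <- stats::runif(6, 0, 5); s <- e + stats::rnorm(6, sd = 0.3)
    base <- evaluate_score(NULL, e, s)
    for (c_ in c(0.01, 3, 1e4))
      expect_equal(evaluate_score(NULL, c_ * e, c_ * s), base, tolerance = 1e-12)
    p <- sample(6)
    expect_equal(evaluate_score(NULL, e[p], s[p]), base, tolerance = 1e-12)
    ## an exactly-matching extra point never increases the default score
    expect_lte(evaluate_score(NULL, c(e, e[1]), c(s, e[1])), base + 1e-12)
  }
})

test_that("degenerate experimental range falls back, then errors", {
  ## flat expt: range falls back to max|expt|
  expect_equal(evaluate_score(NULL, c(2, 2), c(2, 4)), sqrt(1 / 2))
  expect_error(evaluate_score(NULL, c(0, 0), c(1, 2)), "degenerate")
})

test_that("score_experiment is self-consistent and honours normalization", {
  doc <- parse_experiment_tsv(fixture_paths$binding_ts)
  model <- load_model(fixture_paths$binding_model)
  res <- run_single(fixture_paths$binding_model, fixture_paths$binding_ts,
                    quiet = TRUE)
  expect_lt(res$score, 1e-6)
  expect_s3_class(res, "ScoreResult")
  expect_identical(res$experimentId, "binding_ts")

  ## foldChange mode forgives a constant multiplicative offset
  sim <- res$sim
  doc2 <- doc
  doc2$readouts[[1L]]$normalization <- "foldChange"
  doc2$readouts[[1L]]$points$value <- doc2$readouts[[1L]]$points$value * 7.3
  res2 <- score_experiment(doc2, sim)
  expect_lt(res2$score, 1e-6)
  ## percentOfMax likewise
  doc3 <- doc
  doc3$readouts[[1L]]$normalization <- "percentOfMax"
  doc3$readouts[[1L]]$points$value <- doc3$readouts[[1L]]$points$value * 0.2
  expect_lt(score_experiment(doc3, sim)$score, 1e-6)

  ## readout beyond the simulated span is an error
  doc4 <- doc
  doc4$readouts[[1L]]$points$coord[6] <- max(sim$times) + 10
  expect_error(score_experiment(doc4, sim), "outside the simulated span")
})

test_that("battery aggregation is the weighted mean with zero-weight annihilation", {
  mk <- function(s, w) structure(list(experimentId = "x", score = s,
                                      weight = w, perPointResiduals = 0,
                                      formulaUsed = ""), class = "ScoreResult")
  expect_equal(aggregate_battery(list(mk(0.4, 1))), 0.4)
  expect_equal(aggregate_battery(list(mk(0, 1), mk(1, 1))), 0.5)
  expect_equal(aggregate_battery(list(mk(0.4, 1), mk(9.9, 0))), 0.4)
  expect_error(aggregate_battery(list(mk(1, 0), mk(2, 0))), "weights")
  expect_error(aggregate_battery(list()), ">= 1")
  ## aggregate lies within [min, max] of the member scores
  set.seed(5)
  for (i in 1:10) {
    sc <- stats::runif(4); w <- stats::runif(4, 0.1, 2)
    res <- lapply(1:4, function(j) mk(sc[j], w[j]))
    g <- aggregate_battery(res)
    expect_gte(g, min(sc)); expect_lte(g, max(sc))
    expect_equal(g, sum(sc * w) / sum(w), tolerance = 1e-12)
  }
})
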