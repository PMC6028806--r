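## Shared fixtures, built once per test run in the session temp dir.

fixture_paths <- local({
  d <- file.path(tempdir(), "expsim-fixture-suite")
  suppressWarnings(make_fixture_suite(d, noise_sd = 0, seed = 1L))
})

## tiny hand-built models -----------------------------------------------------

make_decay_model <- function(Kf = 0.1) {
  m <- new_reaction_model("decay")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/g")
  m <- add_pool(m, "/g/A", 1)
  m <- add_pool(m, "/g/B", 0)
  add_reaction(m, "/g/decay", c("/g/A" = 1), c("/g/B" = 1), Kf = Kf, Kb = 0)
}

make_pair_model <- function(Kf = 1, Kb = 2) {
  m <- new_reaction_model("pair")
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/g")
  m <- add_pool(m, "/g/A", 1)
  m <- add_pool(m, "/g/B", 0)
  add_reaction(m, "/g/iso", c("/g/A" = 1), c("/g/B" = 1), Kf = Kf, Kb = Kb)
}

## random model generator for property tests ---------------------------------

random_model <- function(seed, n_pools = NULL, n_rx = NULL) {
  set.seed(seed)
  if (is.null(n_pools)) n_pools <- sample(3:8, 1)
  if (is.null(n_rx)) n_rx <- sample(1:6, 1)
  m <- new_reaction_model(sprintf("random%d", seed))
  m <- add_compartment(m, "cell")
  m <- add_group(m, "/p")
  pools <- sprintf("/p/S%d", seq_len(n_pools))
  for (p in pools)
    m <- add_pool(m, p, concInit = round(stats::runif(1, 0, 2), 6),
                  buffered = stats::runif(1) < 0.2)
  for (i in seq_len(n_rx)) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    subs <- stats::setNames(rep(1, ns), sample(pools, ns))
    avail <- setdiff(pools, names(subs))
    np <- min(np, length(avail))
    if (np == 0L) next
    prods <- stats::setNames(rep(1, np), sample(avail, np))
    m <- add_reaction(m, sprintf("/p/r%d", i), subs, prods,
                      Kf = round(stats::runif(1, 0, 3), 6),
                      Kb = round(stats::runif(1, 0, 3), 6))
  }
  m
}

## random experiment document generator ---------------------------------------

random_experiment_doc <- function(seed) {
  set.seed(seed)
  type <- sample(c("TimeSeries", "DoseResponse"), 1)
  cu <- sample(c("M", "mM", "uM", "nM"), 1)
  tu <- sample(c("s", "ms", "min"), 1)
  n <- sample(3:7, 1)
  meta <- list(transcriber = "prop", organization = "test",
               exptSource = "inHouse", citationId = "", authors = "a",
               journal = "")
  ctx <- list(species = "synthetic", cellType = "", preparation = "",
              temperature = round(stats::runif(1, 10, 40), 3),
              pH = round(stats::runif(1, 6, 8), 3), notes = "")
  mm <- list(refModel = "binding.model", solver = "ode_stiff",
             weight = round(stats::runif(1, 0, 2), 6),
             scoringFormula = sample(c("sqrt(mean(((expt-sim)/range)^2))",
                                       "mean(abs(expt-sim))/range",
                                       "max(abs(expt-sim))"), 1),
             subset = subset_spec(
               includePaths = "/binding",
               entityMap = list(L = "/binding/L", RL = "/binding/RL")),
             tEnd = NA_real_, dtOut = NA_real_, settle = NA_real_,
             tMax = 1e5, tol = 1e-6)
  if (type == "TimeSeries") {
    times <- sort(stats::runif(n, 0, 100))
    times <- times + seq_along(times) * 1e-3   # enforce strict increase
    coords <- sort(stats::runif(n, 1, 100)) + seq_len(n) * 1e-3
    mm$tEnd <- 120; mm$dtOut <- 1
    stim <- list(list(entityName = "L", field = "conc", unit = cu,
                      timeUnit = tu,
                      points = data.frame(
                        time = to_canonical(times, tu),
                        value = to_canonical(round(stats::runif(n, 0, 5), 6), cu))))
    rdpts <- data.frame(coord = to_canonical(coords, tu),
                        value = to_canonical(round(stats::runif(n, 0, 5), 6), cu),
                        stderr = ifelse(stats::runif(n) < 0.5,
                                        to_canonical(round(stats::runif(n, .01, .5), 6), cu),
                                        NA_real_))
  } else {
    doses <- sort(round(stats::runif(n, 0.001, 10), 6))
    doses <- doses + seq_len(n) * 1e-6
    stim <- list(list(entityName = "L", field = "conc", unit = cu,
                      timeUnit = "s",
                      points = data.frame(dose = to_canonical(doses, cu))))
    rdpts <- data.frame(coord = to_canonical(doses, cu),
                        value = to_canonical(round(stats::runif(n, 0, 5), 6), cu),
                        stderr = NA_real_)
  }
  experiment_doc(
    exptType = type, experimentId = sprintf("prop_%d", seed),
    metadata = meta, context = ctx, stimuli = stim,
    readouts = list(list(entityName = "RL", field = "conc", unit = cu,
                         normalization = sample(c("absolute", "foldChange"), 1),
                         timeUnit = if (type == "TimeSeries") tu else "s",
                         points = rdpts)),
    modelMap = mm)
}

nm0 <- function(x) if (is.null(names(x))) character(0) else names(x)

## canonical form of a dangling report / brute-force scan for comparison
canon_dangling <- function(x) {
  if (length(x) == 0L) return(list())
  x <- lapply(x, sort)
  x[order(names(x))]
}

## numerical equality helpers --------------------------------------------------

expect_doc_equal <- function(a, b, tol = 1e-12) {
  expect_true(isTRUE(all.equal(a, b, tolerance = tol, check.attributes = FALSE)))
}

## moiety (left null space) vectors of a model's stoichiometry matrix
moiety_vectors <- function(model) {
  pools <- names(model$pools)
  S <- matrix(0, nrow = length(pools), ncol = 0,
              dimnames = list(pools, NULL))
  for (r in model$reactions) {
    col <- stats::setNames(numeric(length(pools)), pools)
    col[names(r$substrates)] <- col[names(r$substrates)] - r$substrates
    col[names(r$products)] <- col[names(r$products)] + r$products
    S <- cbind(S, col)
  }
  for (e in model$enzymes) {
    col <- stats::setNames(numeric(length(pools)), pools)
    col[[e$substrate]] <- -1
    col[[e$product]] <- 1
    S <- cbind(S, col)
  }
  if (ncol(S) == 0L) return(diag(length(pools)))
  sv <- svd(S, nu = nrow(S))
  null_idx <- which(c(sv$d, rep(0, nrow(S) - length(sv$d))) < 1e-10)
  sv$u[, null_idx, drop = FALSE]
}
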