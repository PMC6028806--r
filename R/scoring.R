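## ---------------------------------------------------------------------------
## Model-vs-experiment scoring: the user-defined scoring expression applied
## to paired readout series, and weighted aggregation over an experiment
## battery. 0 is a perfect fit.
## ---------------------------------------------------------------------------

#' Evaluate a scoring expression
#'
#' Binds `expt`, `sim`, optional `sem`, and `range` (max(expt) - min(expt),
#' falling back to max|expt| when the experimental series is flat) and
#' evaluates the formula under the whitelisted grammar of
#' [parse_score_formula()]. The default formula is the range-normalized
#' root-mean-square residual, `r DEFAULT_SCORE_FORMULA`.
#'
#' @param formula expression string; `NULL` or `""` selects the default
#' @param expt experimental values
#' @param sim simulated values, same length
#' @param sem optional standard errors, same length
#' @return non-negative scalar score
#' @export
evaluate_score <- function(formula, expt, sim, sem = NULL) {
  if (is.null(formula) || !nzchar(formula)) formula <- DEFAULT_SCORE_FORMULA
  if (length(expt) != length(sim))
    stop_expsim("scoring: |expt| = %d but |sim| = %d", length(expt), length(sim))
  if (length(expt) == 0L) stop_expsim("scoring: no points to compare")
  rng <- max(expt) - min(expt)
  if (rng == 0) rng <- max(abs(expt))
  if (rng == 0 && grepl("range", formula))
    stop_expsim("scoring: experimental range is degenerate (all values 0)")
  env <- list(expt = expt, sim = sim, range = rng)
  if (!is.null(sem)) {
    if (length(sem) != length(expt))
      stop_expsim("scoring: |sem| = %d but |expt| = %d", length(sem), length(expt))
    env$sem <- sem
  }
  val <- parse_score_formula(formula)(env)
  if (length(val) != 1L || !is.finite(val))
    stop_expsim("scoring formula must evaluate to one finite number")
  val
}

apply_normalization <- function(values, mode) {
  switch(mode,
    absolute = values,
    foldChange = {
      if (values[[1L]] == 0)
        stop_expsim("foldChange normalization: first point is 0")
      values / values[[1L]]
    },
    percentOfMax = {
      m <- max(abs(values))
      if (m == 0) stop_expsim("percentOfMax normalization: all values are 0")
      100 * values / m
    },
    stop_expsim("unknown normalization '%s'", mode))
}

#' Score one experiment against a simulation output
#'
#' Interpolates the simulated readout series linearly to the experimental
#' coordinates (times or doses; combination labels are matched exactly),
#' applies the readout's normalization mode to both series independently,
#' and evaluates the document's scoring formula. Multiple readout entries
#' are scored jointly by concatenating their point sets.
#'
#' @param doc an `ExperimentDoc`
#' @param output a `SimOutput` from the matching run
#' @return an object of class `ScoreResult`: experimentId, score,
#'   perPointResiduals, formulaUsed, weight and a comparison table
#' @export
score_experiment <- function(doc, output) {
  stopifnot(inherits(doc, "ExperimentDoc"), inherits(output, "SimOutput"))
  expt_all <- numeric(0); sim_all <- numeric(0); sem_all <- numeric(0)
  tables <- list()
  any_sem <- FALSE
  for (r in doc$readouts) {
    traj <- output$trajectories[[r$entityName]]
    if (is.null(traj))
      stop_expsim("readout '%s' has no simulated trajectory", r$entityName)
    if (doc$exptType == "MultiStimulus") {
      idx <- match(r$points$coord, output$labels)
      if (anyNA(idx))
        stop_expsim("readout '%s': combination(s) %s not simulated", r$entityName,
                    paste(r$points$coord[is.na(idx)], collapse = ", "))
      sim_v <- traj[idx]
    } else {
      if (any(r$points$coord < min(output$times) - 1e-12) ||
          any(r$points$coord > max(output$times) + 1e-12))
        stop_expsim("readout '%s': coordinate outside the simulated span [%g, %g]",
                    r$entityName, min(output$times), max(output$times))
      sim_v <- stats::approx(output$times, traj, xout = r$points$coord,
                             rule = 1)$y
    }
    expt_v <- apply_normalization(r$points$value, r$normalization)
    sim_v  <- apply_normalization(sim_v, r$normalization)
    sem_v <- r$points$stderr
    if (r$normalization != "absolute") sem_v <- rep(NA_real_, length(sem_v))
    any_sem <- any_sem || any(!is.na(sem_v))
    expt_all <- c(expt_all, expt_v)
    sim_all <- c(sim_all, sim_v)
    sem_all <- c(sem_all, sem_v)
    tables[[length(tables) + 1L]] <-
      data.frame(readout = r$entityName, coordinate = r$points$coord,
                 expt = expt_v, sim = sim_v, stderr = sem_v,
                 stringsAsFactors = FALSE)
  }
  if (length(expt_all) == 0L) stop_expsim("experiment has no readout points")
  sem_arg <- if (any_sem && all(is.finite(sem_all)) && all(sem_all > 0))
    sem_all else NULL
  score <- evaluate_score(doc$modelMap$scoringFormula, expt_all, sim_all,
                          sem = sem_arg)
  rng <- max(expt_all) - min(expt_all)
  if (rng == 0) rng <- max(abs(expt_all), 1)
  structure(list(experimentId = doc$experimentId,
                 score = score,
                 perPointResiduals = (expt_all - sim_all) / rng,
                 formulaUsed = doc$modelMap$scoringFormula %||% DEFAULT_SCORE_FORMULA,
                 weight = doc$modelMap$weight %||% 1,
                 comparison = do.call(rbind, tables)),
            class = "ScoreResult")
}

#' @export
print.ScoreResult <- function(x, ...) {
  cat(sprintf("ScoreResult '%s': score = %.6g (weight %.3g, %d points)\n",
              x$experimentId, x$score, x$weight, length(x$perPointResiduals)))
  invisible(x)
}

#' Aggregate per-experiment scores into a battery score
#'
#' The global score is the weighted mean `sum(w_i * s_i) / sum(w_i)`;
#' experiments with weight 0 are reported but do not influence the global
#' score.
#'
#' @param results list of `ScoreResult`
#' @return the weighted global score (scalar)
#' @export
aggregate_battery <- function(results) {
  if (length(results) < 1L) stop_expsim("battery aggregation needs >= 1 result")
  w <- vapply(results, `[[`, 0, "weight")
  s <- vapply(results, `[[`, 0, "score")
  if (sum(w) <= 0) stop_expsim("battery aggregation: all weights are zero")
  sum(w * s) / sum(w)
}
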