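# expsim

Anchor biochemical reaction-network models to structured experimental
data. `expsim` is for modellers who maintain a large, hierarchical
signalling model and want to test it — pathway by pathway — against a
battery of heterogeneous experiments: time-series stimulus/response,
dose–response, multi-stimulus (drug combination) panels, and
Hodgkin–Huxley current-clamp recordings.

Each experiment lives in a five-block tab-separated file (metadata,
biological context, stimuli, readouts, model mapping). The mapping block
names the pathway groups to extract from the composite model, entities to
delete, parameter overrides that reproduce experimental conditions
(buffers, inhibitors), and a dictionary from the experimenter's entity
names to model paths. The extracted sub-model is simulated on a stiff ODE
engine (mass action plus Michaelis–Menten kinetics,
`v = kcat·[E]·[S]/(Km+[S])`) or, for electrical experiments, a
single-compartment Hodgkin–Huxley engine, and scored against the readouts
with a user-defined expression over `{expt, sim, sem, range}` — default

```
score = sqrt( mean( ((expt − sim)/range)² ) ),   range = max(expt) − min(expt)
```

so 0 is a perfect fit. Weighted per-experiment scores aggregate into a
battery score, `Σ wᵢ·scoreᵢ / Σ wᵢ`, which a derivative-free local
optimizer can minimize over bounded model parameters.

Models are read and written in a diffable native text dialect and in SBML
Level 3 (pathway hierarchy via the SBML *groups* package, buffered pools
as boundary-condition species, stimuli as events). Both formats, and the
experiment dialect, are documented under `inst/extdata/`.

## Worked example

```r
library(expsim)
dir <- file.path(tempdir(), "demo")
fx <- make_fixture_suite(dir)            # toy models + experiments
res <- run_single(fx$composite_model, fx$binding_dr)
#> [load] model '.../composite.model'
#> [parse] experiment '.../binding_dr.tsv'
#> [extract] subset (strict policy)
#> [simulate] DoseResponse experiment 'binding_dr'
#> [score] evaluating 'sqrt(mean(((expt-sim)/range)^2))'
print(res)
#> ScoreResult 'binding_dr': score = 0 (weight 1, 7 points)

rep <- run_battery(fx$composite_model, fx$manifest)
print(rep$results); cat(sprintf("global score: %.3g\n", rep$global))
#>       experiment score weight status message
#> 1     binding_ts     0      1     ok
#> 2     binding_dr     0      1     ok
#> 3     cascade_ms     0      1     ok
#> 4 translation_ts     0      1     ok
#> global score: 0
```

The fixture experiments were generated from the composite model itself,
so every score is 0: the pipeline — parsing, sub-model extraction,
condition overrides, simulation, unit handling, scoring — reproduces its
own input exactly. Perturb a rate constant and the battery notices; the
optimizer recovers it:

```r
m <- apply_condition(load_model(fx$binding_model),
                     list(list(path = "/binding/bind", field = "Kf", value = 3)))
write_native_model(m, file.path(dir, "perturbed.model"))
fit <- optimize_parameters(file.path(dir, "perturbed.model"),
                           data.frame(exptFile = fx$binding_ts, weight = 1),
                           data.frame(path = "/binding/bind", field = "Kf",
                                      lower = 0.1, upper = 10))
cat(sprintf("score %.3g -> %.3g, fitted Kf = %.4f\n",
            fit$initialScore, fit$finalScore, fit$params$fitted))
#> score 7.03 -> 1.6e-08, fitted Kf = 1.0000
```

(The binding time-series readouts were generated at the true `Kf = 1`.)

The same three operations are available from a shell through the script
installed at `inst/cli/expsim`:

```sh
expsim run      --model composite.model --expt binding_dr.tsv [--prune] [--dump-subset sub.sbml] [--out DIR]
expsim battery  --model composite.model --manifest battery.tsv [--jobs 4] [--out DIR]
expsim optimize --model perturbed.model --manifest battery.tsv --params params.tsv [--seed 1] [--out DIR]
```

A `--config FILE` of `key=value` lines mirrors any flag; logs go to
stderr with stage tags (`[load]`, `[extract]`, `[simulate]`, `[score]`).

## Package layout

| module | contents |
|---|---|
| `R/model_core.R`, `R/native_io.R`, `R/sbml_io.R` | hierarchical model, path addressing, validation, native + SBML I/O |
| `R/subset_extract.R` | pathway extraction, deletions, dangling-reaction report, condition overrides |
| `R/experiment_def.R`, `R/units.R` | five-block experiment dialect, JSON mirror, unit frame, validation |
| `R/sim_engine.R`, `R/electro_engine.R` | stiff ODE engine with event restarts; Hodgkin–Huxley current clamp |
| `R/score_expr.R`, `R/scoring.R` | whitelisted scoring grammar, per-experiment scoring, battery aggregation |
| `R/pipeline.R` | `run_single`, `run_battery`, `optimize_parameters`, CLI |
| `R/fixtures.R` | toy-model and experiment generators, composite model, fixture suite |

See `vignettes/experiment-mapping.Rmd` for the full account of the
model semantics, numerical choices and design decisions.
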