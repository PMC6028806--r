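---
title: "Mapping structured experiments onto reaction-network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structured experiments onto reaction-network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expsim)
```

## The problem

Any single biochemical or electrophysiological experiment monitors and
perturbs only a small slice of a cell's signalling network, while models of
that network keep growing. Keeping a large composite model honest therefore
means confronting it with *many* experiments, each touching a different,
overlapping sub-part — and doing so reproducibly, from structured files
rather than ad-hoc scripts. `expsim` implements that workflow end to end:

1. a **model** is read from a native text dialect or from SBML Level 3
   (pathway grouping via the SBML `groups` package);
2. an **experiment definition** — a five-block tab-separated file
   (metadata, biological context, stimuli, readouts, model mapping) — is
   parsed, range-checked, and converted to canonical units;
3. the model-mapping block names the pathway groups to **extract**, the
   entities to delete, the parameter overrides that reproduce experimental
   conditions (buffers, inhibitors), and a dictionary from the
   experimenter's names to model paths;
4. the extracted sub-model is **simulated** under the experiment's
   stimulus protocol on a deterministic stiff-ODE engine (an embedded
   Hodgkin–Huxley engine covers current-clamp experiments);
5. simulation and readouts are compared by a user-defined **scoring
   expression**; per-experiment scores aggregate into a weighted battery
   score that can drive local parameter **optimization**.

## Model representation and kinetics

A `ReactionModel` is a tree of pathway groups addressed by rooted,
`/`-separated, case-sensitive paths (`/cell/MAPK/MAPK_p`). Selection is
exact-match: a selector naming a group takes its whole subtree, a selector
naming a leaf takes that leaf. Wildcards are deliberately absent — subtree
selection already covers the "take these pathways" use case, and exact
matching keeps failures loud (an unmatched selector is an error, never an
empty selection).

Three entity kinds carry dynamics, all in canonical units of millimolar,
seconds and litres:

* **Pools** — species with `concInit` ≥ 0; a *buffered* pool is clamped at
  `concInit` for the whole integration (derivative forced to zero), which
  is how bath-applied buffers and dose clamps are represented.
* **Reactions** — mass action, flux
  $\phi = K_f \prod_i [S_i]^{n_i} - K_b \prod_j [P_j]^{m_j}$.
* **Enzymes** — Michaelis–Menten,
  $v = k_{cat}\,[E]\,[S]/(K_m + [S])$, with the enzyme pool unconsumed.

Compartment volumes are carried and validated (> 0) but the rate equations
are written directly in concentrations; cross-compartment volume scaling is
out of scope along with diffusion and stochastic kinetics.

### SBML without libSBML

No libSBML binding is available to R, so the SBML Level 3 subset this
package needs is read and written directly over `xml2`: species
(`boundaryCondition` ↔ buffered), mass-action and Michaelis–Menten kinetic
laws, the `groups` package for hierarchy, and events for time-series
stimuli. Entity paths travel in SBML `name` attributes because SBML ids
cannot contain `/`. On import, kinetic laws are recognized through their
canonical local parameters (`Kf`/`Kb`; `Km`/`kcat` plus exactly one
modifier); any other rate law raises an error naming the offending
reaction rather than guessing. `validate_sbml_structure()` performs a
structural conformance check (root element, namespaces, required
attributes) in place of schema validation.

## Sub-model extraction

`extract_subset()` resolves the include selectors, removes the deletions
(a group path deletes its subtree), and reports **dangling reactions** —
reactions or enzymes left with an unresolvable participant. The default
policy is *strict*: any dangling entry is an error carrying the full
report, because silently dropping reactions hides modelling errors. The
*prune* policy, an explicit opt-in, removes them but logs every pruned
path as a warning. A subtler hazard — extraction severing a regulatory
input so a signal builds up without restraint — is *not* auto-detected;
it requires inspecting the simulated outcome, so the design leaves that
judgement to the user.

The entity map is many-to-one-capable: one experiment readout name may map
to several model pools whose concentrations are summed at readout time,
which is how protein isoforms lumped in a measurement but split in the
model are handled.

## Experiment classes and simulation semantics

* **Time series** — stimuli are (time, value) assignments; integration is
  restarted at every event (left-limit state, instantaneous assignment,
  continue). Before t = 0 the model is relaxed to steady state by default
  (`settle` absent); setting `settle` to 0 starts from the declared
  initial conditions, a positive value pre-integrates that long. The
  default is an interpretation — most wet-lab preparations sit in the bath
  long enough to equilibrate before the stimulus — and is configurable per
  experiment.
* **Dose response** — the dose entity is *clamped* (buffered) at each dose,
  matching bath application; each dose resets to initial conditions,
  integrates to steady state, and records the readout. "Steady state" is
  declared when $\max|\dot C| / \max(1, \max|C|) < \text{tol}$ with
  tol = 1e-6 s⁻¹ by default and a horizon `tMax` = 1e5 s; a dose that
  fails to converge is flagged but still reported, with a warning. The
  criterion is this package's own definition (configurable), since
  "steady state" is otherwise underspecified.
* **Multi-stimulus** — named combinations of settings applied at t = 0,
  each integrated independently for a stated settle time; one bar per
  combination, no state carry-over.
* **Current clamp** — a time-series experiment with `field = current`
  stimuli and a `Vm` readout, run on the classic squid-axon
  Hodgkin–Huxley compartment (no temperature correction; the shipped
  parameter set demonstrates the format, not a calibrated neuron). It
  flows through the identical parse → simulate → score path as the
  chemical classes.

### Numerical choices

The chemical integrator is `deSolve::lsoda` (stiff-capable; kinase
cascades routinely are) with rtol 1e-6 and atol 1e-9 mM, overridable per
experiment; `ode_nonstiff` selects an Adams method. Concentrations that
undershoot zero by less than 10 × atol are clipped to zero with a logged
warning; larger excursions are treated as solver failure. Simultaneous
events on distinct entities commute (verified by property test), and runs
are bit-deterministic — there is no hidden randomness anywhere in the
engine.

## Scoring

Experiment files are untrusted input, so the scoring formula is evaluated
by a purpose-built recursive-descent parser over a whitelisted grammar —
arithmetic, comparisons, and `sum`, `mean`, `sqrt`, `abs`, `min`, `max`
over the bound vectors `expt`, `sim`, `sem`, `range` — never by `eval()`.
The default formula, used when an experiment states none, is the
range-normalized root-mean-square residual

$$\text{score} = \sqrt{\operatorname{mean}\!\left(\left(\frac{expt - sim}{range}\right)^{2}\right)},
\qquad range = \max(expt) - \min(expt),$$

falling back to $\max|expt|$ for flat series. Zero is a perfect fit; the
default score is scale-invariant and permutation-symmetric. Normalization
modes `foldChange` (each series divided by its own first point) and
`percentOfMax` are applied to simulation and experiment independently
before scoring, so a readout reported in relative units never forces the
model into absolute agreement. Subjective quality judgements enter only
through the per-experiment *weight*, and the battery score is the weighted
mean $\sum w_i s_i / \sum w_i$.

## Optimization

The optimizer is deliberately local and derivative-free (global search is
out of scope): bounded Brent search for a single free parameter,
Nelder–Mead on logit-transformed coordinates for several, minimizing the
battery score. The tuned model is never allowed to score worse than the
input model — if the search ends higher, the initial parameters are
returned. A score trace flat to 1e-12 across all evaluations triggers an
unidentifiability warning.

## What the synthetic fixtures emulate — and what they do not

The fixture generators stand in for a composite cellular model and its
experiment database, which are not shippable here:

* `make_binding_model()` — reversible binding with analytic isotherm
  `RL_ss = Rtot·L/(Kd+L)`; the closed-form oracle for the engine.
* `make_cascade_model()` — a 1–4 tier activation chain with two distinct
  input pathways converging on tier 1, sized so subset selection has
  something real to exclude.
* `make_bistable_model()` — mutual Michaelis–Menten activation of two
  species with saturable (zero-order) dephosphorylation. With the shipped
  parameters the deterministic system has a stable low state, a saddle
  near 0.29 mM, and a stable high state at ≈ 0.859 mM (roots of
  $a^2 - 1.15a + 0.25 = 0$); a train of three 1 mM calcium pulses 600 s
  apart drives it across the saddle into sustained activation, while
  pulses a thousandfold smaller do not.
* `make_translation_fixture()` — a 40S + eIF4E-mRNA → 43S binding step
  plus an extraneous side pathway that the experiment's mapping block
  deletes, exercising extraction end to end.
* `make_experiment_fixture()` — generates an experiment of any class whose
  readouts are the model's *own* simulated output (plus optional Gaussian
  noise under a recorded seed), so a noise-free fixture must score ≈ 0
  through the whole pipeline; that closure property is what the test
  suite leans on.

Fixture parameters are chosen so every run finishes in a few seconds on
one CPU; the test problem sizes (e.g. 50 randomized dangling-detection
instances, 200+ round-trip cases, 6-point readouts) are stated in the
tests themselves. Passing on these fixtures demonstrates internal
consistency — correct extraction arithmetic, unit handling, solver
accuracy against closed forms, scoring algebra — not fidelity to any real
pathway: the generators produce idealized mass-action/Michaelis–Menten
kinetics with optional i.i.d. Gaussian readout noise, and real data's
systematic errors, unmodelled reactions and non-stationary baselines are
exactly what they do not contain.

## Known limitations

* SBML import recognizes the two kinetic-law families above; arbitrary
  MathML rate laws are rejected (by design, with the reaction named).
* Dose–response doses clamp forever; a "apply then washout" protocol must
  be written as a time-series experiment.
* No stochastic or spatial simulation, no chemical–electrical coupling,
  no model merging, and no ontology-driven automatic entity mapping — the
  mapping block is curated by humans on purpose.
* `jobs > 1` in `run_battery()` forks workers; on a single CPU it simply
  costs nothing and changes nothing (the report is identical by contract).
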