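# Experiment definition dialect (v1)

UTF-8, hard tab delimiter, `#` comment lines. Five mandatory blocks, each
introduced by a reserved keyword alone in column 1:
`ExperimentMetadata`, `ExperimentContext`, `Stimuli`, `Readouts`,
`ModelMapping`. A `.json` file with the same field structure (the JSON
mirror emitted by `write_experiment_json`) is accepted everywhere a `.tsv`
is.

Supported units — concentration: `M`, `mM`, `uM`, `nM`, `pM`; time: `s`,
`ms`, `min`, `h`; voltage: `mV`; current: `pA`, `nA`, `uA`. All values are
converted to the canonical frame (mM, s, mV, uA) on parse.

## ExperimentMetadata

Key/value rows: `exptType` (`TimeSeries` | `DoseResponse` |
`MultiStimulus`), `experimentId`, `transcriber`, `organization`,
`exptSource` (`paperReference` | `inHouse` | `database`; `citationId`
mandatory for `paperReference`), `citationId`, `authors`, `journal`.

## ExperimentContext

Key/value rows: `species`, `cellType`, `preparation`, `temperature`
(degrees C, in [0, 60] when given), `pH` (in [0, 14] when given), `notes`.
Optional fields are blank, not omitted.

## Stimuli

* `stimulus <entity> <field> <unit> [timeUnit]` opens a stimulus entry;
  field is `conc`, `concInit`, `buffered` or `current`.
* `point <time> <value>` rows follow (times strictly increasing;
  concentrations >= 0). For `DoseResponse` the rows are `point <dose>` —
  the enumerated doses, strictly increasing.
* MultiStimulus instead uses `combination <label>` followed by
  `setting <entity> <field> <value> <unit>` rows (settings applied at
  t = 0), plus one `settle <seconds>` row giving the readout time.

## Readouts

* `readout <entity> <field> <unit> [normalization] [timeUnit]` opens an
  entry; field is `conc` or `Vm`; normalization is `absolute` (default),
  `foldChange` (sim and expt each divided by their first point) or
  `percentOfMax` (each scaled to its own maximum).
* `point <coordinate> <value> [stderr]` rows follow. Coordinates are
  times (TimeSeries), doses equal to the stimulus doses (DoseResponse) or
  combination labels (MultiStimulus); stderr >= 0 when present.

## ModelMapping

Key/value rows `refModel`, `solver` (`ode_stiff` | `ode_nonstiff` | `hh`),
`weight` (>= 0), `scoringFormula` (whitelisted grammar over `expt`, `sim`,
`sem`, `range`; default `sqrt(mean(((expt-sim)/range)^2))`), simulation
controls `tEnd`, `dtOut`, `settle` (time-series pre-equilibration; absent
= relax to steady state first), `tMax`, `tol`; plus repeatable rows:

* `includePath <selector>` — pathway groups/entities to extract;
* `deletePath <path>` — entities (or whole groups) deleted from the
  extracted subset;
* `override <path> <field> <value>` — condition overrides, field in
  {concInit, buffered, Kf, Kb, Km, kcat, volume};
* `map <exptName> <modelPath> [<modelPath> ...]` — experiment-to-model
  entity dictionary; several model paths are summed at readout time
  (isoform mapping).
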