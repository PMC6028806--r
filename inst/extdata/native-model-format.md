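# Native model dialect (v1)

Line-oriented, UTF-8, hard-tab-separated; one entity per record; `#`
starts a comment line. Numbers are written with 17 significant digits so a
read/write cycle is exact. Canonical units: millimolar, seconds, litres.

| record | fields |
|---|---|
| `model` | name |
| `solver` | `ode_stiff` \| `ode_nonstiff` \| `hh` |
| `compartment` | name, volume (litres, > 0) |
| `group` | rooted path, e.g. `/cell/MAPK` |
| `pool` | path, compartment name, concInit (mM, >= 0), buffered (`0`/`1`) |
| `reaction` | path, Kf, Kb, substrates `path:stoich,...`, products `path:stoich,...` |
| `enzyme` | path, enzyme-pool path, substrate path, product path, Km (mM, > 0), kcat (1/s, >= 0) |
| `hh` | parameter name, value (Hodgkin-Huxley block; `Cm`, `gNa`, `gK`, `gLeak`, `ENa`, `EK`, `ELeak`) |

Paths are rooted, `/`-separated, case-sensitive, exact-match (no
wildcards). Every entity's parent path must be a declared `group` (or the
root `/`). Reaction flux is `Kf * prod([sub]^stoich) - Kb *
prod([prod]^stoich)`; enzyme rate is `kcat * [E] * [S] / (Km + [S])`.
A buffered pool is clamped at its `concInit` during integration.

Example:

```
# expsim native model v1
model	binding
solver	ode_stiff
compartment	cell	1.0000000000000001e-15
group	/binding
pool	/binding/R	cell	1	0
pool	/binding/L	cell	0	0
pool	/binding/RL	cell	0	0
reaction	/binding/bind	1	1	/binding/R:1,/binding/L:1	/binding/RL:1
```
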