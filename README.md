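# csanet

Headless description and generation of multiscale neural-network
connectivity.

`csanet` is aimed at computational neuroscientists who need to describe the
*connectivity* of large network models — hierarchies of neuron populations,
the projections between them, input/output devices — independently of any
particular simulator, and then turn that description into explicit
connection lists a simulator (or a co-simulation framework) can consume.
Models are built programmatically, serialized in a versioned, extended
NetworkML XML dialect (NeuroML 1.8.x lineage; XSD shipped under
`inst/schema/`) or a JSON mirror, expanded through connection-set-algebra
style masks, and — for models that mix simulation scales (point-neuron
spiking networks next to whole-brain neural-mass models) — split into
scale-specific sub-models with a neutral co-simulation interface
configuration.

## The core

A projection carries one declarative connectivity pattern. Each pattern is
a mask, an enumerable set of index pairs (i, j) with 0 ≤ i < N_s, 0 ≤ j <
N_t:

| pattern | mask |
|---|---|
| `conn_all_to_all()` | every ordered pair |
| `conn_one_to_one()` | i = j, i < min(N_s, N_t) |
| `conn_fixed_probability(p)` | each pair independently with probability *p* (pairwise Bernoulli) |
| `conn_per_cell(n)` | fixed fan-in: every target draws *n* distinct sources |
| `conn_gaussian_2d(sigma)` | pair accepted with probability exp(−d²/2σ²), *d* the planar distance (µm) |
| `conn_atlas(file)` | region-to-region weights/tract-length matrices from a connectome-atlas zip |

Weights and delays are drawn per connection from registered distributions
(constant, Gaussian, uniform; extensible via `register_distribution()`).
Every projection consumes an RNG stream derived from `(master seed,
projection name)`, so realizations are reproducible and independent across
projections. For the cortical-microcircuit convention that derives a fixed
total connection count K from a pairwise probability P,

    K = ln(1 − P) / ln((N_n·N_m − 1) / (N_n·N_m))

is exposed as `potjans_connection_count()`; the generator itself realizes
such projections as pairwise Bernoulli draws.

## Worked example

```r
library(csanet)

m <- build_microcircuit(microcircuit_params(), scale_factor = 0.05)
m
#> <network_model 'cortical_microcircuit': 2 groups, 9 populations (3903 neurons),
#>  67 projections, 8 inputs, 1 outputs, 0 translators>

summarize_entity(m, "l_column")
#> $depth
#> [1] 1
#> $total_neurons
#> [1] 3858

inst  <- instantiate_network(m, seed = 42)
conns <- generate_network(inst)
sum(vapply(conns, nrow, 0L))
#> [1] 725084
```

At 5 % scale the eight cortical populations hold 3858 neurons (plus a
45-neuron thalamic region); realizing the 67 Bernoulli projections with
seed 42 yields 725 084 connections, each a `(pre_gid, post_gid, weight,
delay)` record. `export_connection_list(inst, conns, dir)` writes one CSV
per projection plus a YAML manifest of gid ranges and device ids —
byte-identical for a fixed (model, seed).

The two-scale use case and its split:

```r
atlas <- make_synthetic_atlas(68, seed = 1, out_path = tempfile(fileext = ".zip"))
ms    <- build_multiscale(atlas_archive = atlas, scale_factor = 0.05)
sp    <- split_model(ms, multiscale_rules())
sp$interface
#> <cosim_interface: 2 sub-models, 1 proxies, 7 translator links>
emit_cosim_config(sp, "out/")   # nest_point_neuron.xml, tvb_neural_mass.xml, cosim.yaml
```

## Command line

A thin wrapper over the same functions ships as `inst/cli/csanet`:

```sh
csanet fixture microcircuit --scale 0.05 --out micro.xml
csanet validate micro.xml
csanet generate micro.xml --seed 1 --out connections/
csanet atlas --n 68 --seed 1 --out atlas.zip
csanet fixture multiscale --regions 68 --proxy 27 --atlas atlas.zip --out ms.xml
csanet split ms.xml --rules rules.yaml --out cosim/
```

Exit codes: 0 success, 1 validation failure, 2 I/O failure, 64 usage error.

## Acceptance script

`scripts/acceptance.R` re-runs the full toolchain from scratch — builds the
microcircuit, generates and exports its connectivity, builds the two-scale
model over a freshly generated synthetic atlas, splits it and emits the
co-simulation configuration — and writes the report JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/connectivity-generation.Rmd`) describes
the model hierarchy, the mask semantics and their statistical contracts,
the serialization dialect, the multiscale split, and all numerical and
design choices in detail.
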