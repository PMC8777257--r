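---
title: "Describing and generating multiscale network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Describing and generating multiscale network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csanet)
```

## The problem

Large network models in computational neuroscience are mostly
*connectivity*: which populations exist, how many neurons each holds, and
by what rule pairs of neurons are wired. Simulators disagree about almost
everything else, but a connectivity description can be simulator-agnostic
if it is kept declarative — a hierarchy of populations plus, per
projection, a *pattern* (a rule that induces a set of index pairs) and
distributions for the synaptic parameters. `csanet` implements that idea
as a headless library: models are built through an R API or read from a
versioned XML dialect, patterns are expanded into explicit connection
lists, and models that span simulation scales are split into per-scale
sub-models plus a co-simulation interface description.

## The model hierarchy

Populations (leaves, with a size and an opaque `cell_model` tag) are
grouped into super-populations, forming a forest; names are unique
model-wide and all cross-references are by name. Input devices (Poisson
generators), output devices (recorders) and spike/rate translator devices
live *outside* the hierarchy and take part in projections like populations
do. `summarize_entity()` reports a node's depth and total neuron count
(totals are additive by construction), and `aggregate_projections()`
projects leaf-level connectivity onto any higher abstraction level: each
projection contributes its *analytic expected* connection count to the
edge between the level-L ancestors of its endpoints. Using expectations
rather than realized samples keeps aggregation deterministic and RNG-free,
and makes total strength conserved exactly across levels.

`validate_model()` returns diagnostics instead of throwing, so a model can
be inspected mid-construction; deleting an entity cascades to its subtree
but deliberately leaves dependent projections in place as visible
diagnostics rather than silently dropping them.

## Masks and their statistical contracts

A pattern expands to a mask: 0-based pairs (i, j), enumerated
target-major. The random kinds consume exactly one primitive uniform draw
per candidate pair (Bernoulli kinds) or one sampling call per target
(fan-in), in enumeration order, from a Mersenne-Twister stream pinned to
fixed normal/sample algorithms — so a (pattern, sizes, positions, seed)
tuple determines the realization across platforms and R versions.

* `fixed_probability(p)`: pair count is Binomial(N_s·N_t, p); the test
  suite checks a chi-squared goodness of fit over 2000 replicates at
  α = 0.001.
* `per_cell(n)`: every target receives exactly `n` distinct sources
  (fan-in; Table-style fan-out is available as `direction =
  "post_to_pre"`). Sampling is without replacement by default; `multapses
  = TRUE` restores replacement. We forbid `n` larger than the available
  pool in no-multapse mode.
* `gaussian_2d(sigma)`: acceptance probability exp(−d²/2σ²) on the planar
  Euclidean distance between neuron positions (µm); no cutoff radius is
  applied. Positions come either from explicit per-neuron coordinates or
  from a per-axis template distribution sampled at instantiation.
* `one_to_one` on unequal sizes pairs the first min(N_s, N_t) indices
  rather than erroring (the conceptual mask is the infinite diagonal;
  intersecting with finite index ranges forces this).
* Auto-connections permit autapses by default (the common simulator
  default); `allow_autapses = FALSE` removes the diagonal after the draws,
  so toggling it does not shift any other pair's draw.

Every mask implementation is tested against an independent brute-force
membership oracle for all sizes up to 12×12.

### The fixed-total convention

The cortical-microcircuit literature often derives a fixed total
connection count from a pairwise probability,
K = ln(1−P) / ln((N_n·N_m − 1)/(N_n·N_m)), which `potjans_connection_count()`
evaluates (via `log1p`, for precision at large N_n·N_m) and rounds
half-up — the convention requires an integer and no rounding rule is
canonical, so half-up was fixed once. The generator itself realizes
probability patterns as pairwise Bernoulli draws, so realized counts
fluctuate around P·N_s·N_t; both conventions are therefore available, with
Bernoulli as the default.

## Instantiation and generation

`instantiate_network()` assigns 0-based contiguous gid ranges to leaf
populations in declaration order; devices get single ids directly above
the neuron range, so device connections never consume neuron gids.
`generate_projection()` maps mask indices into gid space and draws one
weight and one delay per connection, in enumeration order. Each projection
uses streams derived from `(master seed, projection name)` (a 31-bit
polynomial string hash combined with a multiplicative step), so deleting
or adding one projection never changes another's realization — a property
the suite tests directly. `stream_connections()` exposes the same records
as an iterator of bounded blocks, mirroring how simulators pull
connections from a generation library in batches.

Numerical choices: delays are clamped to a 1e-3 ms floor, since a Gaussian
delay distribution can produce non-positive draws and the connection-list
contract requires delay > 0 (the floor mimics a simulator's minimum
delay). Attribute and CSV numbers are written with the shortest decimal
representation that round-trips the double exactly, keeping file output
deterministic and locale-independent.

## Atlas connectivity

Whole-brain models describe region-to-region connectivity with two square
matrices derived from diffusion imaging: connection weights and tract
lengths (mm). `read_atlas()` loads them from a zip archive
(`weights.txt`/`.csv`, `tract_lengths.txt`/`.csv`). A single atlas
projection declared between the first and last indexed region stands for
the whole parcellation: every sibling population named `..._<index>`
participates, one connection per ordered pair with positive weight, weight
taken from the matrix and delay = tract length / conduction speed (mm over
mm/ms; default speed 1 mm/ms, the whole-brain-simulator convention, and
overridable). Zero weights produce no connection (sparse semantics).
Regions whose cell model is `"proxy"` participate like any other region.

`make_synthetic_atlas()` emulates such archives so nothing external is
ever downloaded: zero diagonals, a chosen density of positive off-diagonal
weights drawn log-uniform in [0.01, 1] (connectome weights span orders of
magnitude), and symmetric tract lengths uniform in [5, 150] mm (the range
of human cortico-cortical fibre distances). These values are plumbing
realism, chosen once and documented here; no test asserts them
numerically. What the generator does *not* emulate: the spatial structure
of real connectomes (distance-dependent weights, hemispheric symmetry,
log-normal weight tails), so a green atlas test establishes the expansion
arithmetic, not biological plausibility.

## The serialization dialect

The XML dialect is self-defined and versioned (`1.8.2-ext.1`), with an
XSD shipped in `inst/schema/`. Section order in a written file is always
populations, projections, inputs, outputs, translators; the parser
processes sections in that order *regardless* of their order in the file,
then resolves every string reference (after a successful parse every
reference is an object reference; an undefined one raises an error naming
the element, with a best-effort line number recovered by text search,
since the XML library does not expose node line numbers). Unknown elements
in the dialect's own namespace are schema errors; elements from foreign
namespaces are tolerated and ignored, as a forward-compatibility valve —
they are not, however, preserved through a read/write cycle, which keeps
model equality well-defined. A JSON mirror (`export_json()` /
`model_from_json()`) carries the same content with stable key order.
Writing is deterministic: a fixed model yields byte-identical files.

Units are declared on the root element: lengths in micrometres, delays in
ms, rates in Hz; weight units are deliberately opaque
(simulator-defined).

## Multiscale splitting

Scale membership is textual by design: each component of a multiscale
model carries a name prefix (`"l"` for the point-neuron scale,
`"Brain_region"` for the neural-mass scale in the shipped fixture), and
`assign_scales()` applies first-match-wins prefix rules to every leaf
population. `split_model()` then copies each population (with its pruned
ancestor chain) into its scale's sub-model, copies intra-scale projections
verbatim, and turns every projection touching a translator device into a
*translator link* in the interface spec — translators themselves are never
copied into sub-models, because the co-simulation framework runs them as
external modules. A direct cross-scale projection without a translator is
an error: every cross-scale information path must traverse exactly one
translator of the correct kind (spikes leave the spiking scale through a
spike-to-rate translator; rates enter it through a rate-to-spike
translator). Proxy populations (cell model `"proxy"`) are recorded with
the region index parsed from the trailing `_<integer>` of their name.
`merge_submodels()` inverts the split up to declaration order, which the
suite uses as a conservation check. `emit_cosim_config()` writes one
dialect XML per sub-model plus `cosim.yaml`; the YAML layout is this
package's own design (the co-simulation frameworks' internal formats are
not standardized), carrying sub-model files, proxy indices, translator
kinds and endpoint wiring, and atlas archive references. More than two
scales are supported by construction, but only the two-scale configuration
is exercised by fixtures.

## The shipped fixtures

`build_microcircuit()` reconstructs a four-layer cortical column (eight
populations: layers 2/3, 4, 5, 6 × excitatory/inhibitory) plus a thalamic
region, with pairwise-Bernoulli projections, Gaussian weight/delay
distributions, one Poisson input per cortical population, a spike
recorder, and thalamic projections restricted to the layer-4 and layer-6
populations. The numeric parameter table (sizes, the 8×8 probability
matrix with its thalamic column, external indegrees, synaptic parameters)
is transcribed from the original microcircuit publication (Potjans &
Diesmann 2014) into editable CSVs under `inst/extdata/`; structural
properties, not these numbers, are what the tests assert. `scale_factor`
shrinks every population multiplicatively (minimum one neuron) so tests
and examples run in seconds — 0.05 is used throughout the suite; expected
Bernoulli connection counts then scale with the factor squared.

`build_multiscale()` embeds that microcircuit (prefix `"l"`) beside a
68-region parcellation (`Brain_region_0` … `Brain_region_67`, cell model
`"nmm kuramoto"`), with region 27 as the `"proxy"` stand-in for the
territory simulated at the fine scale. Wiring follows the tunnelling
scheme: the proxy's output feeds the rate-to-spike translator, whose
output drives the layer-4/6 populations; the layer-5 excitatory population
feeds the spike-to-rate translator, whose output returns to the proxy.
Only model-name metadata is stored for the neural-mass dynamics — the
dynamics themselves, like the numeric spike/rate conversion and the
orchestration of simulators, are out of scope.

## Design decisions that were genuinely open

* **Expected vs realized aggregation** — aggregation uses analytic
  expectations so coarse views are stable under re-seeding.
* **Autapses default-on**, multapses default-off; both are explicit flags.
* **Rounding of K** — half-up, fixed once (see above).
* **Population membership is exclusive** (a forest, not a DAG): a
  population cannot sit under two super-populations, which keeps totals
  additive and gid layout unambiguous.
* **Output devices record from leaf populations only**; inputs may target
  any population by name, but connectivity is always expressed as
  projections to leaves at generation time.
* **Atlas delay** = tract length / conduction speed, default 1 mm/ms.
* **Error contract** — build errors are classed conditions
  (`csanet_naming_error`, `csanet_reference_error`,
  `csanet_validation_error`, `csanet_schema_error`, `csanet_data_error`);
  `validate_model()` alone returns diagnostics instead of throwing.

## Known limitations

* No general connection-set operator algebra (unions/intersections of
  arbitrary expressions) — only the six named patterns.
* The spatial kernel is exactly exp(−d²/2σ²) with no cutoff; other radial
  profiles would need a new pattern kind.
* Foreign-namespace XML content survives validation but not round-trips.
* `stream_connections()` materializes the projection before blocking it;
  the contract (bounded blocks, exact concatenation) is what downstream
  code may rely on, not memory behaviour.
* Generation is single-threaded R; the design favours determinism and
  testability over raw throughput.
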