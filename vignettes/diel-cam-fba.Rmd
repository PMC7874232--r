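---
title: "Diel flux balance analysis of the C3-CAM continuum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diel flux balance analysis of the C3-CAM continuum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camflux)
```

## The modeling problem

Crassulacean acid metabolism (CAM) fixes CO2 at night through PEP carboxylase
(PEPC) into malate, stores the malate in the vacuole, and decarboxylates it
behind closed stomata by day, where the released CO2 is refixed by the
Calvin-Benson cycle. Between ordinary C3 photosynthesis and full CAM lie
recognized intermediates: *CAM cycling* (daytime CO2 fixation, stomata closed
at night, respiratory CO2 refixed into a small nocturnal malate pool) and
*CAM idling* (stomata closed day and night, internal carbon recycling only).

`camflux` treats a leaf as a *diel* stoichiometric model: the metabolic
network is duplicated into a light phase and a dark phase, and designated
*transfer* reactions let a metabolite accumulate in one phase for use in the
other (starch by day, vacuolar malate by night). Flux predictions come from
linear programming: the primary objective minimizes total photon uptake
subject to steady state (`S v = 0`), flux bounds, fixed phloem-export and
maintenance demands — the assumption being that selection favors
energy-efficient metabolism. All four photosynthetic modes are then nothing
but constraint sets on the same network, and the C3-to-CAM transition can be
scanned as a one-parameter family of constraint sets.

## Scenarios

`scenario_spec()` encodes the four canonical constraint columns:

| constraint | C3 | CAM | CAM cycling | CAM idling |
|---|---|---|---|---|
| phloem export | 0.259 | 0.259 | 0.259 | 0 |
| CO2/O2 exchange (light) | free | 0 | free | 0 |
| CO2/O2 exchange (dark) | free | free | 0 | 0 |
| carb:oxy ratio (light) | 3:1 | 5.15:1 | 3:1 | 5.15:1 |
| carb:oxy ratio (dark) | 3:1 | 3:1 | 5.15:1 | 5.15:1 |

Units are umol m-2 s-1 throughout. "Free" encodes as bounds of +/- 1000, the
COBRA convention for practically unbounded exchanges; "0" closes the exchange
with bounds (0, 0). Phloem export is an equality constraint, split 3:1
between light and dark export reactions (`phloem_split`), the usual diel
leaf-model convention for sustained nocturnal export.

The RuBisCO carboxylase:oxygenase ratio is a flux-coupling constraint,
`v_carb - r * v_oxy = 0` per phase. Rather than a solver-specific side
constraint it is installed as a balanced *pseudo-species*: each carboxylase
reaction produces one unit, each oxygenase consumes `r` units, and steady
state of the pseudo-species enforces the coupling. The model therefore stays
a pure `S v = 0` system that any LP backend can consume, and
`apply_scenario()` is idempotent because it strips and reinstalls the
pseudo-rows. The coupling is installed in both phases of every scenario; in
phases where RuBisCO is idle it is satisfied vacuously at zero.

Maintenance ATP/NADPH drains are fixed-bound reactions. `apply_scenario()`
leaves them at the model's preset values unless the spec carries explicit
`maintenance` entries — genome-scale inputs typically arrive with their own
calibrated drains, while the toy model builds its defaults in.

Two restriction switches mirror common sensitivity analyses: `decarb_route`
zeroes either the malic-enzyme or the PEP-carboxykinase reactions to force a
single daytime decarboxylation route, and `storage` closes the diel transfer
reactions of all but one carbohydrate storage pool (a pool that cannot cross
the phase boundary cannot act as diel storage).

## The optimization stack

`minimize_photons()` (alias `fba()`) minimizes the summed flux of all
reactions carrying the `photon_uptake_light` role. Photon reactions exist
only in the light phase, so this is literally the total photon demand.

`pfba()` fixes the photon optimum and minimizes total absolute flux,
removing substrate cycles and picking the least-flux representative among
the alternative optima. Two numerical choices matter:

* The optimum is fixed by an *inequality*, `photons <= optimum * (1 + 1e-6)`,
  not an equality — an exact equality is one rounding error away from an
  infeasible LP.
* Each flux `v` in `[lb, ub]` is split as `v = p - q` with
  `p in [max(lb,0), max(ub,0)]` and `q in [max(-ub,0), max(-lb,0)]`. This box
  split represents the original bounds *exactly* — including fixed positive
  bounds such as the phloem equality — and `sum(p + q)` equals `sum(|v|)` at
  the optimum, so no auxiliary constraint rows are needed.

`fva()` minimizes and maximizes each reaction flux under the same photon
cap. Individual pFBA fluxes through duplicated routes (the two G6PDH
isoforms, parallel storage pools) are degenerate and solver-determined;
every scientific assertion in the package is therefore made against
objective values, accumulation transfers, or FVA ranges, never against an
individual degenerate flux. Conclusions drawn from a single pFBA solution
(accumulation signs in particular) are checked against FVA ranges in the
test suite. Note that the FVA cap's relative slack buys a small amount of
"free" flux — about `optimum * 1e-6 / cost` — so near-zero quantities are
judged at that scale, not at machine precision.

### LP backends

No dedicated LP package is assumed: the generic interface in `lp_problem()`
/ `solve_lp()` has two dense-simplex backends, `"simplex"`
(`boot::simplex()`) and `"dense"` (`pracma::linprog()` with variable bounds
encoded as explicit inequality rows — a genuinely different tableau
formulation, which makes cross-backend agreement a meaningful check; the
test suite requires agreement to 1e-8 on seeded random networks). Three
pre-processing steps make the dense backends reliable on stoichiometric
problems:

1. *Fixed-variable presolve.* Variables with `lb == ub` (closed exchanges,
   maintenance drains, phloem equalities) are substituted out before
   solving.
2. *Bound shifting.* Variables are shifted to `x = v - lb >= 0`, with upper
   bounds as inequality rows.
3. *Row-basis reduction.* The equality block is reduced to a row basis by QR
   factorization: stoichiometric matrices routinely contain linearly
   dependent balance rows, which crash naive dense simplex implementations.
   Every original row (including dropped dependent ones) is re-verified at
   the returned solution with tolerance 1e-6, so an inconsistent dependent
   row is reported as infeasibility rather than silently ignored.

Reported summary fields clamp magnitudes below 1e-7 to zero; raw flux
vectors are never clamped.

## The synthetic toy leaf

`build_toy_leaf()` constructs a lumped two-phase leaf (76 reactions, 41
metabolites) carrying every role the pipeline uses: photon-driven ATP
(cyclic, 3 photons/ATP) and NADPH (linear, 4 photons/NADPH, releasing 0.5 O2
from water splitting); RuBisCO carboxylase (3 ATP + 2 NADPH per CO2, the
textbook Calvin-Benson cost) and oxygenase (releasing 0.5 CO2 per
oxygenation with an ATP recovery cost); glycolysis/gluconeogenesis with the
3-PGA to PEP marker; PEPC, malate dehydrogenase, and an ATP-dependent
tonoplast pump (0.5 ATP/malate, the dominant nocturnal CAM cost); PEPCK and
NADP-malic-enzyme decarboxylation routes; a TCA lump ending in succinate
dehydrogenase; an NADH-dehydrogenase-fronted mitochondrial ETC (P/O 2.5);
plastidial and cytosolic G6PDH fronting an OPPP lump; starch, vacuolar
sucrose and fructan storage with diel transfers; sucrose phloem export; and
fixed maintenance drains (2.0 ATP and 0.5 NADPH per phase — round values of
the right order for a mature leaf). All parameters are configurable through
`toy_config()`; the defaults are the package's standing study conditions,
not tuning knobs.

Two conservation laws hold by construction and are asserted in tests:

* *Carbon*: every metabolite carries a carbon count and every internal
  reaction balances it, so carbon bookkeeping (`carbon_closure()`) is exact.
* *Electrons*: every redox reaction moves electron pairs consistently with
  its O2 stoichiometry. This is why the oxygenase lump's NADPH cost is
  derived as `2 - 2 * photoresp_co2_release` rather than being a free
  parameter, and why maintenance NADPH is drained through an oxidase
  (`NADPH + 0.5 O2 ->`). In the fully closed CAM-idling scenario any
  electron imbalance makes the O2 books unclosable and the LP infeasible;
  with conservation built in, all four scenarios are feasible for any
  admissible parameter set. For the same reason `randomized_variants()`
  jitters only energetic costs and demands (+/- 20 percent), never the
  redox-stoichiometric ratios, which are chemistry.

With the default configuration the four modes reproduce, *emergently*, the
qualitative pattern expected of the starch-malate cycle: photon demand
orders C3 < CAM cycling < CAM with idling lowest; starch accumulation orders
C3 < cycling < CAM; nocturnal malate storage appears exactly in the three
CAM-like modes; PEPC runs at night only where stomata are closed at night;
and in idling the daytime starch carbon exactly equals the nocturnal malate
carbon (6 carbons per glucosyl unit against 4 per malate).

What the toy does **not** emulate — and hence what passing tests do *not*
show about real leaves: there is no proton or charge bookkeeping (the
vacuolar pump cost is charged directly in ATP; the proton machinery of
genome-scale models is exercised by the correction functions instead);
cofactor pools are shared across compartments within a phase; there is no
amino-acid component in phloem export; light-period mitochondrial ATP
synthesis stays at zero because the lumped network has no daytime NADH
surplus, so the rising mitochondrial contribution seen in genome-scale
predictions has no toy counterpart; and dark respiratory fluxes are set by
the fixed maintenance drains, so they do not grow along the continuum as
they do in genome-scale models. Quantitative agreement with published
genome-scale numbers is only meaningful when the pipeline is pointed at the
corresponding genome-scale SBML input.

## The continuum sweep

`run_continuum()` anchors at the C3 solution, reads its light-period CO2
uptake (the genome-scale core model predicts 13.12 umol m-2 s-1; the toy
model's value is auto-detected), then tightens the light CO2 *import* cap
linearly to zero across a uniform grid (default 50 steps; the examples and
tests use 6-11 steps, which resolve the trends). Three design choices:

* The CO2 bound caps the import direction only; export stays free, so
  respiratory CO2 release in the light is never artificially forced. At the
  optimum the leaf never wastes carbon by exporting CO2, so this matches the
  closed-exchange scenario at the endpoint.
* O2 policy: stomatal closure throttles both gases, so the default scales
  the light O2 exchange magnitude bound by the same `(1 - t)` factor applied
  to its C3-solution value (`"unbounded"` is available for sensitivity
  analysis).
* The carboxylase fraction rises linearly from 0.75 (ratio 3:1, typical C3)
  to 0.8374 (ratio 5.15:1, the CAM median), per `carb_fraction_at()` /
  `ratio_at()`. The dark-phase ratio is interpolated identically by default
  (consistent with the CAM-cycling dark column); since dark-phase RuBisCO is
  idle at the photon optimum the choice is vacuous at the endpoints, and a
  `"fixed_3"` switch is provided.

One printed-precision subtlety: the fraction endpoint 0.8374 implies a ratio
of 0.8374/0.1626 = 5.15006, while the scenario table's CAM column uses the
printed 5.15. The sweep endpoint therefore equals a standalone CAM solve at
the *matched* ratio to solver precision (~1e-12 relative in the tests), and
the printed-ratio solve to ~1e-6-1e-5 relative — a rounding artifact of the
published anchors, not a property of the method.

Infeasible steps are flagged in the result and the sweep continues; with the
ratio interpolation disabled the sweep is a pure constraint tightening, so
photon demand is provably non-decreasing, which the tests assert.

## Genome-scale inputs

`read_diel_sbml()` consumes SBML Level 3 (FBC bounds) or Level 2
(kinetic-law bound parameters), clamping infinities to +/- 1000. Because id
conventions vary, all semantics flow through a `role_config()` YAML mapping
role names to reaction ids; the light/dark suffix convention (default "1" =
light, "2" = dark) is validated on load by requiring that the photon-uptake
role lands in the light phase — if the suffixes are swapped the error says
so. `apply_core_modifications()` applies the standard corrections a diel
core leaf model needs for these scenarios (oxygen diel transfer, vacuolar
proton accumulation, blocked free proton flow, reversible IMS proton
transport, proton leaks, the mannose hexokinase compartment fix),
idempotently, with a report of what was applied or skipped;
`reproduce_energetics()` then runs all four scenarios and optionally the
continuum in one call. Supplying the published supplementary core leaf model
this way recomputes its four-column energetics table; the model file itself
is not redistributed with the package.

## Known limitations

* Dense-simplex backends limit practical model size to a few hundred
  reactions per phase; genome-scale models at the upper end of that range
  will solve slowly.
* pFBA flux vectors are unique only up to degenerate alternative optima; use
  FVA ranges for any conclusion about an individual reaction.
* The toy model's lumped stoichiometry supports sign, ordering and
  conservation claims — not quantitative comparison with genome-scale
  predictions.
* No loop-law variant of FVA is provided; plain FVA can report thermodynamically
  infeasible cycle ranges for reactions inside closed loops.
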