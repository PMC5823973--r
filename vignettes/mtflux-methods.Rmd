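---
title: "Modeling metabolic rewiring under graded mitochondrial dysfunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling metabolic rewiring under graded mitochondrial dysfunction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtflux)
```

# The model and its assumptions

`mtflux` treats a cell's central carbon metabolism as a stoichiometric
network at steady state. A flux vector $v$ (µmol·min⁻¹·gDW⁻¹) is feasible
when $S v = 0$ and $lb \le v \le ub$, where $S$ is the stoichiometric matrix
of the packaged reconstruction and the bounds combine structural
irreversibilities, transporter capacities, and measurement-derived
constraints. Flux balance analysis (`fba()`) maximizes the flux of a single
ATP-demand reaction (`ATPM`: ATP + H₂O → ADP + Pi); there is no biomass
objective, because the scientific question is how the network sustains ATP
production, not growth. Flux variability analysis (`fva()`) then reports,
for each reaction, the minimum and maximum flux compatible with the optimum
(or a fraction `gamma` of it), which separates genuinely determined
predictions from alternate optima.

Key simplifications, all standard for small curated reconstructions:

* **Compartments.** Three (extracellular, cytosol, mitochondrion).
  Proton-motive force is a single pseudo-metabolite (`pmf_m`) produced by
  the proton-pumping complexes and consumed by ATP synthase, the
  electrogenic glutamate/aspartate antiporter, a proton leak, and the
  glutamate carrier. Free protons and charge are otherwise not tracked;
  water is tracked only where chemically central (hydrolysis, hydration,
  CIV) and freely exchanged.
* **Respiratory chain.** Lumped complexes with textbook proton
  stoichiometry: 4 H⁺ per 2 e⁻ at CI and CIII, 2 at CIV, and 4 H⁺ per ATP
  at the synthase (3 for the rotor plus 1 for phosphate/adenine-nucleotide
  transport, which are therefore modeled as electroneutral). The mtDNA
  lesion itself is never modeled mechanistically: dysfunction enters purely
  as measured (or synthetic) capacity caps on CI–CIV.
* **Reversibility.** Reactions carry signed flux in `[lb, ub]`; there is no
  forward/backward splitting. MDH1 and IDH1 are reversible and their
  direction is an *output* of the optimization. IDH1 is written with
  carboxylation (2-OG + CO₂ + NADPH → isocitrate) as the positive
  direction, so "reductive carboxylation flux" is simply `v[IDH1] > 0`.
* **Cofactor pools.** Cytosolic and mitochondrial NAD(H) are separate
  species, connected only by the malate–aspartate shuttle (MAS) and the
  glycerol-3-phosphate shuttle. Cytosolic NADPH is produced only by ME1 and
  consumed by reductive IDH1 plus a small bounded biosynthetic demand
  (`NADPHS`, ≤ 0.05); there is deliberately no free NADPH source, because an
  unconstrained one lets the optimizer turn NADPH into mitochondrial
  reducing power through an IDH1/IDH3 shuttle and harvest phantom ATP.
  The pentose phosphate pathway is outside the modeled scope.

## Why the network contains what it contains

Beyond glycolysis, TCA cycle, glutaminolysis, MAS and the reductive branch,
two components were added because the system is not self-consistent without
them:

* **Alanine aminotransferase (ALT).** A cytosolic glutamate → 2-OG
  conversion is required for a reductive-carboxylation mode that does not
  consume the very oxaloacetate it produces (the GOT1 route is circular in
  that respect). ALT disposes of the amino group onto abundant glycolytic
  pyruvate, and the resulting alanine is secreted — a textbook glutaminolysis
  output.
* **Glycerol-3-phosphate shuttle (GPD1/GPD2).** Without an alternative,
  respiratory-chain-coupled cytosolic NADH sink, MDH1 would be 100%
  essential under *every* condition and the condition-dependence of its ATP
  contribution (the scientifically interesting readout) would be
  invisible.

Several capacities are finite on purpose (values in µmol·min⁻¹·gDW⁻¹):
lactate export (`LACt` ≤ 1.6, transporter saturation), the
glutamate/aspartate antiporter (`GAA` ≤ 2, it sets the MAS ceiling together
with complex I), the glycerophosphate shuttle (`GPD2` ≤ 0.1, a minor shuttle
in most cell types), the citrate carrier (`CIC` ≤ 0.05, citrate export for
lipogenesis is a trickle compared to central flux), and a lipogenic
acetyl-CoA demand (`LIPID` ≤ 5). These are structural modeling choices, made
once so that the network expresses the physiology being studied — overflow
lactate at high glycolytic flux, a shuttle hierarchy, and a reductive branch
that only pays when everything else is saturated — and they are all plainly
visible in `inst/extdata/reference_model.json`.

## Atom maps and the tracer simulators

Every carbon-carrying reaction has an atom map in letter-per-carbon
notation (`"akg_c:abcde" + "co2_c:f" -> "icit_c:abcfde"`). Citrate slots 1–4
are the oxaloacetate moiety and 5–6 the acetyl moiety; the
carboxylation-derived carbon occupies slot 4, which makes both oxidative
decarboxylations of a TCA turn release oxaloacetate-derived carbons, as
classical tracer chemistry requires. Fumarate and succinate are declared
symmetric with the reversal permutation; production of a symmetric species
averages the two molecular orientations (50/50 scrambling), which is why
reductively derived malate m+3 stays m+3 while its ME1 product is an
m+2/m+3 mixture — the simulator reports the mixture and no single-value
claim is made for that metabolite.

`simulate_13c()` solves the steady-state labeling problem by EMU
decomposition: elementary metabolite units are generated backward from the
metabolites of interest, grouped by size, and each size class is one linear
solve; convolution couples a size only to strictly smaller sizes. Only net
fluxes are used (reactions are oriented by the sign of their flux);
bidirectional exchange-flux labeling effects are out of scope. CO₂ is an
infinite unlabeled pool unless the tracer itself labels it. The simulator
is checked in the test suite against an entirely independent brute-force
full-isotopomer fixed-point simulation (state space $2^n$ per metabolite) to
1e-9 on randomized atom-mapped networks; both methods share the standard
independence assumption for condensation reactions, so agreement is exact.

`simulate_2h_hydride()` implements the deuterium bookkeeping of
NADH-coupled tracing as a single well-mixed cytosolic NAD(H) pool. The
deuteron of 4-²H-glucose rides its carbon through the atom maps — glucose C4
becomes C1 of the glyceraldehyde-3-phosphate half of the aldolase split, so
at most half of the GAP pool is deuterated at the donor position — and the
pool enrichment is the flux-weighted deuterated share of all NADH-producing
fluxes. Every annotated NADH-consuming reduction labels its product m+1 at
the pool enrichment. No kinetic isotope effects, no solvent exchange, no
mitochondrial NADH deuteration: predicted fractions are upper bounds by
construction, but predicted *mass shifts* (the integer observable) are
exact.

`route_masks()` is the formal version of a labeling schematic: a
deterministic single pass of the tracer's labeled positions along an
ordered reaction list, with co-substrates unlabeled and no mixing. When flux
is genuinely confined to the route, its prediction coincides with the full
simulator's dominant isotopologue (tested).

# Measurement conversion

Exchange rates follow the consumption-and-release logic: `rate =
(spent - fresh) * volume / (cell_time_integral * gdw_per_cell * 60)`,
negative for consumption. The dry-weight-per-cell bridge (default 3e-10
g/cell) and the protein-per-dry-weight bridge used for respirometry
(default 5e5 µg/gDW, with a factor 2 from O₂ to electron pairs) are
configuration constants, not measurements; both are exposed as arguments so
they can be logged and overridden. Measured exchange rates become intervals
`rate ± k·SE` (k = 1 by default; the replicate SE is the sample SD over
√n, zero with a warning for single replicates), and complex-resolved OCR
becomes upper bounds on CI–CIV. Constraints only ever tighten structural
bounds; a measurement that would widen them is clipped with a warning, and
an empty intersection is an error. When a jointly infeasible measurement set
must be used anyway, `elastic_relax()` finds the minimum total (L1)
relaxation of the measured intervals and reports exactly which measurements
moved and by how much.

Isotopologue tables are normalized per sample to the total ion sum and per
metabolite to the total isotopologue sum ("proportion of total pool");
natural-abundance correction is off by default to match that convention,
with a classical binomial-matrix correction available behind
`correct_natural_abundance()`.

# The synthetic heteroplasmy panel

`make_profile(h, seed)` defines the study conditions. Each
respiratory-complex capacity is scaled by `max(0, 1 - 0.9 h)` and glucose
uptake by `1 + 1.5 h`; the functional form is a modeling choice (the data
the panel emulates show monotone dose dependence, not a particular shape),
so the package only ever asserts orderings across `h`, never values.
Baseline capacities (CI 2.4, CII 0.8, CIII 2.6, CIV 2.8, glucose 0.55,
glutamine 0.4 µmol·min⁻¹·gDW⁻¹) were chosen once so that the unperturbed
network respires near capacity with modest overflow lactate. Glucose and
glutamine uptake are pinned (transporter- and program-limited rather than
optimality-chosen), pyruvate uptake is capped by its medium abundance, and
aspartate uptake is zero because the standard medium contains none — the
aspartate-supplemented experiment can be emulated by overriding
`fresh_medium` and `asp_uptake_max` in the base parameter list.

The ground truth of a profile is the deterministic FBA optimum under those
capacities. The qualitative switch falls out of capacity arithmetic rather
than delicate price comparisons: at low `h`, lactate export alone can carry
the glycolytic NADH load and reductive carboxylation is strictly wasteful
(FVA certifies `IDH1 = 0` uniquely); at high `h`, forced glycolytic NADH
exceeds the summed capacity of lactate export, the MAS (itself capped by
complex I) and the glycerophosphate shuttle, so a strictly positive
IDH1–ACL–MDH1 flux is *required for feasibility*, and knocking out IDH1 or
MDH1 collapses the condition entirely. This mirrors the biology the package
models, with one documented departure: because cytosolic NADPH comes only
from ME1, the reductively formed malate is consumed by ME1 rather than
secreted; net malate/fumarate secretion from this route would need an NADPH
source (pentose phosphate pathway) outside the modeled scope.

Generators add multiplicative Gaussian noise (default CV 5%, a typical
plate-assay scale) to concentrations, rates and intensities, clamped at
zero with a flag; plate layouts follow the substrate/inhibitor protocol
(glutamate/malate–rotenone, succinate–antimycin, duroquinol–antimycin,
TMPD/ascorbate–azide). Seeding is one master seed per profile with fixed
per-table offsets, so any dataset is a pure, byte-identical function of
`(profile, arguments)`. Labeling tables report whole-cell pools: cytosolic
and mitochondrial distributions are averaged weighted by each compartment's
production rate, a steady-state proxy for what LC-MS actually measures.

What passing tests do and do not show: the generator emulates capacity
scalings, replicate noise and steady-state labeling, but not pool-size
kinetics, isotopically non-stationary labeling, medium depletion over time,
or biological replicate structure; recovery results on synthetic data
therefore validate the pipeline's arithmetic and the model's qualitative
physiology, not the quantitative accuracy of any particular real dataset.

# Numerical choices

* **LP solver.** A dense two-phase primal simplex with Bland's rule,
  written for this package: the problems are tiny (≤ ~100 variables), and
  Bland's rule guarantees termination on the highly degenerate bases that
  stoichiometric LPs produce. Pivot tolerance 1e-9; contract-level checks
  (mass balance, bound satisfaction, FVA containment) at 1e-6. Solves are
  single-threaded and deterministic, so repeated runs return the same
  vertex; degenerate optima are characterized, not hidden — `fva()` ships
  range information alongside every flux-difference table.
* **Infeasible knockouts** are recorded as a contribution equal to the full
  objective (total loss), which is the natural reading of an in-silico
  deletion that the condition cannot survive.
* **Top-decile flagging** uses `ceiling(0.10 * n)` reactions ranked by
  `|delta|`, ties broken by reaction id; exchange reactions are included
  but labeled, so either convention can be recovered.
* **EMU systems** are solved size-by-size with dense `solve()`; a singular
  system means a traced metabolite has no effective production and is
  reported as such. Isotopologue vectors are clipped at zero and
  renormalized only to remove round-off (≤ 1e-12).
* **Monte-Carlo recovery checks** compare recovered rates against the
  generator's closed-form standard error (the estimator is linear in the
  noisy concentrations, so its exact SE is available); with three
  replicates a sample-SD-based 3·SE interval would have only ~90% coverage
  (Student t with 2 degrees of freedom) and would say nothing about the
  pipeline.

# Known limitations

* Flux predictions are condition-level and qualitative by design: the
  reconstruction is a fresh build of the named pathways, not a byte-level
  copy of any published genome-scale model, so absolute flux values are
  only meaningful relative to its own capacity choices.
* Net-flux labeling only; reversible reactions at thermodynamic
  near-equilibrium would exchange label bidirectionally and broaden real
  distributions relative to the simulation.
* The MAS is inactive at low heteroplasmy in the synthetic panel (lactate
  export is cheaper under the chosen capacities); the shuttle hierarchy,
  not MAS activity per se, is what the acceptance properties exercise.
* The deuterium model's per-molecule fractions are upper bounds (no
  exchange losses); only integer mass shifts should be compared with
  experiments quantitatively.
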