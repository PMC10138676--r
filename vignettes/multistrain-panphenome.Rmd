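---
title: "From one curated model to a species panphenome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From one curated model to a species panphenome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemkit)
```

This vignette explains the models and procedures behind `gemkit`, the
assumptions they rest on, the parameters that matter, and the design choices
we made where more than one defensible option existed.

## The constraint-based model

A genome-scale metabolic model is a stoichiometric matrix $S$ (metabolites ×
reactions), flux bounds $lb \le v \le ub$ in mmol gDW⁻¹ h⁻¹, and per-reaction
gene–protein–reaction (GPR) boolean rules in which AND joins subunits of a
complex and OR joins isozymes. Flux balance analysis (FBA) assumes metabolic
steady state and solves

$$\max\ c^\top v \quad \text{s.t.}\quad S v = 0,\ \ lb \le v \le ub,$$

with the biomass pseudo-reaction as the objective, so the optimum is the
predicted growth rate in h⁻¹. The steady-state assumption means FBA predicts
capabilities, not kinetics: it can say a strain *can* grow on xylose, not how
fast regulation will actually let it.

Conventions follow the BiGG/COBRA community: metabolite ids carry a
compartment suffix (`_c` cytosol, `_e` extracellular), an exchange reaction is
the boundary pseudo-reaction of one extracellular species written `met_e →`,
uptake is a negative exchange flux, and "unconstrained" bounds are ±1000.
Other compartment codes are accepted on read but flagged, since the analyses
here are built around a two-compartment bacterial cell.

### The LP solver

The package carries its own dense bounded-variable two-phase simplex
(`R/lp.R`). At the network sizes the package targets (tens to a few hundred
reactions) a dense method with a full basis refactorisation at every
iteration is fast enough and numerically boring, which is what one wants
underneath thousands of screening solves. Bland's rule engages after a run of
degenerate steps, so termination is guaranteed. The test suite validates the
solver against exhaustive LP-vertex enumeration on small random networks and
against the analytic optima of the synthetic models. Feasibility tolerance is
1e-9; fluxes below 1e-6 are treated as zero in reports. Degenerate alternate
optima are real in FBA; the package guarantees the objective value and the
binary growth call are reproducible, not the full flux vector (no flux
variability analysis is attempted).

## Quality-control diagnostics

Three automated checks mirror the defect categories that dominate manual GEM
curation. All three **report** defects; none of them repairs anything,
because the correct fix is a biochemical judgement, not an algorithmic one.

* **Mass/charge balance.** Formulas are parsed with a Hill-style grammar
  (element symbol + optional count). For each internal reaction we sum
  coefficient × atom count per element and coefficient × charge; a balanced
  reaction has all-zero sums. Reactions touching any species with a missing
  or polymeric formula (`R`, `X` groups) are reported `unknown_formula`
  rather than given a fabricated verdict. Biomass is exempt (it is
  pseudo-stoichiometric by design) and so are exchanges (they create and
  destroy mass by construction).
* **Dead ends.** A species no reaction can consume (or none can produce)
  under the current bounds forces zero flux through its neighbourhood at
  steady state. Reversible reactions count as both producers and consumers of
  every participant.
* **Energy-generating cycles.** With every exchange clamped to `[0, 0]` a
  thermodynamically sound network cannot sustain ATP hydrolysis, so the
  maximum flux through the ATP maintenance (ATPM) reaction must be 0. A
  positive value certifies a futile loop — the classic example being a
  carboxylase-type reaction left reversible so that, run backwards, it
  regenerates ATP for free. Which hydrolysis reaction anchors the check is
  configurable (`atpm_id`), since model nomenclature varies; a reaction named
  `ATPM` is picked up automatically.

## The carbon-source screen

`screen_carbon_sources()` fixes each candidate's uptake at 10 mmol gDW⁻¹ h⁻¹
(the conventional non-limiting rate) on top of a carbon-free base medium and
records growth, the binary growth call, and secreted byproducts. Oxygen
uptake is left unconstrained in aerobic screens unless the base medium fixes
it; `anaerobic = TRUE` closes it.

The binary call uses `growth_threshold = 1e-6` h⁻¹ — three orders of
magnitude above solver tolerance and far below any biologically meaningful
growth rate, so the call is insensitive to either.

Growth rates across sources are not directly comparable because a mole of a
6-carbon sugar feeds three times the carbon of a 2-carbon acid. Two
normalizations are provided and the choice is recorded in the output:

* `per_carbon` (default): divide the growth rate by the carbon count of the
  source; cheap and monotone.
* `carbon_equivalent_uptake`: re-solve with the uptake bound set to
  `60 / n_carbons`, so every source supplies the same carbon flux as glucose
  (6 C) at uptake 10.

Carbon counts come from the formula of the exchanged species; a source with
an unparseable formula is skipped with a warning rather than guessed, since a
wrong carbon count silently corrupts every normalized value downstream.

## Ortholog calling and strain derivation

Presence calling from a gene × strain percent-identity matrix uses a primary
threshold of 70% with a prevalence-triggered relaxation: when a gene's
identity exceeds 40% in **more than** 75% of strains, that gene's threshold
drops to 40% for all strains. Boundary semantics are deliberately literal:
presence uses `>= threshold`, prevalence counts identities **strictly over**
40 and fires **strictly above** 0.75. The prevalence criterion is evaluated
per gene; a cohort-wide reading is conceivable, but the per-gene reading is
the one that makes the rule do useful work (rescuing widely conserved genes
whose alignments are mediocre in every strain).

Strain models are derived by GPR evaluation: a template reaction is removed
when its rule evaluates false under the strain's present-gene set. Reactions
without a GPR — transporters of unknown genetics, spontaneous reactions —
plus all exchanges and the biomass reaction are always retained: absence of
gene evidence is not evidence of absence, and deleting them would fabricate
phenotypes. Retained rules are pruned to the present genes (dead OR branches
disappear) so the strain model's gene list and rules stay mutually
consistent. Two invariants follow by construction and are enforced in tests:
a strain's reaction set is a subset of the template's, and its growth rate on
any medium never exceeds the template's.

## Gap filling

A derived strain that grows on **no** screened source is repaired by adding
reactions from a donor bag (by default the template's reactions absent from
the strain; any donor model can be supplied). The objective is minimum
cardinality — the smallest set of additions that restores growth above the
threshold — because every added reaction is an evidence-free hypothesis and
fewer hypotheses are better. The growth target is the binary-call threshold,
not the template's growth rate: the repair claims viability, not wild-type
fitness.

The implementation is an exact combinatorial search: donor reactions that
cannot carry flux even in the full model+donor union are first discarded (a
sound reduction, since a subset network's flux space is contained in the
union's), then subsets are tested in order of increasing size with a single
pre-assembled LP in which excluded donors are clamped to zero. Ties are
broken lexicographically by reaction id, making results deterministic. At the
donor-bag sizes that arise in template-based derivation this finds the same
optimum a mixed-integer formulation with binary inclusion indicators would;
`max_additions` (default 5) bounds the search depth, and a model that cannot
be repaired even by the full bag is reported `unfillable` rather than
silently passed through. The test suite checks returned cardinalities against
an independent exhaustive enumeration on bags of up to 15 reactions.

## Panphenome classification and clustering

For each carbon source the growth fraction $f$ is the share of functional
strains with a positive growth call. Sources with $f > 0.9$ are *universal*,
$f < 0.3$ *strain-specific*, and *core* in between; both boundaries are read
inclusively into the core class ("between 30% and 90%"). The thresholds are
parameters of `classify_sources()`, and the classes are a function of $f$
alone, so permuting strains can never change a class.

Strains are clustered by agglomerative hierarchical clustering on Manhattan
distances between growth profiles. Manhattan distance treats each source as
an independent coordinate and is robust to a single extreme growth value
dominating the profile, which suits a matrix mixing many moderate rates. The
linkage is complete by default — compact, diameter-controlled clusters that
pair naturally with Manhattan distances — and configurable (Ward linkage is
not offered on Manhattan distances, where its variance interpretation is
incoherent). The two-way cut is labelled by versatility: the group with the
larger mean number of growth-supporting sources is HMV. Within HMV a second
two-way cut yields the α/β subgroups; marker compounds distinguishing the
subgroups are reported from the data, never hard-coded as the split rule. The
clustering layer is the carbon-normalized growth matrix by default, with raw
and binary layers available, since the normalized layer is the one the class
definitions and the heatmap are built on. All-identical profiles are a
degenerate case: a single cluster is reported and labelling is skipped
instead of manufacturing a spurious split.

## Robust flux comparison

Predicted central-carbon fluxes are compared against measured ones with the
biweight midcorrelation: with $u_i = (x_i - \mathrm{med}\,x) / (9\,
\mathrm{mad}\,x)$ (MAD unscaled, no 1.4826 consistency factor — the canonical
bicor definition fixes the 9·MAD denominator), weights
$w_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1]$, and
$\tilde x_i = (x_i - \mathrm{med}\,x) w_i$,

$$\mathrm{bicor}(x, y) = \frac{\sum_i \tilde x_i \tilde y_i}
{\sqrt{\sum_i \tilde x_i^2}\sqrt{\sum_i \tilde y_i^2}}.$$

Flux data are small-n, non-Gaussian and outlier-prone (a single mis-mapped
reaction can be off by an order of magnitude), which is exactly the regime
where Pearson's $r$ fails; the suite demonstrates the contrast on a fixed
contaminated fixture. Significance uses a permutation test (default 10⁴
permutations, seeded, add-one corrected) rather than a t-approximation,
because the per-pathway sample sizes (a TCA cycle has ~8 reactions) are far
too small for asymptotics. Measured fluxes reported for the reverse of a
model reaction are negated through an explicit per-reaction `orientation`
column — sign conventions are data, not something to infer. Degenerate inputs
(fewer than 3 pairs, zero MAD) produce explicit errors or skipped
comparisons, never silent numbers.

## What the synthetic generators emulate — and what they don't

`make_toy_gem()` builds one linear catabolic pathway per carbon source
(exchange → transporter → catabolism → biomass) with exact carbon
conservation (the biomass precursor and overflow byproduct are both CH₂O
units) and an ATP stoichiometry arranged so that at optimum the ATP supply
exactly covers the biomass demand. Consequently the FBA optimum is
*analytically* growth = yield × uptake, and the generator's answer sheet
(expected optima, expected dead ends, expected balance verdicts, required
gene sets per source) is computed by construction-time bookkeeping — never by
running the modules under test, so the oracles are not circular. Planted
defects are opt-in: a mass-unbalanced reaction, a reversible
ATP-regenerating loop, orphan metabolites, or a removed pathway step for
gap-filling.

`make_strain_cohort()` plants i.i.d. gene losses at a configurable rate
(default 5%, a realistic per-gene loss rate within a bacterial species;
sample size default 20 strains) and samples percent identity from
Uniform(85, 100) for retained genes and Uniform(0, 30) for lost ones — far
from both calling thresholds, so threshold recovery is exact by design. A
`borderline_frac` of cells can be resampled inside [35, 65], deliberately
straddling the 40/70 thresholds, to stress the relaxation rule.
`make_flux_measurements()` adds Gaussian noise and replaces a fraction of
measurements by 10× their magnitude.

These generators are deliberately *not* realistic genome-scale networks: no
cofactor coupling across pathways, no branched or cyclic topology, no
correlated gene loss along operons, no homology values that depend on
phylogeny. Passing tests therefore certify the **algorithms** — LP optima,
threshold logic, search minimality, classification arithmetic — on inputs
with known ground truth; they do not certify that any particular organism's
published model is correct, and results on real models inherit all the usual
GEM caveats (biomass composition, bounds provenance, annotation quality).

## Numerical and degenerate-input policy

* Bounds beyond ±1000 are clamped to ±1000 when solving (the community's
  "unconstrained" magnitude); media may narrow but not widen them.
* Infeasible FBA is a *status*, not an exception; screens record it as zero
  growth. Non-optimal solutions refuse to report secretion.
* Growth calls use strictly-greater-than `1e-6` h⁻¹ everywhere (screen,
  gap-fill target, classification), so the same margin separates "grows"
  from solver noise in every module.
* Gap-fill ties (several minimum sets) resolve lexicographically; hclust
  leaf order is deterministic for fixed input, so exports are byte-stable
  across runs.
* Zero strains, empty growth matrices, all-identical profiles, zero-MAD
  vectors and yield requests above the stoichiometric maximum all fail fast
  with typed errors.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on the synthetic
conditions: toy networks of 7–16 reactions (small enough that exhaustive
vertex enumeration is an exact LP oracle), cohorts of 20 strains at 5% gene
loss, donor bags up to 15 reactions for gap-fill minimality, classification
matrices of 100 strains with planted growth fractions {0.95, 0.50, 0.10},
and flux vectors of length 10–12 for the correlation properties (with one
10⁴-point draw for the bicor-versus-Pearson convergence check). These sizes
make every oracle exact while keeping the whole suite comfortably
interactive.

## Known limitations

* No flux variability analysis, parsimonious FBA, or kinetic integration;
  alternate optima are acknowledged, not enumerated.
* Gap filling is exact but exponential in the addition count; it is meant for
  template-derived strains missing a handful of reactions, not for drafting
  models from scratch against a universal reaction database.
* Homology computation is out of scope: the gene × strain identity matrix is
  an input, produced by whatever alignment pipeline the user trusts.
* SBML support targets Level 3 + FBC v2 as written by current tooling; exotic
  constructs (species references with mathematics, non-FBC bounds) are not
  handled.
* The HMV/LMV and α/β labels are descriptive conveniences over a dendrogram
  cut; they are not phylogenetic claims.
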