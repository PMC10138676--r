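# gemkit

Constraint-based multistrain metabolic modeling and panphenome analysis in R.

`gemkit` is for microbiologists and systems biologists who work with
genome-scale metabolic models (GEMs) of bacterial species — the motivating
case is *Bacillus subtilis*, a workhorse of industrial biotechnology — and who
want to go from **one curated reference model** to **a species-wide picture of
metabolic capability**: which carbon sources each sequenced strain can grow
on, which sources are universal to the species versus private to a few
strains, and which strains are metabolically versatile.

## What it does

**Model quality control.** A GEM is a stoichiometric matrix *S* over
metabolites × reactions, with flux bounds and gene–protein–reaction (GPR)
boolean rules. `gemkit` reads and writes SBML Level 3 (FBC v2) and COBRA-style
JSON, and audits the classic curation defects:

* mass/charge balance per reaction (`check_mass_charge_balance()`), from
  Hill-style chemical formulas; unknown formulas are reported, never guessed;
* dead-end metabolites — produced-only or consumed-only species that break
  the steady-state material balance (`find_dead_end_metabolites()`);
* energy-generating cycles: with every exchange closed, the maximal flux
  through the ATP maintenance reaction must be 0; anything more certifies a
  thermodynamically impossible loop (`check_energy_generating_cycle()`).

**Flux balance analysis.** `solve_fba()` solves the linear program

```
max  c'v    s.t.   S v = 0,   lb <= v <= ub
```

with the biomass pseudo-reaction as objective; its optimal flux is the growth
rate (h⁻¹). Media are exchange-reaction bounds (uptake = negative lower
bound), and `screen_carbon_sources()` runs one FBA per candidate source at a
fixed uptake (default 10 mmol gDW⁻¹ h⁻¹), recording growth, secreted
byproducts, and growth normalized by the carbon content of the source. The LP
solver is a dense bounded-variable two-phase simplex built into the package
and validated in the test suite against exhaustive vertex enumeration.

**Multistrain derivation.** Given a gene × strain percent-identity matrix,
`call_orthologs()` marks a gene present in a strain when identity ≥ 70%,
relaxing the threshold to 40% for genes whose identity exceeds 40% in more
than 75% of strains. `derive_strain_model()` then prunes every template
reaction whose GPR evaluates false (exchanges, biomass and GPR-free reactions
are always kept), and `gap_fill()` / `multi_gap_fill()` repair strains that
grow nowhere by adding a provably minimum-cardinality set of donor reactions.

**Panphenome.** `build_growth_matrix()` assembles the strain × carbon-source
growth matrix; `classify_sources()` labels each source *universal* (> 90% of
strains grow), *core* (30–90%) or *strain-specific* (< 30%); and
`cluster_strains()` groups strains by Manhattan-distance hierarchical
clustering into high- and low-metabolic-versatility (HMV/LMV) classes.

**Robust flux comparison.** `bicor()` implements the biweight
midcorrelation — a median/MAD-based correlation that down-weights outliers
with Tukey's biweight — and `compare_flux_sets()` applies it per pathway
(glycolysis, PPP, TCA) to predicted-versus-measured flux tables, with a
permutation p-value.

**Synthetic data.** `make_toy_gem()`, `make_strain_cohort()` and
`make_flux_measurements()` generate small networks with analytically known
FBA optima, cohorts with planted gene losses, and noisy flux measurements, so
the whole pipeline is testable without any external model files.

## Worked example

```r
library(gemkit)

# a small self-contained model: two catabolic pathways, biomass, ATPM
toy <- make_toy_gem(toy_gem_spec(sources = list(
  glc = list(n_carbons = 6, yield = 0.6),
  mal = list(n_carbons = 4, yield = 0.3))))
toy$model
#> <metabolic_model> toygem_seed1
#>   reactions:   10
#>   metabolites: 11
#>   genes:       8
#>   objective:   BIOMASS
#>   atpm:        ATPM

# growth on glucose at an uptake of 10 mmol/gDW/h
sol <- solve_fba(apply_medium(toy$model, medium(list(EX_glc_e = c(-10, 1000)))))
glance(sol)
#> # A tibble: 1 × 3
#>   status  objective_value max_residual
#>   <chr>             <dbl>        <dbl>
#> 1 optimal               6            0
```

The growth rate is 6 h⁻¹ = yield (0.6 per unit uptake) × uptake (10): the toy
network is built so the optimum is known analytically. The carbons not fixed
into biomass leave as overflow byproduct:

```r
predict_secretion(sol)
#> # A tibble: 1 × 2
#>   exchange_id  flux
#>   <chr>       <dbl>
#> 1 EX_waste_e     54
```

A cohort of 20 strains with 25% planted gene loss, derived, screened and
classified:

```r
cohort <- make_strain_cohort(toy, cohort_spec(n_strains = 20,
                                              deletion_rate = 0.25, seed = 7))
presence <- call_orthologs(cohort$homology)
models <- derive_strain_cohort(toy$model, presence)
gm <- build_growth_matrix(models, toy$answer$sources$exchange_id, toy$base_medium)
classify_sources(gm)
#> # A tibble: 2 × 3
#>   carbon_source growth_fraction class
#> 1 EX_glc_e                 0.7  core
#> 2 EX_mal_e                 0.75 core

cluster_strains(gm)
#> <strain_clustering> 20 strains, manhattan distance, complete linkage
#> HMV LMV
#>  14   6
```

70% of the strains retained a working glucose pathway and 75% a malate
pathway, so both sources classify as *core* (between 30% and 90% of strains);
the 14 strains that kept both pathways cluster as HMV, the rest as LMV.
`autoplot(gm, clustering = cluster_strains(gm))` draws the growth heatmap;
`run_pipeline(run_config(...))` performs all stages from files on disk and
writes every intermediate artifact (presence calls, per-strain models,
gap-fill report, panphenome bundle) to an output directory.

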