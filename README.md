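# forestTPD

Trait probability densities and biomass demography for tropical dry
forest censuses.

## The problem

Seasonally dry tropical forests are assembled along two functional
dimensions: a *hydraulic safety–efficiency trade-off* (dense, narrow
vessels with thick fibre walls versus wide conduits, large pits and high
theoretical conductivity) and a gradient of *investment in tissues*
(dense wood and high leaf dry matter content versus cheap, large,
water-rich leaves). When a drought hits a forest between two censuses,
the interesting question is not just how much biomass grew, recruited or
died, but *which trait combinations* carried each of those biomass
fluxes — whether mortality removed biomass from a wider region of the
trait space than growth replaced, and whether net losses and net gains
occupy different functional territory.

`forestTPD` is for ecologists holding (a) an individual-level table of
15 leaf and wood traits, (b) a two-census tree inventory with
survivor/dead/recruit status, and (c) species-level wood densities, who
want that question answered with explicit, testable conventions. A
built-in synthetic community generator with known ground truth makes the
whole chain verifiable without field data.

## What it computes

* **Derived hydraulic traits** — hydraulically weighted vessel diameter
  $d_h = (\sum d_i^4/N)^{1/4}$; theoretical xylem conductivity
  $K_p = \frac{\pi\rho_w}{128\eta} d_h^4\,VD$; water content at fibre
  saturation $WC_{fsp} = 1/WD - 1/WD_0$ and maximal water content
  $WC_{max} = (1.5-WD_0)/(1.5\,WD_0) + WC_{fsp}$ — plus validation
  against global reference ranges.
* **Trait space** — individual-level PCA of the 15 traits (log transforms
  for right-skewed traits), two axes retained, varimax rotation with a
  coordinate-preservation check, and missing-trait imputation by
  iterative random forests with plot and species as predictors.
* **Biomass ledger** — per species × plot: standing biomass and the four
  demographic dimensions from a pluggable allometry: growth of survivors
  (`BG_S`), growth of recruits from a 2.5 cm threshold counted from DBH 0
  (`BG_R`), mortality corrected to the same threshold (`BM`), and the
  identity `NBC = BG_S + BG_R − BM`, enforced per population, per plot
  and network-wide (t ha⁻¹ yr⁻¹).
* **Trait probability densities** — per-population bivariate Gaussian
  kernel densities on a shared grid (unconstrained normal-scale
  bandwidths for n ≥ 3; SD-on-mean regression predictions for rarer
  populations), combined into community densities weighted by any
  biomass dimension; functional richness (area of the 99%
  highest-density region), dominance regions (TPD 20/50/99%) with
  population counts and biomass shares, overlap dissimilarity
  $\beta_O = 1 - \sum \min(a,b)$, and 999-draw randomization nulls for
  richness differences and overlap.

## Worked example

The one-call pipeline on the default synthetic community — 4 one-hectare
plots, 500 trees each from a 60-species pool, censused across a 3-year
drought interval:

```r
library(forestTPD)
res <- run_full_analysis(default_config(seed = 1))
print(res)
```

```
Trait-space / biomass-demography analysis

Two-dimensional functional trait space (PCA + varimax)
  individuals: 921, traits: 15
  retained variance: 63.86% (axis 1 35.80%, axis 2 28.07%)
Rotation fidelity (rank correlation of pre- vs post-rotation scores)
  axis 1: rho = 0.999 (matched to raw axis 1)
  axis 2: rho = 0.999 (matched to raw axis 2)
  coordinate system preserved

Biomass demography ledger
  214 populations over 4 plots (4.0 ha), interval 3.00-3.01 yr
  network totals (t yr^-1): BG_S 3.59 + BG_R 0.05 - BM 3.02 = NBC 0.62
  per-ha means  (t ha^-1 yr^-1): BG_S 0.898, BG_R 0.011, BM 0.754, NBC 0.155
  standing biomass (t): 112.4 at t0, 114.1 at tfin

Functional richness by biomass dimension:
             dimension  fric
   standing_biomass_t0 137.3
 standing_biomass_tfin 134.2
                  bg_s 104.8
                  bg_r 115.6
                    bm 137.6
               nbc_pos 101.7
               nbc_neg 136.7

Null tests:
Randomization test: FRic(BM) - FRic(BG_S) 
  observed = 32.8184, null median = 25.7349, p = 0.0080 (999 draws)
Randomization test: FRic(NBC-) - FRic(NBC+) 
  observed = 35.0097, null median = 24.7921, p = 0.0360 (999 draws)
Randomization test: beta_O(BG_S, BM) 
  observed = 0.2836, null median = 0.2204, p = 0.0430 (999 draws)
Randomization test: beta_O(NBC+, NBC-) 
  observed = 0.4082, null median = 0.3093, p = 0.0390 (999 draws)
```

Reading this: the trait-space fit retains ~64% of the trait variance on
two varimax-rotated axes whose coordinate system the rotation left intact
(rho ≈ 1). Over the drought interval the simulated forest's biomass
mortality (`BM`) occupied **more** of the functional trait space than the
growth of survivors (functional richness 137.6 vs 104.8; difference 32.8,
sign-stable in 99.2% of half-community resamples), and net biomass losses
occupied more space than net gains (136.7 vs 101.7, p = 0.036) — the
generator's built-in drought asymmetry (mortality kernel much broader
over trait space than the growth kernel), recovered end-to-end by the
estimator. The overlap nulls show growth and mortality also *sit* in
significantly different regions (β_O above its randomization null).

Individual stages are available as plain functions returning classed
objects with `print`/`summary`/`predict`/`plot` methods:
`generate_community()`, `impute_traits()`, `fit_trait_space()`,
`demographic_ledger()`, `build_grid()`, `fit_bandwidths()`,
`species_tpd_set()`, `community_tpd()`, `functional_richness()`,
`overlap_dissimilarity()`, `fric_resampling_test()`, `beta_null_test()`.
A thin command-line wrapper with `synth` / `ledger` / `space` / `run`
subcommands lives in `inst/scripts/forest_tpd.R`.

See `vignettes/trait-space-biomass-methods.Rmd` for the models,
conventions and their rationale.

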