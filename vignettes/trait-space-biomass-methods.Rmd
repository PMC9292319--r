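---
title: "Methods: trait probability densities and biomass demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait probability densities and biomass demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`forestTPD` implements a complete analysis chain for asking how the
functional composition of a seasonally dry tropical forest responds to a
drought interval between two censuses: which trait combinations dominate
the standing biomass, which ones carried the biomass that grew, recruited
or died, and whether those demographic "biomass dimensions" occupy
different amounts of trait space. This vignette is the package's account
of the underlying methods: the models, their assumptions, the parameters
that matter, and the conventions adopted where a choice had to be made.

## The trait space

The analysis begins from an individual-level table of 15 leaf and wood
traits spanning two well-established functional dimensions of dry-forest
trees: the *hydraulic safety–efficiency trade-off* (vessel density and
fibre wall thickness versus wide conduits, large pits and high theoretical
conductivity) and *investment in tissues* (wood densities, leaf dry matter
content and leaf thickness versus specific leaf area, leaf area and
maximal water content).

Three wood-hydraulic traits are derived rather than measured directly:

* the hydraulically weighted vessel diameter
  $d_h = (\sum_i d_i^4 / N)^{1/4}$, the order-4 power mean of the conduit
  diameters, which weights conduits by their Hagen–Poiseuille conductance;
* the theoretical xylem-specific conductivity
  $K_p = \frac{\pi \rho_w}{128 \eta} d_h^4 \cdot VD$ with
  $\rho_w = 998.2$ kg m$^{-3}$ and $\eta = 1.002 \times 10^{-9}$ MPa s;
  $d_h$ (µm) and $VD$ (mm$^{-2}$) are converted to SI units internally
  (µm → m: $10^{-6}$; mm$^{-2}$ → m$^{-2}$: $10^{6}$), and the
  conversions are centralized and unit-tested;
* the maximal water content
  $WC_{max} = (1.5 - WD_0)/(1.5\,WD_0) + WC_{fsp}$ with
  $WC_{fsp} = 1/WD - 1/WD_0$, the classical maximum-moisture-content
  formula with cell-wall density 1.5 g cm$^{-3}$. The parenthesization of
  this formula is a deliberate reading of an ambiguous source notation;
  anyone reusing $WC_{max}$ quantitatively should re-verify it against
  the maximum-moisture-content literature. `WD > WD_0` is physically
  impossible (it implies negative water content at fibre saturation) and
  is treated as a data error.

The trait space itself is an individual-level principal component
analysis. Right-skewed traits (areas, conductivities, densities per area:
`LA`, `SLA`, `VA`, `VAmax`, `PA`, `Kp`, `WCmax`, `VD`, `dh`) are
log-transformed first — their reference ranges span orders of magnitude
and PCA loadings on such traits are otherwise unstable — then all traits
are centred and scaled, so the decomposition is of the correlation
matrix. Whether to transform before PCA is a genuine open choice; it is
surfaced here because it changes the variance split between the axes, and
analyses of real data that were run without transforms will not be
numerically comparable.

The two leading axes are retained (axis count is fixed, not selected) and
their $15 \times 2$ correlation-loading matrix is varimax-rotated with
Kaiser normalization (convergence $10^{-10}$). Because the rotation is
orthogonal it preserves the total retained variance; scores are rotated
with the same matrix. Axis orientation is fixed by convention — vessel
density loads positively on axis 1 and wood density positively on
axis 2 — so that refits are deterministic and plots are comparable. The
`check_rotation_fidelity()` report computes the rank correlation between
pre- and post-rotation scores per axis (axes matched by maximal absolute
correlation): a value near 1 means varimax only sharpened the loadings
without moving the coordinate system; values below 0.9 are flagged.

## Missing traits

Missing trait cells (a few percent of the table in typical campaigns) are
filled by iterative random-forest imputation: initialize with per-trait
medians, then cycle over traits in order of increasing missingness,
regressing each trait on all other traits *plus the plot and species
labels* (categorical predictors), re-predicting the missing cells until
the relative change of the imputed vector falls below $10^{-3}$, the
update stops shrinking (the standard stopping rule for this family of
imputers, since forest refits add noise at a floor), or `max_iter` is
reached. Observed cells are never modified, and imputed values are
clamped to the observed range of their column — a forest cannot
extrapolate, and the clamp makes that explicit. The imputation is single
(no uncertainty propagation), which matches how such tables are used
downstream; `score_imputation()` supports mask-and-recover validation
against known values.

## Biomass accounting

Tree biomass is a pluggable log-linear allometry
$\ln B = a + b \ln DBH + c \ln H + d \ln WD$ (DBH cm, height m, wood
density g cm$^{-3}$, biomass t). The default coefficients
($B = 6\times10^{-5} DBH^2 H \cdot WD$) are physically sensible stand-ins
of tropical-tree magnitude and are meant to be replaced by site-calibrated
dry-forest coefficients whenever available; every ledger quantity scales
through whatever model is supplied.

The two-census ledger follows explicit accounting conventions:

* **BG_S** — annual biomass increment of survivors. The final-census
  height of a survivor is its measured first-census height scaled along
  the plot's height–diameter power law,
  $H_{fin} = H_0 \, h(DBH_{fin}) / h(DBH_0)$; this preserves each tree's
  height deviation while guaranteeing that an unchanged DBH contributes
  exactly zero growth. Recorded DBH shrinkage up to 5% (measurement
  error) counts as zero growth; beyond that the record is flagged and
  floored at zero rather than silently subtracted.
* **BG_R** — annual biomass of recruits reaching the 2.5 cm census
  threshold, counted from an initial DBH of 0 (their whole final biomass
  is new growth); a recruit below 2.5 cm is a hard error.
* **BM** — annual biomass of trees that died, counted as first-census
  biomass *minus the biomass of the same tree at 2.5 cm DBH*, so that
  mortality and recruitment are measured over the same size range. The
  height paired with the counterfactual 2.5 cm stem is predicted from the
  plot's height–diameter fit — using the dead tree's full measured height
  would overstate the reference biomass.
* **NBC** $= BG_S + BG_R - BM$, enforced to machine precision per
  population (species × plot), per plot and network-wide.

Census intervals are computed per plot, in decimal years, from the median
census dates; plots censused months apart therefore get their own
annualization rather than a network-wide constant. All rates are per
hectare; network totals are area-weighted sums and network means are
totals over total area.

## Trait probability densities

Each population's trait probability density (TPD) is an equal-weight
mixture of bivariate Gaussian kernels centred on its individuals' scores,
evaluated on a shared grid (default $150 \times 150$ cells, ranges padded
by 15% of the score range per side) and renormalized to sum exactly one.
The grid defaults balance the grid-convergence of the downstream
statistics (richness and overlap change by well under 2% on a doubled
grid for smooth densities) against runtime.

Bandwidths:

* populations with $n \ge 3$ individuals get an unconstrained
  (full-matrix) normal-scale bandwidth
  $H = \left(\tfrac{4}{d+2}\right)^{2/(d+4)} n^{-2/(d+4)} \hat\Sigma$ with
  $d = 2$. At the sample sizes the abundance-weighted sampling scheme
  produces (3–8 individuals per population), higher-stage plug-in
  pipelines estimate curvature functionals from almost no data and are
  noise-dominated; the normal-scale matrix is deterministic, well-defined
  at $n = 3$, and adapts to each population's orientation through
  $\hat\Sigma$. A small eigenvalue floor (1% of the axis range) keeps
  collinear samples positive-definite without inflating ordinary
  kernels.
* populations with $n \le 2$ cannot estimate their own spread; their
  per-axis kernel SD is predicted from a plot-level linear regression of
  population SD on population mean score, fitted per axis over the
  plot's populations with $n \ge 3$, and floored at 5% of the axis range
  so no kernel degenerates. Plots with fewer than three reference
  populations fall back, with a warning, to the plot-wide median SD.

Community-level densities are weighted mixtures: each population's TPD is
rescaled by its share of the chosen *biomass dimension* — standing
biomass at either census, `BG_S`, `BG_R`, `BM`, or the positive and
negative parts of `NBC` taken as two separate non-negative weightings —
and summed. Weights are renormalized to one, so every community TPD is
itself a probability density.

Statistics on these densities:

* **Dominance regions** are highest-density regions: cells ranked by
  mass, accumulated to the target fraction $q$ (ties broken by cell
  index, so regions are nested across $q$). A population is counted
  inside a region when the cell containing its mean score belongs to it;
  assignment by mean is a convention — the mode is an alternative — and
  the partition property (inside-50% plus the 50–99% shell equals
  inside-99%) holds by construction.
* **Functional richness** is the area of the 99% highest-density region.
  The literal positive support of a Gaussian mixture is the entire grid,
  so a mass threshold is unavoidable; the 99% convention is the single
  most influential numerical choice in the package and is stated wherever
  richness is reported.
* **Overlap dissimilarity** $\beta_O = 1 - \sum_{cells} \min(a, b)$
  between two normalized densities: 0 for identical, 1 for disjoint.

Null models, both with add-one permutation p-values (never exactly zero):

* richness differences between two dimensions are assessed by rebuilding
  both community TPDs 999 times from a common random half of the
  populations and recording the richness difference; the p-value is the
  fraction of resampled differences whose sign opposes the full-data
  difference. This sign-stability convention is conservative on small
  communities, where halving the populations genuinely shrinks every
  support.
* overlap dissimilarity is tested by jointly permuting which population
  carries which (A, B) weight pair, 999 times. Permuting the weight pairs
  — rather than the score locations — is a deliberate choice between two
  readings of "randomising TPD scores"; the two nulls are *not*
  equivalent, and this package implements only the weight permutation.

## The synthetic community generator

`generate_community()` produces the three input tables (traits, census,
wood densities) with known ground truth, so every downstream stage can be
validated end-to-end without field data. It emulates:

* two latent trait axes mapped to the 15 traits by a loading matrix with
  clean block structure (each trait loads on one axis), on the analysis
  scale; the hydraulic axis carries more between-species variance than
  the investment axis (SD ratio 1 : 0.75), as in real dry-forest trait
  data, so the leading PCA axis is well determined;
* a geometric-series rank abundance distribution (shape 0.06 over a
  60-species pool) with plot-level rank shuffling, coupled to an
  *assembly filter*: abundance is tilted toward an "adapted manifold" of
  two Gaussian ridges in latent space — high investment × hydraulically
  safe and high investment × hydraulically efficient — so dominant
  species carry adapted trait combinations, which is the dominance
  structure this kind of drought-filtered flora exhibits;
* abundance-weighted trait sampling: 5–8 individuals for species with at
  least five individuals in a plot, 1–3 for rarer species, 1 for
  singletons; 4% of individual × trait cells are masked as missing,
  never blanking a whole individual or a whole trait column;
* drought demography over a 3-year census interval: per-tree death
  probability `baseline_mortality` (0.08) plus
  `drought_mortality_gain` (0.30) times a Gaussian penalty of distance
  from the adapted manifold with scale `mortality_breadth` (2.0 latent
  units) — a *flat, wide* kernel, so mortality removes biomass over most
  of the trait space at 3–7% of stems per year, the severity of a strong
  drought; relative diameter growth concentrated near the manifold with
  the much narrower `growth_breadth` (0.7), effectively zero away from
  it, so surviving growth is restricted to the adapted combinations;
  recruitment (rate 0.05 per standing tree) drawn near the manifold.
  `mortality_breadth > growth_breadth` is the structural asymmetry under
  test downstream: mortality-weighted densities should occupy more trait
  space than growth-weighted ones.

Tree sizes are right-skewed (lognormal DBH above the 2.5 cm census
threshold) with heights from a power law $H = 1.3\,DBH^{0.55}$ times
lognormal noise. Anhydrous wood density is floored at 1.01 × basic
density after generation so the water-content formulas remain defined.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about field data: no climate forcing or spatial structure
within plots; one stem per tree; abundance classes are stationary (no
pre-drought successional trends); the latent axes are exactly two and
exactly linear in the transformed traits, so the trait-space recovery
tests certify the estimator, not the dimensionality of real floras; and
derived traits are generated through the same loading structure as
measured ones rather than through their defining formulas, so synthetic
tables are statistically but not physically self-consistent.

Default problem sizes are 4 plots × 500 trees from a 60-species pool
(roughly 900–1000 trait individuals in 200–220 populations), a scale at
which the full pipeline with 999-draw null models completes in about two
minutes on one core; the full-scale survey this emulates (11 plots,
~22,000 trees, 524 populations) is reached by raising `n_plots`,
`individuals_per_plot` and `n_species_pool`.

## Degenerate inputs and numerical conventions

Scores outside the grid are an error (the grid must be built from all
scores); zero-range axes are expanded by half a unit; all-zero weight
vectors and negative weights are errors; a single-population overlap null
is rejected as degenerate. Every density is renormalized after
discretization, so normalization holds to $10^{-9}$ regardless of how
much kernel mass the padding captures. Permutation p-values use the
add-one convention. All stochastic stages take explicit integer seeds;
the pipeline derives per-stage seeds from one master seed by fixed
offsets, and reruns with the same configuration are byte-identical on
disk.

## Known limitations

Richness at the 99% threshold retains some sensitivity to the number of
populations carrying positive weight, not only to where they sit; on
small communities this makes the half-population resampling test
conservative. The normal-scale bandwidth over-smooths strongly bimodal
populations (rare at $n \le 8$ but possible). The ledger treats each
record as one stem; multi-stem trees must be aggregated upstream. And the
allometry defaults are placeholders: absolute biomass levels are only as
good as the coefficients supplied.
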