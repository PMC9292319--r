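Package: forestTPD
Title: Trait Probability Densities and Biomass Demography for Tropical
    Dry Forest Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds two-dimensional functional trait spaces from
    individual-level tree trait measurements (principal component analysis
    with varimax rotation), estimates trait probability densities (TPD) per
    species population with kernel methods, combines them into
    community-level densities weighted by standing biomass or demographic
    biomass fluxes (growth of survivors, growth of recruits, mortality, net
    biomass change), and quantifies functional richness, dominance regions
    and overlap dissimilarity with randomization null models. Includes
    derived wood hydraulic trait formulas (hydraulically weighted vessel
    diameter, theoretical xylem conductivity, maximal water content),
    iterative random-forest imputation of missing trait values, two-census
    biomass accounting with explicit recruit and mortality conventions, and
    a synthetic multi-plot community generator with known latent trait axes
    and trait-dependent drought demography for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
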