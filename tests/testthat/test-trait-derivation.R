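# Derived wood-hydraulic traits.

test_that("hydraulically weighted diameter is the order-4 power mean", {
  # direct arithmetic oracle
  expect_equal(hydraulic_diameter(c(10, 20)), ((10^4 + 20^4) / 2)^0.25)
  expect_equal(hydraulic_diameter(c(10, 20)), 17.0747648517414,
               tolerance = 1e-12)
  # homogeneity and permutation symmetry
  expect_equal(hydraulic_diameter(rep(37.2, 9)), 37.2)
  set.seed(4)
  d <- runif(25, 5, 120)
  expect_equal(hydraulic_diameter(d), hydraulic_diameter(sample(d)))
  # power-mean dominance and boundedness on random lists
  for (i in 1:20) {
    d <- runif(sample(2:40, 1), 1, 200)
    dh <- hydraulic_diameter(d)
    expect_gte(dh, mean(d))
    expect_gte(dh, min(d))
    expect_lte(dh, max(d))
  }
  expect_error(hydraulic_diameter(numeric(0)), "non-empty")
  expect_error(hydraulic_diameter(c(10, -1)), "positive")
})

test_that("theoretical conductivity tracks a unit-checked recomputation", {
  # scaling laws of the Hagen-Poiseuille form
  expect_equal(potential_conductivity(2 * 50, 70),
               16 * potential_conductivity(50, 70))
  expect_equal(potential_conductivity(50, 2 * 70),
               2 * potential_conductivity(50, 70))
  # brute-force unit-tracked oracle across random valid inputs
  set.seed(9)
  for (i in 1:50) {
    dh <- runif(1, 5, 200); vd <- runif(1, 2, 500)
    expect_equal(potential_conductivity(dh, vd),
                 oracle_conductivity(dh, vd), tolerance = 1e-12)
  }
  # community trait means give a value inside the global reference range
  kp <- potential_conductivity(58.64, 71.71)
  expect_equal(kp, 20.7321964830047, tolerance = 1e-10)
  ref <- trait_reference()
  expect_gte(kp, ref$lower[ref$trait == "Kp"])
  expect_lte(kp, ref$upper[ref$trait == "Kp"])
  expect_error(potential_conductivity(0, 10), "dh")
})

test_that("water content formulas behave over the wood-density range", {
  # saturation-point collapse: WD = WD0
  wc <- water_content_max(0.7, 0.7)
  expect_equal(wc$WC_fsp, 0)
  expect_equal(wc$WC_max, (1.5 - 0.7) / (1.5 * 0.7))
  # community trait means, independent hand evaluation
  wc <- water_content_max(0.63, 0.72)
  expect_equal(wc$WC_fsp, 0.198412698412698, tolerance = 1e-12)
  expect_equal(wc$WC_max, 0.920634920634921, tolerance = 1e-12)
  ref <- trait_reference()
  expect_gte(wc$WC_max, ref$lower[ref$trait == "WCmax"])
  expect_lte(wc$WC_max, ref$upper[ref$trait == "WCmax"])
  # the two WD0 terms cancel: WC_max depends only on basic density
  wd0 <- seq(0.5, 1.4, by = 0.05)
  out <- sapply(wd0, function(w0) water_content_max(0.45, w0)$WC_max)
  expect_equal(out, rep(1 / 0.45 - 2 / 3, length(wd0)), tolerance = 1e-12)
  # ... and is strictly decreasing in basic density
  wds <- seq(0.3, 1.0, by = 0.05)
  out <- sapply(wds, function(w) water_content_max(w, 1.2)$WC_max)
  expect_true(all(diff(out) < 0))
  for (w0 in wd0) {
    wc <- water_content_max(0.45, w0)
    expect_gte(wc$WC_fsp, 0)
    expect_gte(wc$WC_max, wc$WC_fsp)
  }
  expect_error(water_content_max(0.8, 0.7), "WD > WD0")
  expect_error(water_content_max(0.8, 1.6), "1.5")
})

test_that("reference-range validation flags and only flags out-of-range values", {
  expect_identical(nrow(validate_trait_ranges(list(WD = 0.63))), 0L)
  fl <- validate_trait_ranges(list(WD = 0.63, SLA = 500))
  expect_identical(fl$trait, "SLA")
  expect_identical(nrow(validate_trait_ranges(list())), 0L)
  # whole-table form reports row numbers
  tab <- data.frame(WD = c(0.5, 2.0), FWT = c(5, 5))
  fl <- validate_trait_ranges(tab)
  expect_identical(fl$row, 2L)
  expect_identical(fl$trait, "WD")
})

test_that("wood traits derive consistently from anatomy measurements", {
  anatomy <- list(list(vessel_diameters = c(30, 40, 50, 60),
                       vessel_areas = c(700, 1200, 1900, 2800),
                       counted_area = 0.08))
  traits <- data.frame(WD = 0.6, WD0 = 0.68, dh = NA, VD = NA, VA = NA,
                       VAmax = NA, Kp = NA, WCmax = NA)
  out <- derive_wood_traits(anatomy, traits)
  expect_equal(out$dh, hydraulic_diameter(c(30, 40, 50, 60)))
  expect_equal(out$VD, 4 / 0.08)
  expect_equal(out$VAmax, 2800)  # only one conduit above the 75th pctile
  expect_equal(out$Kp, potential_conductivity(out$dh, out$VD))
  expect_equal(out$WCmax, water_content_max(0.6, 0.68)$WC_max)
})
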