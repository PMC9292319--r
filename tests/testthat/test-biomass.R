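# Allometry and the two-census demographic ledger.

test_that("the log-linear allometry reduces to its closed form", {
  m <- allometry_model(c(a = log(0.05), b = 2, c = 1, d = 1))
  # B = k D^2 H WD
  expect_equal(tree_biomass(10, 8, 0.6, m), 0.05 * 100 * 8 * 0.6)
  expect_equal(tree_biomass(20, 8, 0.6, m), 4 * tree_biomass(10, 8, 0.6, m))
  # default coefficients, independent hand evaluation
  expect_equal(tree_biomass(10, 8, 0.6), 6e-5 * 10^2 * 8 * 0.6)
  expect_error(allometry_model(c(a = 1, b = 2)), "coefficients")
  expect_error(tree_biomass(-1, 8, 0.6), "dbh")
})

test_that("NBC identity reproduces hand-fed accounting", {
  expect_equal(net_biomass_change(2.23, 0.10, 0.65), 1.68)
  expect_equal(net_biomass_change(24.5, 1.10, 7.2), 18.4)
})

make_toy_census <- function() {
  data.frame(
    tree_id = c("t1", "t2", "t3"),
    species = c("spA", "spB", "spA"),
    plot = "p1",
    status = c("survivor", "dead", "recruit"),
    dbh_t0 = c(10, 20, NA),
    height_t0 = c(10, 14, NA),
    dbh_tfin = c(12, NA, 3),
    date_t0 = as.Date("2013-01-01"),
    date_tfin = as.Date("2015-01-01"),
    wood_density = c(0.6, 0.7, 0.5),
    stringsAsFactors = FALSE
  )
}

test_that("three-tree toy census matches the hand-worked ledger", {
  led <- demographic_ledger(make_toy_census(),
                            height_model = list(a = 2, b = 0.5))
  # hand-computed with B = 6e-5 D^2 H WD, H(D) = 2 sqrt(D), interval
  # 730 d / 365.25, survivor t_fin height 10 * h(12)/h(10)
  expect_equal(led$network$totals[["bg_s"]], 0.0104010565162603,
               tolerance = 1e-10)
  expect_equal(led$network$totals[["bg_r"]], 0.00046797402880938,
               tolerance = 1e-10)
  expect_equal(led$network$totals[["bm"]], 0.117265214722211,
               tolerance = 1e-10)
  expect_equal(led$network$totals[["nbc"]], -0.106396184177141,
               tolerance = 1e-10)
  expect_equal(led$intervals[["p1"]], 730 / 365.25)
})

test_that("a static census yields an all-zero ledger", {
  cen <- make_toy_census()[1, ]
  cen$dbh_tfin <- cen$dbh_t0
  led <- demographic_ledger(cen, height_model = list(a = 2, b = 0.5))
  expect_equal(unname(led$network$totals[c("bg_s", "bg_r", "bm", "nbc")]),
               rep(0, 4))
})

test_that("ledger identities hold on a synthetic census", {
  com <- small_community()
  led <- demographic_ledger(com$census_table,
                            wood_density_table = com$wood_density_table)
  p <- led$populations
  # NBC identity per population, per plot, network-wide
  expect_equal(p$nbc, p$bg_s + p$bg_r - p$bm, tolerance = 1e-12)
  expect_equal(led$plots$nbc, led$plots$bg_s + led$plots$bg_r - led$plots$bm,
               tolerance = 1e-12)
  expect_equal(led$network$totals[["nbc"]],
               led$network$totals[["bg_s"]] + led$network$totals[["bg_r"]] -
                 led$network$totals[["bm"]], tolerance = 1e-12)
  expect_true(all(p$bg_s >= 0 & p$bg_r >= 0 & p$bm >= 0))
  # additivity: plot rows are sums of their populations, network of plots
  for (pl in led$plots$plot) {
    expect_equal(led$plots$bg_s[led$plots$plot == pl],
                 sum(p$bg_s[p$plot == pl]))
  }
  expect_equal(led$network$totals[["bm"]],
               sum(led$plots$bm * led$plots$area_ha))
  # positive/negative decomposition of network NBC
  expect_equal(led$network$totals[["nbc"]],
               sum(pmax(p$nbc, 0)) - sum(pmax(-p$nbc, 0)), tolerance = 1e-9)
})

test_that("shrinking survivors are tolerated, flagged or rejected correctly", {
  cen <- make_toy_census()[1, ]
  # 3% shrinkage: within tolerance, counted as zero growth, no flag
  cen$dbh_tfin <- cen$dbh_t0 * 0.97
  led <- demographic_ledger(cen, height_model = list(a = 2, b = 0.5))
  expect_equal(led$network$totals[["bg_s"]], 0)
  expect_length(led$flags, 0)
  # 10% shrinkage: flagged, floored at zero
  cen$dbh_tfin <- cen$dbh_t0 * 0.90
  led <- demographic_ledger(cen, height_model = list(a = 2, b = 0.5))
  expect_equal(led$network$totals[["bg_s"]], 0)
  expect_identical(led$flags, "t1")
  # undersized recruit is a hard error
  cen <- make_toy_census()
  cen$dbh_tfin[3] <- 2.0
  expect_error(demographic_ledger(cen, height_model = list(a = 2, b = 0.5)),
               "2.5 cm")
})
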