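# Synthetic community generator.

test_that("identical seeds give identical communities", {
  a <- generate_community(synthetic_config(n_plots = 2,
                                           individuals_per_plot = 120,
                                           seed = 5))
  b <- generate_community(synthetic_config(n_plots = 2,
                                           individuals_per_plot = 120,
                                           seed = 5))
  expect_identical(a$trait_table, b$trait_table)
  expect_identical(a$census_table, b$census_table)
  expect_identical(a$true_latent_scores, b$true_latent_scores)
})

test_that("invalid configuration is rejected with the field name", {
  expect_error(synthetic_config(missing_fraction = 1.2), "missing_fraction")
  expect_error(synthetic_config(mortality_breadth = 0), "mortality_breadth")
  expect_error(synthetic_config(abundance_shape = 0), "abundance_shape")
  expect_error(synthetic_config(trait_loading_matrix = diag(2)),
               "trait_loading_matrix")
  expect_error(synthetic_config(baseline_mortality = NaN),
               "baseline_mortality")
})

test_that("trait sampling follows the abundance-class rule exactly", {
  com <- small_community()
  t0 <- com$census_table[com$census_table$status != "recruit", ]
  ab <- table(paste(t0$species, t0$plot))
  ns <- table(paste(com$trait_table$species, com$trait_table$plot))
  expect_true(all(names(ns) %in% names(ab)))
  for (k in names(ab)) {
    n_census <- ab[[k]]
    n_traits <- if (k %in% names(ns)) ns[[k]] else 0L
    expect_gte(n_traits, 1)   # every population has a trait record
    if (n_census >= 5) {
      expect_true(n_traits >= 5 && n_traits <= 8)
    } else if (n_census >= 2) {
      expect_true(n_traits >= 1 && n_traits <= 3)
    } else {
      expect_identical(as.integer(n_traits), 1L)
    }
  }
})

test_that("census records respect the status conventions", {
  com <- small_community()
  cen <- com$census_table
  expect_true(all(is.na(cen$dbh_t0[cen$status == "recruit"])))
  expect_true(all(is.na(cen$dbh_tfin[cen$status == "dead"])))
  expect_true(all(cen$dbh_t0[cen$status != "recruit"] >= 2.5))
  expect_true(all(cen$dbh_tfin[cen$status == "recruit"] >= 2.5))
  expect_true(all(cen$date_tfin > cen$date_t0))
  # survivors never shrink in this generator
  s <- cen$status == "survivor"
  expect_true(all(cen$dbh_tfin[s] >= cen$dbh_t0[s]))
})

test_that("masking hits the requested fraction and never blanks rows or columns", {
  com <- small_community()
  full <- com$trait_table_complete
  expect_false(anyNA(full[, trait_names()]))

  m <- mask_traits(full, 0.04, seed = 3)
  n_cells <- nrow(full) * 15
  frac <- sum(m$mask) / n_cells
  # binomial check on the masked-cell fraction
  ci <- 0.04 + c(-4, 4) * sqrt(0.04 * 0.96 / n_cells)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  expect_true(all(colSums(!m$mask) > 0))
  expect_true(all(rowSums(!m$mask) > 0))
  # identity at zero and determinism
  expect_identical(mask_traits(full, 0)$trait_table, full)
  expect_identical(mask_traits(full, 0.04, seed = 3)$mask, m$mask)
  expect_false(identical(mask_traits(full, 0.04, seed = 4)$mask, m$mask))
  expect_error(mask_traits(full, 1), "missing_fraction")
})

test_that("zero missing_fraction and zero mortality gain are true null cases", {
  cfg <- synthetic_config(n_plots = 1, individuals_per_plot = 300,
                          missing_fraction = 0,
                          drought_mortality_gain = 0, seed = 8)
  com <- generate_community(cfg)
  expect_false(anyNA(com$trait_table[, trait_names()]))

  # with no trait-dependent mortality, death is independent of latent
  # position: pool several communities and regress
  dat <- do.call(rbind, lapply(c(8, 9, 10), function(s) {
    com <- generate_community(synthetic_config(
      n_plots = 1, individuals_per_plot = 400, missing_fraction = 0,
      drought_mortality_gain = 0, seed = s))
    cen <- com$census_table
    tt <- merge(com$trait_table[, c("individual_id", "species", "plot")],
                com$true_latent_scores)
    cen <- merge(cen, tt, by.x = "tree_id", by.y = "individual_id")
    data.frame(dead = cen$status == "dead",
               dist = sqrt(pmin((cen$ax1 + 1)^2, (cen$ax1 - 1)^2) +
                             (cen$ax2 - 1)^2))
  }))
  fit <- suppressWarnings(glm(dead ~ dist, family = binomial, data = dat))
  expect_gt(summary(fit)$coefficients["dist", "Pr(>|z|)"], 0.05)
})
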