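# TPD grid, bandwidths, densities and statistics.

test_that("grid arithmetic, degenerate axes and determinism", {
  sc <- cbind(c(0, 1), c(0, 1))
  g <- build_grid(sc, cells_per_axis = 100, padding_fraction = 0.1)
  expect_equal(g$min, c(-0.1, -0.1))
  expect_equal(g$max, c(1.1, 1.1))
  expect_equal(g$cell_width, c(0.012, 0.012))
  expect_equal(g$cell_area, 0.012^2)
  # single point: finite nonzero-range grid
  g1 <- build_grid(rbind(c(2, 3)))
  expect_true(all(g1$max > g1$min))
  # determinism
  expect_identical(build_grid(sc), build_grid(sc))
  expect_error(build_grid(sc, cells_per_axis = 5), ">= 10")
})

test_that("species TPDs are normalized mixtures centred on their data", {
  set.seed(6)
  sc <- toy_scores()
  g <- build_grid(sc)
  # single observation: discretized Gaussian whose peak cell contains it
  tpd1 <- species_tpd(rbind(sc[1, ]), diag(0.3^2, 2), g)
  expect_equal(sum(tpd1$mass), 1, tolerance = 1e-12)
  peak <- which.max(tpd1$mass)
  i <- (peak - 1) %% g$cells[1] + 1
  j <- (peak - 1) %/% g$cells[1] + 1
  expect_lt(abs(g$x1[i] - sc[1, 1]), g$cell_width[1])
  expect_lt(abs(g$x2[j] - sc[1, 2]), g$cell_width[2])
  # normalization for random inputs and full bandwidth matrices
  for (i in 1:5) {
    n <- sample(2:12, 1)
    H <- crossprod(matrix(rnorm(4, sd = 0.4), 2)) + diag(0.05, 2)
    tpd <- species_tpd(sc[sample(nrow(sc), n), ], H, g)
    expect_equal(sum(tpd$mass), 1, tolerance = 1e-9)
    expect_true(all(tpd$mass >= 0))
  }
  expect_error(species_tpd(rbind(c(100, 0)), diag(2), g), "outside")
})

test_that("half of a single Gaussian's mass lies in its analytic 50% ellipse", {
  tpd <- gaussian_tpd(sigma = 1)
  g <- tpd$grid
  r2 <- qchisq(0.5, df = 2)
  xx <- outer(g$x1^2, g$x2^2, "+")
  expect_equal(sum(tpd$mass[as.vector(xx) <= r2]), 0.5, tolerance = 0.02)
  # and the 50% HDR captures just above half the mass
  reg <- dominance_region(tpd, 0.5)
  expect_gte(reg$mass, 0.5)
  expect_lt(reg$mass, 0.5 + 0.01)
})

test_that("functional richness matches analytic ellipse areas", {
  # isotropic Gaussian: 99% HDR area = pi sigma^2 chi2_0.99
  for (sigma in c(0.6, 1)) {
    tpd <- gaussian_tpd(sigma = sigma, cells = 260, half_width = 6 * sigma)
    expect_equal(functional_richness(tpd),
                 pi * sigma^2 * qchisq(0.99, 2), tolerance = 0.05)
  }
  # two far-separated equal Gaussians: additivity of disjoint supports
  g <- build_grid(rbind(c(-14, 0), c(14, 0), c(0, -4), c(0, 4)),
                  cells_per_axis = 300, padding_fraction = 0.05)
  one <- species_tpd(rbind(c(-10, 0)), diag(1, 2), g)
  two <- species_tpd(rbind(c(-10, 0), c(10, 0)), diag(1, 2), g)
  expect_equal(functional_richness(two), 2 * functional_richness(one),
               tolerance = 0.04)
  # widening the bandwidth strictly increases the occupied area
  wide <- species_tpd(rbind(c(-10, 0), c(10, 0)), diag(1.5, 2), g)
  expect_gt(functional_richness(wide), functional_richness(two))
})

test_that("overlap dissimilarity is a bounded symmetric divergence", {
  sc <- toy_scores()
  g <- build_grid(sc)
  a <- species_tpd(sc[1:40, ], diag(0.2, 2), g)
  b <- species_tpd(sc[61:100, ], diag(0.2, 2), g)
  expect_equal(overlap_dissimilarity(a, a), 0)
  expect_equal(overlap_dissimilarity(a, b), overlap_dissimilarity(b, a))
  expect_gte(overlap_dissimilarity(a, b), 0)
  expect_lte(overlap_dissimilarity(a, b), 1)
  # disjoint supports
  gd <- build_grid(rbind(c(-30, -1), c(30, 1)), cells_per_axis = 200)
  da <- species_tpd(rbind(c(-25, 0)), diag(0.25, 2), gd)
  db <- species_tpd(rbind(c(25, 0)), diag(0.25, 2), gd)
  expect_equal(overlap_dissimilarity(da, db), 1, tolerance = 1e-6)
  expect_error(overlap_dissimilarity(a, da), "different grids")
})

test_that("overlap of two offset Gaussians matches numeric integration", {
  for (d in c(1, 2.5)) {
    g <- build_grid(rbind(c(-6, -6), c(6 + d, 6)), cells_per_axis = 260,
                    padding_fraction = 0.02)
    a <- species_tpd(rbind(c(0, 0)), diag(1, 2), g)
    b <- species_tpd(rbind(c(d, 0)), diag(1, 2), g)
    got <- overlap_dissimilarity(a, b)
    want <- 1 - oracle_gaussian_overlap(d)
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("highest-density regions are nested and partition populations", {
  sc <- toy_scores()
  g <- build_grid(sc)
  tpd <- species_tpd(sc, diag(0.3, 2), g)
  qs <- c(0.2, 0.5, 0.8, 0.99)
  regs <- lapply(qs, function(q) dominance_region(tpd, q))
  for (i in seq_len(length(qs) - 1)) {
    expect_true(all(regs[[i]]$cells %in% regs[[i + 1]]$cells))
  }
  # membership partition: inside-50 plus the 50-99 shell equals inside-99
  pm <- matrix(rnorm(40, sd = 1.5), ncol = 2,
               dimnames = list(sprintf("pop%02d", 1:20), NULL))
  r50 <- dominance_region(tpd, 0.5, pop_means = pm)
  r99 <- dominance_region(tpd, 0.99, pop_means = pm)
  shell <- setdiff(r99$members, r50$members)
  expect_true(all(r50$members %in% r99$members))
  expect_identical(r50$n_members + length(shell), r99$n_members)
})

test_that("normal-scale bandwidths agree with the analytic normal reference", {
  set.seed(14)
  n <- 3000
  sc <- rbind(matrix(rnorm(2 * n), ncol = 2),
              matrix(rnorm(60, sd = 0.5), ncol = 2),
              matrix(rnorm(60, 1, 0.5), ncol = 2))
  popn <- c(rep("big", n), rep("p2", 30), rep("p3", 30))
  bw <- fit_bandwidths(sc, popn, rep("plot1", length(popn)))
  H <- bw$H[["big"]]
  h_ref <- n^(-1 / 6)        # (4/(d+2))^(1/(d+4)) = 1 for d = 2, sigma = 1
  expect_equal(sqrt(H[1, 1]), h_ref, tolerance = 0.2)
  expect_equal(sqrt(H[2, 2]), h_ref, tolerance = 0.2)
  expect_lt(abs(H[1, 2]), 0.05 * h_ref^2 + 0.05)
})

test_that("rare populations borrow bandwidths from the SD-on-mean regression", {
  set.seed(15)
  # populations with identical SDs: slope ~ 0, rare species get that SD
  sds <- 0.4
  sc <- do.call(rbind, lapply(1:6, function(k) {
    cbind(rnorm(20, k, sds), rnorm(20, -k, sds))
  }))
  sc <- rbind(sc, c(10, 10))   # one singleton far out
  popn <- c(rep(sprintf("pop%d", 1:6), each = 20), "rare")
  bw <- fit_bandwidths(sc, popn, rep("plotA", nrow(sc)))
  for (ax in 1:2) {
    expect_lt(abs(bw$regression[["plotA"]][[ax]]$slope), 0.05)
  }
  H_rare <- bw$H[["rare"]]
  expect_equal(H_rare[1, 2], 0)
  expect_equal(sqrt(H_rare[1, 1]), sds, tolerance = 0.35)
  # a singleton's TPD is one Gaussian centred on its score
  g <- build_grid(sc)
  tpd <- species_tpd(rbind(c(10, 10)), H_rare, g)
  peak <- which.max(tpd$mass)
  i <- (peak - 1) %% g$cells[1] + 1
  expect_lt(abs(g$x1[i] - 10), g$cell_width[1])
  # too few reference populations: warned fallback (one warning per axis)
  w <- capture_warnings(fit_bandwidths(sc[1:21, ], popn[1:21],
                                       rep("plotA", 21)))
  expect_match(w, "fewer than 3 populations", all = TRUE)
  expect_length(w, 2)
})

test_that("community TPDs are normalized mixtures with degenerate limits", {
  sc <- toy_scores()
  g <- build_grid(sc)
  popn <- rep(c("a", "b"), each = 60)
  bw <- suppressWarnings(fit_bandwidths(sc, popn, rep("p", 120)))
  tset <- species_tpd_set(sc, popn, bw, g)
  expect_equal(unname(colSums(tset$M)), c(1, 1), tolerance = 1e-9)
  # single positive weight: community equals that species
  ct <- community_tpd(tset, c(a = 1, b = 0))
  expect_equal(ct$mass, tset$M[, "a"], tolerance = 1e-12)
  # identical TPDs under any weights: mixture degeneracy
  tset2 <- tset; tset2$M[, "b"] <- tset2$M[, "a"]
  ct2 <- community_tpd(tset2, c(a = 0.3, b = 0.7))
  expect_equal(ct2$mass, tset2$M[, "a"], tolerance = 1e-12)
  # random weights stay normalized
  set.seed(2)
  for (i in 1:5) {
    w <- runif(2)
    expect_equal(sum(community_tpd(tset, setNames(w, c("a", "b")))$mass), 1,
                 tolerance = 1e-9)
  }
  expect_error(community_tpd(tset, c(a = 0, b = 0)), "all weights")
  expect_error(community_tpd(tset, c(a = -1, b = 2)), "non-negative")
})

test_that("statistics are stable under grid refinement", {
  sc <- toy_scores()
  for (cells in c(150, 300)) {
    g <- build_grid(sc, cells_per_axis = cells)
    a <- species_tpd(sc[1:60, ], diag(0.3, 2), g)
    b <- species_tpd(sc[61:120, ], diag(0.4, 2), g)
    assign(paste0("f", cells), functional_richness(a))
    assign(paste0("o", cells), overlap_dissimilarity(a, b))
  }
  expect_lt(abs(f300 - f150) / f150, 0.02)
  expect_lt(abs(o300 - o150) / max(o150, 1e-9), 0.02)
})

test_that("richness resampling test: degenerate, determinism and separation", {
  set.seed(31)
  npop <- 12
  centers <- cbind(runif(npop, -3, 3), runif(npop, -3, 3))
  sc <- centers[rep(1:npop, each = 4), ] + matrix(rnorm(96, sd = 0.3), ncol = 2)
  popn <- rep(sprintf("p%02d", 1:npop), each = 4)
  bw <- fit_bandwidths(sc, popn, rep("pl", nrow(sc)))
  tset <- species_tpd_set(sc, popn, bw, build_grid(sc))
  w_all <- setNames(rep(1, npop), sprintf("p%02d", 1:npop))
  # identical dimensions: zero difference, p = 1
  t0 <- fric_resampling_test(tset, w_all, w_all, 99, seed = 1)
  expect_equal(t0$observed, 0)
  expect_equal(t0$p_value, 1)
  # determinism
  w_half <- w_all; w_half[1:6] <- 0
  t1 <- fric_resampling_test(tset, w_all, w_half, 99, seed = 7)
  t2 <- fric_resampling_test(tset, w_all, w_half, 99, seed = 7)
  expect_identical(t1$null, t2$null)
  expect_error(fric_resampling_test(tset, w_all, w_all, 0), "n_resamples")
})

test_that("overlap null test: degenerate, separation scenario, determinism", {
  set.seed(32)
  npop <- 10
  centers <- cbind(c(runif(5, -4, -2), runif(5, 2, 4)), runif(npop, -1, 1))
  sc <- centers[rep(1:npop, each = 4), ] + matrix(rnorm(80, sd = 0.3), ncol = 2)
  popn <- rep(sprintf("p%02d", 1:npop), each = 4)
  bw <- fit_bandwidths(sc, popn, rep("pl", nrow(sc)))
  tset <- species_tpd_set(sc, popn, bw, build_grid(sc))
  ids <- sprintf("p%02d", 1:npop)
  w_all <- setNames(rep(1, npop), ids)
  # identical weights: observed 0, p = 1
  t0 <- beta_null_test(tset, w_all, w_all, 99, seed = 1)
  expect_equal(t0$observed, 0)
  expect_equal(t0$p_value, 1)
  # A concentrated left, B concentrated right: strong observed, small p
  wa <- setNames(c(rep(1, 5), rep(0, 5)), ids)
  wb <- setNames(c(rep(0, 5), rep(1, 5)), ids)
  t1 <- beta_null_test(tset, wa, wb, 199, seed = 2)
  expect_gt(t1$observed, median(t1$null))
  expect_lt(t1$p_value, 0.05)
  expect_gte(t1$observed, 0); expect_lte(t1$observed, 1)
  # determinism and degenerate guard
  t2 <- beta_null_test(tset, wa, wb, 199, seed = 2)
  expect_identical(t1$null, t2$null)
  one <- tset; one$M <- one$M[, 1, drop = FALSE]
  expect_error(beta_null_test(one, c(p01 = 1), c(p01 = 1)), "degenerate")
})
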