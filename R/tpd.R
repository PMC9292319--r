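# Trait probability densities on a shared 2-D grid: per-population kernel
# densities, biomass-weighted community mixtures, dominance regions,
# functional richness, overlap dissimilarity, and randomization nulls.

#' Build the shared 2-D evaluation grid
#'
#' Regular grid covering all individual scores, expanded by a padding
#' fraction on each side so kernel mass is not clipped. A degenerate
#' (zero-range) axis is expanded by half a unit on each side.
#'
#' @param scores n x 2 matrix of trait-space coordinates.
#' @param cells_per_axis cells per axis (>= 10); default 150.
#' @param padding_fraction padding added to each side as a fraction of the
#'   axis range; default 0.15.
#' @return Object of class `tpd_grid`: list with `min`, `max`, `cells`,
#'   cell-centre vectors `x1`, `x2`, `cell_area` and `ncell`.
#' @export
build_grid <- function(scores, cells_per_axis = 150L,
                       padding_fraction = 0.15) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1L || ncol(scores) != 2L || any(!is.finite(scores))) {
    stop("scores must be a finite n x 2 matrix")
  }
  if (cells_per_axis < 10L) stop("cells_per_axis must be >= 10")
  lo <- apply(scores, 2, min)
  hi <- apply(scores, 2, max)
  span <- hi - lo
  pad <- ifelse(span > 0, span * padding_fraction, 0.5)
  lo <- lo - pad
  hi <- hi + pad
  w <- (hi - lo) / cells_per_axis
  g <- list(min = lo, max = hi,
            cells = rep(as.integer(cells_per_axis), 2L),
            x1 = lo[1] + (seq_len(cells_per_axis) - 0.5) * w[1],
            x2 = lo[2] + (seq_len(cells_per_axis) - 0.5) * w[2],
            cell_width = w, cell_area = prod(w),
            ncell = as.integer(cells_per_axis)^2)
  class(g) <- "tpd_grid"
  g
}

#' @export
print.tpd_grid <- function(x, ...) {
  cat(sprintf("TPD grid: %d x %d cells, axis1 [%.3f, %.3f], axis2 [%.3f, %.3f], cell area %.3g\n",
              x$cells[1], x$cells[2], x$min[1], x$max[1], x$min[2],
              x$max[2], x$cell_area))
  invisible(x)
}

.same_grid <- function(a, b) {
  isTRUE(all.equal(a$min, b$min)) && isTRUE(all.equal(a$max, b$max)) &&
    all(a$cells == b$cells)
}

# cell index (column-major over x1-fast layout) of points on a grid
.cell_of <- function(grid, pts) {
  pts <- matrix(pts, ncol = 2)
  i <- pmin(pmax(ceiling((pts[, 1] - grid$min[1]) / grid$cell_width[1]), 1L),
            grid$cells[1])
  j <- pmin(pmax(ceiling((pts[, 2] - grid$min[2]) / grid$cell_width[2]), 1L),
            grid$cells[2])
  (j - 1L) * grid$cells[1] + i
}

#' Per-population kernel bandwidths
#'
#' Selects the kernel covariance (bandwidth) of every population's trait
#' probability density. Populations with at least three individuals get an
#' unconstrained (full-matrix) normal-scale bandwidth,
#' \deqn{H = \left(\frac{4}{d+2}\right)^{2/(d+4)} n^{-2/(d+4)} \hat\Sigma,}
#' with \eqn{d = 2} and \eqn{\hat\Sigma} the population's sample
#' covariance, floored to be symmetric positive-definite. For populations
#' with one or two individuals the per-axis kernel SD is predicted from a
#' plot-level linear regression of population SD on population mean score
#' (fitted per axis over the plot's populations with n >= 3), floored at
#' `min_sd_frac` of the axis range.
#'
#' @param scores n x 2 matrix of individual scores.
#' @param population factor/character: species x plot population of each
#'   individual.
#' @param plot factor/character: plot of each individual.
#' @param min_sd_frac floor on predicted kernel SDs, as a fraction of each
#'   axis's score range.
#' @return Object of class `bandwidth_model`: list with `H` (named list:
#'   2 x 2 matrix per population), `n` (individuals per population),
#'   `regression` (per plot per axis coefficients), `min_sd`.
#' @export
fit_bandwidths <- function(scores, population, plot, min_sd_frac = 0.05) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(population),
            length(population) == length(plot))
  population <- as.character(population)
  plot <- as.character(plot)
  rng <- apply(scores, 2, range)
  min_sd <- pmax((rng[2, ] - rng[1, ]) * min_sd_frac, .Machine$double.eps)

  pops <- split(seq_len(nrow(scores)), population)
  n_pop <- vapply(pops, length, integer(1))
  pop_plot <- vapply(pops, function(ix) plot[ix[1]], character(1))
  pop_mean <- t(vapply(pops, function(ix) {
    colMeans(scores[ix, , drop = FALSE])
  }, numeric(2)))
  pop_sd <- t(vapply(pops, function(ix) {
    if (length(ix) >= 2) apply(scores[ix, , drop = FALSE], 2, stats::sd)
    else c(NA_real_, NA_real_)
  }, numeric(2)))

  # plot-level SD-on-mean regressions over populations with n >= 3
  regression <- list()
  for (pl in unique(pop_plot)) {
    sel <- pop_plot == pl & n_pop >= 3
    regression[[pl]] <- lapply(1:2, function(ax) {
      if (sum(sel) >= 3) {
        co <- stats::coef(stats::lm(pop_sd[sel, ax] ~ pop_mean[sel, ax]))
        list(intercept = unname(co[1]), slope = unname(co[2]),
             fallback = FALSE)
      } else {
        warning("plot '", pl, "': fewer than 3 populations with n >= 3; ",
                "rare-species SDs fall back to the plot-wide median SD")
        med <- stats::median(pop_sd[pop_plot == pl, ax], na.rm = TRUE)
        if (!is.finite(med)) med <- min_sd[ax]
        list(intercept = med, slope = 0, fallback = TRUE)
      }
    })
  }

  nsf <- function(n) (4 / (2 + 2))^(2 / (2 + 4)) * n^(-2 / (2 + 4))
  H <- vector("list", length(pops))
  names(H) <- names(pops)
  for (k in seq_along(pops)) {
    ix <- pops[[k]]
    n <- length(ix)
    if (n >= 3) {
      Hm <- nsf(n) * stats::cov(scores[ix, , drop = FALSE])
      # numerical SPD guard: collinear samples get a thin but positive
      # kernel (1/5 of the rare-species SD floor)
      e <- eigen(Hm, symmetric = TRUE)
      ev <- pmax(e$values, (min(min_sd) / 5)^2)
      Hm <- e$vectors %*% diag(ev) %*% t(e$vectors)
    } else {
      reg <- regression[[pop_plot[k]]]
      sds <- vapply(1:2, function(ax) {
        max(reg[[ax]]$intercept + reg[[ax]]$slope * pop_mean[k, ax],
            min_sd[ax])
      }, numeric(1))
      Hm <- diag(sds^2)
    }
    H[[k]] <- Hm
  }
  out <- list(H = H, n = n_pop, mean = pop_mean, plot = pop_plot,
              regression = regression, min_sd = min_sd)
  class(out) <- "bandwidth_model"
  out
}

#' @export
print.bandwidth_model <- function(x, ...) {
  cat(sprintf("Bandwidth model: %d populations (%d with n >= 3, %d rare)\n",
              length(x$H), sum(x$n >= 3), sum(x$n < 3)))
  cat(sprintf("  SD floor: (%.4f, %.4f)\n", x$min_sd[1], x$min_sd[2]))
  invisible(x)
}

# bivariate Gaussian mass on the grid for one kernel; returns a vector of
# length ncell (x1-fast layout), un-normalized density times cell area
.gauss_cell_mass <- function(grid, mu, H) {
  Q <- solve(H)
  d1 <- grid$x1 - mu[1]
  d2 <- grid$x2 - mu[2]
  quad <- outer(Q[1, 1] * d1^2, Q[2, 2] * d2^2, "+") +
    2 * Q[1, 2] * outer(d1, d2)
  dens <- exp(-quad / 2) / (2 * pi * sqrt(det(H)))
  as.vector(dens) * grid$cell_area
}

#' Trait probability density of one population
#'
#' Equal-weight mixture of bivariate Gaussian kernels centred on the
#' population's individual scores, evaluated at the grid cell centres,
#' converted to cell masses and renormalized to sum exactly 1.
#'
#' @param scores n x 2 matrix of the population's individual scores; every
#'   score must lie inside the grid.
#' @param bandwidth 2 x 2 kernel covariance matrix (or a length-2 vector of
#'   per-axis SDs, used as a diagonal covariance).
#' @param grid a [build_grid()] grid.
#' @param population optional population id stored with the result.
#' @return Object of class `tpd`: list with `mass` (vector of cell masses
#'   summing to 1), `grid`, `population`, `n_obs`.
#' @export
species_tpd <- function(scores, bandwidth, grid, population = NULL) {
  scores <- matrix(as.matrix(scores), ncol = 2)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(scores[, 1] < grid$min[1] | scores[, 1] > grid$max[1] |
            scores[, 2] < grid$min[2] | scores[, 2] > grid$max[2])) {
    stop("score(s) outside the grid; build the grid from all scores")
  }
  if (!is.matrix(bandwidth)) bandwidth <- diag(as.numeric(bandwidth)^2)
  mass <- 0
  for (i in seq_len(nrow(scores))) {
    mass <- mass + .gauss_cell_mass(grid, scores[i, ], bandwidth)
  }
  mass <- mass / nrow(scores)
  mass <- mass / sum(mass)
  structure(list(mass = mass, grid = grid, population = population,
                 n_obs = nrow(scores)), class = "tpd")
}

#' @export
print.tpd <- function(x, ...) {
  cat(sprintf("TPD%s on %d x %d grid (mass %.6f)\n",
              if (!is.null(x$population)) paste0(" of ", x$population) else "",
              x$grid$cells[1], x$grid$cells[2], sum(x$mass)))
  invisible(x)
}

#' @export
plot.tpd <- function(x, ...) {
  graphics::image(x$grid$x1, x$grid$x2,
                  matrix(x$mass, x$grid$cells[1], x$grid$cells[2]),
                  xlab = "axis 1", ylab = "axis 2",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  invisible(x)
}

#' Trait probability densities of all populations on one grid
#'
#' @param scores n x 2 matrix of individual scores.
#' @param population population (species x plot) of each individual.
#' @param bandwidths a [fit_bandwidths()] model for these populations.
#' @param grid a [build_grid()] grid.
#' @return Object of class `tpd_set`: list with `M` (ncell x n_populations
#'   matrix of cell masses, each column summing to 1), `grid`, `pop_means`
#'   (population mean scores), `n`.
#' @export
species_tpd_set <- function(scores, population, bandwidths, grid) {
  scores <- as.matrix(scores)
  population <- as.character(population)
  pops <- split(seq_len(nrow(scores)), population)
  M <- matrix(0, grid$ncell, length(pops),
              dimnames = list(NULL, names(pops)))
  for (k in seq_along(pops)) {
    ix <- pops[[k]]
    M[, k] <- species_tpd(scores[ix, , drop = FALSE],
                          bandwidths$H[[names(pops)[k]]], grid)$mass
  }
  pm <- t(vapply(pops, function(ix) colMeans(scores[ix, , drop = FALSE]),
                 numeric(2)))
  structure(list(M = M, grid = grid, pop_means = pm,
                 n = vapply(pops, length, integer(1))),
            class = "tpd_set")
}

#' @export
print.tpd_set <- function(x, ...) {
  cat(sprintf("TPD set: %d populations on a %d x %d grid\n",
              ncol(x$M), x$grid$cells[1], x$grid$cells[2]))
  invisible(x)
}

#' Community-level TPD weighted by a biomass dimension
#'
#' Sums the population TPDs rescaled by the relative share of each
#' population in the chosen biomass dimension (standing biomass, growth of
#' survivors, growth of recruits, mortality, or the positive/negative parts
#' of net biomass change).
#'
#' @param tpd_set a [species_tpd_set()].
#' @param weights non-negative weights named by population (unnamed vectors
#'   must match the column order of the set); at least one positive.
#' @param dimension label of the biomass dimension.
#' @return Object of class `c("community_tpd", "tpd")` with the normalized
#'   mixture `mass`, the normalized `weights` and the `dimension` label.
#' @export
community_tpd <- function(tpd_set, weights, dimension = "biomass") {
  stopifnot(inherits(tpd_set, "tpd_set"))
  w <- .align_weights(tpd_set, weights)
  mass <- as.vector(tpd_set$M %*% w)
  mass <- mass / sum(mass)
  structure(list(mass = mass, grid = tpd_set$grid, weights = w,
                 dimension = dimension, population = dimension),
            class = c("community_tpd", "tpd"))
}

.align_weights <- function(tpd_set, weights) {
  pops <- colnames(tpd_set$M)
  if (!is.null(names(weights))) {
    w <- stats::setNames(rep(0, length(pops)), pops)
    common <- intersect(names(weights), pops)
    w[common] <- weights[common]
  } else {
    if (length(weights) != length(pops)) {
      stop("unnamed weights must have one entry per population")
    }
    w <- stats::setNames(as.numeric(weights), pops)
  }
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative")
  }
  if (sum(w) <= 0) stop("all weights are zero")
  w / sum(w)
}

#' Highest-density (dominance) region of a TPD
#'
#' The smallest set of grid cells whose cumulative mass reaches the
#' fraction `q`: cells are ranked by mass (ties broken by cell index, so
#' regions are nested across `q`). Optionally counts which populations fall
#' inside the region, a population being assigned to the cell containing
#' its mean score.
#'
#' @param tpd a `tpd` or `community_tpd`.
#' @param q probability threshold in (0, 1), e.g. 0.5 for the functional
#'   dominance region.
#' @param pop_means optional matrix of population mean scores (rownames =
#'   population ids) for membership counting.
#' @return Object of class `dominance_region`: list with `cells` (indices),
#'   `mass` (cumulative mass captured), `q`, `area` (cells x cell area),
#'   and when `pop_means` is given `members` (population ids inside) and
#'   `n_members`.
#' @export
dominance_region <- function(tpd, q, pop_means = NULL) {
  if (!is.numeric(q) || q <= 0 || q >= 1) stop("q must be in (0, 1)")
  ord <- order(tpd$mass, decreasing = TRUE)
  cum <- cumsum(tpd$mass[ord])
  k <- which(cum >= q)[1]
  if (is.na(k)) k <- length(ord)
  cells <- ord[seq_len(k)]
  out <- list(cells = cells, mass = cum[k], q = q,
              area = k * tpd$grid$cell_area)
  if (!is.null(pop_means)) {
    cell_idx <- .cell_of(tpd$grid, as.matrix(pop_means))
    inside <- cell_idx %in% cells
    out$members <- rownames(pop_means)[inside]
    out$n_members <- sum(inside)
  }
  class(out) <- "dominance_region"
  out
}

#' @export
print.dominance_region <- function(x, ...) {
  cat(sprintf("Dominance region q = %.2f: %d cells (area %.3f, mass %.4f)",
              x$q, length(x$cells), x$area, x$mass))
  if (!is.null(x$n_members)) cat(sprintf(", %d populations", x$n_members))
  cat("\n")
  invisible(x)
}

#' Functional richness of a TPD
#'
#' Area of trait space occupied by the density's support, operationalized
#' as the area of the highest-density region holding fraction `q` of the
#' probability mass (default 0.99; the literal "positive" support of a
#' Gaussian mixture would be the whole grid).
#'
#' @param tpd a `tpd` or `community_tpd`.
#' @param q support mass threshold; default 0.99.
#' @return Occupied area, in squared trait-space units.
#' @export
functional_richness <- function(tpd, q = 0.99) {
  dominance_region(tpd, q)$area
}

#' Overlap-based dissimilarity between two TPDs
#'
#' \eqn{\beta_O = 1 - \sum_{cells} \min(a, b)} for two normalized densities
#' on the same grid: 0 for identical densities, 1 for disjoint supports.
#'
#' @param tpd_a,tpd_b two `tpd` objects on the same grid.
#' @return Dissimilarity in `[0, 1]`.
#' @export
overlap_dissimilarity <- function(tpd_a, tpd_b) {
  if (!.same_grid(tpd_a$grid, tpd_b$grid)) {
    stop("TPDs are on different grids")
  }
  min(max(1 - sum(pmin(tpd_a$mass, tpd_b$mass)), 0), 1)
}

# columnwise functional richness for a matrix of (normalized) cell masses
.fric_cols <- function(M, cell_area, q = 0.99) {
  apply(M, 2, function(m) {
    cum <- cumsum(sort(m, decreasing = TRUE))
    (which(cum >= q)[1]) * cell_area
  })
}

#' Resampling test for functional-richness differences
#'
#' Tests whether the functional richness of the community TPD weighted by
#' dimension A exceeds that weighted by dimension B. In each of
#' `n_resamples` draws, half of the populations (floor(n/2), without
#' replacement, the same subset for both dimensions) are retained, both
#' community TPDs are rebuilt from the subset, and the richness difference
#' A - B is recorded. The p-value is the add-one fraction of resampled
#' differences whose sign opposes (or is zero against) the observed
#' full-data difference; an observed difference of exactly zero reports
#' p = 1.
#'
#' @param tpd_set a [species_tpd_set()].
#' @param weights_a,weights_b the two biomass-dimension weight vectors
#'   (named by population).
#' @param n_resamples number of half-community resamples; default 999.
#' @param seed integer seed.
#' @param q functional-richness support threshold.
#' @param labels length-2 labels of the dimensions.
#' @return Object of class `tpd_null_test` with `observed` (richness
#'   difference A - B), `fric_a`, `fric_b`, `null` (resampled differences),
#'   `p_value`, `n`, `seed`.
#' @export
fric_resampling_test <- function(tpd_set, weights_a, weights_b,
                                 n_resamples = 999L, seed = 1L, q = 0.99,
                                 labels = c("A", "B")) {
  stopifnot(inherits(tpd_set, "tpd_set"))
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  wa <- .align_weights(tpd_set, weights_a)
  wb <- .align_weights(tpd_set, weights_b)
  npop <- ncol(tpd_set$M)
  if (npop < 4L) stop("need at least 4 populations")
  ca <- tpd_set$grid$cell_area
  fa <- unname(.fric_cols(tpd_set$M %*% cbind(wa), ca, q))
  fb <- unname(.fric_cols(tpd_set$M %*% cbind(wb), ca, q))
  observed <- fa - fb

  k <- floor(npop / 2)
  set.seed(as.integer(seed))
  Wa <- matrix(0, npop, n_resamples)
  Wb <- matrix(0, npop, n_resamples)
  for (r in seq_len(n_resamples)) {
    for (try in 1:1000) {
      sub <- sample.int(npop, k)
      if (sum(wa[sub]) > 0 && sum(wb[sub]) > 0) break
      if (try == 1000) stop("could not draw a half-community with positive ",
                            "weight in both dimensions")
    }
    Wa[sub, r] <- wa[sub] / sum(wa[sub])
    Wb[sub, r] <- wb[sub] / sum(wb[sub])
  }
  Ma <- tpd_set$M %*% Wa
  Mb <- tpd_set$M %*% Wb
  Ma <- sweep(Ma, 2, colSums(Ma), "/")
  Mb <- sweep(Mb, 2, colSums(Mb), "/")
  nulls <- .fric_cols(Ma, ca, q) - .fric_cols(Mb, ca, q)

  p <- if (observed == 0) {
    1
  } else {
    (1 + sum(nulls * sign(observed) <= 0)) / (n_resamples + 1)
  }
  structure(list(statistic = sprintf("FRic(%s) - FRic(%s)", labels[1],
                                     labels[2]),
                 observed = observed, fric_a = fa, fric_b = fb,
                 null = nulls, p_value = p, n = n_resamples,
                 seed = as.integer(seed)),
            class = "tpd_null_test")
}

#' Randomization null for overlap dissimilarity
#'
#' Tests whether the overlap dissimilarity between the A- and B-weighted
#' community TPDs exceeds chance expectation. The null model jointly
#' permutes which population carries which (A, B) weight pair across
#' populations (the pairing of the two dimensions is preserved; which
#' kernel they rescale is randomized), recomputing the dissimilarity each
#' time. p = add-one fraction of null dissimilarities at least as large as
#' the observed one.
#'
#' @inheritParams fric_resampling_test
#' @param n_randomizations number of permutations; default 999.
#' @return Object of class `tpd_null_test` with observed dissimilarity,
#'   the null distribution, and the p-value.
#' @export
beta_null_test <- function(tpd_set, weights_a, weights_b,
                           n_randomizations = 999L, seed = 1L,
                           labels = c("A", "B")) {
  stopifnot(inherits(tpd_set, "tpd_set"))
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1")
  npop <- ncol(tpd_set$M)
  if (npop < 2L) stop("overlap randomization is degenerate with fewer than ",
                      "2 populations")
  wa <- .align_weights(tpd_set, weights_a)
  wb <- .align_weights(tpd_set, weights_b)
  obs_a <- as.vector(tpd_set$M %*% wa)
  obs_b <- as.vector(tpd_set$M %*% wb)
  observed <- min(max(1 - sum(pmin(obs_a / sum(obs_a), obs_b / sum(obs_b))),
                      0), 1)
  set.seed(as.integer(seed))
  Pa <- matrix(0, npop, n_randomizations)
  Pb <- matrix(0, npop, n_randomizations)
  for (r in seq_len(n_randomizations)) {
    perm <- sample.int(npop)
    Pa[, r] <- wa[perm]
    Pb[, r] <- wb[perm]
  }
  Ma <- tpd_set$M %*% Pa
  Mb <- tpd_set$M %*% Pb
  Ma <- sweep(Ma, 2, colSums(Ma), "/")
  Mb <- sweep(Mb, 2, colSums(Mb), "/")
  nulls <- 1 - colSums(pmin(Ma, Mb))
  p <- (1 + sum(nulls >= observed)) / (n_randomizations + 1)
  structure(list(statistic = sprintf("beta_O(%s, %s)", labels[1], labels[2]),
                 observed = observed, null = nulls, p_value = p,
                 n = n_randomizations, seed = as.integer(seed)),
            class = "tpd_null_test")
}

#' @export
print.tpd_null_test <- function(x, ...) {
  cat("Randomization test:", x$statistic, "\n")
  cat(sprintf("  observed = %.4f, null median = %.4f, p = %.4f (%d draws)\n",
              x$observed, stats::median(x$null), x$p_value, x$n))
  invisible(x)
}
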