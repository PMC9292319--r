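# Synthetic multi-plot community generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# latent trait trade-off axes (hydraulic safety--efficiency, investment in
# tissues), right-skewed species abundances, abundance-weighted trait
# sampling, and drought demography in which biomass mortality is spread
# more widely over the trait space than survivor growth.

#' Default latent-axis loading matrix
#'
#' Maps the two latent community axes to the 15 traits on their analysis
#' scale (log for right-skewed traits, identity otherwise; see
#' [trait_reference()]). Axis 1 is the hydraulic safety (negative) to
#' efficiency (positive) trade-off: wide vessels, large pits and high
#' theoretical conductivity load positively, vessel density and fibre wall
#' thickness negatively. Axis 2 is investment in tissues: wood densities,
#' LDMC and leaf thickness load positively, SLA, leaf area and maximal
#' water content negatively.
#'
#' @return A 15 x 2 matrix with trait rownames and columns
#'   `c("hydraulic", "investment")`.
#' @export
default_trait_loadings <- function() {
  tr <- trait_names()
  L <- matrix(0, nrow = length(tr), ncol = 2,
              dimnames = list(tr, c("hydraulic", "investment")))
  L["FWT", ]   <- c(-0.70,  0.00)
  L["dh", ]    <- c( 0.80,  0.00)
  L["LA", ]    <- c( 0.00, -0.60)
  L["LDMC", ]  <- c( 0.00,  0.80)
  L["Lth", ]   <- c( 0.00,  0.50)
  L["VAmax", ] <- c( 0.70,  0.00)
  L["PA", ]    <- c( 0.60,  0.00)
  L["DApit", ] <- c( 0.55,  0.00)
  L["SLA", ]   <- c( 0.00, -0.80)
  L["VA", ]    <- c( 0.80,  0.00)
  L["VD", ]    <- c(-0.80,  0.00)
  L["WD", ]    <- c( 0.00,  0.80)
  L["WD0", ]   <- c( 0.00,  0.80)
  L["WCmax", ] <- c( 0.00, -0.70)
  L["Kp", ]    <- c( 0.85,  0.00)
  L
}

# Trait location/scale on the analysis scale, matched to the magnitudes of
# field measurements in seasonally dry tropical forests.
.trait_scale_table <- function() {
  ref <- trait_reference()
  mean_raw <- c(FWT = 5.54, dh = 58.64, LA = 1.25e4, LDMC = 379.38,
                Lth = 0.21, VAmax = 2942.59, PA = 19.68, DApit = 2.90,
                SLA = 15.39, VA = 1676.93, VD = 71.71, WD = 0.63,
                WD0 = 0.72, WCmax = 1.05, Kp = 25.09)
  sd_raw <- c(FWT = 1.52, dh = 22.39, LA = 2.15e4, LDMC = 91.31,
              Lth = 0.06, VAmax = 2623.32, PA = 16.30, DApit = 1.19,
              SLA = 7.33, VA = 1484.11, VD = 50.54, WD = 0.15,
              WD0 = 0.17, WCmax = 0.61, Kp = 43.78)
  mean_raw <- mean_raw[ref$trait]
  sd_raw <- sd_raw[ref$trait]
  loc <- ifelse(ref$log_scale, log(mean_raw), mean_raw)
  # on the log scale use the coefficient of variation, capped so that
  # back-transformed values stay within plausible orders of magnitude
  scl <- ifelse(ref$log_scale, pmin(sd_raw / mean_raw, 0.9), sd_raw)
  data.frame(trait = ref$trait, loc = loc, scale = scl,
             log_scale = ref$log_scale, stringsAsFactors = FALSE)
}

#' Configuration of the synthetic community generator
#'
#' Assembles and validates the parameter set of [generate_community()].
#' Defaults describe a desk-scale stand-in for an 11-plot tropical dry
#' forest network: 4 one-hectare plots of 500 trees drawn from a 60-species
#' pool, censused twice across a drought interval.
#'
#' @param n_plots number of plots.
#' @param n_species_pool size of the regional species pool.
#' @param individuals_per_plot trees per plot at the first census.
#' @param trait_loading_matrix 15 x 2 matrix mapping the two latent axes to
#'   the traits (analysis scale); default [default_trait_loadings()].
#' @param trait_noise_sd standard deviation of trait noise around the
#'   latent prediction, in units of each trait's scale.
#' @param within_species_sd spread of individual latent positions around
#'   their species position.
#' @param abundance_shape parameter in (0, 1) of the geometric-series rank
#'   abundance distribution; larger values give steeper dominance.
#' @param census_interval_years time between the two censuses.
#' @param baseline_mortality per-tree probability of death over the census
#'   interval for trees on the adapted trait manifold.
#' @param drought_mortality_gain additional mortality probability for trees
#'   maximally distant from the adapted manifold.
#' @param mortality_breadth standard deviation (latent-axis units) of the
#'   Gaussian mortality kernel around the adapted manifold. Larger values
#'   flatten the kernel, spreading mortality over a wider region of the
#'   trait space; must exceed `growth_breadth` to emulate drought mortality
#'   being more widespread in the functional space than survivor growth.
#' @param growth_breadth standard deviation of the Gaussian growth kernel.
#' @param recruit_rate expected recruits per standing tree over the
#'   interval.
#' @param missing_fraction fraction of individual x trait cells masked as
#'   missing (default 0.04).
#' @param height_a,height_b coefficients of the height--diameter power law
#'   \eqn{H = a \cdot DBH^b} used to generate tree heights.
#' @param seed integer seed; identical seeds give identical communities.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_plots = 4,
                             n_species_pool = 60,
                             individuals_per_plot = 500,
                             trait_loading_matrix = default_trait_loadings(),
                             trait_noise_sd = 0.5,
                             within_species_sd = 0.3,
                             abundance_shape = 0.06,
                             census_interval_years = 3,
                             baseline_mortality = 0.08,
                             drought_mortality_gain = 0.30,
                             mortality_breadth = 2.0,
                             growth_breadth = 0.7,
                             recruit_rate = 0.05,
                             missing_fraction = 0.04,
                             height_a = 1.3,
                             height_b = 0.55,
                             seed = 1L) {
  cfg <- list(n_plots = n_plots, n_species_pool = n_species_pool,
              individuals_per_plot = individuals_per_plot,
              trait_loading_matrix = trait_loading_matrix,
              trait_noise_sd = trait_noise_sd,
              within_species_sd = within_species_sd,
              abundance_shape = abundance_shape,
              census_interval_years = census_interval_years,
              baseline_mortality = baseline_mortality,
              drought_mortality_gain = drought_mortality_gain,
              mortality_breadth = mortality_breadth,
              growth_breadth = growth_breadth,
              recruit_rate = recruit_rate,
              missing_fraction = missing_fraction,
              height_a = height_a, height_b = height_b,
              seed = as.integer(seed))
  .validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

.check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop("field '", field, "' must be a single finite number", call. = FALSE)
  }
  if (x < lower || x > upper || (strict_lower && x <= lower)) {
    stop("field '", field, "' out of range [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  invisible(x)
}

.validate_synthetic_config <- function(cfg) {
  .check_scalar(cfg$n_plots, "n_plots", 1)
  .check_scalar(cfg$n_species_pool, "n_species_pool", 2)
  .check_scalar(cfg$individuals_per_plot, "individuals_per_plot", 10)
  .check_scalar(cfg$trait_noise_sd, "trait_noise_sd", 0)
  .check_scalar(cfg$within_species_sd, "within_species_sd", 0)
  .check_scalar(cfg$abundance_shape, "abundance_shape", 0, 1, strict_lower = TRUE)
  .check_scalar(cfg$census_interval_years, "census_interval_years", 0,
                strict_lower = TRUE)
  .check_scalar(cfg$baseline_mortality, "baseline_mortality", 0, 1)
  .check_scalar(cfg$drought_mortality_gain, "drought_mortality_gain", 0)
  .check_scalar(cfg$mortality_breadth, "mortality_breadth", 0,
                strict_lower = TRUE)
  .check_scalar(cfg$growth_breadth, "growth_breadth", 0, strict_lower = TRUE)
  .check_scalar(cfg$recruit_rate, "recruit_rate", 0, 1)
  .check_scalar(cfg$missing_fraction, "missing_fraction", 0, 1)
  .check_scalar(cfg$height_a, "height_a", 0, strict_lower = TRUE)
  .check_scalar(cfg$height_b, "height_b", 0, strict_lower = TRUE)
  .check_scalar(cfg$seed, "seed")
  L <- cfg$trait_loading_matrix
  if (!is.matrix(L) || nrow(L) != 15L || ncol(L) != 2L ||
      any(!is.finite(L))) {
    stop("field 'trait_loading_matrix' must be a finite 15 x 2 matrix",
         call. = FALSE)
  }
  invisible(cfg)
}

# Centres of the two "adapted" trait combinations: high investment with
# hydraulic safety, and high investment with hydraulic efficiency.
.adapted_ridges <- function() {
  rbind(safe = c(-1, 1), efficient = c(1, 1))
}

# Affinity in (0, 1] of a latent position for the adapted manifold:
# Gaussian kernel on distance to the nearest ridge centre, scale `breadth`.
.manifold_affinity <- function(z, breadth) {
  ridges <- .adapted_ridges()
  d2 <- sapply(seq_len(nrow(ridges)), function(k) {
    (z[, 1] - ridges[k, 1])^2 + (z[, 2] - ridges[k, 2])^2
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  exp(-apply(d2, 1, min) / (2 * breadth^2))
}

#' Generate a synthetic multi-plot community
#'
#' Simulates a two-census tree inventory and an abundance-weighted trait
#' table over `n_plots` plots. Species occupy positions on two latent trait
#' axes; the 15 traits are linear images of those axes (via
#' `trait_loading_matrix`) plus noise, back-transformed from the log scale
#' where appropriate. Over the census interval each tree dies with
#' probability `baseline_mortality` plus a penalty that grows with distance
#' from the adapted manifold (two Gaussian ridges: high investment x
#' hydraulically safe, high investment x hydraulically efficient), survivors
#' grow in diameter with a trait-dependent mean, and recruits enter near the
#' 2.5 cm census threshold.
#'
#' Trait sampling follows the abundance-weighted scheme: within each plot,
#' species with at least five individuals get 5--8 sampled trait
#' individuals, species with two to four get 1--3, and singletons get 1.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_community`: a list with
#'   `trait_table` (individual trait records, possibly with missing cells),
#'   `census_table` (two-census inventory), `wood_density_table` (species x
#'   plot wood density), `true_latent_scores` (ground-truth latent 2-vectors
#'   of the trait-sampled individuals), `trait_mask` (logical matrix of
#'   masked cells) and `config`.
#' @examples
#' com <- generate_community(synthetic_config(n_plots = 2,
#'   individuals_per_plot = 120, seed = 7))
#' head(com$trait_table[, 1:6])
#' @export
generate_community <- function(config = synthetic_config()) {
  .validate_synthetic_config(config)
  set.seed(config$seed)
  scl <- .trait_scale_table()
  L <- config$trait_loading_matrix
  tr <- trait_names()

  # species pool: latent positions and leaf habit; the hydraulic trade-off
  # (axis 1) carries more between-species variance than investment in
  # tissues (axis 2), as in field trait data, so the leading PCA axis is
  # well determined
  sp_lat <- cbind(ax1 = stats::rnorm(config$n_species_pool),
                  ax2 = 0.75 * stats::rnorm(config$n_species_pool))
  sp_names <- sprintf("sp%03d", seq_len(config$n_species_pool))
  habit_p <- stats::plogis(0.8 * sp_lat[, 1] - 0.3 * sp_lat[, 2])
  sp_habit <- ifelse(stats::runif(config$n_species_pool) < habit_p,
                     "deciduous", "evergreen")

  ab_p <- (1 - config$abundance_shape)^(seq_len(config$n_species_pool) - 1)
  ab_p <- ab_p / sum(ab_p)

  census <- list()
  traits <- list()
  latents <- list()
  wd_tab <- list()

  for (pl in seq_len(config$n_plots)) {
    plot_id <- sprintf("plot%02d", pl)
    n <- config$individuals_per_plot
    # plot-level shuffle of abundance ranks so plots differ in
    # composition; environmental filtering couples abundance to the
    # adapted manifold, so dominant species carry adapted trait
    # combinations (assembly-filter kernel scale 1 latent unit, floor 0.3)
    rank_perm <- sample.int(config$n_species_pool)
    filt <- .manifold_affinity(sp_lat, 1.0) + 0.3
    sp_idx <- sample.int(config$n_species_pool, n, replace = TRUE,
                         prob = ab_p[rank_perm] * filt)
    plot_shift <- stats::rnorm(2, 0, 0.15)

    ind_lat <- sp_lat[sp_idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, 0, config$within_species_sd), ncol = 2)
    ind_lat <- sweep(ind_lat, 2, plot_shift, "+")

    dbh0 <- 2.5 + stats::rlnorm(n, meanlog = log(6), sdlog = 0.8)
    h0 <- config$height_a * dbh0^config$height_b *
      exp(stats::rnorm(n, 0, 0.15))

    # drought demography over the census interval: mortality probability
    # rises with distance from the adapted manifold (kernel scale
    # mortality_breadth: large scale = flat kernel = mortality spread over
    # the whole trait space), while relative diameter growth is
    # concentrated near the manifold (scale growth_breadth)
    aff_m <- .manifold_affinity(ind_lat, config$mortality_breadth)
    p_die <- pmin(config$baseline_mortality +
                    config$drought_mortality_gain * (1 - aff_m), 0.95)
    dead <- stats::runif(n) < p_die

    aff_g <- .manifold_affinity(ind_lat, config$growth_breadth)
    # relative diameter growth (yr^-1): effectively zero away from the
    # adapted manifold -- during the drought interval only well-adapted
    # trait combinations keep growing
    rel_inc <- pmax(0.035 * aff_g - 0.004 +
                      stats::rnorm(n, 0, 0.002), 0)
    dbh_fin <- dbh0 * (1 + rel_inc)^config$census_interval_years
    dbh_fin[dead] <- NA_real_

    date0 <- as.Date("2013-06-01") + round(stats::runif(1, 0, 400)) +
      sample(-15:15, n, replace = TRUE)
    date1 <- date0 + round(config$census_interval_years * 365.25) +
      sample(-15:15, n, replace = TRUE)

    cen <- data.frame(
      tree_id = sprintf("%s_t%04d", plot_id, seq_len(n)),
      species = sp_names[sp_idx],
      plot = plot_id,
      status = ifelse(dead, "dead", "survivor"),
      dbh_t0 = dbh0,
      height_t0 = h0,
      dbh_tfin = dbh_fin,
      date_t0 = date0,
      date_tfin = date1,
      stringsAsFactors = FALSE
    )

    # recruits: favour species near the adapted manifold
    n_rec <- stats::rbinom(1, n, config$recruit_rate)
    if (n_rec > 0) {
      sp_here <- unique(sp_idx)
      rec_w <- ab_p[rank_perm][sp_here] *
        (.manifold_affinity(sp_lat[sp_here, , drop = FALSE],
                            config$growth_breadth) + 0.05)
      rec_sp <- sp_here[sample.int(length(sp_here), n_rec, replace = TRUE,
                                   prob = rec_w)]
      rec <- data.frame(
        tree_id = sprintf("%s_r%04d", plot_id, seq_len(n_rec)),
        species = sp_names[rec_sp],
        plot = plot_id,
        status = "recruit",
        dbh_t0 = NA_real_,
        height_t0 = NA_real_,
        dbh_tfin = stats::runif(n_rec, 2.5, 4.5),
        date_t0 = date0[1] + sample(-15:15, n_rec, replace = TRUE),
        date_tfin = date1[1] + sample(-15:15, n_rec, replace = TRUE),
        stringsAsFactors = FALSE
      )
      cen <- rbind(cen, rec)
    }
    census[[pl]] <- cen

    # abundance-weighted trait sampling from the standing (t0) trees
    for (s in sort(unique(sp_idx))) {
      rows <- which(sp_idx == s)
      n_sp <- length(rows)
      n_samp <- if (n_sp >= 5) {
        sample(5:8, 1)
      } else if (n_sp >= 2) {
        sample(1:3, 1)
      } else 1L
      n_samp <- min(n_samp, n_sp)
      pick <- if (n_sp == 1L) rows else sample(rows, n_samp)

      z <- ind_lat[pick, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(pick) * 15, 0, config$trait_noise_sd),
                    ncol = 15)
      val_t <- z %*% t(L) + eps            # analysis scale, standardized
      val <- sweep(sweep(val_t, 2, scl$scale, "*"), 2, scl$loc, "+")
      val[, scl$log_scale] <- exp(val[, scl$log_scale])
      colnames(val) <- tr
      # anhydrous density cannot fall below basic density
      val[, "WD0"] <- pmax(val[, "WD0"], val[, "WD"] * 1.01)

      rec <- data.frame(
        individual_id = cen$tree_id[pick],
        species = sp_names[s],
        plot = plot_id,
        habit = sp_habit[s],
        stringsAsFactors = FALSE
      )
      rec <- cbind(rec, as.data.frame(val))
      traits[[length(traits) + 1L]] <- rec
      latents[[length(latents) + 1L]] <- data.frame(
        individual_id = cen$tree_id[pick], ax1 = z[, 1], ax2 = z[, 2],
        stringsAsFactors = FALSE
      )
      wd_tab[[length(wd_tab) + 1L]] <- data.frame(
        species = sp_names[s], plot = plot_id,
        wood_density = mean(val[, "WD"]),
        stringsAsFactors = FALSE
      )
    }
  }

  trait_table <- do.call(rbind, traits)
  rownames(trait_table) <- NULL
  census_table <- do.call(rbind, census)
  rownames(census_table) <- NULL
  true_latent <- do.call(rbind, latents)
  rownames(true_latent) <- NULL
  wood_density_table <- do.call(rbind, wd_tab)
  rownames(wood_density_table) <- NULL

  masked <- mask_traits(trait_table, config$missing_fraction,
                        seed = config$seed + 1L)

  out <- list(trait_table = masked$trait_table,
              census_table = census_table,
              wood_density_table = wood_density_table,
              true_latent_scores = true_latent,
              trait_mask = masked$mask,
              trait_table_complete = trait_table,
              config = config)
  class(out) <- "synthetic_community"
  out
}

#' Mask trait cells as missing
#'
#' Sets a fraction of individual x trait cells to `NA`, uniformly at random,
#' without ever blanking an entire individual or an entire trait column.
#' Used both inside [generate_community()] and for mask-and-recover
#' validation of [impute_traits()].
#'
#' @param trait_table a trait table with the canonical trait columns.
#' @param missing_fraction fraction of cells to mask, in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical masks.
#' @param max_redraws redraws allowed when a draw would empty a column or an
#'   individual.
#' @return list with `trait_table` (masked copy) and `mask` (logical matrix,
#'   `TRUE` where a cell was masked).
#' @export
mask_traits <- function(trait_table, missing_fraction, seed = 1L,
                        max_redraws = 100L) {
  if (!is.numeric(missing_fraction) || missing_fraction < 0 ||
      missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  tr <- intersect(trait_names(), names(trait_table))
  X <- as.matrix(trait_table[, tr, drop = FALSE])
  mask <- matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X))
  if (missing_fraction > 0 && nrow(X) > 0) {
    set.seed(as.integer(seed))
    n_cells <- length(X)
    n_mask <- round(missing_fraction * n_cells)
    for (attempt in seq_len(max_redraws)) {
      idx <- sample.int(n_cells, n_mask)
      m <- matrix(FALSE, nrow(X), ncol(X))
      m[idx] <- TRUE
      ok_col <- all(colSums(!m & !is.na(X)) > 0)
      ok_row <- all(rowSums(!m) > 0)
      if (ok_col && ok_row) { mask[] <- m; break }
      if (attempt == max_redraws) {
        stop("could not draw a mask that keeps every trait column and ",
             "every individual partially observed")
      }
    }
    X[mask] <- NA_real_
  }
  out <- trait_table
  out[, tr] <- as.data.frame(X)
  list(trait_table = out, mask = mask)
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("Synthetic multi-plot community\n")
  cat(sprintf("  plots: %d, census records: %d, species: %d\n",
              length(unique(x$census_table$plot)),
              nrow(x$census_table),
              length(unique(x$census_table$species))))
  cat(sprintf("  trait individuals: %d (%d populations), missing cells: %d\n",
              nrow(x$trait_table),
              nrow(unique(x$trait_table[, c("species", "plot")])),
              sum(x$trait_mask)))
  tab <- table(x$census_table$status)
  cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic community configuration\n")
  flat <- x[!vapply(x, is.matrix, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, format(flat[[nm]])))
  invisible(x)
}
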