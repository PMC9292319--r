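# End-to-end orchestration: data (synthetic or read from disk) -> trait
# imputation -> trait space -> biomass ledger -> community TPDs per
# biomass dimension -> richness, dominance and dissimilarity statistics.

#' Default full-analysis configuration
#'
#' Nested configuration for [run_full_analysis()]. Either supply
#' `input = list(trait_table=, census_table=, wood_density_table=)` paths
#' to read the three tables from disk, or leave `input = NULL` to generate
#' a synthetic community from the `synthetic` section.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it (stage offsets of 1000).
#' @param synthetic arguments passed to [synthetic_config()].
#' @param tpd grid and null-model settings: `cells_per_axis`,
#'   `padding_fraction`, `fric_q`, `dominance_q`, `n_resamples`.
#' @param allometry coefficients for [allometry_model()].
#' @param impute settings for [impute_traits()].
#' @param input optional list of input table paths.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, synthetic = list(), tpd = list(),
                           allometry = NULL, impute = list(),
                           input = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    input = input,
    synthetic = synthetic,
    impute = utils::modifyList(list(max_iter = 10L, tol = 1e-3,
                                    num_trees = 100L), impute),
    allometry = allometry,
    tpd = utils::modifyList(list(cells_per_axis = 150L,
                                 padding_fraction = 0.15,
                                 fric_q = 0.99,
                                 dominance_q = c(0.2, 0.5, 0.99),
                                 n_resamples = 999L), tpd)
  )
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full trait-space / biomass-demography analysis
#'
#' Orchestrates all stages on one configuration: obtain the three input
#' tables (synthetic generation or disk), impute missing trait cells, fit
#' the two-dimensional trait space, build the demographic biomass ledger,
#' estimate per-population TPDs on a shared grid, combine them into
#' community TPDs weighted by each biomass dimension (standing biomass at
#' both censuses, growth of survivors, growth of recruits, mortality, and
#' the positive and negative parts of net biomass change), and compute
#' functional richness, dominance-region summaries and the two
#' randomization null tests (richness difference and overlap dissimilarity
#' for growth vs. mortality and for positive vs. negative net change).
#'
#' The run is deterministic given the configuration: all stage seeds are
#' derived from the master seed.
#'
#' @param config a [default_config()] list, or a path to a YAML file with
#'   the same structure.
#' @param out_dir optional directory; when given, result tables, TPD grids
#'   and a run manifest are written there (only after the whole analysis
#'   succeeded).
#' @return Object of class `forest_tpd_analysis`: list with `community`
#'   (when synthetic), `imputation`, `trait_space`, `ledger`, `tpd_set`,
#'   `community_tpds` (named list), `fric` (table), `dominance` (table),
#'   `tests` (named list of `tpd_null_test`), and `config`.
#' @export
run_full_analysis <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  seed <- as.integer(config$seed)

  # --- data ---------------------------------------------------------------
  community <- NULL
  if (!is.null(config$input)) {
    dat <- .stage("read-input", {
      list(trait_table = read_trait_table(config$input$trait_table),
           census_table = read_census_table(config$input$census_table),
           wood_density_table =
             read_wood_density_table(config$input$wood_density_table))
    })
  } else {
    community <- .stage("synthesize", {
      generate_community(do.call(synthetic_config,
                                 utils::modifyList(list(seed = seed),
                                                   config$synthetic)))
    })
    dat <- community[c("trait_table", "census_table", "wood_density_table")]
  }

  # --- imputation ---------------------------------------------------------
  imputation <- .stage("impute", {
    impute_traits(dat$trait_table, max_iter = config$impute$max_iter,
                  tol = config$impute$tol, seed = seed + 1000L,
                  num_trees = config$impute$num_trees)
  })

  # --- trait space --------------------------------------------------------
  space <- .stage("trait-space", fit_trait_space(imputation$data))
  fidelity <- check_rotation_fidelity(space)

  # --- biomass ledger -----------------------------------------------------
  model <- if (is.null(config$allometry)) {
    allometry_model()
  } else {
    allometry_model(unlist(config$allometry))
  }
  ledger <- .stage("ledger", {
    demographic_ledger(dat$census_table, model = model,
                       wood_density_table = dat$wood_density_table)
  })

  # --- TPDs ---------------------------------------------------------------
  pop <- paste(imputation$data$species, imputation$data$plot, sep = ":")
  grid <- .stage("tpd-grid", {
    build_grid(space$scores, config$tpd$cells_per_axis,
               config$tpd$padding_fraction)
  })
  bw <- .stage("bandwidths", {
    fit_bandwidths(space$scores, pop, imputation$data$plot)
  })
  tset <- .stage("species-tpds", species_tpd_set(space$scores, pop, bw, grid))

  led <- ledger$populations
  led_key <- paste(led$species, led$plot, sep = ":")
  wvec <- function(col, pos = FALSE, neg = FALSE) {
    v <- led[[col]]
    if (pos) v <- pmax(v, 0)
    if (neg) v <- pmax(-v, 0)
    stats::setNames(v, led_key)
  }
  dims <- list(
    standing_biomass_t0 = wvec("standing_t0"),
    standing_biomass_tfin = wvec("standing_tfin"),
    bg_s = wvec("bg_s"),
    bg_r = wvec("bg_r"),
    bm = wvec("bm"),
    nbc_pos = wvec("nbc", pos = TRUE),
    nbc_neg = wvec("nbc", neg = TRUE)
  )
  ctpds <- .stage("community-tpds", {
    lapply(names(dims), function(d) community_tpd(tset, dims[[d]], d))
  })
  names(ctpds) <- names(dims)

  fq <- config$tpd$fric_q
  fric <- data.frame(
    dimension = names(ctpds),
    fric = vapply(ctpds, functional_richness, numeric(1), q = fq),
    stringsAsFactors = FALSE
  )
  rownames(fric) <- NULL

  dominance <- .stage("dominance", {
    do.call(rbind, lapply(names(ctpds), function(d) {
      do.call(rbind, lapply(config$tpd$dominance_q, function(q) {
        reg <- dominance_region(ctpds[[d]], q, pop_means = tset$pop_means)
        w <- ctpds[[d]]$weights
        share <- sum(w[names(w) %in% reg$members])
        data.frame(dimension = d, q = q, n_cells = length(reg$cells),
                   area = reg$area, n_populations = reg$n_members,
                   weight_share = share, stringsAsFactors = FALSE)
      }))
    }))
  })

  nres <- config$tpd$n_resamples
  tests <- .stage("null-tests", list(
    fric_growth_vs_mortality =
      fric_resampling_test(tset, dims$bm, dims$bg_s, nres,
                           seed = seed + 3000L, q = fq,
                           labels = c("BM", "BG_S")),
    fric_nbc_neg_vs_pos =
      fric_resampling_test(tset, dims$nbc_neg, dims$nbc_pos, nres,
                           seed = seed + 4000L, q = fq,
                           labels = c("NBC-", "NBC+")),
    beta_growth_vs_mortality =
      beta_null_test(tset, dims$bg_s, dims$bm, nres,
                     seed = seed + 5000L, labels = c("BG_S", "BM")),
    beta_nbc_pos_vs_neg =
      beta_null_test(tset, dims$nbc_pos, dims$nbc_neg, nres,
                     seed = seed + 6000L, labels = c("NBC+", "NBC-"))
  ))

  out <- list(community = community, imputation = imputation,
              trait_space = space, rotation_fidelity = fidelity,
              ledger = ledger, grid = grid, bandwidths = bw,
              tpd_set = tset, community_tpds = ctpds, weights = dims,
              fric = fric, dominance = dominance, tests = tests,
              config = config)
  class(out) <- "forest_tpd_analysis"

  if (!is.null(out_dir)) .write_analysis(out, out_dir)
  out
}

.write_analysis <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_table(x$imputation$data, file.path(out_dir, "trait_table_completed.csv"))
  sc <- cbind(x$trait_space$ids,
              as.data.frame(x$trait_space$scores))
  .write_table(sc, file.path(out_dir, "trait_space_scores.csv"))
  ld <- format(as.data.frame(x$trait_space$loadings), digits = 10)
  ld <- cbind(trait = rownames(x$trait_space$loadings), ld)
  .write_table(ld, file.path(out_dir, "trait_space_loadings.csv"))
  .write_table(x$ledger$populations, file.path(out_dir, "ledger_populations.csv"))
  .write_table(x$ledger$plots, file.path(out_dir, "ledger_plots.csv"))
  .write_table(x$fric, file.path(out_dir, "fric.csv"))
  .write_table(x$dominance, file.path(out_dir, "dominance.csv"))
  tests <- do.call(rbind, lapply(names(x$tests), function(nm) {
    t <- x$tests[[nm]]
    data.frame(test = nm, statistic = t$statistic, observed = t$observed,
               null_median = stats::median(t$null), p_value = t$p_value,
               n = t$n, stringsAsFactors = FALSE)
  }))
  .write_table(tests, file.path(out_dir, "null_tests.csv"))
  for (d in names(x$community_tpds)) {
    write_tpd(x$community_tpds[[d]],
              file.path(out_dir, paste0("tpd_", d, ".csv")))
  }
  manifest <- list(
    package = "forestTPD",
    version = as.character(utils::packageVersion("forestTPD")),
    seed = x$config$seed,
    config = x$config[setdiff(names(x$config), "input")],
    input = x$config$input,
    config_checksum = sum(utf8ToInt(paste(deparse(
      x$config[sort(names(x$config))]), collapse = "")))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(out_dir)
}

#' @export
print.forest_tpd_analysis <- function(x, ...) {
  cat("Trait-space / biomass-demography analysis\n\n")
  print(x$trait_space)
  print(x$rotation_fidelity)
  cat("\n")
  print(x$ledger)
  cat("\nFunctional richness by biomass dimension:\n")
  print(x$fric, row.names = FALSE, digits = 4)
  cat("\nNull tests:\n")
  for (t in x$tests) print(t)
  invisible(x)
}
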