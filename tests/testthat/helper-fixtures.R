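# Shared fixtures. Expensive objects are memoized so the suite builds each
# of them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small community for module-level tests
small_community <- function() {
  memo("small_community", generate_community(
    synthetic_config(n_plots = 2, individuals_per_plot = 200, seed = 11)))
}

# full default-scale analysis (the study conditions), shared by the
# recovery and acceptance tests
default_analysis <- function() {
  memo("default_analysis",
       suppressWarnings(run_full_analysis(default_config(seed = 1))))
}

# simple scores for grid/TPD tests: one tight cluster, one spread cluster
toy_scores <- function(n = 60, seed = 2) {
  set.seed(seed)
  cbind(c(rnorm(n, -2, 0.4), rnorm(n, 2, 0.8)),
        c(rnorm(n, 0, 0.5), rnorm(n, 1, 0.7)))
}

# single-Gaussian TPD on a fine private grid
gaussian_tpd <- function(sigma = 1, cells = 220, half_width = 5) {
  g <- build_grid(rbind(c(-half_width, -half_width),
                        c(half_width, half_width)),
                  cells_per_axis = cells, padding_fraction = 0)
  species_tpd(rbind(c(0, 0)), diag(sigma^2, 2), g)
}
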