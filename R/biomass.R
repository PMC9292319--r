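# Two-census biomass accounting: standing biomass and the four demographic
# biomass dimensions (growth of survivors, growth of recruits, mortality,
# net biomass change).

#' Allometric biomass model
#'
#' A log-linear aboveground-biomass allometry
#' \deqn{\ln B = a + b \ln DBH + c \ln H + d \ln WD}
#' with DBH in cm, height in m, wood density in g cm^-3 and biomass in
#' tons. The default coefficients are replaceable stand-ins of plausible
#' tropical-tree magnitude (\eqn{B = 6\times 10^{-5} DBH^2 H\, WD} t); any
#' site-calibrated coefficient set for dry forests can be supplied
#' instead.
#'
#' @param coef named numeric vector with elements `a` (intercept on the log
#'   scale), `b` (DBH exponent), `c` (height exponent), `d` (wood-density
#'   exponent).
#' @param name label used in messages.
#' @return Object of class `allometry_model`.
#' @examples
#' m <- allometry_model()
#' tree_biomass(10, 8, 0.6, m)
#' @export
allometry_model <- function(coef = c(a = log(6e-5), b = 2, c = 1, d = 1),
                            name = "default-loglinear") {
  need <- c("a", "b", "c", "d")
  if (!is.numeric(coef) || !all(need %in% names(coef)) ||
      any(!is.finite(coef[need]))) {
    stop("allometry model '", name,
         "' needs finite named coefficients a, b, c, d")
  }
  if (coef[["b"]] <= 0) {
    stop("allometry model '", name,
         "' must be increasing in DBH (b > 0)")
  }
  structure(list(coef = coef[need], name = name), class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("Allometry '%s': ln B = %.4f + %.3f ln DBH + %.3f ln H + %.3f ln WD\n",
              x$name, x$coef[["a"]], x$coef[["b"]], x$coef[["c"]],
              x$coef[["d"]]))
  invisible(x)
}

#' Individual tree biomass
#'
#' Evaluates an [allometry_model()] for vectors of tree measurements.
#'
#' @param dbh diameter at breast height (cm), > 0.
#' @param height tree height (m), > 0.
#' @param wood_density stem wood density (g cm^-3), > 0.
#' @param model an [allometry_model()].
#' @return Biomass in tons.
#' @export
tree_biomass <- function(dbh, height, wood_density,
                         model = allometry_model()) {
  if (!inherits(model, "allometry_model")) model <- allometry_model(model)
  if (any(!is.finite(dbh)) || any(dbh <= 0)) stop("dbh must be finite and > 0")
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be finite and > 0")
  }
  if (any(!is.finite(wood_density)) || any(wood_density <= 0)) {
    stop("wood_density must be finite and > 0")
  }
  co <- model$coef
  exp(co[["a"]] + co[["b"]] * log(dbh) + co[["c"]] * log(height) +
        co[["d"]] * log(wood_density))
}

#' Net biomass change identity
#'
#' The accounting identity \eqn{NBC = BG_S + BG_R - BM}: net biomass change
#' equals growth of survivors plus growth of recruits minus biomass
#' mortality, all in the same units (typically t ha^-1 yr^-1).
#'
#' @param bg_s biomass growth of survivors.
#' @param bg_r biomass growth of recruits.
#' @param bm biomass mortality.
#' @return Net biomass change.
#' @examples
#' net_biomass_change(2.23, 0.10, 0.65)
#' @export
net_biomass_change <- function(bg_s, bg_r, bm) bg_s + bg_r - bm

# Power-law height-diameter model, fitted per plot on log scales.
.fit_height_power <- function(dbh, height) {
  ok <- is.finite(dbh) & is.finite(height) & dbh > 0 & height > 0
  if (sum(ok) < 3L) return(NULL)
  fit <- stats::lm(log(height[ok]) ~ log(dbh[ok]))
  co <- stats::coef(fit)
  list(a = exp(unname(co[1])), b = unname(co[2]))
}

.predict_height <- function(hm, dbh) hm$a * dbh^hm$b

#' Demographic biomass ledger from a two-census inventory
#'
#' Converts a two-census tree table into a per-population (species x plot)
#' ledger of standing biomass and the four demographic biomass dimensions,
#' with the following conventions:
#'
#' * `BG_S` (growth of survivors): annual biomass increment of trees alive
#'   at both censuses. The final-census height of a survivor is its first
#'   -census height scaled along the plot's height--diameter curve, so a
#'   tree with unchanged DBH contributes exactly zero.
#' * `BG_R` (growth of recruits): annual biomass of trees reaching the
#'   2.5 cm DBH threshold by the final census, counted from an initial DBH
#'   of 0 (their whole final biomass is new growth).
#' * `BM` (mortality): annual biomass of trees dying in the interval,
#'   counted as first-census biomass minus the biomass of the same tree
#'   evaluated at the 2.5 cm threshold (with threshold height from the
#'   plot's height--diameter curve), so mortality and recruitment are
#'   measured over the same size range.
#' * `NBC = BG_S + BG_R - BM` per population, per plot and network-wide.
#'
#' Census intervals are computed per plot, in decimal years, from the
#' median census dates. Survivors whose recorded DBH shrank by at most
#' `shrink_tol` (fractional) are treated as zero growth; larger shrinkage
#' is flagged as a data error and floored at zero.
#'
#' @param census data frame with columns `tree_id`, `species`, `plot`,
#'   `status` (`survivor`/`dead`/`recruit`), `dbh_t0`, `height_t0`,
#'   `dbh_tfin`, `date_t0`, `date_tfin` and optionally `wood_density`.
#' @param model an [allometry_model()].
#' @param wood_density_table optional data frame `species`, `plot`,
#'   `wood_density`, used when `census` lacks a `wood_density` column;
#'   species x plot combinations absent from the table fall back to the
#'   table's median.
#' @param plot_area_ha area of each plot in hectares (scalar or named by
#'   plot).
#' @param shrink_tol tolerated fractional DBH shrinkage of survivors.
#' @param height_model optional list `(a, b)` for \eqn{H = a\,DBH^b}; when
#'   `NULL`, fitted per plot from the first-census measurements.
#' @return Object of class `biomass_ledger`: list with `populations` (one
#'   row per species x plot with `standing_t0`, `standing_tfin`, `bg_s`,
#'   `bg_r`, `bm`, `nbc` in t ha^-1 (yr^-1 for rates)), `plots`, `network`
#'   (totals in t yr^-1 and per-ha means), `intervals`, and `flags`
#'   (tree ids with out-of-tolerance shrinkage).
#' @examples
#' com <- generate_community(synthetic_config(n_plots = 2,
#'   individuals_per_plot = 150, seed = 11))
#' led <- demographic_ledger(com$census_table,
#'   wood_density_table = com$wood_density_table)
#' led
#' @export
demographic_ledger <- function(census, model = allometry_model(),
                               wood_density_table = NULL,
                               plot_area_ha = 1, shrink_tol = 0.05,
                               height_model = NULL) {
  need <- c("tree_id", "species", "plot", "status", "dbh_t0", "height_t0",
            "dbh_tfin", "date_t0", "date_tfin")
  missing_cols <- setdiff(need, names(census))
  if (length(missing_cols)) {
    stop("census table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_status <- setdiff(unique(census$status),
                        c("survivor", "dead", "recruit"))
  if (length(bad_status)) {
    stop("unknown census status value(s): ", paste(bad_status, collapse = ", "))
  }
  is_rec <- census$status == "recruit"
  is_dead <- census$status == "dead"
  is_sur <- census$status == "survivor"
  if (any(is_rec & (!is.finite(census$dbh_tfin) | census$dbh_tfin < 2.5))) {
    stop("recruit(s) with final DBH below the 2.5 cm census threshold: ",
         paste(utils::head(census$tree_id[is_rec &
           (!is.finite(census$dbh_tfin) | census$dbh_tfin < 2.5)]),
           collapse = ", "))
  }
  if (any(!is_rec & (!is.finite(census$dbh_t0) | census$dbh_t0 < 2.5))) {
    stop("non-recruit record(s) without a valid first-census DBH >= 2.5 cm")
  }
  if (any(is_sur & !is.finite(census$dbh_tfin))) {
    stop("survivor(s) without a final-census DBH")
  }

  # wood density: column, else join on species x plot
  if (!"wood_density" %in% names(census)) {
    if (is.null(wood_density_table)) {
      stop("census has no wood_density column and no wood_density_table given")
    }
    key <- paste(census$species, census$plot, sep = "\r")
    tkey <- paste(wood_density_table$species, wood_density_table$plot,
                  sep = "\r")
    wd <- wood_density_table$wood_density[match(key, tkey)]
    wd[!is.finite(wd)] <- stats::median(wood_density_table$wood_density,
                                        na.rm = TRUE)
    census$wood_density <- wd
  }

  plots <- sort(unique(census$plot))
  area <- if (length(plot_area_ha) == 1L) {
    stats::setNames(rep(plot_area_ha, length(plots)), plots)
  } else plot_area_ha[plots]

  # per-plot census interval in decimal years from median dates
  intervals <- vapply(plots, function(pl) {
    r <- census[census$plot == pl, ]
    as.numeric(stats::median(as.Date(r$date_tfin)) -
                 stats::median(as.Date(r$date_t0))) / 365.25
  }, numeric(1))
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("census interval must be positive for every plot")
  }

  # per-plot height-diameter curves
  hmods <- lapply(plots, function(pl) {
    r <- census[census$plot == pl & !is_rec, ]
    .fit_height_power(r$dbh_t0, r$height_t0)
  })
  names(hmods) <- plots
  global_hm <- if (!is.null(height_model)) {
    height_model
  } else {
    .fit_height_power(census$dbh_t0[!is_rec], census$height_t0[!is_rec])
  }
  if (is.null(global_hm)) {
    stop("cannot fit a height-diameter curve; supply height_model")
  }
  hm_of <- function(pl) {
    if (!is.null(height_model)) return(height_model)
    hm <- hmods[[pl]]
    if (is.null(hm)) global_hm else hm
  }

  iv <- intervals[census$plot]
  B_t0 <- rep(NA_real_, nrow(census))
  B_t0[!is_rec] <- tree_biomass(census$dbh_t0[!is_rec],
                                census$height_t0[!is_rec],
                                census$wood_density[!is_rec], model)

  # survivors: final height = first height scaled along the plot curve
  inc <- rep(0, nrow(census))
  flags <- character(0)
  if (any(is_sur)) {
    s <- which(is_sur)
    hmv_a <- vapply(census$plot[s], function(pl) hm_of(pl)$a, numeric(1))
    hmv_b <- vapply(census$plot[s], function(pl) hm_of(pl)$b, numeric(1))
    h_fin <- census$height_t0[s] *
      (hmv_a * census$dbh_tfin[s]^hmv_b) /
      (hmv_a * census$dbh_t0[s]^hmv_b)
    B_fin <- tree_biomass(census$dbh_tfin[s], h_fin,
                          census$wood_density[s], model)
    gi <- B_fin - B_t0[s]
    shrink <- (census$dbh_t0[s] - census$dbh_tfin[s]) / census$dbh_t0[s]
    over <- shrink > shrink_tol
    if (any(over)) flags <- census$tree_id[s][over]
    gi[shrink > 0] <- 0          # shrinkage within tolerance: zero growth
    gi[over] <- 0                # beyond tolerance: flagged, floored
    inc[s] <- gi
  }

  # recruits: full final biomass counts as growth (initial DBH taken as 0)
  B_rec <- rep(0, nrow(census))
  if (any(is_rec)) {
    r <- which(is_rec)
    h_r <- vapply(seq_along(r), function(k) {
      .predict_height(hm_of(census$plot[r[k]]), census$dbh_tfin[r[k]])
    }, numeric(1))
    B_rec[r] <- tree_biomass(census$dbh_tfin[r], h_r,
                             census$wood_density[r], model)
  }

  # dead: first-census biomass minus biomass at the 2.5 cm threshold
  B_dead <- rep(0, nrow(census))
  if (any(is_dead)) {
    d <- which(is_dead)
    h_ref <- vapply(census$plot[d], function(pl) {
      .predict_height(hm_of(pl), 2.5)
    }, numeric(1))
    B_ref <- tree_biomass(rep(2.5, length(d)), h_ref,
                          census$wood_density[d], model)
    B_dead[d] <- pmax(B_t0[d] - B_ref, 0)
  }

  a_tree <- area[census$plot]
  pop_key <- interaction(census$species, census$plot, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, pop_key, sum))
  first_of <- function(v) as.character(tapply(as.character(v), pop_key,
                                              `[`, 1L))
  populations <- data.frame(
    species = first_of(census$species),
    plot = first_of(census$plot),
    standing_t0 = agg(ifelse(is_rec, 0, B_t0) / a_tree),
    standing_tfin = agg(ifelse(is_dead, 0,
                               ifelse(is_rec, B_rec,
                                      B_t0 + inc)) / a_tree),
    bg_s = pmax(agg(inc / iv / a_tree), 0),
    bg_r = pmax(agg(B_rec / iv / a_tree), 0),
    bm = pmax(agg(B_dead / iv / a_tree), 0),
    stringsAsFactors = FALSE
  )
  populations$nbc <- net_biomass_change(populations$bg_s, populations$bg_r,
                                        populations$bm)
  populations <- populations[order(populations$plot, populations$species), ]
  rownames(populations) <- NULL

  plot_tab <- do.call(rbind, lapply(plots, function(pl) {
    p <- populations[populations$plot == pl, ]
    data.frame(plot = pl, area_ha = unname(area[pl]),
               interval_years = unname(intervals[pl]),
               standing_t0 = sum(p$standing_t0),
               standing_tfin = sum(p$standing_tfin),
               bg_s = sum(p$bg_s), bg_r = sum(p$bg_r), bm = sum(p$bm),
               nbc = sum(p$nbc), stringsAsFactors = FALSE)
  }))
  rownames(plot_tab) <- NULL

  total_area <- sum(area)
  totals <- c(standing_t0 = sum(plot_tab$standing_t0 * plot_tab$area_ha),
              standing_tfin = sum(plot_tab$standing_tfin * plot_tab$area_ha),
              bg_s = sum(plot_tab$bg_s * plot_tab$area_ha),
              bg_r = sum(plot_tab$bg_r * plot_tab$area_ha),
              bm = sum(plot_tab$bm * plot_tab$area_ha))
  totals["nbc"] <- net_biomass_change(totals[["bg_s"]], totals[["bg_r"]],
                                      totals[["bm"]])
  network <- list(totals = totals, per_ha = totals / total_area,
                  total_area_ha = total_area)

  out <- list(populations = populations, plots = plot_tab,
              network = network, intervals = intervals, flags = flags,
              model = model)
  class(out) <- "biomass_ledger"
  out
}

#' @export
print.biomass_ledger <- function(x, ...) {
  n <- x$network
  cat("Biomass demography ledger\n")
  cat(sprintf("  %d populations over %d plots (%.1f ha), interval %.2f-%.2f yr\n",
              nrow(x$populations), nrow(x$plots), n$total_area_ha,
              min(x$intervals), max(x$intervals)))
  cat(sprintf("  network totals (t yr^-1): BG_S %.2f + BG_R %.2f - BM %.2f = NBC %.2f\n",
              n$totals[["bg_s"]], n$totals[["bg_r"]], n$totals[["bm"]],
              n$totals[["nbc"]]))
  cat(sprintf("  per-ha means  (t ha^-1 yr^-1): BG_S %.3f, BG_R %.3f, BM %.3f, NBC %.3f\n",
              n$per_ha[["bg_s"]], n$per_ha[["bg_r"]], n$per_ha[["bm"]],
              n$per_ha[["nbc"]]))
  cat(sprintf("  standing biomass (t): %.1f at t0, %.1f at tfin\n",
              n$totals[["standing_t0"]], n$totals[["standing_tfin"]]))
  if (length(x$flags)) {
    cat("  flagged shrinking survivors:", length(x$flags), "\n")
  }
  invisible(x)
}

#' @export
summary.biomass_ledger <- function(object, ...) {
  print(object)
  cat("\nPer-plot rates (t ha^-1 yr^-1):\n")
  print(object$plots[, c("plot", "bg_s", "bg_r", "bm", "nbc")],
        row.names = FALSE, digits = 3)
  invisible(object)
}
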