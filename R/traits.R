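# Derived wood-hydraulic traits and trait-table conventions.

#' Canonical trait columns
#'
#' Names, units and global reference ranges of the 15 functional traits the
#' package works with: four leaf traits and eleven wood traits spanning the
#' hydraulic safety--efficiency trade-off and the investment-in-tissues axis.
#'
#' @format A data frame with one row per trait and columns `trait` (column
#'   name used in trait tables), `unit`, `lower`, `upper` (global reference
#'   range used by [validate_trait_ranges()]) and `log_scale` (whether the
#'   trait is treated on the log scale by [fit_trait_space()] and the
#'   synthetic generator).
#' @seealso [validate_trait_ranges()], [fit_trait_space()]
#' @export
trait_reference <- function() {
  data.frame(
    trait = c("FWT", "dh", "LA", "LDMC", "Lth", "VAmax", "PA", "DApit",
              "SLA", "VA", "VD", "WD", "WD0", "WCmax", "Kp"),
    unit  = c("um", "um", "mm2", "mg/g", "mm", "um2", "um2", "um",
              "mm2/mg", "um2", "vessels/mm2", "g/cm3", "g/cm3",
              "kg/kg", "kg/m/s/MPa"),
    lower = c(4, 1, 1, 50, 0.11, 7853, 12, 0.5, 0, 196, 1, 0.1, 0.1, 0.2, 0.3),
    upper = c(12, 300, 2e7, 700, 0.74, 31415, 78, 7, 300, 37600, 1000,
              1.2, 1.5, 5.0, 200),
    log_scale = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname trait_reference
#' @export
trait_names <- function() trait_reference()$trait

# Physical constants for theoretical xylem conductivity.
# Water density (kg m^-3) and dynamic viscosity expressed in MPa s.
.rho_water <- 998.2
.eta_water <- 1.002e-9

#' Hydraulically weighted vessel diameter
#'
#' Computes the hydraulically weighted diameter of xylem conduits,
#' \eqn{d_h = (\sum_i d_i^4 / N)^{1/4}}, the order-4 power mean of the
#' measured conduit diameters. Because conductance scales with the fourth
#' power of conduit diameter (Hagen--Poiseuille), this mean weights wide
#' vessels according to their contribution to flow.
#'
#' @param vessel_diameters numeric vector of conduit diameters (um), all
#'   positive.
#' @return Hydraulically weighted diameter in the units of the input.
#' @examples
#' hydraulic_diameter(c(10, 20))
#' @export
hydraulic_diameter <- function(vessel_diameters) {
  d <- vessel_diameters
  if (length(d) == 0L) stop("vessel_diameters must be a non-empty vector")
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("vessel_diameters must be finite and strictly positive")
  }
  (sum(d^4) / length(d))^0.25
}

#' Theoretical xylem-specific hydraulic conductivity
#'
#' Potential (theoretical) hydraulic conductivity of xylem per unit
#' cross-sectional area from the Hagen--Poiseuille law,
#' \deqn{K_p = \frac{\pi \rho_w}{128 \eta} d_h^4 \, VD,}
#' with water density \eqn{\rho_w = 998.2} kg m^-3 and viscosity
#' \eqn{\eta = 1.002 \times 10^{-9}} MPa s. Inputs are given in the
#' anatomical measurement units (um and vessels mm^-2) and converted to SI
#' internally (um to m: 1e-6; mm^-2 to m^-2: 1e6).
#'
#' @param dh hydraulically weighted diameter (um), from
#'   [hydraulic_diameter()].
#' @param vd vessel density (vessels per mm^2).
#' @return Conductivity in kg m^-1 s^-1 MPa^-1.
#' @examples
#' potential_conductivity(dh = 58.64, vd = 71.71)
#' @export
potential_conductivity <- function(dh, vd) {
  if (any(!is.finite(dh)) || any(dh <= 0)) stop("dh must be finite and > 0")
  if (any(!is.finite(vd)) || any(vd <= 0)) stop("vd must be finite and > 0")
  dh_m <- dh * 1e-6
  vd_m2 <- vd * 1e6
  (pi * .rho_water / (128 * .eta_water)) * dh_m^4 * vd_m2
}

#' Wood water content at fibre saturation and at maximal capacity
#'
#' Water content at the fibre saturation point,
#' \eqn{WC_{fsp} = 1/WD - 1/WD_0}, and maximal (saturated) water content,
#' \eqn{WC_{max} = (1.5 - WD_0) / (1.5\, WD_0) + WC_{fsp}}, the classical
#' maximum-moisture-content formula with a cell-wall density of
#' 1.5 g cm^-3. `WD` is basic wood density (dry mass over saturated volume)
#' and `WD0` anhydrous density (dry mass over anhydrous volume), so
#' physically `WD <= WD0 < 1.5`.
#'
#' Note that the two `WD0` terms cancel algebraically:
#' \eqn{WC_{max} = 1/WD - 2/3}. `WD0` still matters for `WC_fsp` and for
#' input validation, but the maximal water content itself depends only on
#' basic density under this parameterization.
#'
#' @param WD basic wood density (g cm^-3).
#' @param WD0 anhydrous wood density (g cm^-3).
#' @return A list with components `WC_fsp` and `WC_max` (kg water per kg dry
#'   wood).
#' @examples
#' water_content_max(WD = 0.63, WD0 = 0.72)
#' @export
water_content_max <- function(WD, WD0) {
  if (any(!is.finite(WD)) || any(WD <= 0)) stop("WD must be finite and > 0")
  if (any(!is.finite(WD0)) || any(WD0 <= 0)) stop("WD0 must be finite and > 0")
  if (any(WD0 >= 1.5)) {
    stop("WD0 must be < 1.5 g cm^-3 (cell-wall density)")
  }
  if (any(WD > WD0)) {
    stop("WD > WD0: basic density cannot exceed anhydrous density ",
         "(would give negative WC_fsp); check the input data")
  }
  wc_fsp <- 1 / WD - 1 / WD0
  wc_max <- (1.5 - WD0) / (1.5 * WD0) + wc_fsp
  list(WC_fsp = wc_fsp, WC_max = wc_max)
}

#' Mean conduit area of the largest-vessel quartile
#'
#' Maximum vessel area (`VAmax`) defined as the mean conduit area among
#' conduits above the 75th percentile of the per-individual vessel-area
#' distribution.
#'
#' @param vessel_areas numeric vector of conduit areas (um^2).
#' @return Mean area of the upper quartile (um^2).
#' @export
max_vessel_area <- function(vessel_areas) {
  a <- vessel_areas
  if (length(a) == 0L || any(!is.finite(a)) || any(a <= 0)) {
    stop("vessel_areas must be non-empty, finite and positive")
  }
  q3 <- stats::quantile(a, 0.75, names = FALSE)
  top <- a[a > q3]
  if (length(top) == 0L) top <- max(a)
  mean(top)
}

#' Derive the wood-hydraulic traits from raw anatomy measurements
#'
#' Fills the derived columns of a trait table: `dh` from per-individual
#' vessel diameter lists, `VD` from conduit counts per area, `Kp` from `dh`
#' and `VD`, `VAmax` from vessel areas, and `WCmax` from the wood
#' densities.
#'
#' @param anatomy a list per individual with components `vessel_diameters`
#'   (um), `vessel_areas` (um^2) and `counted_area` (mm^2).
#' @param traits data frame holding at least `WD` and `WD0` for the same
#'   individuals (rows aligned with `anatomy`).
#' @return `traits` with columns `dh`, `VD`, `VAmax`, `VA`, `Kp`, `WCmax`
#'   filled.
#' @export
derive_wood_traits <- function(anatomy, traits) {
  stopifnot(length(anatomy) == nrow(traits))
  for (i in seq_along(anatomy)) {
    an <- anatomy[[i]]
    if (is.null(an$counted_area) || an$counted_area <= 0) {
      stop("counted_area must be > 0 for individual ", i)
    }
    traits$dh[i] <- hydraulic_diameter(an$vessel_diameters)
    traits$VD[i] <- length(an$vessel_diameters) / an$counted_area
    traits$VA[i] <- mean(an$vessel_areas)
    traits$VAmax[i] <- max_vessel_area(an$vessel_areas)
    traits$Kp[i] <- potential_conductivity(traits$dh[i], traits$VD[i])
    wc <- water_content_max(traits$WD[i], traits$WD0[i])
    traits$WCmax[i] <- wc$WC_max
  }
  traits
}

#' Flag trait values outside their global reference range
#'
#' Checks each present trait value of a record (or each row of a trait
#' table) against the global reference ranges of [trait_reference()].
#' Flags are warnings about plausibility, not rejections: a flagged value is
#' left in the data.
#'
#' @param record a named list, one-row data frame, or full trait table with
#'   (a subset of) the canonical trait columns.
#' @return A data frame with columns `row`, `trait`, `value`, `lower`,
#'   `upper`, one row per out-of-range value; zero rows when nothing is
#'   flagged.
#' @examples
#' validate_trait_ranges(list(WD = 0.63, SLA = 500))
#' @export
validate_trait_ranges <- function(record) {
  ref <- trait_reference()
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  flags <- list()
  for (j in intersect(names(df), ref$trait)) {
    r <- ref[ref$trait == j, ]
    v <- df[[j]]
    bad <- which(is.finite(v) & (v < r$lower | v > r$upper))
    if (length(bad)) {
      flags[[j]] <- data.frame(row = bad, trait = j, value = v[bad],
                               lower = r$lower, upper = r$upper,
                               stringsAsFactors = FALSE)
    }
  }
  if (length(flags) == 0L) {
    return(data.frame(row = integer(), trait = character(),
                      value = numeric(), lower = numeric(),
                      upper = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out[order(out$row, out$trait), , drop = FALSE]
}
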