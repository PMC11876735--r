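#' Radionuclide emission data for sphere dose factors
#'
#' Energy emitted per decay, split into a non-penetrating component (beta
#' particles, conversion and Auger electrons; absorbed locally in a sphere
#' much larger than the electron range) and a penetrating photon component
#' whose absorbed fraction depends on sphere mass.
#'
#' @param delta_nonpenetrating Mean non-penetrating energy per decay
#'   (J/decay), positive.
#' @param delta_penetrating Mean photon energy per decay (J/decay), positive.
#' @param photon_absorbed_fraction Data frame (`mass_g`, `phi`) with the
#'   photon absorbed fraction on a mass grid, phi in [0, 1] and non-decreasing
#'   in mass; may be `NULL` for electron-only tables.
#' @return An object of class `emission_data`.
#' @export
emission_data <- function(delta_nonpenetrating, delta_penetrating = 0,
                          photon_absorbed_fraction = NULL) {
  stopifnot(delta_nonpenetrating > 0, delta_penetrating >= 0)
  if (!is.null(photon_absorbed_fraction)) {
    paf <- photon_absorbed_fraction
    stopifnot(is.data.frame(paf), all(c("mass_g", "phi") %in% names(paf)),
              all(paf$phi >= 0 & paf$phi <= 1),
              !is.unsorted(paf$mass_g, strictly = TRUE))
    if (is.unsorted(paf$phi)) stop("photon absorbed fraction must be non-decreasing in mass")
  }
  structure(
    list(delta_nonpenetrating = delta_nonpenetrating,
         delta_penetrating = delta_penetrating,
         photon_absorbed_fraction = photon_absorbed_fraction),
    class = "emission_data"
  )
}

#' Lu-177 emission data
#'
#' Mean emitted energies per decay of Lu-177: 0.1479 MeV non-penetrating
#' (beta + conversion/Auger electrons) and 0.0345 MeV photons, converted to
#' joules. The photon absorbed fraction versus sphere mass is a synthetic
#' smooth approximation adequate for unit-density spheres at these photon
#' energies (phi is small, <= 0.2 below 1 kg); the electron term dominates
#' sphere doses.
#'
#' @return An [emission_data()] for Lu-177.
#' @export
lu177_emission <- function() {
  mev <- 1.602176634e-13  # J per MeV
  paf <- utils::read.csv(
    system.file("extdata", "lu177_sphere_phi_synthetic.csv",
                package = "prrtdose"),
    stringsAsFactors = FALSE)
  emission_data(delta_nonpenetrating = 0.1479 * mev,
                delta_penetrating = 0.0345 * mev,
                photon_absorbed_fraction = paf)
}

# Interpolate the photon absorbed fraction at a mass (linear in log-mass).
phi_at <- function(emission, mass_g) {
  paf <- emission$photon_absorbed_fraction
  if (is.null(paf)) return(rep(0, length(mass_g)))
  if (any(mass_g < min(paf$mass_g)) || any(mass_g > max(paf$mass_g)))
    stop("mass outside the photon absorbed-fraction grid")
  stats::approx(log(paf$mass_g), paf$phi, xout = log(mass_g))$y
}

#' Build a unit-density-sphere dose factor table
#'
#' Sphere dose factor at mass m:
#' `df(m) = decays_per_MBq_hour * (delta_np + phi_p(m) * delta_p) / m_kg`
#' in Gy/(MBq.h). With photons disabled the factor is exactly proportional
#' to 1/m.
#'
#' @param emission An [emission_data()].
#' @param mass_grid Strictly increasing sphere masses (g), >= 2 points.
#' @param constants [physical_constants()].
#' @return An object of class `sphere_dose_factor_table` with `mass_grid`
#'   and `df`.
#' @export
build_sphere_table <- function(emission, mass_grid = 10^seq(0, 3, by = 0.25),
                               constants = physical_constants()) {
  stopifnot(inherits(emission, "emission_data"), length(mass_grid) >= 2L,
            all(mass_grid > 0))
  if (is.unsorted(mass_grid, strictly = TRUE))
    stop("mass grid must be strictly increasing")
  phi <- phi_at(emission, mass_grid)
  df <- constants$decays_per_MBq_hour *
    (emission$delta_nonpenetrating + phi * emission$delta_penetrating) /
    (mass_grid / 1000)
  if (any(diff(df) >= 0))
    stop("sphere dose factors must be strictly decreasing in mass")
  structure(list(mass_grid = mass_grid, df = df),
            class = "sphere_dose_factor_table")
}

#' Interpolate a sphere dose factor by lesion mass
#'
#' Log-log linear interpolation between bracketing grid points; exact for
#' power-law tables (hence exact in the electron-only limit where
#' `df ~ 1/m`). Queries outside the grid raise by default; power-law
#' extrapolation from the nearest grid segment can be enabled and is flagged
#' with a warning.
#'
#' @param table A [build_sphere_table()] result.
#' @param mass Lesion mass (g), positive; vectorised.
#' @param extrapolate Allow power-law extrapolation outside the grid.
#' @return Dose factor(s) in Gy/(MBq.h).
#' @export
interp_df <- function(table, mass, extrapolate = FALSE) {
  stopifnot(inherits(table, "sphere_dose_factor_table"))
  if (any(mass <= 0)) stop("mass must be positive")
  lo <- min(table$mass_grid); hi <- max(table$mass_grid)
  outside <- mass < lo | mass > hi
  if (any(outside) && !extrapolate)
    stop(sprintf("mass %.4g g outside the dose-factor grid [%.4g, %.4g] g",
                 mass[outside][1], lo, hi))
  if (any(outside))
    warning("power-law extrapolation outside the dose-factor grid")
  exp(stats::approx(log(table$mass_grid), log(table$df), xout = log(mass),
                    rule = 2)$y) *
    ifelse(outside, extrap_factor(table, mass), 1)
}

# Power-law continuation beyond the grid ends using the end segment's slope.
extrap_factor <- function(table, mass) {
  lm_ <- log(table$mass_grid); ld <- log(table$df)
  n <- length(lm_)
  slope_lo <- (ld[2] - ld[1]) / (lm_[2] - lm_[1])
  slope_hi <- (ld[n] - ld[n - 1]) / (lm_[n] - lm_[n - 1])
  out <- rep(1, length(mass))
  below <- mass < exp(lm_[1]); above <- mass > exp(lm_[n])
  out[below] <- exp(slope_lo * (log(mass[below]) - lm_[1]))
  out[above] <- exp(slope_hi * (log(mass[above]) - lm_[n]))
  out
}

#' Lesion absorbed dose for one administration
#'
#' `D = administered [MBq] * tiac [h] * df(mass) [Gy/(MBq.h)]`: cumulated
#' activity in the lesion times the sphere dose factor interpolated at the
#' lesion mass.
#'
#' @param tiac Lesion TIAC (h), >= 0.
#' @param mass Lesion mass (g).
#' @param table A [build_sphere_table()] result.
#' @param administered Administered activity (MBq), positive.
#' @param extrapolate Passed to [interp_df()].
#' @return Absorbed dose in Gy.
#' @export
lesion_dose <- function(tiac, mass, table, administered,
                        extrapolate = FALSE) {
  if (administered <= 0) stop("administered activity must be positive")
  if (any(tiac < 0)) stop("tiac must be non-negative")
  administered * tiac * interp_df(table, mass, extrapolate = extrapolate)
}

#' Cumulative lesion dose over a course
#'
#' Lesion uptake is assumed proportional to mass, giving a constant absorbed
#' dose at every cycle for equal injected activity; the course dose scales
#' the reference-cycle dose by total administered over reference-cycle
#' activity.
#'
#' @param dose_per_admin Dose at the reference cycle (Gy).
#' @param admin An [administration_record()].
#' @param mode `"actual"` (default) uses the administered cycle activities;
#'   `"planned"` uses the planned course activity.
#' @return Cumulative dose in Gy.
#' @export
cumulative_lesion_dose <- function(dose_per_admin, admin,
                                   mode = c("actual", "planned")) {
  mode <- match.arg(mode)
  stopifnot(dose_per_admin >= 0, inherits(admin, "administration_record"))
  ref <- admin$cycle_activities[admin$reference_cycle]
  total <- switch(mode, actual = sum(admin$cycle_activities),
                  planned = admin$planned_course)
  dose_per_admin * total / ref
}

#' Fraction of lesions at or above dose thresholds
#'
#' @param cumulative_doses Numeric vector of lesion doses (Gy), non-empty.
#' @param thresholds Dose thresholds (Gy).
#' @return Data frame with `threshold_Gy`, `n_at_or_above`, `n`, and
#'   `percent` (rounded to one decimal).
#' @export
fractions_at_thresholds <- function(cumulative_doses,
                                    thresholds = c(100, 50)) {
  if (!length(cumulative_doses)) stop("empty dose list")
  n <- length(cumulative_doses)
  k <- vapply(thresholds, function(th) sum(cumulative_doses >= th),
              numeric(1))
  data.frame(threshold_Gy = thresholds, n_at_or_above = as.integer(k), n = n,
             percent = round(100 * k / n, 1))
}
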