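#' Construct an S-value (dose factor) table
#'
#' MIRD-schema dose factors for a reference phantom: absorbed dose to a
#' target region per unit time-integrated activity in a source region, in
#' Gy/(GBq.h) (numerically equal to mGy/(MBq.h)). The table also carries the
#' phantom organ masses needed for the mass-weighted remainder-of-body
#' correction.
#'
#' @param s_values Data frame with columns `target`, `source`,
#'   `s_value_Gy_per_GBq_h` (non-negative). The total body source must be
#'   named `"total body"`.
#' @param organ_masses Named numeric vector or data frame (`organ`, `mass_g`)
#'   of phantom organ masses in grams, including `"total body"`.
#' @param phantom Phantom identifier string.
#' @return An object of class `dose_factor_table`.
#' @export
dose_factor_table <- function(s_values, organ_masses, phantom = "toy") {
  stopifnot(is.data.frame(s_values),
            all(c("target", "source", "s_value_Gy_per_GBq_h") %in%
                  names(s_values)))
  if (any(s_values$s_value_Gy_per_GBq_h < 0))
    stop("S-values must be non-negative")
  if (is.data.frame(organ_masses)) {
    stopifnot(all(c("organ", "mass_g") %in% names(organ_masses)))
    organ_masses <- stats::setNames(organ_masses$mass_g, organ_masses$organ)
  }
  if (!"total body" %in% names(organ_masses))
    stop("organ_masses must include 'total body'")
  if (any(organ_masses <= 0)) stop("organ masses must be positive")
  m_tb <- organ_masses[["total body"]]
  m_org <- organ_masses[setdiff(names(organ_masses), "total body")]
  if (sum(m_org) > m_tb)
    stop("sum of organ masses exceeds total body mass")
  orgs <- unique(c(s_values$target, s_values$source))
  missing_mass <- setdiff(orgs, names(organ_masses))
  if (length(missing_mass))
    stop("organs lacking a mass entry: ", paste(missing_mass, collapse = ", "))
  structure(
    list(phantom = phantom, s_values = s_values, masses = organ_masses),
    class = "dose_factor_table"
  )
}

# Look up S(target <- source); error naming the pair when absent.
s_value <- function(table, target, source) {
  hit <- table$s_values$target == target & table$s_values$source == source
  if (!any(hit))
    stop(sprintf("missing S-value for pair (%s <- %s)", target, source))
  table$s_values$s_value_Gy_per_GBq_h[which(hit)[1]]
}

#' Remainder-of-body TIAC
#'
#' The remainder of body collects total-body activity not assigned to
#' explicit source organs: `tau_RoB = tau_TB - sum(tau_sources)`. A negative
#' remainder signals inconsistent quantification (organ activity exceeding
#' whole-body activity) and raises rather than clipping.
#'
#' @param total_body_tiac Total-body TIAC (h), positive.
#' @param source_tiacs Named numeric vector of explicit source TIACs (h).
#' @return Remainder TIAC in hours.
#' @export
remainder_tiac <- function(total_body_tiac, source_tiacs) {
  stopifnot(total_body_tiac > 0, all(source_tiacs >= 0))
  s <- sum(source_tiacs)
  if (s > total_body_tiac)
    stop(sprintf(
      "source TIACs (%.4g h) exceed total-body TIAC (%.4g h): inconsistent quantification",
      s, total_body_tiac))
  total_body_tiac - s
}

#' Remainder-of-body S-value
#'
#' Mass-weighted correction of the total-body S-value for the activity
#' carried by explicit sources:
#' `S(t <- RoB) = (S(t <- TB) * M_TB - sum_s S(t <- s) * M_s) / M_RoB` with
#' `M_RoB = M_TB - sum_s M_s`. A negative corrected value is floored at 0
#' with a warning.
#'
#' @param table A [dose_factor_table()].
#' @param target Target organ.
#' @param explicit_sources Character vector of explicit source organs
#'   (may be empty, giving `S(t <- TB)` unchanged).
#' @return S-value in Gy/(GBq.h).
#' @export
remainder_s_value <- function(table, target, explicit_sources = character(0)) {
  stopifnot(inherits(table, "dose_factor_table"))
  m_tb <- table$masses[["total body"]]
  if (!length(explicit_sources))
    return(s_value(table, target, "total body"))
  m_s <- vapply(explicit_sources, function(s) table$masses[[s]], numeric(1))
  m_rob <- m_tb - sum(m_s)
  if (m_rob <= 0) stop("remainder mass is non-positive")
  num <- s_value(table, target, "total body") * m_tb -
    sum(vapply(explicit_sources, function(s) s_value(table, target, s),
               numeric(1)) * m_s)
  s_rob <- num / m_rob
  if (s_rob < 0) {
    warning(sprintf("remainder S-value for target '%s' negative; floored at 0",
                    target))
    s_rob <- 0
  }
  s_rob
}

#' Organ absorbed dose per unit administered activity
#'
#' MIRD sum `D/A0 = sum_s tau_s * S(target <- s)` over all source terms.
#' The TIAC vector must include a `"remainder"` term (possibly 0); its
#' S-value is derived with [remainder_s_value()] from the other sources.
#'
#' @param tiacs Named numeric vector of TIACs (h), including `"remainder"`.
#' @param table A [dose_factor_table()].
#' @param target Target organ.
#' @return Dose per unit administered activity, Gy/GBq.
#' @export
organ_dose_per_unit <- function(tiacs, table, target) {
  stopifnot(inherits(table, "dose_factor_table"), all(tiacs >= 0))
  if (!"remainder" %in% names(tiacs))
    stop("tiacs must include a 'remainder' term (use remainder_tiac())")
  explicit <- setdiff(names(tiacs), "remainder")
  d <- sum(vapply(explicit, function(s)
    tiacs[[s]] * s_value(table, target, s), numeric(1)))
  if (tiacs[["remainder"]] > 0)
    d <- d + tiacs[["remainder"]] * remainder_s_value(table, target, explicit)
  d
}

#' Blood-based red-marrow TIAC
#'
#' Marrow cumulated activity from the blood activity concentration curve:
#' `tau_RM = integral(c_blood) [h/kg] * marrow_mass [kg] * ratio`, the
#' standard blood-based model for peptides with no specific marrow binding
#' (marrow-to-blood activity concentration ratio defaulting to 1).
#'
#' @param blood_fit A `kinetic_fit` of blood concentration in fraction of
#'   injected activity per kg.
#' @param marrow_mass Red marrow mass (kg), default 1.17 (adult reference).
#' @param marrow_to_blood_ratio Marrow-to-blood activity concentration ratio.
#' @return Red-marrow TIAC in hours.
#' @export
red_marrow_tiac <- function(blood_fit, marrow_mass = 1.17,
                            marrow_to_blood_ratio = 1.0) {
  if (marrow_mass <= 0) stop("marrow mass must be positive")
  if (marrow_to_blood_ratio < 0) stop("marrow-to-blood ratio must be >= 0")
  tiac_analytic(blood_fit) * marrow_mass * marrow_to_blood_ratio
}

#' Administration record of a treatment course
#'
#' @param cycle_activities Administered activity per cycle (GBq), positive.
#' @param planned_course Planned cumulative activity (GBq); default 29.6
#'   (four 7.4-GBq administrations).
#' @param reference_cycle Index of the cycle at which dosimetry was measured.
#' @return An object of class `administration_record`.
#' @export
administration_record <- function(cycle_activities = rep(7.4, 4),
                                  planned_course = 29.6,
                                  reference_cycle = 1L) {
  stopifnot(all(cycle_activities > 0), planned_course > 0,
            reference_cycle >= 1L,
            reference_cycle <= length(cycle_activities))
  structure(
    list(cycle_activities = as.numeric(cycle_activities),
         planned_course = planned_course,
         reference_cycle = as.integer(reference_cycle)),
    class = "administration_record"
  )
}

#' Project a full-course organ dose
#'
#' @param dose_per_unit Dose per unit activity (Gy/GBq), >= 0.
#' @param admin An [administration_record()].
#' @param mode `"planned"` multiplies by the planned course activity
#'   (e.g. 29.6 GBq); `"actual"` by the sum of administered cycle activities.
#' @return Course dose in Gy.
#' @export
course_dose <- function(dose_per_unit, admin, mode = c("planned", "actual")) {
  mode <- match.arg(mode)
  stopifnot(dose_per_unit >= 0, inherits(admin, "administration_record"))
  ga <- switch(mode, planned = admin$planned_course,
               actual = sum(admin$cycle_activities))
  dose_per_unit * ga
}
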