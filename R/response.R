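#' Percentage tumor size change from baseline (by area)
#'
#' `((T_t / T_bl) - 1) * 100` on lesion areas `L * W`. Positive values are
#' growth, negative values shrinkage.
#'
#' @param area_t Area at the measured time (mm^2).
#' @param area_baseline Baseline area (mm^2), positive.
#' @return Percent change; vectorised over `area_t`.
#' @export
size_change_pct <- function(area_t, area_baseline) {
  if (any(area_baseline <= 0)) stop("baseline area must be positive")
  (area_t / area_baseline - 1) * 100
}

#' Best tumor size change of a lesion
#'
#' The greatest size reduction, or for lesions that never shrank, the lowest
#' increase: the minimum of the per-time-point percent changes.
#'
#' @param changes Numeric vector of post-baseline percent changes, >= 1.
#' @return The best (minimum) percent change.
#' @export
best_change <- function(changes) {
  if (!length(changes)) stop("no post-baseline changes supplied")
  min(changes)
}

#' Percentage size change by single diameter
#'
#' Uses the short axis (W) for lymph-node lesions and the long axis (L)
#' otherwise, with the same percent-change formula as the area statistic.
#'
#' @param L_t,W_t Axes at the measured time (mm).
#' @param L_bl,W_bl Baseline axes (mm), positive.
#' @param is_lymph_node Logical.
#' @return Percent change.
#' @export
diameter_change_pct <- function(L_t, W_t, L_bl, W_bl, is_lymph_node) {
  if (any(L_bl <= 0) || any(W_bl <= 0)) stop("baseline axes must be positive")
  n <- max(length(L_t), length(W_t), length(L_bl), length(W_bl),
           length(is_lymph_node))
  node <- rep_len(is_lymph_node, n)
  d_t <- ifelse(node, rep_len(W_t, n), rep_len(L_t, n))
  d_bl <- ifelse(node, rep_len(W_bl, n), rep_len(L_bl, n))
  (d_t / d_bl - 1) * 100
}

#' Per-lesion response table from a measurement series
#'
#' Computes per-time-point area and diameter changes against the week-0
#' baseline and the per-lesion best change for both statistics.
#'
#' @param measurements Data frame with `lesion_id`, `week`, `L_mm`, `W_mm`,
#'   `is_lymph_node` (as produced by [simulate_lesion_course()]).
#' @return Data frame with one row per lesion: `lesion_id`, `n_timepoints`,
#'   `best_area_change_pct`, `best_diameter_change_pct`.
#' @export
lesion_response_table <- function(measurements) {
  stopifnot(all(c("lesion_id", "week", "L_mm", "W_mm", "is_lymph_node") %in%
                  names(measurements)))
  out <- lapply(split(measurements, measurements$lesion_id), function(d) {
    d <- d[order(d$week), , drop = FALSE]
    if (d$week[1] != 0) stop(sprintf("lesion %s: no baseline measurement",
                                     d$lesion_id[1]))
    if (nrow(d) < 2L) return(NULL)  # needs at least one post-baseline point
    bl <- d[1, ]
    post <- d[-1, , drop = FALSE]
    area <- size_change_pct(post$L_mm * post$W_mm, bl$L_mm * bl$W_mm)
    diam <- diameter_change_pct(post$L_mm, post$W_mm, bl$L_mm, bl$W_mm,
                                bl$is_lymph_node)
    data.frame(lesion_id = d$lesion_id[1], n_timepoints = nrow(d),
               best_area_change_pct = best_change(area),
               best_diameter_change_pct = best_change(diam))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fraction of lesions with tumor shrinkage
#'
#' Shrinkage is a negative best change. Optionally restricted to lesions at
#' or above a cumulative-dose floor. Percent is rounded to the nearest
#' integer.
#'
#' @param best_changes Per-lesion best percent changes.
#' @param cumulative_doses Per-lesion cumulative doses (Gy); required when
#'   `dose_floor` is used.
#' @param dose_floor Restrict to lesions with dose >= this value (Gy), or
#'   `NULL` for all lesions.
#' @return A list with `n_shrinking`, `n`, `percent`.
#' @export
shrinkage_fraction <- function(best_changes, cumulative_doses = NULL,
                               dose_floor = NULL) {
  keep <- rep(TRUE, length(best_changes))
  if (!is.null(dose_floor)) {
    if (is.null(cumulative_doses) ||
        length(cumulative_doses) != length(best_changes))
      stop("cumulative_doses must accompany dose_floor")
    keep <- cumulative_doses >= dose_floor
  }
  bc <- best_changes[keep]
  if (!length(bc)) stop("no lesions left after dose filtering")
  n_shrink <- sum(bc < 0)
  list(n_shrinking = as.integer(n_shrink), n = length(bc),
       percent = round(100 * n_shrink / length(bc)))
}

#' Dose-response association (rank correlation)
#'
#' Spearman rank correlation (ties mid-ranked) between cumulative absorbed
#' dose and best percent size change, with a two-sided p-value from the
#' t approximation. The underlying study question is whether higher lesion
#' doses produce larger shrinkage; a scatter-ready table is returned for
#' plotting.
#'
#' @param cumulative_doses Lesion cumulative doses (Gy), >= 3 values.
#' @param best_changes Matching best percent changes.
#' @return A list with `rho`, `p_value`, `n`, `undefined` (TRUE when either
#'   vector is constant) and `table` (dose, best_change).
#' @export
dose_response_association <- function(cumulative_doses, best_changes) {
  stopifnot(length(cumulative_doses) == length(best_changes))
  if (length(cumulative_doses) < 3L) stop("at least 3 pairs are required")
  tab <- data.frame(cumulative_dose_Gy = cumulative_doses,
                    best_change_pct = best_changes)
  if (stats::sd(cumulative_doses) == 0 || stats::sd(best_changes) == 0)
    return(list(rho = NA_real_, p_value = NA_real_,
                n = length(best_changes), undefined = TRUE, table = tab))
  ct <- suppressWarnings(
    stats::cor.test(cumulative_doses, best_changes, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(best_changes), undefined = FALSE, table = tab)
}

#' Renal function decline rate
#'
#' Least-squares slope of percent change from baseline creatinine clearance
#' versus years; flagged when the slope is at or below the renal-impairment
#' threshold (default -20% per year).
#'
#' @param years Times in years, >= 2 points, first point is baseline.
#' @param crcl Creatinine clearance values; baseline (first) must be > 0.
#' @param threshold Flagging threshold in percent per year (default -20).
#' @return A list with `slope_pct_per_year`, `flag`.
#' @export
renal_decline_rate <- function(years, crcl, threshold = -20) {
  stopifnot(length(years) == length(crcl), length(years) >= 2L)
  if (crcl[1] <= 0) stop("baseline clearance must be positive")
  pct <- (crcl / crcl[1] - 1) * 100
  slope <- unname(stats::coef(stats::lm(pct ~ years))[2])
  # tolerance keeps an exactly-threshold slope flagged despite rounding in
  # the least-squares solve
  list(slope_pct_per_year = slope,
       flag = slope <= threshold + 1e-9 * abs(threshold))
}

#' Toxicity thresholds
#'
#' Conservative organ-at-risk course-dose thresholds: 23 Gy to the kidneys
#' and 2 Gy to the red marrow, plus the renal decline limit of -20% per year.
#'
#' @param kidney_course_Gy,marrow_course_Gy Positive course-dose thresholds.
#' @param renal_decline_pct_per_year Renal decline threshold.
#' @return An object of class `toxicity_thresholds`.
#' @export
toxicity_thresholds <- function(kidney_course_Gy = 23, marrow_course_Gy = 2,
                                renal_decline_pct_per_year = -20) {
  stopifnot(kidney_course_Gy > 0, marrow_course_Gy > 0)
  structure(list(kidney_course_Gy = kidney_course_Gy,
                 marrow_course_Gy = marrow_course_Gy,
                 renal_decline_pct_per_year = renal_decline_pct_per_year),
            class = "toxicity_thresholds")
}

#' Organ-at-risk threshold flags
#'
#' Strict-inequality flags against the toxicity thresholds: kidney course
#' dose > 23 Gy, marrow course dose > 2 Gy (defaults).
#'
#' @param kidney_dose_Gy,marrow_dose_Gy Course doses (Gy), >= 0.
#' @param thresholds A [toxicity_thresholds()].
#' @return A list with logical `kidney_flag` and `marrow_flag` (vectorised).
#' @export
threshold_flags <- function(kidney_dose_Gy, marrow_dose_Gy,
                            thresholds = toxicity_thresholds()) {
  stopifnot(all(kidney_dose_Gy >= 0), all(marrow_dose_Gy >= 0))
  list(kidney_flag = kidney_dose_Gy > thresholds$kidney_course_Gy,
       marrow_flag = marrow_dose_Gy > thresholds$marrow_course_Gy)
}

#' Incidence proportion
#'
#' @param events Event count, `0 <= events <= n`.
#' @param n Denominator, positive.
#' @return Percent to one decimal.
#' @export
incidence_proportion <- function(events, n) {
  if (n <= 0) stop("n must be positive")
  stopifnot(events >= 0, events <= n)
  round(100 * events / n, 1)
}

#' Cohort summary statistics
#'
#' Sample mean, sample SD (n - 1 denominator), median, min and max, the
#' summary layout used for per-organ cohort dose tables.
#'
#' @param values Numeric vector, >= 1 value.
#' @return A list with `mean`, `sd`, `median`, `min`, `max`, `n`,
#'   `degenerate` (TRUE for a single value, where SD is reported as 0).
#' @export
summarize_cohort <- function(values) {
  if (!length(values)) stop("no values to summarise")
  degenerate <- length(values) == 1L
  list(mean = mean(values),
       sd = if (degenerate) 0 else stats::sd(values),
       median = stats::median(values),
       min = min(values), max = max(values),
       n = length(values), degenerate = degenerate)
}

#' Cohort summary table for several metrics
#'
#' @param metrics Named list of numeric vectors.
#' @return Data frame with one row per metric: mean, sd, median, min, max, n.
#' @export
cohort_summary_table <- function(metrics) {
  stopifnot(is.list(metrics), length(metrics) >= 1L, !is.null(names(metrics)))
  rows <- lapply(names(metrics), function(nm) {
    s <- summarize_cohort(metrics[[nm]])
    data.frame(metric = nm, mean = s$mean, sd = s$sd, median = s$median,
               min = s$min, max = s$max, n = s$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
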