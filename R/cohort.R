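#' Simulate a dosimetry study cohort
#'
#' Generates a full synthetic cohort with known ground truth, structured like
#' a planar-dosimetry substudy of a four-cycle 7.4-GBq Lu-177 DOTATATE
#' course:
#' \itemize{
#'   \item 20 patients with evaluable organ dosimetry, imaged at 4 (3
#'     patients), 5 (14) or 6 (3) time points within 7 days; a subset of
#'     kidneys shows an uptake phase peaking near 24 h; terminal effective
#'     half-lives are drawn inside 21-161 h; each patient has a biexponential
#'     blood clearance curve and an administration record (15 patients
#'     complete 4 cycles, 3 stop after 3, 1 after 2, 1 after 1).
#'   \item 65 target lesions in 17 of the patients (masses ~1-1000 g,
#'     locations liver/lymph node/bone/other), with ground-truth TIACs chosen
#'     so that cumulative doses fall in three strata: 34 lesions >= 100 Gy,
#'     14 in [50, 100) Gy and 17 below 50 Gy.
#'   \item 52 of the lesions carry CT size courses over 72 weeks (38 from the
#'     >= 50 Gy strata, 14 from the low-dose stratum); 35 of the 38 and 12 of
#'     the 14 shrink (plateau area shrinkage 10-56.5%), the rest grow.
#'   \item per-patient creatinine clearance series over 5 years with known
#'     decline slopes.
#' }
#' All draws derive from the single `seed` via named substreams, so the
#' cohort is fully reproducible.
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients with organ dosimetry.
#' @param lesion_strata Integer vector `c(ge100, ge50lt100, lt50)` lesion
#'   counts per cumulative-dose stratum.
#' @param measured_per_stratum Integer vector `c(high, low)`: lesions with CT
#'   courses among the >= 50 Gy strata and the < 50 Gy stratum.
#' @param shrinking_per_stratum Integer vector `c(high, low)`: how many of
#'   the measured lesions in each group shrink.
#' @param sphere_table Sphere dose-factor table used to translate target
#'   doses into ground-truth lesion TIACs; defaults to the Lu-177 table.
#' @return An object of class `synthetic_cohort`: list with `patients` (each
#'   with `phantom`, `scan_times`, `scan_duration`, `admin`, `blood_times`,
#'   `renal`), `lesions` (data frame incl. ground-truth TIAC and dose),
#'   `lesion_courses` (CT measurement long table) and `seed`.
#' @export
simulate_cohort <- function(seed = 1L,
                            n_patients = 20L,
                            lesion_strata = c(34L, 14L, 17L),
                            measured_per_stratum = c(38L, 14L),
                            shrinking_per_stratum = c(35L, 12L),
                            sphere_table = build_sphere_table(lu177_emission())) {
  stopifnot(n_patients >= 1L, length(lesion_strata) == 3L,
            measured_per_stratum[1] <= sum(lesion_strata[1:2]),
            measured_per_stratum[2] <= lesion_strata[3],
            all(shrinking_per_stratum <= measured_per_stratum))
  patients <- with_substream(seed, "patients",
                             make_patients(seed, n_patients))
  lesions <- with_substream(seed, "lesions",
                            make_lesions(seed, n_patients, lesion_strata,
                                         measured_per_stratum,
                                         shrinking_per_stratum, sphere_table))
  courses <- make_lesion_courses(lesions, seed)
  structure(list(patients = patients, lesions = lesions,
                 lesion_courses = courses, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# Patient-level phantoms, scan schedules, blood curves, administrations and
# renal follow-up. Runs inside the "patients" substream.
make_patients <- function(seed, n_patients) {
  # scan schedules: 4, 5 or 6 time points; last point at 3 d for some
  # patients and 6-7 d for the rest
  n4 <- max(round(n_patients * 3 / 20), 1L)
  n6 <- max(round(n_patients * 3 / 20), 1L)
  n5 <- n_patients - n4 - n6
  npts <- sample(c(rep(4L, n4), rep(5L, n5), rep(6L, n6)))
  # cycles received: most complete 4
  cyc_pool <- c(rep(4L, n_patients - 5L), 4L, 3L, 3L, 3L, 2L, 1L)[1:n_patients]
  cycles <- sample(cyc_pool)

  lapply(seq_len(n_patients), function(i) {
    uptake <- stats::runif(1) < 0.3
    t_term <- stats::runif(1, 30, 150)          # h, inside 21-161
    l_term <- log(2) / t_term
    l_fast <- log(2) / stats::runif(1, 2, 15)

    a_kid <- stats::runif(1, 0.01, 0.05)
    kid <- if (uptake) {
      l_up <- log(2) / stats::runif(1, 6, 12)   # uptake peaks near 24-35 h
      phantom_organ("kidneys", c(a_kid, -a_kid * stats::runif(1, 0.5, 0.9)),
                    c(l_term, l_up), mass = 310,
                    footprint = c(34L, 41L, 26L, 33L), depth = 13)
    } else {
      phantom_organ("kidneys", a_kid * c(0.35, 0.65),
                    c(l_fast, l_term), mass = 310,
                    footprint = c(34L, 41L, 26L, 33L), depth = 13)
    }
    a_liv <- stats::runif(1, 0.04, 0.16)
    liv <- phantom_organ("liver", a_liv * c(0.3, 0.7),
                         c(log(2) / stats::runif(1, 5, 20),
                           log(2) / stats::runif(1, 60, 155)),
                         mass = 1800, footprint = c(14L, 27L, 36L, 49L),
                         depth = 8)
    a_spl <- stats::runif(1, 0.01, 0.05)
    spl <- phantom_organ("spleen", a_spl * c(0.3, 0.7),
                         c(log(2) / stats::runif(1, 5, 20),
                           log(2) / stats::runif(1, 60, 155)),
                         mass = 180, footprint = c(14L, 21L, 12L, 19L),
                         depth = 9)

    blood_a <- c(stats::runif(1, 0.010, 0.020), stats::runif(1, 0.004, 0.010))
    blood_l <- c(stats::runif(1, 0.25, 0.45),
                 log(2) / stats::runif(1, 40, 120))

    times <- switch(as.character(npts[i]),
                    "4" = c(2, 24, 48, 72),
                    "5" = if (i %% 2 == 0) c(2, 16, 24, 48, 72)
                          else c(2, 24, 48, 96, 168),
                    "6" = c(2, 24, 48, 96, 120, 168))

    phant <- phantom_spec(
      organs = list(kid, liv, spl),
      body_thickness = stats::runif(1, 18, 24),
      camera_sensitivity = 10,
      injected_activity = 7400,
      background_fraction = 0.7,
      background_rates = c(stats::runif(1, 0.1, 0.2),
                           log(2) / stats::runif(1, 70, 130)),
      blood_amplitudes = blood_a, blood_rates = blood_l,
      image_dim = c(64L, 64L),
      seed = substream_seed(seed, paste0("patient/", i)))

    renal_years <- 0:5
    renal_slope <- stats::runif(1, -15, 2)  # true %/y, above the -20 limit
    crcl0 <- stats::runif(1, 70, 120)
    crcl <- crcl0 * (1 + renal_slope / 100 * renal_years) *
      (1 + pmin(pmax(stats::rnorm(length(renal_years), 0, 0.02), -0.06), 0.06))
    crcl[1] <- crcl0

    list(id = sprintf("P%02d", i),
         phantom = phant,
         scan_times = times,
         scan_duration = 120,
         admin = administration_record(rep(7.4, cycles[i]),
                                       reference_cycle = 1L),
         blood_times = c(0.5, 2, 6, 24, 48, 96),
         renal = data.frame(years = renal_years, crcl = crcl,
                            true_slope = renal_slope))
  })
}

# Lesion table with ground-truth TIACs backed out of target cumulative doses
# through the sphere dose-factor table. Runs inside the "lesions" substream.
make_lesions <- function(seed, n_patients, strata, measured, shrinking,
                         sphere_table) {
  n_total <- sum(strata)
  # cumulative doses (4 planned 7.4-GBq cycles): lognormal-ish inside strata,
  # kept clear of the 50/100 Gy boundaries so downstream classification is
  # unambiguous under floating-point round trips
  d_hi <- exp(stats::runif(strata[1], log(110), log(2200)))
  d_mid <- stats::runif(strata[2], 55, 95)
  d_lo <- exp(stats::runif(strata[3], log(7), log(45)))
  doses <- c(d_hi, d_mid, d_lo)
  stratum <- rep(c("ge100", "ge50lt100", "lt50"), strata)

  loc <- sample(c(rep("liver", 33), rep("lymph node", 16), rep("bone", 2),
                  rep("other", 14))[seq_len(n_total)])
  mass <- pmin(pmax(stats::rlnorm(n_total, log(25), 1.2), 1.05), 990)

  # lesion dosimetry patients: 17 of the cohort (or fewer for tiny cohorts)
  n_lp <- min(17L, n_patients)
  patient <- sprintf("P%02d", sample(seq_len(n_patients), n_total,
                                     replace = TRUE) %% n_lp + 1L)

  # constant-uptake assumption: dose identical at each of the 4 planned
  # cycles, so the per-admin dose is a quarter of the cumulative dose
  df <- interp_df(sphere_table, mass)
  tiac <- (doses / 4) / (7400 * df)

  # CT-measured subset and shrinkage assignment
  hi_idx <- which(stratum != "lt50")
  lo_idx <- which(stratum == "lt50")
  meas_hi <- sample(hi_idx, measured[1])
  meas_lo <- sample(lo_idx, measured[2])
  is_meas <- seq_len(n_total) %in% c(meas_hi, meas_lo)
  shrink <- rep(NA_real_, n_total)
  sh_hi <- sample(meas_hi, shrinking[1])
  sh_lo <- sample(meas_lo, shrinking[2])
  grow <- setdiff(c(meas_hi, meas_lo), c(sh_hi, sh_lo))
  shrink[c(sh_hi, sh_lo)] <- stats::runif(shrinking[1] + shrinking[2],
                                          0.10, 0.565)
  shrink[grow] <- -stats::runif(length(grow), 0.08, 0.30)

  bl_W <- stats::runif(n_total, 8, 40)
  bl_L <- bl_W * stats::runif(n_total, 1.0, 1.8)

  data.frame(
    lesion_id = sprintf("L%03d", seq_len(n_total)),
    patient = patient, location_class = loc, mass_g = mass,
    tiac_h = tiac, dose_per_admin_Gy = doses / 4,
    cumulative_dose_Gy = doses, dose_stratum = stratum,
    measured = is_meas, shrinkage = shrink,
    baseline_L_mm = bl_L, baseline_W_mm = bl_W,
    n_followup = with_substream(seed, "lesions/followup",
                                sample(1:6, n_total, replace = TRUE)),
    row.names = NULL)
}

# CT courses for all measured lesions.
make_lesion_courses <- function(lesions, seed) {
  meas <- lesions[lesions$measured, , drop = FALSE]
  rows <- lapply(seq_len(nrow(meas)), function(i) {
    r <- meas[i, ]
    les <- phantom_lesion(r$lesion_id, mass = r$mass_g,
                          amplitudes = 1e-3, effective_rates = 0.005,
                          location_class = r$location_class,
                          baseline_L = r$baseline_L_mm,
                          baseline_W = r$baseline_W_mm,
                          shrinkage = r$shrinkage, shrink_tau = 4)
    simulate_lesion_course(les, weeks = seq(0, 12 * r$n_followup, by = 12),
                           seed = seed)
  })
  do.call(rbind, rows)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic dosimetry cohort (seed %d)\n  %d patients with organ dosimetry\n  %d lesions (%d with CT follow-up)\n",
    x$seed, length(x$patients), nrow(x$lesions), sum(x$lesions$measured)))
  invisible(x)
}
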