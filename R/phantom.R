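#' Define a phantom source organ
#'
#' A source organ in the slab-body phantom is a sum-of-exponentials
#' time-activity curve (fractions of injected activity) attached to a
#' rectangular pixel footprint at a given depth below the anterior body
#' surface. An uptake phase (e.g. kidneys filling over the first day) is
#' expressed as one negative amplitude term.
#'
#' @param name Organ identifier (e.g. `"kidneys"`).
#' @param amplitudes Numeric vector, fractions of injected activity; at most
#'   one term may be negative (uptake phase) and the sum must lie in [0, 1].
#' @param effective_rates Positive effective clearance rates (1/h), one per
#'   amplitude; effective = biological + physical decay.
#' @param mass Organ mass in grams.
#' @param footprint Integer vector `c(row1, row2, col1, col2)`: the inclusive
#'   pixel rectangle the organ projects onto.
#' @param depth Depth of the organ centre below the anterior surface (cm).
#' @return An object of class `phantom_organ`.
#' @export
phantom_organ <- function(name, amplitudes, effective_rates, mass,
                          footprint, depth) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  amplitudes <- as.numeric(amplitudes)
  effective_rates <- as.numeric(effective_rates)
  if (length(amplitudes) != length(effective_rates))
    stop("amplitudes and effective_rates must have equal length")
  if (any(effective_rates <= 0)) stop("effective rates must be positive")
  s <- sum(amplitudes)
  if (s < 0 || s > 1)
    stop("sum of amplitudes must lie in [0, 1] (fraction of injected activity)")
  # non-negativity of A(t) checked on a dense grid out to ~10 terminal
  # half-lives
  tgrid <- seq(0, 10 * log(2) / min(effective_rates), length.out = 512L)
  a_grid <- vapply(tgrid, function(t) sum(amplitudes * exp(-effective_rates * t)),
                   numeric(1))
  if (any(a_grid < -1e-12))
    stop(sprintf("organ '%s': activity curve goes negative", name))
  stopifnot(is.numeric(mass), mass > 0, is.numeric(depth), depth >= 0)
  footprint <- as.integer(footprint)
  if (length(footprint) != 4L || footprint[1] > footprint[2] ||
      footprint[3] > footprint[4] || any(footprint < 1L))
    stop("footprint must be c(row1, row2, col1, col2) with row1<=row2, col1<=col2")
  structure(
    list(name = name, amplitudes = amplitudes,
         effective_rates = effective_rates, mass = mass,
         footprint = footprint, depth = depth),
    class = "phantom_organ"
  )
}

#' Define a phantom lesion
#'
#' Lesions carry kinetics like organs (for dosimetry) plus baseline CT axes
#' and a shrinkage model for the 72-week follow-up course. Shrinkage `s` is
#' defined on lesion AREA: at plateau the area L*W has changed by `-100*s`
#' percent (both axes are scaled by `sqrt(1 - s)`), so the area-based
#' size-change statistic reaches `-s` directly. `s <= 0` models growth.
#'
#' @param id Lesion identifier.
#' @param mass Lesion mass (g), unit density assumed.
#' @param amplitudes,effective_rates Kinetic terms as fractions of injected
#'   activity, rates in 1/h.
#' @param location_class One of `"liver"`, `"lymph node"`, `"bone"`, `"other"`.
#' @param baseline_L,baseline_W Baseline longest and perpendicular diameters
#'   (mm), `baseline_L >= baseline_W > 0`.
#' @param shrinkage Plateau area shrinkage `s` in (-Inf, 1); 0.3 means the
#'   lesion area settles 30% below baseline.
#' @param shrink_tau Time constant of the shrinkage course (weeks).
#' @return An object of class `phantom_lesion`.
#' @export
phantom_lesion <- function(id, mass, amplitudes, effective_rates,
                           location_class = c("liver", "lymph node", "bone",
                                              "other"),
                           baseline_L = 30, baseline_W = 20,
                           shrinkage = 0, shrink_tau = 4) {
  location_class <- match.arg(location_class)
  stopifnot(mass > 0, baseline_L > 0, baseline_W > 0,
            baseline_L >= baseline_W, shrinkage < 1, shrink_tau > 0)
  amplitudes <- as.numeric(amplitudes)
  effective_rates <- as.numeric(effective_rates)
  stopifnot(length(amplitudes) == length(effective_rates),
            all(effective_rates > 0))
  structure(
    list(id = as.character(id), mass = mass, amplitudes = amplitudes,
         effective_rates = effective_rates, location_class = location_class,
         baseline_L = baseline_L, baseline_W = baseline_W,
         shrinkage = shrinkage, shrink_tau = shrink_tau),
    class = "phantom_lesion"
  )
}

#' Assemble a slab-body phantom
#'
#' The phantom is a uniform slab of tissue of fixed thickness viewed by an
#' ideal anterior/posterior camera pair: each organ's counts are attenuated
#' by `exp(-mu * depth)` (anterior) or `exp(-mu * (thickness - depth))`
#' (posterior), the standard conjugate-view geometry. A spatially uniform
#' soft-tissue background (equal in both views) models non-source activity.
#'
#' @param organs List of [phantom_organ()] objects; footprints must fit the
#'   frame and may not overlap.
#' @param lesions Optional list of [phantom_lesion()] objects.
#' @param body_thickness Slab thickness (cm).
#' @param attenuation_coefficient Effective linear attenuation coefficient at
#'   208 keV (1/cm); default 0.136 for soft tissue.
#' @param camera_sensitivity Counts per MBq.s.
#' @param injected_activity Injected activity (MBq); default 7400 (7.4 GBq).
#' @param background_fraction Fraction of injected activity initially in the
#'   uniform soft-tissue/blood-pool background compartment, in [0, 1); the
#'   compartment clears biexponentially (`background_weights`,
#'   `background_rates`) and is rendered at mid-slab depth. Together with the
#'   organs it makes up the phantom's whole-body retention.
#' @param background_weights,background_rates Shape of the background
#'   clearance: non-negative weights summing to 1 and positive rates (1/h).
#' @param blood_amplitudes,blood_rates Biexponential blood concentration
#'   model, fraction of injected activity per kg and 1/h.
#' @param blood_noise_cv Lognormal coefficient of variation of blood sample
#'   measurements when noise is enabled.
#' @param image_dim Frame size `c(nrow, ncol)` in pixels.
#' @param seed Integer seed driving all stochastic draws of this phantom via
#'   named substreams.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(organs, lesions = list(),
                         body_thickness = 20,
                         attenuation_coefficient = 0.136,
                         camera_sensitivity = 10,
                         injected_activity = 7400,
                         background_fraction = 0.7,
                         background_weights = c(0.4, 0.6),
                         background_rates = c(0.15, 0.007),
                         blood_amplitudes = c(0.014, 0.006),
                         blood_rates = c(0.35, 0.012),
                         blood_noise_cv = 0.05,
                         image_dim = c(64L, 64L),
                         seed = 1L) {
  stopifnot(length(organs) >= 1L,
            all(vapply(organs, inherits, logical(1), "phantom_organ")),
            all(vapply(lesions, inherits, logical(1), "phantom_lesion")),
            body_thickness > 0, attenuation_coefficient > 0,
            camera_sensitivity > 0, injected_activity > 0,
            background_fraction >= 0, background_fraction < 1,
            length(background_weights) == length(background_rates),
            all(background_weights >= 0), all(background_rates > 0),
            abs(sum(background_weights) - 1) < 1e-9,
            length(blood_amplitudes) == length(blood_rates),
            all(blood_rates > 0), blood_noise_cv >= 0)
  image_dim <- as.integer(image_dim)
  stopifnot(length(image_dim) == 2L, all(image_dim >= 2L))
  occ <- matrix(FALSE, image_dim[1], image_dim[2])
  for (og in organs) {
    fp <- og$footprint
    if (fp[2] > image_dim[1] || fp[4] > image_dim[2])
      stop(sprintf("organ '%s': footprint outside the image frame", og$name))
    block <- occ[fp[1]:fp[2], fp[3]:fp[4]]
    if (any(block))
      stop(sprintf("organ '%s': footprint overlaps another organ", og$name))
    occ[fp[1]:fp[2], fp[3]:fp[4]] <- TRUE
    if (og$depth > body_thickness)
      stop(sprintf("organ '%s': depth exceeds body thickness", og$name))
  }
  nm <- vapply(organs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate organ names")
  names(organs) <- nm
  a0 <- sum(vapply(organs, function(o) sum(o$amplitudes), numeric(1)))
  if (a0 + background_fraction > 1 + 1e-9)
    stop("initial organ + background fractions exceed the injected activity")
  if (length(lesions))
    names(lesions) <- vapply(lesions, `[[`, character(1), "id")
  structure(
    list(organs = organs, lesions = lesions,
         body_thickness = body_thickness,
         attenuation_coefficient = attenuation_coefficient,
         camera_sensitivity = camera_sensitivity,
         injected_activity = injected_activity,
         background_fraction = background_fraction,
         background_weights = as.numeric(background_weights),
         background_rates = as.numeric(background_rates),
         blood_amplitudes = as.numeric(blood_amplitudes),
         blood_rates = as.numeric(blood_rates),
         blood_noise_cv = blood_noise_cv,
         image_dim = image_dim, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' True organ activity at a time point
#'
#' Evaluates the ground-truth sum-of-exponentials curve
#' `A(t) = A0 * sum(a_i * exp(-lambda_i * t))`.
#'
#' @param organ A [phantom_organ()] (or [phantom_lesion()]).
#' @param t Time post injection (h), non-negative; vectorised.
#' @param A0 Injected activity (MBq).
#' @return Activity in MBq, same length as `t`.
#' @examples
#' k <- phantom_organ("kidneys", 0.02, 0.01, 300, c(1, 4, 1, 4), 7)
#' true_activity(k, c(0, 24, 168), A0 = 7400)
#' @export
true_activity <- function(organ, t, A0) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(A0 > 0)
  vapply(t, function(ti)
    A0 * sum(organ$amplitudes * exp(-organ$effective_rates * ti)),
    numeric(1))
}

# Analytic ground-truth TIAC (h) of a sum-of-exponentials source:
# integral over [0, Inf) of the fraction-of-IA curve = sum(a_i / lambda_i).
true_tiac <- function(organ) sum(organ$amplitudes / organ$effective_rates)

# Background compartment activity (MBq) at time t.
background_activity <- function(spec, t) {
  spec$injected_activity * spec$background_fraction *
    sum(spec$background_weights * exp(-spec$background_rates * t))
}

# Ground-truth whole-body fraction of injected activity and TIAC: organs
# plus the background compartment.
true_wholebody_fraction <- function(spec, t) {
  orgs <- sum(vapply(spec$organs, true_activity, numeric(1), t = t, A0 = 1))
  orgs + background_activity(spec, t) / spec$injected_activity
}

true_wholebody_tiac <- function(spec) {
  sum(vapply(spec$organs, true_tiac, numeric(1))) +
    spec$background_fraction *
      sum(spec$background_weights / spec$background_rates)
}

# Expected (noise-free) count matrices for one view.
# view = +1 anterior, -1 posterior.
expected_view <- function(spec, t, duration, view) {
  mu <- spec$attenuation_coefficient
  thick <- spec$body_thickness
  k <- spec$camera_sensitivity * duration
  img <- matrix(0, spec$image_dim[1], spec$image_dim[2])
  for (og in spec$organs) {
    a <- true_activity(og, t, spec$injected_activity)
    d <- if (view > 0) og$depth else thick - og$depth
    fp <- og$footprint
    npx <- (fp[2] - fp[1] + 1L) * (fp[4] - fp[3] + 1L)
    img[fp[1]:fp[2], fp[3]:fp[4]] <-
      img[fp[1]:fp[2], fp[3]:fp[4]] + k * a * exp(-mu * d) / npx
  }
  # uniform background at mid-slab depth, identical in the two views
  bg_total <- k * background_activity(spec, t) * exp(-mu * thick / 2)
  img + bg_total / length(img)
}

#' Render one anterior/posterior planar image pair
#'
#' Forward-projects the phantom at time `t` into expected anterior and
#' posterior count matrices and (optionally) draws Poisson counts,
#' reproducibly under the phantom seed. The ground truth (true activities and
#' analytic TIACs per organ) is returned alongside so downstream stages can
#' be validated.
#'
#' @param spec A [phantom_spec()].
#' @param t Time post injection (h).
#' @param duration Acquisition duration (s), positive.
#' @param noise Draw Poisson counts (`TRUE`, default) or return expected
#'   counts (`FALSE`).
#' @return A list with `anterior` and `posterior` count matrices, `time_h`,
#'   `duration_s`, `sensitivity`, and `truth`, a data frame of per-organ true
#'   activity (MBq), fraction of injected activity and analytic TIAC (h).
#' @export
render_planar_pair <- function(spec, t, duration, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (t < 0) stop("t must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  ant <- expected_view(spec, t, duration, +1)
  post <- expected_view(spec, t, duration, -1)
  if (noise) {
    stream <- sprintf("planar/t=%.6g/dur=%.6g", t, duration)
    drawn <- with_substream(spec$seed, stream, {
      a <- matrix(stats::rpois(length(ant), ant), nrow(ant))
      p <- matrix(stats::rpois(length(post), post), nrow(post))
      list(a, p)
    })
    ant <- drawn[[1]]; post <- drawn[[2]]
  }
  truth <- data.frame(
    source = vapply(spec$organs, `[[`, character(1), "name"),
    time_h = t,
    true_activity_MBq = vapply(spec$organs, true_activity, numeric(1),
                               t = t, A0 = spec$injected_activity),
    row.names = NULL
  )
  truth$true_fraction_ia <- truth$true_activity_MBq / spec$injected_activity
  truth$true_tiac_h <- vapply(spec$organs, true_tiac, numeric(1))
  list(anterior = ant, posterior = post, time_h = t, duration_s = duration,
       sensitivity = spec$camera_sensitivity, truth = truth)
}

#' Sample the phantom's blood activity concentration
#'
#' The blood curve is biexponential in fraction of injected activity per kg.
#' With noise enabled each sample is multiplied by a lognormal error with
#' coefficient of variation `spec$blood_noise_cv`, seeded from the phantom
#' seed ("blood" substream) so repeated calls return identical series.
#'
#' @param spec A [phantom_spec()].
#' @param times Sampling times (h), non-negative and strictly increasing.
#' @param noise Apply measurement noise (default `TRUE`).
#' @return Data frame with `time_h` and `conc_frac_ia_per_kg`.
#' @export
sample_blood <- function(spec, times, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(times) == 0L) stop("times must be non-empty")
  if (any(times < 0)) stop("times must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  conc <- vapply(times, function(ti)
    sum(spec$blood_amplitudes * exp(-spec$blood_rates * ti)), numeric(1))
  if (noise && spec$blood_noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$blood_noise_cv^2))
    eps <- with_substream(spec$seed, "blood",
                          stats::rlnorm(length(times), -sdlog^2 / 2, sdlog))
    conc <- conc * eps
  }
  data.frame(time_h = times, conc_frac_ia_per_kg = conc)
}

#' Simulate a lesion's CT size course
#'
#' Axis diameters follow
#' `L(t) = L0 * sqrt(1 - s * (1 - exp(-t / tau)))` (same for W), so lesion
#' AREA settles at `(1 - s)` times baseline: the plateau area change is
#' `-100 * s` percent by construction. Measurement jitter is a symmetric
#' multiplicative error on each axis, clamped at 3 relative SD, so the sign
#' of a plateau change larger than the jitter bound is preserved.
#'
#' @param lesion A [phantom_lesion()].
#' @param weeks Measurement weeks, a subset of `{0, 12, 24, 36, 48, 60, 72}`
#'   including 0 (baseline).
#' @param noise Apply measurement jitter (default `TRUE`).
#' @param axis_cv Relative SD of the per-axis measurement error.
#' @param seed Integer seed (substream per lesion id).
#' @return Data frame with `lesion_id`, `week`, `L_mm`, `W_mm`,
#'   `is_lymph_node`.
#' @export
simulate_lesion_course <- function(lesion, weeks = seq(0, 72, by = 12),
                                   noise = TRUE, axis_cv = 0.01, seed = 1L) {
  stopifnot(inherits(lesion, "phantom_lesion"))
  if (!all(weeks %in% seq(0, 72, by = 12)))
    stop("weeks must be a subset of {0, 12, ..., 72}")
  if (!0 %in% weeks) stop("weeks must include the baseline week 0")
  if (lesion$baseline_L <= 0 || lesion$baseline_W <= 0)
    stop("baseline axes must be positive")
  weeks <- sort(unique(weeks))
  area_factor <- 1 - lesion$shrinkage * (1 - exp(-weeks / lesion$shrink_tau))
  g <- sqrt(area_factor)
  L <- lesion$baseline_L * g
  W <- lesion$baseline_W * g
  if (noise && axis_cv > 0) {
    eps <- with_substream(seed, paste0("lesion/", lesion$id), {
      e <- stats::rnorm(2L * length(weeks), 0, axis_cv)
      pmin(pmax(e, -3 * axis_cv), 3 * axis_cv)
    })
    n <- length(weeks)
    # baseline (week 0) is left noise-free: changes are relative to it
    post <- weeks > 0
    L[post] <- L[post] * (1 + eps[seq_len(n)][post])
    W[post] <- W[post] * (1 + eps[n + seq_len(n)][post])
  }
  data.frame(lesion_id = lesion$id, week = weeks, L_mm = L, W_mm = W,
             is_lymph_node = lesion$location_class == "lymph node",
             row.names = NULL)
}
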