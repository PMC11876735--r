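test_that("true_activity follows the sum-of-exponentials ground truth", {
  lu <- physical_constants()
  og <- phantom_organ("kidneys", 1.0, lu$decay_constant, 300,
                      c(1L, 4L, 1L, 4L), 5)
  # one physical half-life halves the activity
  expect_equal(true_activity(og, 159.53, A0 = 100), 50, tolerance = 1e-12)
  # t = 0 returns the injected activity
  expect_equal(true_activity(og, 0, A0 = 7400), 7400)

  up <- phantom_organ("kidneys", c(0.06, -0.02), c(0.004, 0.08), 300,
                      c(1L, 4L, 1L, 4L), 5)
  expected <- 1000 * (0.06 * exp(-0.004 * 24) - 0.02 * exp(-0.08 * 24))
  expect_equal(true_activity(up, 24, A0 = 1000), expected, tolerance = 1e-12)
  expect_error(true_activity(og, -1, 100), "non-negative")
})

test_that("phantom organ validation rejects unphysical curves", {
  expect_error(phantom_organ("x", c(0.5, 0.8), c(0.01, 0.1), 10,
                             c(1L, 2L, 1L, 2L), 1), "sum of amplitudes")
  expect_error(phantom_organ("x", c(-0.02, 0.03), c(0.001, 0.1), 10,
                             c(1L, 2L, 1L, 2L), 1), "goes negative")
  expect_error(phantom_organ("x", 0.5, c(0.01, 0.1), 10,
                             c(1L, 2L, 1L, 2L), 1), "equal length")
})

test_that("phantom_spec validates geometry", {
  ok <- phantom_organ("a", 0.1, 0.01, 10, c(1L, 4L, 1L, 4L), 2)
  overlap <- phantom_organ("b", 0.1, 0.01, 10, c(3L, 6L, 3L, 6L), 2)
  outside <- phantom_organ("c", 0.1, 0.01, 10, c(60L, 70L, 1L, 4L), 2)
  deep <- phantom_organ("d", 0.1, 0.01, 10, c(10L, 12L, 10L, 12L), 50)
  expect_error(phantom_spec(list(ok, overlap), image_dim = c(32L, 32L)),
               "overlaps")
  expect_error(phantom_spec(list(outside), image_dim = c(32L, 32L)),
               "outside the image frame")
  expect_error(phantom_spec(list(ok, deep), image_dim = c(32L, 32L)),
               "depth exceeds")
})

test_that("noiseless renders have the analytic expected counts", {
  # exp(-mu * depth) = 0.5 and exp(-mu * thickness) = 0.16
  mu <- 0.1
  depth <- log(2) / mu
  thickness <- log(1 / 0.16) / mu
  ph <- phantom_spec(
    organs = list(phantom_organ("kidneys", 100 / 7400, 1e-9, 300,
                                c(10L, 17L, 10L, 17L), depth)),
    body_thickness = thickness, attenuation_coefficient = mu,
    camera_sensitivity = 10, injected_activity = 7400,
    background_fraction = 0, image_dim = c(32L, 32L), seed = 1L)
  pair <- render_planar_pair(ph, t = 0, duration = 60, noise = FALSE)
  expect_equal(sum(pair$anterior), 10 * 60 * 100 * 0.5, tolerance = 1e-9)
  # conjugate-view depth cancellation: GM = counts * sqrt(exp(-mu*thickness))
  gm <- sqrt(sum(pair$anterior) * sum(pair$posterior))
  expect_equal(gm, 10 * 60 * 100 * sqrt(0.16), tolerance = 1e-9)
})

test_that("geometric mean of noiseless views is depth-invariant", {
  gms <- vapply(c(0, 3, 6, 9, 12, 18), function(d) {
    ph <- simple_phantom(depth = d)
    pair <- render_planar_pair(ph, 24, 60, noise = FALSE)
    sqrt(sum(pair$anterior) * sum(pair$posterior))
  }, numeric(1))
  expect_lt(diff(range(gms)) / gms[1], 1e-10)
})

test_that("renders are reproducible under the phantom seed", {
  ph <- simple_phantom(seed = 99L)
  p1 <- render_planar_pair(ph, 24, 60)
  p2 <- render_planar_pair(ph, 24, 60)
  expect_identical(p1$anterior, p2$anterior)
  expect_identical(p1$posterior, p2$posterior)
  p3 <- render_planar_pair(simple_phantom(seed = 100L), 24, 60)
  expect_false(identical(p1$anterior, p3$anterior))
})

test_that("Poisson draws match the analytic means", {
  ph <- simple_phantom(seed = 5L)
  expected <- render_planar_pair(ph, 24, 1, noise = FALSE)$anterior
  fp <- ph$organs[[1]]$footprint
  mean_expected <- sum(expected[fp[1]:fp[2], fp[3]:fp[4]])
  draws <- vapply(seq_len(1000L), function(i) {
    phi <- simple_phantom(seed = 5L + i)
    p <- render_planar_pair(phi, 24, 1)
    sum(p$anterior[fp[1]:fp[2], fp[3]:fp[4]])
  }, numeric(1))
  se <- sqrt(mean_expected / length(draws))  # Poisson SE of the mean
  expect_lt(abs(mean(draws) - mean_expected), 3 * se)
})

test_that("blood sampling follows the biexponential model", {
  ph <- phantom_spec(list(phantom_organ("k", 0.02, 0.01, 300,
                                        c(10L, 13L, 10L, 13L), 5)),
                     blood_amplitudes = c(0.012, 0.006),
                     blood_rates = c(0.3, 0.01),
                     image_dim = c(32L, 32L), seed = 3L)
  b0 <- sample_blood(ph, 0, noise = FALSE)
  expect_equal(b0$conc_frac_ia_per_kg, 0.018)
  mono <- phantom_spec(list(phantom_organ("k", 0.02, 0.01, 300,
                                          c(10L, 13L, 10L, 13L), 5)),
                       blood_amplitudes = 0.01, blood_rates = log(2) / 24,
                       image_dim = c(32L, 32L), seed = 3L)
  b <- sample_blood(mono, c(0, 24), noise = FALSE)
  expect_equal(b$conc_frac_ia_per_kg[2], b$conc_frac_ia_per_kg[1] / 2,
               tolerance = 1e-12)
  n1 <- sample_blood(ph, c(1, 24, 48))
  n2 <- sample_blood(ph, c(1, 24, 48))
  expect_identical(n1, n2)
  expect_error(sample_blood(ph, numeric(0)), "non-empty")
  expect_error(sample_blood(ph, c(24, 1)), "strictly increasing")
})

test_that("lesion courses plateau at the configured area shrinkage", {
  les <- phantom_lesion("L1", 20, 1e-3, 0.005, "liver", baseline_L = 30,
                        baseline_W = 20, shrinkage = 0.3, shrink_tau = 1e-9)
  cs <- simulate_lesion_course(les, c(0, 12, 24), noise = FALSE)
  area <- cs$L_mm * cs$W_mm
  change <- (area[-1] / area[1] - 1) * 100
  expect_equal(change, c(-30, -30), tolerance = 1e-9)

  flat <- phantom_lesion("L2", 20, 1e-3, 0.005, "liver", shrinkage = 0)
  cf <- simulate_lesion_course(flat, c(0, 12, 24, 36), noise = FALSE)
  expect_equal((cf$L_mm * cf$W_mm) / (cf$L_mm[1] * cf$W_mm[1]),
               rep(1, 4), tolerance = 1e-12)

  expect_error(simulate_lesion_course(les, c(0, 10)), "subset")
  expect_error(phantom_lesion("x", 20, 1e-3, 0.005, baseline_L = -1),
               "baseline_L")
})

test_that("ground-truth TIAC matches numeric quadrature", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    a <- stats::runif(k, 0.01, 0.3)
    l <- stats::runif(k, 0.002, 0.5)
    og <- phantom_organ("x", a, l, 10, c(1L, 2L, 1L, 2L), 1)
    tau <- sum(a / l)
    quad <- oracle_tiac_quadrature(a, l)
    expect_lt(abs(tau - quad) / tau, 1e-3)
  }
})
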