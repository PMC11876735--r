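make_toy_scan <- function(ant, post = ant, t = 24, dur = 100, sens = 10) {
  planar_scan(ant, post, t, dur, sens)
}

test_that("roi_counts subtracts per-pixel background and floors at zero", {
  img <- matrix(10, 20, 20)            # background mean 10 counts/px
  img[1:10, 1:10] <- 100               # ROI sum 10,000 over 100 px
  labels <- matrix(0L, 20, 20)
  labels[1:10, 1:10] <- 1L
  labels[15:20, 15:20] <- 2L
  rs <- roi_set(labels, c(kidneys = 1L), background_label = 2L,
                transmission = c(kidneys = 0.2))
  cc <- roi_counts(make_toy_scan(img), rs, "kidneys")
  expect_equal(cc$anterior, 10000 - 10 * 100)
  expect_false(cc$clipped)

  # background exceeding the ROI floors at 0 with a warning
  img2 <- img
  img2[1:10, 1:10] <- 5
  expect_warning(cc2 <- roi_counts(make_toy_scan(img2), rs, "kidneys"),
                 "floored")
  expect_equal(cc2$anterior, 0)
  expect_true(cc2$clipped)
})

test_that("roi_counts equals a brute-force pixel loop on random images", {
  set.seed(21)
  for (i in 1:10) {
    img_a <- matrix(rpois(400, 20), 20, 20)
    img_p <- matrix(rpois(400, 15), 20, 20)
    img_a[3:9, 4:12] <- img_a[3:9, 4:12] + rpois(63, 60)
    img_p[3:9, 4:12] <- img_p[3:9, 4:12] + rpois(63, 40)
    labels <- matrix(0L, 20, 20)
    labels[3:9, 4:12] <- 1L
    labels[15:19, 2:6] <- 2L
    rs <- roi_set(labels, c(src = 1L), background_label = 2L,
                  transmission = c(src = 0.3))
    cc <- roi_counts(make_toy_scan(img_a, img_p), rs, "src")
    expect_equal(cc$anterior, oracle_roi_counts(img_a, labels == 1L,
                                                labels == 2L))
    expect_equal(cc$posterior, oracle_roi_counts(img_p, labels == 1L,
                                                 labels == 2L))
  }
})

test_that("conjugate-view activity matches the geometric-mean formula", {
  s <- make_toy_scan(matrix(0, 2, 2), dur = 100, sens = 10)  # sens*dur = 1000
  expect_equal(conjugate_view_activity(8000, 2000, 0.16, s), 10)
  expect_equal(conjugate_view_activity(0, 0, 0.5, s), 0)
  expect_error(conjugate_view_activity(10, 10, 0, s), "transmission")
  expect_error(conjugate_view_activity(10, 10, 1.2, s), "transmission")
  expect_error(conjugate_view_activity(-1, 10, 0.5, s), "non-negative")
})

test_that("noiseless phantom quantification recovers ground truth exactly", {
  for (depth in c(2, 6, 14)) {
    ph <- simple_phantom(depth = depth, amplitudes = c(0.03, 0.01),
                         rates = c(0.1, 0.005))
    roiset <- phantom_roi_set(ph, whole_body = FALSE)
    for (t in c(1, 24, 96, 168)) {
      pair <- render_planar_pair(ph, t, 120, noise = FALSE)
      scan <- planar_scan(pair$anterior, pair$posterior, t, 120, 10)
      cc <- roi_counts(scan, roiset, "kidneys")
      a <- conjugate_view_activity(cc$anterior, cc$posterior,
                                   roiset$transmission[["kidneys"]], scan)
      truth <- pair$truth$true_activity_MBq[pair$truth$source == "kidneys"]
      expect_lt(abs(a - truth) / truth, 1e-9)
    }
  }
})

test_that("time-activity series: fractions, normalisation and errors", {
  ph <- simple_phantom(amplitudes = 0.01, rates = 1e-9,
                       background_fraction = 0)
  roiset <- phantom_roi_set(ph)
  scans <- lapply(c(1, 24), function(t) {
    p <- render_planar_pair(ph, t, 100, noise = FALSE)
    planar_scan(p$anterior, p$posterior, t, 100, 10)
  })
  ser <- build_time_activity_series(scans, roiset, 7400)
  kid <- ser[ser$source == "kidneys", ]
  expect_equal(kid$fraction_ia, c(0.01, 0.01), tolerance = 1e-6)

  # whole-body normalisation rescales everything by the first WB fraction
  ser_n <- build_time_activity_series(scans, roiset, 7400,
                                      normalize_first_wholebody = TRUE)
  wb1 <- ser[ser$source == "whole body" & ser$time_h == 1, "fraction_ia"]
  expect_equal(ser_n$fraction_ia, ser$fraction_ia / wb1, tolerance = 1e-12)
  expect_equal(ser_n$fraction_ia[ser_n$source == "whole body" &
                                   ser_n$time_h == 1], 1)

  rs_nowb <- phantom_roi_set(ph, whole_body = FALSE)
  expect_error(build_time_activity_series(scans, rs_nowb, 7400,
                                          normalize_first_wholebody = TRUE),
               "whole-body ROI")
  expect_error(build_time_activity_series(rev(scans), roiset, 7400),
               "strictly increasing")
})

test_that("recovered activity is linear in injected activity", {
  f <- function(A0, seed) {
    ph <- phantom_spec(
      organs = list(phantom_organ("kidneys", 0.03, 0.005, 300,
                                  c(10L, 17L, 10L, 17L), 6)),
      body_thickness = 18, camera_sensitivity = 10, injected_activity = A0,
      background_fraction = 0, image_dim = c(32L, 32L), seed = seed)
    roiset <- phantom_roi_set(ph, whole_body = FALSE)
    pair <- render_planar_pair(ph, 24, 600)
    scan <- planar_scan(pair$anterior, pair$posterior, 24, 600, 10)
    cc <- roi_counts(scan, roiset, "kidneys")
    conjugate_view_activity(cc$anterior, cc$posterior,
                            roiset$transmission[["kidneys"]], scan)
  }
  a1 <- f(7400, 17L)
  a2 <- f(14800, 18L)
  expect_equal(a2 / a1, 2, tolerance = 0.05)  # Poisson noise at ~1e6 counts
})

test_that("whole-body fraction is non-increasing for washout-only phantoms", {
  ph <- simple_phantom(amplitudes = c(0.03, 0.01), rates = c(0.1, 0.005),
                       background_fraction = 0.5)
  roiset <- phantom_roi_set(ph)
  scans <- lapply(c(2, 24, 48, 96, 168), function(t) {
    p <- render_planar_pair(ph, t, 120, noise = FALSE)
    planar_scan(p$anterior, p$posterior, t, 120, 10)
  })
  ser <- build_time_activity_series(scans, roiset, 7400)
  wb <- ser[ser$source == "whole body", ]
  expect_true(all(diff(wb$fraction_ia[order(wb$time_h)]) <= 0))
})
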