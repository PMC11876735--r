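test_that("area size change follows the ratio formula", {
  expect_equal(size_change_pct(400, 400), 0)
  expect_equal(size_change_pct(300, 400), -25)
  expect_equal(size_change_pct(800, 400), 100)
  expect_error(size_change_pct(300, 0), "positive")
})

test_that("best change is the most favourable time point", {
  expect_equal(best_change(c(10, -20, -5)), -20)
  expect_equal(best_change(c(10, 4)), 4)
  expect_equal(best_change(-3.6), -3.6)
  expect_error(best_change(numeric(0)), "no post-baseline")
})

test_that("diameter change uses the axis matching the lesion type", {
  expect_equal(diameter_change_pct(12, 8, 12, 10, is_lymph_node = TRUE), -20)
  expect_equal(diameter_change_pct(25, 10, 20, 10, is_lymph_node = FALSE), 25)
  # node with unchanged short axis but changed long axis: 0%
  expect_equal(diameter_change_pct(30, 10, 20, 10, is_lymph_node = TRUE), 0)
})

test_that("size change is scale-invariant and area/diameter agree in sign", {
  set.seed(51)
  for (i in 1:20) {
    L0 <- stats::runif(1, 10, 50); W0 <- L0 * stats::runif(1, 0.4, 1)
    g <- stats::runif(1, 0.5, 1.5)  # proportional change of both axes
    k <- stats::runif(1, 0.1, 10)   # unit rescaling
    a1 <- size_change_pct(g * L0 * g * W0, L0 * W0)
    a2 <- size_change_pct(k * g * L0 * k * g * W0, k * L0 * k * W0)
    expect_equal(a1, a2, tolerance = 1e-10)
    d <- diameter_change_pct(g * L0, g * W0, L0, W0, is_lymph_node = i %% 2 == 0)
    expect_equal(sign(round(a1, 10)), sign(round(d, 10)))
  }
})

test_that("lesion response table computes best changes against baseline", {
  m <- data.frame(
    lesion_id = rep("L1", 3), week = c(0, 12, 24),
    L_mm = c(20, 22, 16), W_mm = c(10, 11, 8),
    is_lymph_node = FALSE)
  rt <- lesion_response_table(m)
  expect_equal(rt$best_area_change_pct,
               (16 * 8) / (20 * 10) * 100 - 100, tolerance = 1e-12)
  expect_equal(rt$best_diameter_change_pct, -20, tolerance = 1e-12)
  expect_true(rt$best_area_change_pct <=
                size_change_pct(22 * 11, 200))
})

test_that("shrinkage fractions count negative best changes", {
  bc <- c(-10, -5, 3)
  s <- shrinkage_fraction(bc)
  expect_equal(s$n_shrinking, 2L)
  expect_equal(s$percent, 67)
  # dose-floor filtering: 35 shrinking of 38 at >= 50 Gy reports 92%
  bc38 <- c(rep(-20, 35), rep(5, 3))
  s38 <- shrinkage_fraction(bc38, cumulative_doses = rep(60, 38),
                            dose_floor = 50)
  expect_equal(s38$n_shrinking, 35L)
  expect_equal(s38$percent, 92)
  # 47 of 52 with no floor reports 90%
  s52 <- shrinkage_fraction(c(rep(-1, 47), rep(1, 5)))
  expect_equal(s52$percent, 90)
  expect_error(shrinkage_fraction(bc, rep(1, 3), dose_floor = 50),
               "no lesions left")
})

test_that("dose-response association is a tie-aware Spearman correlation", {
  x <- 1:10
  perfect <- dose_response_association(x, -x)
  expect_equal(perfect$rho, -1, tolerance = 1e-12)
  # tied doses: matches the explicit mid-rank formula
  set.seed(52)
  xd <- sample(c(50, 50, 100, 100, 150, 200, 200, 300), 8)
  yd <- stats::rnorm(8)
  got <- dose_response_association(xd, yd)
  expect_equal(got$rho, oracle_spearman(xd, yd), tolerance = 1e-12)
  const <- dose_response_association(rep(5, 4), c(1, 2, 3, 4))
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
  expect_error(dose_response_association(1:2, 1:2), "3 pairs")
})

test_that("independent doses and responses show no spurious correlation", {
  set.seed(53)
  rhos <- vapply(1:1000, function(i) {
    x <- stats::rlnorm(52, 4, 1)
    y <- stats::rnorm(52, -20, 15)
    dose_response_association(x, y)$rho
  }, numeric(1))
  # under independence sd(rho) = 1/sqrt(n - 1) = 0.14, so |rho| < 0.28 is a
  # 2-SD event with probability 0.9545; allow 3 binomial SDs of simulation
  # noise around that value
  p0 <- 0.9545
  se <- sqrt(p0 * (1 - p0) / length(rhos))
  expect_gte(mean(abs(rhos) < 0.28), p0 - 3 * se)
  expect_lt(abs(mean(rhos)), 3 / sqrt(51) / sqrt(1000) * 3 + 0.02)
})

test_that("renal decline slope and flag follow the -20%/year rule", {
  r <- renal_decline_rate(c(0, 0.5), c(100, 90))
  expect_equal(r$slope_pct_per_year, -20, tolerance = 1e-12)
  expect_true(r$flag)
  r0 <- renal_decline_rate(c(0, 1, 2), c(80, 80, 80))
  expect_equal(r0$slope_pct_per_year, 0, tolerance = 1e-12)
  expect_false(r0$flag)
  # noisy series with a true -10%/y slope stays unflagged
  set.seed(54)
  yrs <- 0:5
  crcl <- 100 * (1 - 0.10 * yrs) + stats::rnorm(6, 0, 1.5)
  rn <- renal_decline_rate(yrs, crcl)
  expect_false(rn$flag)
  expect_equal(rn$slope_pct_per_year, -10, tolerance = 0.35)
  expect_error(renal_decline_rate(c(0, 1), c(0, 10)), "positive")
})

test_that("organ-at-risk flags use strict thresholds", {
  f <- threshold_flags(19.4, 1.0)
  expect_false(f$kidney_flag); expect_false(f$marrow_flag)
  f2 <- threshold_flags(28, 3.2)
  expect_true(f2$kidney_flag); expect_true(f2$marrow_flag)
  # exactly at threshold: not flagged (strict inequality)
  f3 <- threshold_flags(23, 2)
  expect_false(f3$kidney_flag); expect_false(f3$marrow_flag)
})

test_that("incidence proportion rounds to one decimal", {
  expect_equal(incidence_proportion(3, 133), 2.3)
  expect_equal(incidence_proportion(0, 50), 0.0)
  expect_equal(incidence_proportion(50, 50), 100.0)
  expect_error(incidence_proportion(1, 0), "positive")
})

test_that("cohort summaries match brute-force formulas", {
  s <- summarize_cohort(c(10, 20, 30))
  expect_equal(s$mean, 20); expect_equal(s$sd, 10)
  expect_equal(s$median, 20); expect_equal(c(s$min, s$max), c(10, 30))
  one <- summarize_cohort(5)
  expect_equal(one$sd, 0); expect_true(one$degenerate)
  set.seed(55)
  for (i in 1:10) {
    v <- stats::rnorm(sample(2:50, 1))
    s <- summarize_cohort(v)
    expect_equal(s$mean, sum(v) / length(v), tolerance = 1e-12)
    expect_equal(s$sd, sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
    expect_true(s$min <= s$median && s$median <= s$max)
  }
  expect_error(summarize_cohort(numeric(0)), "no values")
})
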