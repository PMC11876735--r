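# Independent brute-force oracles used across the suite.

# Background-corrected ROI counts by an explicit pixel loop.
oracle_roi_counts <- function(img, mask, bmask) {
  raw <- 0; n <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (mask[i, j]) { raw <- raw + img[i, j]; n <- n + 1 }
  }
  bsum <- 0; bn <- 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (bmask[i, j]) { bsum <- bsum + img[i, j]; bn <- bn + 1 }
  }
  max(raw - bsum / bn * n, 0)
}

# TIAC of a sum-of-exponentials curve by adaptive quadrature. The integrand
# mixes very different time scales, so integrate each piecewise dyadic window
# and sum; windows continue until the remainder is negligible.
oracle_tiac_quadrature <- function(amplitudes, rates, upper = Inf) {
  f <- function(t)
    vapply(t, function(ti) sum(amplitudes * exp(-rates * ti)), numeric(1))
  lo <- 0; hi <- 1; total <- 0
  limit <- if (is.finite(upper)) upper else 30 / min(rates)
  repeat {
    hi_w <- min(hi, limit)
    total <- total + stats::integrate(f, lo, hi_w, rel.tol = 1e-11,
                                      subdivisions = 500L)$value
    if (hi_w >= limit) break
    lo <- hi_w; hi <- hi * 2
  }
  total
}

# MIRD double sum by an explicit loop over (target, source) rows.
oracle_mird_sum <- function(tiacs, s_df, target) {
  d <- 0
  for (s in names(tiacs)) {
    hit <- s_df$target == target & s_df$source == s
    d <- d + tiacs[[s]] * s_df$s_value_Gy_per_GBq_h[hit][1]
  }
  d
}

# Spearman rho through the explicit rank formula with mid-ranks for ties.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# A minimal one-organ phantom used by several quantification tests.
simple_phantom <- function(depth = 6, amplitudes = 0.04,
                           rates = log(2) / 80, seed = 1L,
                           background_fraction = 0, sensitivity = 10,
                           thickness = 18) {
  phantom_spec(
    organs = list(phantom_organ("kidneys", amplitudes, rates, 300,
                                c(10L, 17L, 10L, 17L), depth)),
    body_thickness = thickness, camera_sensitivity = sensitivity,
    injected_activity = 7400, background_fraction = background_fraction,
    image_dim = c(32L, 32L), seed = seed)
}
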