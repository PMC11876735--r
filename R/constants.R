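#' Physical constants for a radionuclide
#'
#' Bundles the physical half-life, the derived decay constant and the number
#' of nuclear transformations per MBq.h, the three constants every absorbed
#' dose calculation in this package depends on. The default is Lu-177
#' (physical half-life 159.53 h, i.e. 6.647 d).
#'
#' @param physical_half_life Physical half-life in hours.
#' @param decays_per_MBq_hour Nuclear transformations per MBq.h of cumulated
#'   activity; 1 MBq = 1e6 decays/s, so one MBq.h is 3.6e9 decays.
#' @return An object of class `physical_constants` with fields
#'   `physical_half_life` (h), `decay_constant` (1/h) and
#'   `decays_per_MBq_hour`.
#' @examples
#' lu <- physical_constants()
#' lu$decay_constant * lu$physical_half_life  # log(2)
#' @export
physical_constants <- function(physical_half_life = 159.53,
                               decays_per_MBq_hour = 3.6e9) {
  stopifnot(is.numeric(physical_half_life), length(physical_half_life) == 1L,
            physical_half_life > 0,
            is.numeric(decays_per_MBq_hour), decays_per_MBq_hour > 0)
  structure(
    list(
      physical_half_life = physical_half_life,
      decay_constant = log(2) / physical_half_life,
      decays_per_MBq_hour = decays_per_MBq_hour
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat(sprintf(
    "Radionuclide physical constants\n  T_phys: %.4g h (%.4g d)\n  lambda: %.6g 1/h\n  decays per MBq.h: %.4g\n",
    x$physical_half_life, x$physical_half_life / 24,
    x$decay_constant, x$decays_per_MBq_hour))
  invisible(x)
}

# Derive a reproducible integer sub-seed for a named artifact from one global
# cohort seed, so images, blood samples and lesion courses each consume an
# independent stream. Plain 32-bit string hash folded with the seed.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(as.character(name))) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate an expression under a local RNG state seeded from (seed, name),
# restoring the caller's .Random.seed afterwards.
with_substream <- function(seed, name, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(substream_seed(seed, name))
  expr
}
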