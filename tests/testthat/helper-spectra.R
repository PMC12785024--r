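# Helpers used across tests: small synthetic spectra with known truth.

# single-window Voigt spectrum plus linear baseline and optional noise
mk_voigt_spectrum <- function(centers, sigmas, gammas, areas,
                              lo, hi, spacing = 0.5,
                              baseline = c(0, 0), noise_sd = 0, seed = NULL) {
  nu <- seq(lo, hi, by = spacing)
  y <- baseline[1] + baseline[2] * nu
  for (i in seq_along(centers)) {
    y <- y + voigt_profile(nu, centers[i], sigmas[i], gammas[i], areas[i])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(nu), 0, noise_sd)
  }
  ir_spectrum(nu, y)
}

# minimal fast scenario for tracking tests: small grid, few bands
mk_mini_scenario <- function(bands, rate = 0.4, noise_sd = 2e-4,
                             grid = c(1000, 1700, 0.5),
                             times = c(0, 12, 1.5), ...) {
  scenario("mini", bands = bands, grid = grid, times = times,
           rate = rate, noise_sd = noise_sd, ...)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), rel_tol)
}
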