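test_that("noiseless single Voigt plus baseline is recovered essentially exactly", {
  truth <- c(area = 1, center = 1077, sigma = 4, gamma = 6)
  s <- mk_voigt_spectrum(1077, 4, 6, 1, 1000, 1150, 0.5, baseline = c(0.01, 1e-5))
  m0 <- initial_window_model(s, 1000, 1150, k = 1)
  fit <- fit_window(s, m0, fit_constraints(center_tol = 10), noise_sd = 1e-6)
  expect_true(fit$converged)
  cm <- fit$model$components
  expect_rel_equal(cm$area, truth["area"], 1e-6)
  expect_lt(abs(cm$center - truth["center"]), 1077 * 1e-6)
  expect_rel_equal(cm$sigma, truth["sigma"], 1e-5)
  expect_rel_equal(cm$gamma, truth["gamma"], 1e-5)
  expect_equal(fit$model$baseline, c(0.01, 1e-5), tolerance = 1e-4)
  # residual floor on in-family noiseless data
  expect_lt(fit$rss, (1e-8 * max(s$absorbance))^2 * nrow(fit$data))
})

test_that("an all-zero window yields zero area at the bound", {
  s <- ir_spectrum(seq(1000, 1100, 0.5), rep(0, 201))
  m0 <- window_model(1000, 1100, tibble::tibble(area = 0.1, center = 1050,
                                                sigma = 3, gamma = 2))
  fit <- fit_window(s, m0, fit_constraints(), noise_sd = 1e-9)
  expect_lt(fit$model$components$area, 1e-10)
  expect_lt(max(abs(fit$model$baseline)), 1e-8)
})

test_that("fitted parameters respect the stated bounds exactly", {
  fc <- fit_constraints()
  set.seed(31)
  for (i in 1:10) {
    sigma <- runif(1, 1, 15); gamma <- runif(1, 1, 20)
    ctr <- 1300 + runif(1, -5, 5)
    s <- mk_voigt_spectrum(ctr, sigma, gamma, 0.4, 1240, 1360, 0.5,
                           noise_sd = 5e-4, seed = 1000 + i)
    m0 <- initial_window_model(s, 1240, 1360, 1, centers = 1300)
    fit <- fit_window(s, m0, fc, 5e-4, ref_centers = 1300)
    cm <- fit$model$components
    expect_gte(cm$area, 0)
    expect_gte(cm$sigma, fc$sigma_bounds[1]); expect_lte(cm$sigma, fc$sigma_bounds[2])
    expect_gte(cm$gamma, fc$gamma_bounds[1]); expect_lte(cm$gamma, fc$gamma_bounds[2])
    expect_gte(cm$center, 1300 - fc$center_tol)
    expect_lte(cm$center, 1300 + fc$center_tol)
  }
})

test_that("overlapped pair centres are recovered across noisy replicates", {
  hits <- 0L
  n_rep <- 25L
  for (i in seq_len(n_rep)) {
    s <- mk_voigt_spectrum(c(1606, 1617), c(3.5, 3.5), c(2, 2), c(0.4, 0.4),
                           1570, 1650, 0.5, noise_sd = 2e-4, seed = 300 + i)
    m0 <- initial_window_model(s, 1570, 1650, 2, centers = c(1606, 1617))
    fit <- fit_window(s, m0, fit_constraints(center_tol = 5), 2e-4,
                      ref_centers = c(1606, 1617))
    cm <- fit$model$components
    if (fit$converged &&
        abs(cm$center[1] - 1606) < 0.3 && abs(cm$center[2] - 1617) < 0.3) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("grid-shift equivariance: shifting the axis shifts only the centres", {
  s <- mk_voigt_spectrum(1345, 3.5, 3, 0.35, 1300, 1390, 0.5,
                         noise_sd = 2e-4, seed = 77)
  fit1 <- fit_window(s, initial_window_model(s, 1300, 1390, 1, centers = 1345),
                     fit_constraints(), 2e-4)
  sh <- ir_spectrum(s$wavenumber + 50, s$absorbance)
  fit2 <- fit_window(sh, initial_window_model(sh, 1350, 1440, 1, centers = 1395),
                     fit_constraints(), 2e-4)
  c1 <- fit1$model$components; c2 <- fit2$model$components
  expect_equal(c2$center - c1$center, 50, tolerance = 1e-6)
  expect_equal(c2$area, c1$area, tolerance = 1e-6)
  expect_equal(c2$sigma, c1$sigma, tolerance = 1e-6)
  expect_equal(c2$gamma, c1$gamma, tolerance = 1e-6)
})

test_that("family selection prefers the generating family and breaks ties simply", {
  # noiseless Gaussian data: voigt's extra parameter cannot beat the tie rule
  s <- mk_voigt_spectrum(1500, 4, 0, 0.5, 1450, 1550, 0.5)
  m0 <- initial_window_model(s, 1450, 1550, 1, centers = 1500)
  sel <- select_family(s, m0, fit_constraints(center_tol = 10), noise_sd = 1e-7)
  expect_equal(sel$family, "gaussian")

  # small Monte Carlo at SNR 100: gaussian-generated data selects gaussian
  n_ok <- 0L
  for (i in 1:20) {
    noise <- 2e-4
    area <- 100 * noise / apex_height(0, 4, 0, 1)
    s <- mk_voigt_spectrum(1500, 4, 0, area, 1450, 1550, 0.5,
                           noise_sd = noise, seed = 500 + i)
    m0 <- initial_window_model(s, 1450, 1550, 1, centers = 1500)
    sel <- tryCatch(
      select_family(s, m0, fit_constraints(center_tol = 10), noise),
      error = function(e) NULL)
    if (!is.null(sel) && sel$family == "gaussian") n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 17L)
})

test_that("component-count selection follows the residual and BIC gates", {
  # single band at high SNR: k = 1 retained
  s1 <- mk_voigt_spectrum(1345, 3.5, 3, 0.5, 1300, 1390, 0.5,
                          noise_sd = 1e-4, seed = 61)
  fit1 <- select_components(s1, 1300, 1390, fit_constraints(), noise_sd = 1e-4)
  expect_equal(nrow(fit1$model$components), 1L)

  # overlapped pair closer than the combined FWHM: k = 2 accepted
  s2 <- mk_voigt_spectrum(c(1606, 1617), c(3.5, 3.5), c(2, 2), c(0.4, 0.4),
                          1575, 1650, 0.5, noise_sd = 1e-4, seed = 62)
  fit2 <- select_components(s2, 1575, 1650, fit_constraints(center_tol = 6),
                            noise_sd = 1e-4)
  expect_equal(nrow(fit2$model$components), 2L)
  expect_lt(max(abs(sort(fit2$model$components$center) - c(1606, 1617))), 0.5)

  # three overlapped bands: k = 3 and never more (hard cap)
  s3 <- mk_voigt_spectrum(c(1583, 1595, 1606), rep(3.5, 3), rep(2, 3),
                          c(0.3, 0.35, 0.3), 1550, 1650, 0.5,
                          noise_sd = 1e-4, seed = 63)
  fit3 <- select_components(s3, 1550, 1650, fit_constraints(center_tol = 6),
                            noise_sd = 1e-4)
  expect_lte(nrow(fit3$model$components), 3L)
  expect_equal(nrow(fit3$model$components), 3L)
})

test_that("static reference fitting recovers the enzyme band table", {
  alp <- generate_static("ALP", noise_sd = 2e-4, seed = 8)
  refs <- fit_static_references(list(ALP = alp$spectrum))
  expect_equal(nrow(refs), 11L)
  expect_false(any(refs$missing))
  expect_true(all(abs(refs$fitted_center - refs$literature_center) < 0.5))
  expect_true(all(refs$track_tol == 7.5))
})

test_that("the product marker band is located precisely in the phosphate window", {
  pi_s <- generate_static("Pi", noise_sd = 2e-4, seed = 9)
  refs <- fit_static_references(list(Pi = pi_s$spectrum))
  r1077 <- refs[refs$band_id == "Pi_1077", ]
  expect_false(r1077$missing)
  expect_lt(abs(r1077$fitted_center - 1077), 0.2)
})

test_that("an empty spectrum marks every reference band missing", {
  nu <- seq(400, 4000, 0.25)
  empty <- ir_spectrum(nu, rep(0, length(nu)))
  refs <- fit_static_references(list(ALP = empty))
  expect_true(all(refs$missing))
  expect_true(all(is.na(refs$fitted_center)))
})
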