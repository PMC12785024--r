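mini_plan <- function() {
  tibble::tibble(
    band_id = c("a_1345", "b_1460"),
    ref_center = c(1345, 1460),
    track_tol = c(7.5, 6),
    window_lo = c(1322, 1442),
    window_hi = c(1368, 1477),
    role = c("marker", "control"))
}

mini_bands <- function(drift_1460 = 0) {
  list(
    band_spec("a_1345", 1345, 1340, area_start = 0.35),
    band_spec("b_1460", 1460, 1460 + drift_1460, area_start = 0.25))
}

test_that("null-dynamics series yields flat trajectories", {
  sc <- mk_mini_scenario(list(
    band_spec("a_1345", 1345, 1345, area_start = 0.35),
    band_spec("b_1460", 1460, 1460, area_start = 0.25)),
    grid = c(1250, 1550, 0.5))
  gen <- generate_series(sc, seed = 4)
  traj <- track_series(gen$series, mini_plan())
  expect_true(all(traj$converged))
  sh <- compute_shift(traj)
  expect_true(all(abs(sh$delta_cm1) <= pmax(2.5 * sh$delta_sd, 0.1)))
  for (b in unique(traj$band_id)) {
    ctr <- traj$center[traj$band_id == b]
    expect_lt(max(ctr) - min(ctr), 0.3)
  }
})

test_that("slice order on disk does not affect trajectories", {
  sc <- mk_mini_scenario(mini_bands(), grid = c(1250, 1550, 0.5),
                         times = c(0, 7.5, 1.5))
  gen <- generate_series(sc, seed = 12)
  d <- withr::local_tempdir()
  man <- write_series(gen$series, d)
  traj1 <- track_series(read_series(man), mini_plan())
  # shuffle the manifest rows; read_series sorts by time
  lines <- readLines(man)
  writeLines(c(lines[1], rev(lines[-1])), man)
  traj2 <- track_series(read_series(man), mini_plan())
  expect_equal(tibble::as_tibble(traj1), tibble::as_tibble(traj2), tolerance = 1e-10)
})

test_that("net shifts are endpoint differences with propagated uncertainty", {
  traj <- tibble::tibble(
    band_id = "x", time_min = c(0, 1, 2),
    center = c(1500, 1501, 1504), center_sd = c(0.3, 0.1, 0.4),
    converged = c(TRUE, TRUE, TRUE))
  sh <- compute_shift(traj)
  expect_equal(sh$delta_cm1, 4)
  expect_equal(sh$delta_sd, sqrt(0.3^2 + 0.4^2))
  traj$converged <- c(TRUE, FALSE, FALSE)
  expect_error(compute_shift(traj), "fewer than 2")
})

test_that("redistribution between fixed components reproduces a drifting centroid", {
  # amplitude exchange A_lo = A e^-kt, A_hi = A (1 - e^-kt), centres fixed
  k <- 0.35
  times <- seq(0, 12, 1.5)
  specs <- lapply(times, function(t) {
    mk_voigt_spectrum(c(1606, 1617), c(3.5, 3.5), c(2.5, 2.5),
                      c(0.5 * exp(-k * t), 0.5 * (1 - exp(-k * t))),
                      1560, 1660, 0.5, noise_sd = 1e-4, seed = round(1e4 + t * 10))
  })
  ser <- ir_series(specs, times)
  red <- redistribution_analysis(ser, 1592, 1632, centers = c(1606, 1617))
  tb <- red$table
  expect_true(all(tb$converged))
  expect_true(all(tb$f >= 0 & tb$f <= 1))
  expect_lt(sqrt(mean((tb$f - (1 - exp(-k * times)))^2)), 0.03)
  expect_lt(red$max_center_motion, 0.5)
  expect_gt(red$centroid_drift, 5)
})

test_that("redistribution degenerate cases behave", {
  times <- c(0, 1.5, 3)
  eq <- lapply(times, function(t) {
    mk_voigt_spectrum(c(1606, 1617), c(3.5, 3.5), c(2.5, 2.5), c(0.4, 0.4),
                      1560, 1660, 0.5)
  })
  red_eq <- redistribution_analysis(ir_series(eq, times), 1592, 1632)
  expect_true(all(abs(red_eq$table$f - 0.5) < 0.01))

  lo <- lapply(times, function(t) {
    mk_voigt_spectrum(c(1606, 1617), c(3.5, 3.5), c(2.5, 2.5), c(0.5, 0),
                      1560, 1660, 0.5)
  })
  red_lo <- redistribution_analysis(ir_series(lo, times), 1592, 1632)
  expect_true(all(red_lo$table$f < 0.02))
  expect_true(all(abs(red_lo$table$centroid - 1606) < 1))
})

test_that("plateau kinetics recover the closed-form completion time", {
  k <- 0.6657
  times <- seq(0, 33, 1.5)
  a <- 0.02 + 0.5 * (1 - exp(-k * times))
  pf <- fit_plateau(times, a)
  expect_false(pf$no_rise)
  expect_equal(pf$t95, log(20) / k, tolerance = 1e-6)
  expect_equal(pf$k, k, tolerance = 1e-6)

  const <- fit_plateau(times, rep(0.4, length(times)))
  expect_true(const$no_rise)
  expect_true(is.na(const$t95))

  expect_error(fit_plateau(c(0, 1, 2), c(1, 2, 3)), "5 time points")
})

test_that("the drift-control stability check flags injected drift", {
  sc_ok <- mk_mini_scenario(mini_bands(0), grid = c(1250, 1550, 0.5))
  gen_ok <- generate_series(sc_ok, seed = 6)
  st_ok <- stability_check(track_series(gen_ok$series, mini_plan()))
  expect_true(st_ok$pass)
  expect_lt(st_ok$max_excursion, 0.3)
  expect_equal(st_ok$band_id, "b_1460")

  sc_bad <- mk_mini_scenario(mini_bands(3), grid = c(1250, 1550, 0.5))
  gen_bad <- generate_series(sc_bad, seed = 6)
  st_bad <- stability_check(track_series(gen_bad$series, mini_plan()), tol = 1)
  expect_false(st_bad$pass)
  expect_gt(st_bad$max_excursion, 2.5)
  expect_lt(st_bad$max_excursion, 3.5)
})

test_that("scenario comparison reports zero spread for identical runs", {
  sc <- mk_mini_scenario(mini_bands(), grid = c(1250, 1550, 0.5),
                         times = c(0, 7.5, 1.5))
  gen <- generate_series(sc, seed = 13)
  sh <- compute_shift(track_series(gen$series, mini_plan()))
  cmp <- compare_scenarios(list(run1 = sh, run2 = sh))
  expect_equal(nrow(cmp), 4L)
  expect_true(all(t0_spread(cmp)$spread_cm1 == 0))
  expect_warning(compare_scenarios(list(only = sh)), "one scenario")
})
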