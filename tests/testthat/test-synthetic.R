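test_that("generation is deterministic for a given seed", {
  st1 <- generate_static("PNPP", noise_sd = 2e-4, seed = 5)
  st2 <- generate_static("PNPP", noise_sd = 2e-4, seed = 5)
  expect_identical(st1$spectrum$absorbance, st2$spectrum$absorbance)
  st3 <- generate_static("PNPP", noise_sd = 2e-4, seed = 6)
  expect_false(identical(st1$spectrum$absorbance, st3$spectrum$absorbance))

  sc <- mk_mini_scenario(list(band_spec("x", 1345, 1340, area_start = 0.3)),
                         grid = c(1300, 1400, 0.5), times = c(0, 4.5, 1.5))
  g1 <- generate_series(sc, seed = 3)
  g2 <- generate_series(sc, seed = 3)
  expect_identical(g1$series$absorbance, g2$series$absorbance)
})

test_that("a species with no reference bands yields pure baseline plus noise", {
  st <- generate_static("NOSPECIES", noise_sd = 1e-4, seed = 2,
                        grid = c(1000, 1100, 0.5))
  expect_equal(nrow(st$truth), 0L)
  expect_lt(max(abs(st$spectrum$absorbance)), 6 * 1e-4)
  expect_lt(abs(stats::sd(st$spectrum$absorbance) - 1e-4) / 1e-4, 0.2)
})

test_that("ensemble noise statistics match the configured level", {
  sc <- mk_mini_scenario(list(band_spec("x", 1050, 1050, area_start = 0.3)),
                         grid = c(1020, 1080, 0.5), times = c(0, 3, 1.5),
                         noise_sd = 2e-4, drift_slope = 0, drift_intercept = 0)
  probes <- matrix(NA_real_, nrow = 200, ncol = 5)
  for (i in 1:200) {
    g <- generate_series(sc, seed = i)
    sl <- series_slice(g$series, 0)
    probes[i, ] <- sl$absorbance[c(5, 30, 60, 90, 115)]
  }
  sds <- apply(probes, 2, stats::sd)
  # a sample SD over 200 draws has relative sampling error ~1/sqrt(2*199)
  # (about 5%); the ensemble mean must sit within 5% of the configured
  # level and each probe point within a 4-sigma band of it
  expect_true(all(abs(sds - 2e-4) / 2e-4 < 4 / sqrt(2 * 199)))
  expect_lt(abs(mean(sds) - 2e-4) / 2e-4, 0.05)
})

test_that("the infinite-rate limit jumps straight to the end state", {
  sc <- mk_mini_scenario(list(band_spec("x", 1340, 1350, area_start = 0.2,
                                        area_end = 0.5)),
                         rate = 1e6, noise_sd = 0,
                         grid = c(1300, 1400, 0.5), times = c(0, 6, 1.5),
                         drift_slope = 0, drift_intercept = 0)
  g <- generate_series(sc, seed = 1)
  ts <- series_times(g$series)
  end_state <- series_slice(g$series, ts[length(ts)])$absorbance
  for (t in ts[-1]) {
    expect_equal(series_slice(g$series, t)$absorbance, end_state, tolerance = 1e-12)
  }
  # and t = 0 is the start state, distinct from the end state
  expect_gt(max(abs(series_slice(g$series, 0)$absorbance - end_state)), 1e-3)
})

test_that("the product-band rise passes through 95% of its plateau at t95", {
  k <- log(20) / 4.5
  sc <- scenario("pi_only",
                 bands = list(band_spec("pi", 1077, 1077,
                                        area_start = 0.02, area_end = 0.52)),
                 grid = c(900, 1250, 0.5), times = c(0, 33, 1.5), rate = k,
                 noise_sd = 0, drift_slope = 0, drift_intercept = 0)
  g <- generate_series(sc, seed = 1)
  expect_equal(g$truth$t95, 4.5, tolerance = 1e-9)
  sl <- series_slice(g$series, 4.5)  # t95 lies on the time grid
  h <- 0.5
  num_area <- sum(sl$absorbance) * h
  truth_area <- 0.02 + 0.95 * 0.5
  # quadrature over a finite window loses the Lorentzian tail mass,
  # ~2*gamma/(pi*X) at X ~ 175 cm-1, about 1%
  expect_lt(abs(num_area - truth_area) / truth_area, 0.02)
})

test_that("scenario files round-trip and reject schema violations", {
  sc <- mk_mini_scenario(list(band_spec("x", 1345, 1340, area_start = 0.3)))
  f <- withr::local_tempfile(fileext = ".yaml")
  save_scenario(sc, f)
  sc2 <- load_scenario(f)
  expect_equal(sc2$name, sc$name)
  expect_equal(sc2$grid, sc$grid)
  expect_equal(sc2$times, sc$times)
  expect_equal(sc2$rate, sc$rate)
  expect_equal(sc2$bands[[1]], sc$bands[[1]])

  y <- yaml::read_yaml(f)
  y$grid$spacing <- -0.5
  yaml::write_yaml(y, f)
  expect_error(load_scenario(f), "spacing")

  y$grid$spacing <- 0.5
  y$frobnicate <- 1
  yaml::write_yaml(y, f)
  expect_error(load_scenario(f), "frobnicate")

  expect_error(load_scenario("missing.yaml"), "not found")
  expect_error(band_spec("w", 1000, 1000, sigma = 30), "bounds")
  expect_error(scenario("bad", list(band_spec("x", 50, 50)),
                        grid = c(400, 4000, 0.5)), "leaves the grid")
})

test_that("packaged scenarios encode the printed trajectory endpoints", {
  mid <- scenario_mid_alp()
  ends <- vapply(mid$bands, function(b) b$center_end, numeric(1))
  names(ends) <- vapply(mid$bands, function(b) b$band_id, character(1))
  expect_equal(unname(ends[c("B1_1510", "B2_1494", "B3_1345", "B4_1294")]),
               c(1510.542, 1494.2, 1343.1, 1290.7))
  high <- scenario_high_alp()
  sh <- vapply(high$bands, function(b) b$center_end - b$center_start, numeric(1))
  names(sh) <- vapply(high$bands, function(b) b$band_id, character(1))
  expect_equal(unname(sh[c("B1_1510", "B2_1494", "B3_1345", "B4_1294")]),
               c(8, 5, -5, -4))
  expect_equal(log(20) / high$rate, 4.5, tolerance = 1e-6)
  low <- scenario_low_alp()
  expect_equal(length(low$bands), 14L)
})
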