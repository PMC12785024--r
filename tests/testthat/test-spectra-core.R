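test_that("spectrum construction validates and normalises the grid", {
  s <- ir_spectrum(c(1002, 1000, 1001), c(0.1, 0.3, 0.2))
  expect_equal(s$wavenumber, c(1000, 1001, 1002))
  expect_equal(s$absorbance, c(0.3, 0.2, 0.1))
  expect_error(ir_spectrum(c(1000, 1000), c(1, 2)), "increasing")
  expect_error(ir_spectrum(c(1000, 1001), c(1, NA)), "finite")
  expect_error(ir_spectrum(1:3, 1:2), "same length")
  # negative absorbance (difference spectra) is preserved
  expect_silent(ir_spectrum(1:5, c(-1, 0, 1, -2, 3)))
})

test_that("csv reader parses, sorts, and names bad lines", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0.1", "1001,0.2", "1002,0.1"), f)
  s <- read_spectrum(f)
  expect_equal(nrow(s), 3)
  expect_equal(s$wavenumber, c(1000, 1001, 1002))

  # reversed file order gives the identical spectrum
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1002,0.1", "1001,0.2", "1000,0.1"), f2)
  s2 <- read_spectrum(f2)
  expect_equal(s2$wavenumber, s$wavenumber)
  expect_equal(s2$absorbance, s$absorbance)

  # header line tolerated, tab delimiter sniffed
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber\tabs", "1000\t0.1", "1001\t0.2"), f3)
  expect_equal(nrow(read_spectrum(f3)), 2)

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1000,0.1", "oops,bad", "1002,0.1"), f4)
  expect_error(read_spectrum(f4), "line 2")

  expect_error(read_spectrum("no/such/file.csv"), "not found")
})

test_that("write/read round-trips preserve the grid and absorbance", {
  set.seed(42)
  nu <- seq(900, 1100, 0.5)
  s <- ir_spectrum(nu, 0.1 + 0.05 * sin(nu / 20) + rnorm(length(nu), 0, 1e-4))
  for (fmt in c("csv", "jcamp")) {
    f <- withr::local_tempfile(fileext = if (fmt == "csv") ".csv" else ".jdx")
    write_spectrum(s, f, format = fmt)
    s2 <- read_spectrum(f)
    expect_equal(s2$wavenumber, s$wavenumber, tolerance = 1e-9)
    expect_lt(max(abs(s2$absorbance - s$absorbance)), 1e-6)
  }
})

test_that("JCAMP reader rejects compressed dialects loudly", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=x", "##JCAMP-DX=4.24", "##FIRSTX=1000", "##LASTX=1003",
               "##NPOINTS=4", "##XYDATA=(X++(Y..Y))",
               "1000 A123 B456", "##END="), f)
  expect_error(read_spectrum(f), "SQZ|AFFN|compressed")
  f2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=x", "##XYDATA=(XY..XY)", "1000,0.1", "##END="), f2)
  expect_error(read_spectrum(f2), "unsupported")
})

test_that("resample interpolates linearly and refuses to extrapolate", {
  nu <- seq(1000, 1100, 1)
  s <- ir_spectrum(nu, nu)  # linear ramp A = nu
  expect_equal(resample(s, nu)$absorbance, s$absorbance)
  g <- seq(1000.25, 1099.75, 0.25)
  r <- resample(s, g)
  expect_equal(r$absorbance, g)  # linearity preserved exactly
  expect_error(resample(s, seq(990, 1010, 1)), "extrapolate")

  # curvature bound: sine resampled to half-spacing, error < (grid spacing)^2
  h <- 0.5
  nu2 <- seq(0, 50, h)
  s2 <- ir_spectrum(nu2 + 1000, sin(nu2))
  g2 <- seq(1000 + h / 2, 1050 - h / 2, h)
  r2 <- resample(s2, g2)
  expect_lt(max(abs(r2$absorbance - sin(g2 - 1000))), h^2)
})

test_that("blank subtraction is pointwise and records provenance", {
  nu <- seq(1000, 1200, 0.5)
  s <- ir_spectrum(nu, 0.2 + 0.1 * exp(-(nu - 1100)^2 / 50))
  expect_true(all(subtract_blank(s, s)$absorbance == 0))
  blank <- ir_spectrum(nu, rep(0.05, length(nu)))
  sp <- ir_spectrum(nu, s$absorbance + 0.05)
  back <- subtract_blank(sp, blank)
  expect_equal(back$absorbance, s$absorbance, tolerance = 1e-12)
  expect_false(is.null(spectrum_meta(back)$blank))
  # disjoint spans error
  far <- ir_spectrum(seq(3000, 3100, 0.5), rep(0, 201))
  expect_error(subtract_blank(s, far), "extrapolate")
})

test_that("window extraction is inclusive, idempotent, and guards sparsity", {
  nu <- seq(1000, 1200, 0.5)
  s <- ir_spectrum(nu, sin(nu))
  expect_equal(extract_window(s, 1000, 1200)$absorbance, s$absorbance)
  w <- extract_window(s, 1050, 1150)
  expect_equal(nrow(w), 201)
  expect_equal(extract_window(w, 1050, 1150)$absorbance, w$absorbance)
  expect_error(extract_window(s, 1100, 1102), "8")
})

test_that("subtract_blank and extract_window commute on shared grids", {
  nu <- seq(1000, 1200, 0.5)
  set.seed(7)
  s <- ir_spectrum(nu, runif(length(nu)))
  b <- ir_spectrum(nu, runif(length(nu)))
  a <- extract_window(subtract_blank(s, b), 1050, 1150)
  z <- subtract_blank(extract_window(s, 1050, 1150), extract_window(b, 1050, 1150))
  expect_equal(a$absorbance, z$absorbance)
})

test_that("series constructor enforces one shared grid and ordered times", {
  nu <- seq(1000, 1100, 0.5)
  s1 <- ir_spectrum(nu, rep(0.1, length(nu)))
  s2 <- ir_spectrum(nu, rep(0.2, length(nu)))
  ser <- ir_series(list(s1, s2), c(0, 1.5))
  expect_equal(series_times(ser), c(0, 1.5))
  s3 <- ir_spectrum(nu + 0.5, rep(0.1, length(nu)))  # off-grid by one step
  expect_error(ir_series(list(s1, s3), c(0, 1.5)), "shared")
  s4 <- ir_spectrum(nu[-5], rep(0.1, length(nu) - 1))  # one point dropped
  expect_error(ir_series(list(s1, s4), c(0, 1.5)), "shared")
  expect_error(ir_series(list(s1, s2), c(1.5, 0)), "increasing")
  expect_error(ir_series(list(s1), 0), "2 time points")
})

test_that("manifest and wide-table series layouts round-trip", {
  nu <- seq(1000, 1050, 0.5)
  ser <- ir_series(list(ir_spectrum(nu, sin(nu)), ir_spectrum(nu, cos(nu))),
                   c(0, 1.5))
  d <- withr::local_tempdir()
  man <- write_series(ser, d)
  ser2 <- read_series(man)
  expect_equal(ser2$absorbance, ser$absorbance, tolerance = 1e-9)
  expect_equal(series_times(ser2), series_times(ser))

  # wide layout
  wf <- file.path(d, "wide.csv")
  writeLines(c("wavenumber,0,1.5",
               sprintf("%.12g,%.12g,%.12g", nu, sin(nu), cos(nu))), wf)
  ser3 <- read_series(wf, layout = "wide")
  expect_equal(ser3$absorbance, ser$absorbance, tolerance = 1e-9)
})
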