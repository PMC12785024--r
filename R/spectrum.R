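#' Construct an infrared spectrum
#'
#' An `ir_spectrum` is a tibble with columns `wavenumber` (cm^-1, strictly
#' ascending) and `absorbance` (AU). Rows are sorted by wavenumber on
#' construction, so files exported high-to-low by a spectrometer are
#' normalised to one internal convention. Negative absorbance is allowed:
#' difference spectra legitimately go below zero.
#'
#' @param wavenumber Numeric vector of wavenumbers in cm^-1.
#' @param absorbance Numeric vector of absorbance values in AU, same length.
#' @param metadata Named list of free-form metadata (species label, source
#'   path, acquisition settings).
#' @return A tibble of class `ir_spectrum` with attribute `ir_meta`.
#' @export
#' @examples
#' s <- ir_spectrum(c(1000, 1000.5, 1001), c(0.1, 0.2, 0.1))
#' s
ir_spectrum <- function(wavenumber, absorbance, metadata = list()) {
  if (length(wavenumber) != length(absorbance)) {
    abort("`wavenumber` and `absorbance` must have the same length.")
  }
  if (anyNA(wavenumber) || anyNA(absorbance) ||
      any(!is.finite(wavenumber)) || any(!is.finite(absorbance))) {
    abort("spectrum values must be finite (no NA/NaN/Inf).")
  }
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  absorbance <- absorbance[ord]
  if (any(diff(wavenumber) <= 0)) {
    abort("`wavenumber` must be strictly increasing after sorting (duplicated grid points found).")
  }
  out <- tibble(wavenumber = wavenumber, absorbance = absorbance)
  class(out) <- c("ir_spectrum", class(out))
  attr(out, "ir_meta") <- metadata
  out
}

#' Coerce a two-column data frame to an `ir_spectrum`
#'
#' @param x A data frame whose first two columns are wavenumber and absorbance.
#' @param metadata Named list of metadata.
#' @return An [ir_spectrum()].
#' @export
as_ir_spectrum <- function(x, metadata = list()) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  ir_spectrum(as.numeric(x[[1]]), as.numeric(x[[2]]), metadata)
}

#' @export
print.ir_spectrum <- function(x, ...) {
  meta <- spectrum_meta(x)
  cat(sprintf("<ir_spectrum> %d points, %.6g-%.6g cm-1%s\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber),
              if (!is.null(meta$species)) paste0(", species: ", meta$species) else ""))
  NextMethod()
}

#' Spectrum metadata
#' @param s An [ir_spectrum()].
#' @return The named metadata list.
#' @export
spectrum_meta <- function(s) attr(s, "ir_meta") %||% list()

set_meta <- function(s, ...) {
  meta <- spectrum_meta(s)
  upd <- list(...)
  meta[names(upd)] <- upd
  attr(s, "ir_meta") <- meta
  s
}

grid_spacing <- function(s) {
  d <- diff(s$wavenumber)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) NA_real_ else stats::median(d)
}

#' Read a spectrum from disk
#'
#' Supports two plain-text formats: delimited text (comma or tab, sniffed;
#' two numeric columns wavenumber, absorbance; one optional header line) and
#' a minimal JCAMP-DX 4.24 subset (`##XYDATA=(X++(Y..Y))` with AFFN numeric
#' records only). Files stored high-to-low wavenumber are sorted ascending.
#' Compressed JCAMP dialects (SQZ/DIF/DUP) are rejected loudly rather than
#' risk mis-parsing.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"jcamp"`.
#' @return An [ir_spectrum()] with source path recorded in its metadata.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  switch(format,
    csv = read_spectrum_csv(path),
    jcamp = read_spectrum_jcamp(path)
  )
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty spectrum file: ", path))
  delim <- if (sum(grepl("\t", lines)) > sum(grepl(",", lines))) "\t" else ","
  parse_row <- function(l) suppressWarnings(as.numeric(strsplit(l, delim, fixed = TRUE)[[1]]))
  first <- parse_row(lines[[1]])
  start <- if (anyNA(first[1:2])) 2L else 1L
  rows <- lapply(lines[start:length(lines)], parse_row)
  bad <- which(vapply(rows, function(r) length(r) < 2 || anyNA(r[1:2]), logical(1)))
  if (length(bad)) {
    abort(sprintf("non-numeric data at line %d of %s", bad[1] + start - 1L, path))
  }
  wn <- vapply(rows, `[`, numeric(1), 1L)
  ab <- vapply(rows, `[`, numeric(1), 2L)
  ir_spectrum(wn, ab, metadata = list(source = path, format = "csv"))
}

# AFFN-only XYDATA reader: each data line is "X Y Y Y ..."; any letter-coded
# (SQZ/DIF/DUP) payload triggers an unsupported-dialect error.
read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^##", key, "="), "", hit[1])) else NULL
  }
  i0 <- grep("^##XYDATA=", lines)
  if (!length(i0)) abort(paste0("no ##XYDATA record in ", path))
  spec <- trimws(sub("^##XYDATA=", "", lines[i0[1]]))
  if (!grepl("\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", spec)) {
    abort(paste0("unsupported JCAMP XYDATA form '", spec,
                 "': only (X++(Y..Y)) AFFN is supported"))
  }
  iend <- grep("^##", lines)
  iend <- iend[iend > i0[1]]
  body <- lines[(i0[1] + 1):(if (length(iend)) iend[1] - 1 else length(lines))]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", body))) {
    abort("compressed JCAMP data (SQZ/DIF/DUP) is not supported; export as AFFN (X++(Y..Y)).")
  }
  xf <- as.numeric(hdr("XFACTOR") %||% "1")
  yf <- as.numeric(hdr("YFACTOR") %||% "1")
  npt <- as.numeric(hdr("NPOINTS"))
  fx <- as.numeric(hdr("FIRSTX")); lx <- as.numeric(hdr("LASTX"))
  if (!length(npt) || is.na(npt) || is.na(fx) || is.na(lx)) {
    abort("JCAMP header must supply FIRSTX, LASTX and NPOINTS.")
  }
  dx <- (lx - fx) / (npt - 1)
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]]))
    if (anyNA(vals)) abort(paste0("non-numeric JCAMP data line: ", ln))
    x1 <- vals[1] * xf
    y <- vals[-1] * yf
    xs <- c(xs, x1 + dx * (seq_along(y) - 1))
    ys <- c(ys, y)
  }
  if (length(ys) != npt) {
    warn(sprintf("JCAMP NPOINTS=%d but %d values read", npt, length(ys)))
  }
  ir_spectrum(xs, ys, metadata = list(
    source = path, format = "jcamp",
    title = hdr("TITLE"), xunits = hdr("XUNITS"), yunits = hdr("YUNITS")
  ))
}

#' Write a spectrum to disk
#'
#' @inheritParams read_spectrum
#' @param s An [ir_spectrum()].
#' @param digits Significant digits written (default preserves 1e-6 AU
#'   round-trips comfortably).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("auto", "csv", "jcamp"), digits = 10) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") {
    writeLines(c("wavenumber,absorbance",
                 sprintf("%.*g,%.*g", digits, s$wavenumber, digits, s$absorbance)),
               path)
  } else {
    d <- grid_spacing(s)
    if (is.na(d)) abort("JCAMP (X++(Y..Y)) requires an evenly spaced grid.")
    meta <- spectrum_meta(s)
    n <- nrow(s)
    per <- 6L
    starts <- seq(1L, n, by = per)
    body <- vapply(starts, function(i) {
      j <- min(i + per - 1L, n)
      paste(c(sprintf("%.*g", digits, s$wavenumber[i]),
              sprintf("%.*g", digits, s$absorbance[i:j])), collapse = " ")
    }, character(1))
    writeLines(c(
      paste0("##TITLE=", meta$title %||% meta$species %||% "spectrum"),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
      "##XFACTOR=1", "##YFACTOR=1",
      sprintf("##FIRSTX=%.*g", digits, s$wavenumber[1]),
      sprintf("##LASTX=%.*g", digits, s$wavenumber[n]),
      sprintf("##NPOINTS=%d", n),
      "##XYDATA=(X++(Y..Y))",
      body,
      "##END="
    ), path)
  }
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; the target grid must lie within the source span
#' (extrapolation is an error). Needed because static references (0.25 cm^-1
#' spacing) and time-resolved series (0.5 cm^-1) are acquired on different
#' grids.
#'
#' @param s An [ir_spectrum()].
#' @param grid Target wavenumber grid (strictly increasing, cm^-1).
#' @return An [ir_spectrum()] on `grid`.
#' @export
resample <- function(s, grid) {
  grid <- sort(as.numeric(grid))
  if (min(grid) < min(s$wavenumber) - 1e-9 || max(grid) > max(s$wavenumber) + 1e-9) {
    abort(sprintf(
      "resample would extrapolate: target [%.6g, %.6g] outside source span [%.6g, %.6g]",
      min(grid), max(grid), min(s$wavenumber), max(s$wavenumber)))
  }
  a <- approx(s$wavenumber, s$absorbance, xout = grid, method = "linear")$y
  ir_spectrum(grid, a, metadata = c(spectrum_meta(s), list(resampled = TRUE)))
}

#' Subtract a blank (buffer) spectrum
#'
#' Pointwise difference after resampling the blank onto the sample grid when
#' grids differ. Corrects for buffer contribution and constant instrumental
#' offsets; the result may be negative.
#'
#' @param sample,blank [ir_spectrum()] objects. The blank span must cover the
#'   sample span if resampling is needed.
#' @return An [ir_spectrum()] with the blank provenance recorded.
#' @export
subtract_blank <- function(sample, blank) {
  same_grid <- nrow(sample) == nrow(blank) &&
    isTRUE(all.equal(sample$wavenumber, blank$wavenumber, tolerance = 1e-10))
  if (!same_grid) blank <- resample(blank, sample$wavenumber)
  out <- ir_spectrum(sample$wavenumber, sample$absorbance - blank$absorbance,
                     metadata = spectrum_meta(sample))
  set_meta(out, blank = spectrum_meta(blank)$source %||% "in-memory blank")
}

#' Extract a spectral window
#'
#' Returns the sub-spectrum with `lo <= wavenumber <= hi` (both bounds
#' inclusive). Windows are required to contain at least 8 grid points so
#' that a band-plus-baseline model remains fittable.
#'
#' @param s An [ir_spectrum()].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return An [ir_spectrum()].
#' @export
extract_window <- function(s, lo, hi) {
  stopifnot(lo < hi)
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (sum(keep) < 8) {
    abort(sprintf("window [%g, %g] contains %d grid points; at least 8 are required for fitting.",
                  lo, hi, sum(keep)))
  }
  out <- s[keep, ]
  class(out) <- class(s)
  attr(out, "ir_meta") <- spectrum_meta(s)
  out
}

#' Construct a time-resolved spectral series
#'
#' A long tibble with columns `time_min`, `wavenumber`, `absorbance`. All
#' member spectra must share one wavenumber grid exactly; times must be
#' strictly increasing with at least two slices. The first time defines
#' t = 0 of the reaction record.
#'
#' @param spectra List of [ir_spectrum()] objects, one per time point.
#' @param times Numeric vector of acquisition times in minutes.
#' @param metadata Named list of series-level metadata.
#' @return A tibble of class `ir_series`.
#' @export
ir_series <- function(spectra, times, metadata = list()) {
  if (length(spectra) != length(times)) abort("one spectrum per time point required.")
  if (length(times) < 2) abort("a series needs at least 2 time points.")
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  ref <- spectra[[1]]$wavenumber
  for (i in seq_along(spectra)) {
    g <- spectra[[i]]$wavenumber
    if (length(g) != length(ref) || any(g != ref)) {
      abort(sprintf("spectrum %d is not on the shared wavenumber grid.", i))
    }
  }
  out <- purrr::map2_dfr(spectra, times, function(s, t) {
    tibble(time_min = t, wavenumber = s$wavenumber, absorbance = s$absorbance)
  })
  class(out) <- c("ir_series", class(out))
  attr(out, "ir_meta") <- metadata
  out
}

#' @export
print.ir_series <- function(x, ...) {
  ts <- series_times(x)
  cat(sprintf("<ir_series> %d time points (%.3g-%.3g min), %d grid points\n",
              length(ts), min(ts), max(ts), length(unique(x$wavenumber))))
  NextMethod()
}

#' Times of a spectral series
#' @param series An [ir_series()].
#' @return Sorted unique acquisition times (minutes).
#' @export
series_times <- function(series) sort(unique(series$time_min))

#' Extract one time slice of a series as a spectrum
#' @param series An [ir_series()].
#' @param time The exact `time_min` value of the slice.
#' @return An [ir_spectrum()].
#' @export
series_slice <- function(series, time) {
  sl <- series[series$time_min == time, ]
  if (nrow(sl) == 0) abort(sprintf("no slice at t = %g min", time))
  ir_spectrum(sl$wavenumber, sl$absorbance,
              metadata = c(spectrum_meta(series), list(time_min = time)))
}

#' Read a spectral series from a manifest or a wide table
#'
#' Two on-disk layouts are accepted: a manifest csv with columns
#' `time_min,path` pointing at per-slice spectrum files (paths resolved
#' relative to the manifest), or a single wide table whose first column is
#' wavenumber and remaining columns are named by acquisition time in
#' minutes.
#'
#' @param path Path to the manifest csv or wide table.
#' @param layout `"manifest"` or `"wide"`.
#' @return An [ir_series()].
#' @export
read_series <- function(path, layout = c("manifest", "wide")) {
  layout <- match.arg(layout)
  if (layout == "manifest") {
    man <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
    if (!all(c("time_min", "path") %in% names(man))) {
      abort("manifest must have columns time_min,path")
    }
    base <- dirname(path)
    specs <- lapply(man$path, function(p) {
      full <- if (file.exists(p)) p else file.path(base, p)
      read_spectrum(full)
    })
    ord <- order(man$time_min)
    ir_series(specs[ord], man$time_min[ord], metadata = list(source = path))
  } else {
    wide <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
    wn <- as.numeric(wide[[1]])
    times <- as.numeric(names(wide)[-1])
    if (anyNA(times)) abort("wide-table column names (after the first) must be times in minutes.")
    specs <- lapply(seq_along(times), function(j) ir_spectrum(wn, as.numeric(wide[[j + 1]])))
    ord <- order(times)
    ir_series(specs[ord], times[ord], metadata = list(source = path))
  }
}

#' Write a spectral series as per-slice files plus a manifest
#'
#' @param series An [ir_series()].
#' @param dir Output directory (created if missing).
#' @param stem File-name stem for the per-slice csv files.
#' @return Path of the manifest csv, invisibly.
#' @export
write_series <- function(series, dir, stem = "slice") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- series_times(series)
  files <- sprintf("%s_%03d.csv", stem, seq_along(ts) - 1L)
  for (i in seq_along(ts)) {
    write_spectrum(series_slice(series, ts[i]), file.path(dir, files[i]), format = "csv")
  }
  man <- file.path(dir, "manifest.csv")
  writeLines(c("time_min,path", sprintf("%.10g,%s", ts, files)), man)
  invisible(man)
}
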