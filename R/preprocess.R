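#' Savitzky-Golay smoothing
#'
#' Light polynomial smoothing used to stabilise derivative-based peak
#' detection before fitting. Smoothing is for initialization only; fits are
#' always performed on the raw (blank-subtracted) absorbance.
#'
#' @param s An [ir_spectrum()].
#' @param window_pts Odd filter length, between 5 and 9 points (default 7).
#' @param order Polynomial order (default 2); must be `< window_pts`.
#' @return An [ir_spectrum()] on the same grid.
#' @export
savgol_smooth <- function(s, window_pts = 7L, order = 2L) {
  check_sg_args(window_pts, order)
  y <- signal::sgolayfilt(s$absorbance, p = order, n = window_pts)
  ir_spectrum(s$wavenumber, y, metadata = spectrum_meta(s))
}

check_sg_args <- function(window_pts, order) {
  if (window_pts %% 2 == 0) {
    abort(sprintf("`window_pts` must be odd (got %d): a symmetric Savitzky-Golay filter needs a centre point.",
                  window_pts))
  }
  if (window_pts < 5 || window_pts > 9) {
    abort("`window_pts` must be 5, 7, or 9.")
  }
  if (order >= window_pts) abort("`order` must be smaller than `window_pts`.")
  invisible(TRUE)
}

#' Savitzky-Golay derivative of a spectrum
#'
#' First or second derivative with respect to wavenumber, scaled by the
#' actual grid spacing (units AU*cm for order 1, AU*cm^2 for order 2).
#'
#' @param s An [ir_spectrum()] on an even grid.
#' @param deriv Derivative order, 1 or 2.
#' @param window_pts,polyorder As in [savgol_smooth()]; `polyorder` must be
#'   at least `deriv`.
#' @return An [ir_spectrum()] whose `absorbance` column holds the derivative.
#' @export
sg_derivative <- function(s, deriv = 2L, window_pts = 7L, polyorder = 2L) {
  stopifnot(deriv %in% c(1L, 2L))
  check_sg_args(window_pts, polyorder)
  if (polyorder < deriv) abort("`polyorder` must be >= `deriv`.")
  h <- grid_spacing(s)
  if (is.na(h)) abort("derivatives require an evenly spaced grid; resample first.")
  y <- signal::sgolayfilt(s$absorbance, p = polyorder, n = window_pts, m = deriv, ts = h)
  ir_spectrum(s$wavenumber, y, metadata = spectrum_meta(s))
}

#' Robust noise estimate from a quiet spectral region
#'
#' Estimates the per-point noise standard deviation as
#' `1.4826 * MAD(diff(A)) / sqrt(2)` within a signal-free window. The
#' first-difference filter removes baseline trends, and the MAD makes the
#' estimate insensitive to the occasional band edge leaking into the window.
#' The default window 1900-2250 cm^-1 sits between the fingerprint region
#' and the X-H stretches, where aqueous-phase spectra carry no bands.
#'
#' @param s An [ir_spectrum()].
#' @param quiet_lo,quiet_hi Bounds of the quiet window (cm^-1).
#' @return Estimated noise SD in AU.
#' @export
estimate_noise <- function(s, quiet_lo = 1900, quiet_hi = 2250) {
  q <- extract_window(s, quiet_lo, quiet_hi)
  d <- diff(q$absorbance)
  stats::mad(d, constant = 1.4826) / sqrt(2)
}

#' Detect candidate peaks for fit initialization
#'
#' Candidates are the union of (i) local maxima of the lightly smoothed
#' signal and (ii) negative-curvature minima of the Savitzky-Golay second
#' derivative, which resolve partially overlapping components that do not
#' produce distinct maxima. Candidates closer than `merge_tol` are merged,
#' keeping the larger prominence (ties: the lower wavenumber). Guesses are
#' for initialization only, never for quantitative reporting.
#'
#' For second-derivative candidates the component height is reconstructed
#' from the curvature: a Gaussian of apex height `H` and width `sigma` has
#' `d2A/dnu2 = -H / sigma^2` at its centre, with `sigma` read off the
#' flanking zero crossings of the second derivative.
#'
#' @param s An [ir_spectrum()].
#' @param lo,hi Window bounds (cm^-1); defaults to the full span.
#' @param min_prominence Minimum prominence in AU; default `5 *` the noise
#'   estimate from [estimate_noise()] when the quiet window is available,
#'   else 5 * the in-window first-difference noise.
#' @param merge_tol Merge tolerance in cm^-1; default 4 (the instrument
#'   resolution -- peaks closer than the resolution are not independently
#'   detectable).
#' @param window_pts,polyorder Smoothing parameters, see [savgol_smooth()].
#' @return A tibble with columns `center`, `height`, `prominence`, `channel`,
#'   sorted by descending prominence.
#' @export
detect_peaks <- function(s, lo = min(s$wavenumber), hi = max(s$wavenumber),
                         min_prominence = NULL, merge_tol = 4,
                         window_pts = 7L, polyorder = 2L) {
  w <- extract_window(s, lo, hi)
  sig <- tryCatch(estimate_noise(s), error = function(e) {
    stats::mad(diff(w$absorbance), constant = 1.4826) / sqrt(2)
  })
  if (is.null(min_prominence)) min_prominence <- 5 * sig
  # numerical floor: smoothing a constant leaves ~1e-17 ripples that must
  # never count as peaks, even at min_prominence = 0
  eps_num <- 1e-10 * max(abs(w$absorbance), 1e-300)
  min_prominence <- max(min_prominence, eps_num)
  sm <- savgol_smooth(w, window_pts, polyorder)
  d2 <- sg_derivative(w, 2L, window_pts, polyorder)
  y <- sm$absorbance
  nu <- sm$wavenumber
  n <- length(y)

  cand <- tibble(center = numeric(0), height = numeric(0),
                 prominence = numeric(0), channel = character(0))

  # channel 1: local maxima of the smoothed signal, classic prominence
  imax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(imax)) {
    prom <- vapply(imax, function(i) {
      lmin <- if (any(y[seq_len(i - 1)] > y[i])) {
        j <- max(which(y[seq_len(i - 1)] > y[i]))
        min(y[j:i])
      } else min(y[1:i])
      rmin <- if (any(y[(i + 1):n] > y[i])) {
        j <- i + min(which(y[(i + 1):n] > y[i]))
        min(y[i:j])
      } else min(y[i:n])
      y[i] - max(lmin, rmin)
    }, numeric(1))
    base <- y[imax] - prom
    cand <- bind_rows(cand, tibble(center = nu[imax], height = prom,
                                   prominence = prom, channel = "signal"))
  }

  # channel 2: negative-curvature minima of the second derivative. A dip
  # only counts when it is deeper than 5x the second-derivative noise
  # floor, computed exactly from the filter coefficients (the derivative
  # filter amplifies white noise by sqrt(sum(c^2))/h^2).
  z <- d2$absorbance
  h <- grid_spacing(w)
  mid <- (window_pts + 1L) %/% 2L
  crow <- signal::sgolay(p = polyorder, n = window_pts, m = 2L)[mid, ]
  d2_noise <- sig * sqrt(sum(crow^2)) / h^2
  imin <- which(diff(sign(diff(z))) == 2) + 1L
  imin <- imin[z[imin] < -max(5 * d2_noise, 1e-10 * max(abs(z), 1e-300))]
  if (length(imin)) {
    sigma_loc <- vapply(imin, function(i) {
      left <- which(z[seq_len(i)] >= 0)
      right <- which(z[i:n] >= 0)
      il <- if (length(left)) max(left) else 1L
      ir <- if (length(right)) i + min(right) - 1L else n
      max((nu[ir] - nu[il]) / 2, h)
    }, numeric(1))
    # a curvature dip wider than the largest fittable Gaussian width is
    # broad background structure (e.g. an X-H envelope), not a band
    keep <- sigma_loc <= 15
    imin <- imin[keep]; sigma_loc <- sigma_loc[keep]
    est <- -z[imin] * sigma_loc^2
    cand <- bind_rows(cand, tibble(center = nu[imin], height = est,
                                   prominence = est, channel = "curvature"))
  }

  cand <- cand[cand$prominence >= min_prominence, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(center = numeric(0), height = numeric(0),
                  prominence = numeric(0), channel = character(0)))
  }

  # merge candidates closer than merge_tol; keep larger prominence,
  # ties resolved toward the lower wavenumber
  cand <- cand[order(-cand$prominence, cand$center), ]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0 || all(abs(kept$center - cand$center[i]) >= merge_tol)) {
      kept <- bind_rows(kept, cand[i, ])
    }
  }
  kept[order(-kept$prominence, kept$center), ]
}
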