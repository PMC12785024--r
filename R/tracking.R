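#' Default tracking plan for the PNPP hydrolysis assay
#'
#' One row per tracked band: the reference centre, the tracking tolerance,
#' and the fitting window. Bands sharing a window are fitted jointly in one
#' multi-component model. The four reaction markers are the nitro/aromatic
#' pair (1510, 1494 cm^-1, blue-shifting) and the substrate-side
#' fingerprint pair (1345, 1294 cm^-1, red-shifting); the 1077 cm^-1
#' inorganic-phosphate band is the product readout (the ~990 cm^-1 region
#' is avoided because it overlaps protein ~925 cm^-1 and the broad
#' phosphate ~847 cm^-1 tail), and the 1460 cm^-1 CH2 scissoring band is a
#' drift control expected to stay put.
#'
#' @param refs Optional tibble from [fit_static_references()] used to
#'   replace the nominal reference centres by fitted ones (matched by
#'   nearest centre within the tracking tolerance).
#' @return A tibble with columns `band_id, ref_center, track_tol,
#'   window_lo, window_hi, role`.
#' @export
default_track_plan <- function(refs = NULL) {
  plan <- tibble(
    band_id   = c("B1_1510", "B2_1494", "B3_1345", "B4_1294",
                  "pi_1077", "ctx_1045", "ctrl_1460"),
    ref_center = c(1510, 1494, 1345, 1294, 1077, 1045, 1460),
    track_tol = c(10, 7.5, 7.5, 7.5, 7.5, 6, 6),
    window_lo = c(1475, 1475, 1322, 1270, 1028, 1028, 1442),
    window_hi = c(1535, 1535, 1368, 1318, 1105, 1105, 1477),
    role      = c("marker", "marker", "marker", "marker",
                  "product", "context", "control")
  )
  if (!is.null(refs)) {
    ok <- refs[!refs$missing, ]
    for (i in seq_len(nrow(plan))) {
      d <- abs(ok$fitted_center - plan$ref_center[i])
      if (length(d) && min(d) <= plan$track_tol[i]) {
        plan$ref_center[i] <- ok$fitted_center[which.min(d)]
      }
    }
  }
  plan
}

#' Track band trajectories across a reaction series
#'
#' Every time slice is fitted independently -- no information flows between
#' slices except the shared reference constraints -- following the windowed
#' Voigt-plus-linear-baseline workflow. Bands sharing a window are fitted as
#' one multi-component model, and fitted components are assigned to band
#' ids by minimum total centre distance, which prevents label switching
#' along the series. A slice that fails to converge for a window is flagged
#' and the trajectory continues.
#'
#' @param series An [ir_series()].
#' @param plan A tracking plan, see [default_track_plan()].
#' @param fc Width/area constraints ([fit_constraints()]); the centre
#'   tolerance is taken per band from the plan.
#' @param family Line-shape family (voigt by default, as selected by
#'   AIC/BIC on this class of data).
#' @return A tibble of class `peak_trajectories` with one row per
#'   (band, time): fitted centre, area, apex height, widths, 1-sigma
#'   uncertainties and convergence flags. Per-slice fits are retained in
#'   attribute `fits` for audit.
#' @export
track_series <- function(series, plan = default_track_plan(),
                         fc = fit_constraints(), family = "voigt") {
  stopifnot(all(c("band_id", "ref_center", "track_tol", "window_lo", "window_hi")
                %in% names(plan)))
  ts <- series_times(series)
  wkey <- paste(plan$window_lo, plan$window_hi)
  rows <- list()
  fits <- list()
  for (t in ts) {
    sl <- series_slice(series, t)
    noise <- tryCatch(estimate_noise(sl), error = function(e) {
      stats::mad(diff(sl$absorbance), constant = 1.4826) / sqrt(2)
    })
    for (wk in unique(wkey)) {
      grp <- plan[wkey == wk, ]
      grp <- grp[order(grp$ref_center), ]
      fc_g <- fc
      fc_g$center_tol <- max(grp$track_tol)
      # initialize centres from derivative-based detection where a candidate
      # falls inside the band's tolerance; the bound anchors stay at the
      # reference centres
      pk <- tryCatch(
        detect_peaks(sl, grp$window_lo[1], grp$window_hi[1],
                     min_prominence = 3 * noise),
        error = function(e) NULL)
      centers0 <- grp$ref_center
      if (!is.null(pk) && nrow(pk) > 0) {
        used <- rep(FALSE, nrow(pk))
        for (i in seq_len(nrow(grp))) {
          d <- abs(pk$center - grp$ref_center[i])
          d[used] <- Inf
          if (min(d) <= grp$track_tol[i]) {
            j <- which.min(d)
            centers0[i] <- pk$center[j]
            used[j] <- TRUE
          }
        }
      }
      if (is.unsorted(centers0)) centers0 <- grp$ref_center
      m0 <- initial_window_model(sl, grp$window_lo[1], grp$window_hi[1],
                                 k = nrow(grp), family = family,
                                 centers = centers0)
      fit <- tryCatch(fit_window(sl, m0, fc_g, noise, ref_centers = grp$ref_center),
                      error = function(e) NULL)
      if (is.null(fit)) {
        rows[[length(rows) + 1]] <- tibble(
          band_id = grp$band_id, time_min = t,
          center = NA_real_, center_sd = NA_real_,
          area = NA_real_, area_sd = NA_real_, height = NA_real_,
          sigma = NA_real_, gamma = NA_real_, converged = FALSE, rss = NA_real_)
        next
      }
      fits[[paste(t, wk)]] <- fit
      cm <- fit$model$components
      idx <- permute_match(cm$center, grp$ref_center)
      csd <- component_sd(fit, "center")
      asd <- component_sd(fit, "area")
      rows[[length(rows) + 1]] <- tibble(
        band_id = grp$band_id, time_min = t,
        center = cm$center[idx], center_sd = csd[idx],
        area = cm$area[idx], area_sd = asd[idx],
        height = cm$height[idx],
        sigma = cm$sigma[idx], gamma = cm$gamma[idx],
        converged = fit$converged, rss = fit$rss)
    }
  }
  out <- arrange(bind_rows(rows), .data$band_id, .data$time_min)
  class(out) <- c("peak_trajectories", class(out))
  attr(out, "plan") <- plan
  attr(out, "fits") <- fits
  out
}

#' Net centre shift of tracked bands
#'
#' For each band, the endpoint difference
#' `delta = center(t_last) - center(t_first)` over converged time points
#' (positive = blue shift), with the propagated 1-sigma uncertainty
#' `sqrt(sd_first^2 + sd_last^2)`. Endpoint differences (rather than slopes
#' of a smoothed trajectory) match how concentration-series shifts are
#' conventionally reported.
#'
#' @param traj A `peak_trajectories` tibble from [track_series()] (or any
#'   tibble with `band_id, time_min, center, center_sd, converged`).
#' @return A tibble with one row per band: `band_id, start_cm1, end_cm1,
#'   delta_cm1, delta_sd, n_converged`.
#' @export
compute_shift <- function(traj) {
  bands <- unique(traj$band_id)
  out <- lapply(bands, function(b) {
    tb <- traj[traj$band_id == b & traj$converged & !is.na(traj$center), ]
    if (nrow(tb) < 2) {
      abort(sprintf("band %s has fewer than 2 converged time points; no shift can be computed.", b))
    }
    tb <- tb[order(tb$time_min), ]
    tibble(band_id = b,
           start_cm1 = tb$center[1], end_cm1 = tb$center[nrow(tb)],
           delta_cm1 = tb$center[nrow(tb)] - tb$center[1],
           delta_sd = sqrt(tb$center_sd[1]^2 + tb$center_sd[nrow(tb)]^2),
           n_converged = nrow(tb))
  })
  bind_rows(out)
}

#' Intensity-redistribution analysis of two overlapping components
#'
#' Fits each time slice with two Voigt components whose centres are tightly
#' constrained (default +/- 2 cm^-1) around fixed positions, leaving areas
#' and widths free. Reports per-slice areas and heights, the product
#' fraction `f(t) = A_hi / (A_lo + A_hi)`, and the apparent single-peak
#' centroid of the baseline-subtracted window -- demonstrating that a
#' visually drifting composite band can be explained by amplitude exchange
#' between two stationary components.
#'
#' @param series An [ir_series()].
#' @param lo,hi Analysis window (cm^-1).
#' @param centers Length-2 fixed component centres `(nu_lo, nu_hi)`.
#' @param center_tol Allowed centre excursion (cm^-1, default 2).
#' @param fc Width/area constraints.
#' @return An object of class `redistribution_result` whose `table` element
#'   has one row per slice.
#' @export
redistribution_analysis <- function(series, lo = 1598, hi = 1627,
                                    centers = c(1606, 1617),
                                    center_tol = 2, fc = fit_constraints()) {
  stopifnot(length(centers) == 2, centers[1] < centers[2])
  fc$center_tol <- center_tol
  ts <- series_times(series)
  rows <- list()
  for (t in ts) {
    sl <- series_slice(series, t)
    noise <- tryCatch(estimate_noise(sl), error = function(e) {
      stats::mad(diff(sl$absorbance), constant = 1.4826) / sqrt(2)
    })
    m0 <- initial_window_model(sl, lo, hi, k = 2, family = "voigt",
                               centers = centers)
    fit <- tryCatch(fit_window(sl, m0, fc, noise), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[length(rows) + 1]] <- tibble(
        time_min = t, center_lo = NA_real_, center_hi = NA_real_,
        area_lo = NA_real_, area_hi = NA_real_,
        height_lo = NA_real_, height_hi = NA_real_,
        f = NA_real_, centroid = NA_real_, converged = FALSE)
      next
    }
    cm <- fit$model$components
    idx <- permute_match(cm$center, centers)
    w <- fit$data
    bl <- fit$model$baseline[1] + fit$model$baseline[2] * w$wavenumber
    sig <- pmax(w$absorbance - bl, 0)
    centroid <- sum(w$wavenumber * sig) / sum(sig)
    a <- cm$area[idx]
    rows[[length(rows) + 1]] <- tibble(
      time_min = t, center_lo = cm$center[idx][1], center_hi = cm$center[idx][2],
      area_lo = a[1], area_hi = a[2],
      height_lo = cm$height[idx][1], height_hi = cm$height[idx][2],
      f = a[2] / (a[1] + a[2]), centroid = centroid, converged = fit$converged)
  }
  tbl <- bind_rows(rows)
  ok <- tbl[tbl$converged, ]
  structure(list(
    table = tbl, centers = centers, window = c(lo, hi),
    centroid_drift = if (nrow(ok) >= 2) ok$centroid[nrow(ok)] - ok$centroid[1] else NA_real_,
    max_center_motion = if (nrow(ok) >= 2) {
      max(abs(ok$center_lo - ok$center_lo[1]), abs(ok$center_hi - ok$center_hi[1]))
    } else NA_real_
  ), class = "redistribution_result")
}

#' @export
print.redistribution_result <- function(x, ...) {
  cat(sprintf("<redistribution_result> components %.1f / %.1f cm-1 in [%g, %g]\n",
              x$centers[1], x$centers[2], x$window[1], x$window[2]))
  cat(sprintf("apparent centroid drift: %.2f cm-1; max component centre motion: %.3f cm-1\n",
              x$centroid_drift, x$max_center_motion))
  invisible(x)
}

#' Exponential-plateau fit of a product-band amplitude trajectory
#'
#' Least-squares fit of `A(t) = A0 + Ainf * (1 - exp(-k t))`. The
#' completion time is reported as `t95 = ln(20) / k`, the time at which the
#' rise reaches 95% of its plateau. When the fitted rise amplitude does not
#' exceed twice the noise scale (or the rate collapses to zero) the result
#' carries a `no_rise` flag instead of kinetic parameters.
#'
#' @param times Times in minutes (at least 5).
#' @param amplitudes Band amplitudes (fitted areas) per slice.
#' @param noise_sd Optional amplitude noise scale used for the no-rise
#'   check; default is the robust SD of first differences.
#' @return An object of class `plateau_fit` with elements `a0`, `ainf`,
#'   `k` (min^-1), `t95` (min), `rss`, `no_rise`, `data`.
#' @export
fit_plateau <- function(times, amplitudes, noise_sd = NULL) {
  stopifnot(length(times) == length(amplitudes))
  if (length(times) < 5) abort("plateau fitting needs at least 5 time points.")
  ok <- is.finite(times) & is.finite(amplitudes)
  times <- times[ok]; amplitudes <- amplitudes[ok]
  if (length(times) < 5) abort("plateau fitting needs at least 5 finite time points.")
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(amplitudes), constant = 1.4826) / sqrt(2)
  }
  a0_0 <- amplitudes[1]
  ainf_0 <- max(amplitudes[length(amplitudes)] - a0_0, 1e-12)
  # initial rate from the half-rise time
  half <- a0_0 + ainf_0 / 2
  i_half <- which(amplitudes >= half)
  k0 <- if (length(i_half) && times[i_half[1]] > 0) log(2) / times[i_half[1]] else 0.5
  fn <- function(p) p[1] + p[2] * (1 - exp(-p[3] * times)) - amplitudes
  fit <- minpack.lm::nls.lm(
    par = c(a0_0, ainf_0, k0),
    lower = c(-Inf, 0, 1e-8), upper = c(Inf, Inf, Inf), fn = fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 400))
  p <- fit$par
  no_rise <- p[2] <= 2 * noise_sd + 1e-12 || p[3] <= 1e-6
  structure(list(
    a0 = p[1], ainf = p[2], k = p[3],
    t95 = if (no_rise) NA_real_ else log(20) / p[3],
    rss = fit$deviance, no_rise = no_rise,
    data = tibble(time_min = times, amplitude = amplitudes,
                  fitted = fn(p) + amplitudes)
  ), class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  if (x$no_rise) {
    cat("<plateau_fit> no significant rise detected (no-rise flag)\n")
  } else {
    cat(sprintf("<plateau_fit> A0 = %.4g, Ainf = %.4g, k = %.4g min-1, t95 = %.3g min\n",
                x$a0, x$ainf, x$k, x$t95))
  }
  invisible(x)
}

#' Drift-control stability check
#'
#' Verifies that a designated control band (by default the 1460 cm^-1 CH2
#' scissoring band, present in both the enzyme and the product and expected
#' to show negligible centre motion) stays within `tol` of its initial
#' fitted centre. Run with every tracking analysis as a guard against
#' baseline or film-thickness drift masquerading as chemistry.
#'
#' @param traj A `peak_trajectories` tibble.
#' @param band_id Control band id; default picks the plan's `control` role
#'   band, else the band whose reference is closest to 1460 cm^-1.
#' @param tol Maximum allowed excursion (cm^-1).
#' @return A list of class `stability_check`: `pass`, `max_excursion`,
#'   `band_id`, `tol`.
#' @export
stability_check <- function(traj, band_id = NULL, tol = 1) {
  if (is.null(band_id)) {
    plan <- attr(traj, "plan")
    band_id <- if (!is.null(plan) && any(plan$role == "control")) {
      plan$band_id[plan$role == "control"][1]
    } else {
      bands <- unique(traj$band_id)
      means <- vapply(bands, function(b) mean(traj$center[traj$band_id == b], na.rm = TRUE),
                      numeric(1))
      bands[which.min(abs(means - 1460))]
    }
  }
  tb <- traj[traj$band_id == band_id & traj$converged & !is.na(traj$center), ]
  if (nrow(tb) == 0) abort(sprintf("no converged points for control band %s", band_id))
  tb <- tb[order(tb$time_min), ]
  exc <- max(abs(tb$center - tb$center[1]))
  structure(list(pass = exc <= tol, max_excursion = exc,
                 band_id = band_id, tol = tol),
            class = "stability_check")
}

#' @export
print.stability_check <- function(x, ...) {
  cat(sprintf("<stability_check> band %s: %s (max excursion %.3f cm-1, tol %.3g)\n",
              x$band_id, if (x$pass) "PASS" else "FAIL", x$max_excursion, x$tol))
  invisible(x)
}

#' Compare tracked shifts across scenarios or conditions
#'
#' Stacks per-band shift summaries from two or more tracked runs and
#' reports, per band, the spread of starting centres across runs (the
#' t0-consistency statistic: markers are expected to share common starting
#' positions while shift amplitudes scale with enzyme loading).
#'
#' @param shifts Named list of [compute_shift()] tibbles (or
#'   `peak_trajectories`, which are summarised on the fly); names label the
#'   scenarios.
#' @return A tibble of class `shift_comparison` (`scenario, band_id,
#'   start_cm1, end_cm1, delta_cm1, delta_sd`) with attribute `t0_spread`
#'   (per-band `spread_cm1`, `spread_sd`).
#' @export
compare_scenarios <- function(shifts) {
  stopifnot(is.list(shifts), !is.null(names(shifts)))
  if (length(shifts) < 2) {
    warn("only one scenario supplied; no between-scenario statistics computed.")
  }
  tbl <- bind_rows(lapply(names(shifts), function(nm) {
    x <- shifts[[nm]]
    if (inherits(x, "peak_trajectories")) x <- compute_shift(x)
    mutate(x, scenario = nm)
  }))
  tbl <- select(tbl, "scenario", "band_id", "start_cm1", "end_cm1",
                "delta_cm1", "delta_sd", dplyr::everything())
  spread <- tbl |>
    group_by(.data$band_id) |>
    summarise(spread_cm1 = max(.data$start_cm1) - min(.data$start_cm1),
              spread_sd = sqrt(sum(.data$delta_sd^2, na.rm = TRUE)),
              n_scenarios = dplyr::n(), .groups = "drop")
  class(tbl) <- c("shift_comparison", class(tbl))
  attr(tbl, "t0_spread") <- spread
  tbl
}

#' t0-consistency statistic of a shift comparison
#' @param comparison A [compare_scenarios()] result.
#' @return The per-band starting-centre spread tibble.
#' @export
t0_spread <- function(comparison) attr(comparison, "t0_spread")
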