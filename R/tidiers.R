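#' Tidy a fitted window model
#'
#' One row per fitted component with area, centre, widths, apex height,
#' FWHM and 1-sigma uncertainties.
#'
#' @param x A `window_fit` from [fit_window()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy window_fit
#' @export
tidy.window_fit <- function(x, ...) {
  cm <- x$model$components
  tibble(
    component = seq_len(nrow(cm)),
    area = cm$area, area_sd = component_sd(x, "area"),
    center = cm$center, center_sd = component_sd(x, "center"),
    sigma = cm$sigma, gamma = cm$gamma,
    height = cm$height,
    fwhm = vapply(seq_len(nrow(cm)),
                  function(i) voigt_fwhm(cm$sigma[i], cm$gamma[i]), numeric(1))
  )
}

#' Glance at a fitted window model
#'
#' @param x A `window_fit`.
#' @param ... Unused.
#' @return A one-row tibble: window, family, component count, rss, AIC/BIC,
#'   noise SD, convergence.
#' @method glance window_fit
#' @export
glance.window_fit <- function(x, ...) {
  tibble(window_lo = x$model$lo, window_hi = x$model$hi,
         family = x$model$family, n_components = nrow(x$model$components),
         n = x$ic$n, k = x$ic$k, rss = x$rss,
         aic = x$ic$aic, bic = x$ic$bic,
         noise_sd = x$noise_sd, converged = x$converged,
         n_starts_used = x$n_starts_used)
}

#' Augmented data of a fitted window model
#'
#' @param x A `window_fit`.
#' @param ... Unused.
#' @return The windowed data with `.fitted` and `.resid` columns.
#' @method augment window_fit
#' @export
augment.window_fit <- function(x, ...) {
  tibble(wavenumber = x$data$wavenumber,
         absorbance = x$data$absorbance,
         .fitted = x$data$absorbance + x$residuals,
         .resid = -x$residuals)
}

#' Tidy a plateau fit
#' @param x A `plateau_fit` from [fit_plateau()].
#' @param ... Unused.
#' @return One row per parameter (`a0`, `ainf`, `k`, `t95`).
#' @method tidy plateau_fit
#' @export
tidy.plateau_fit <- function(x, ...) {
  tibble(term = c("a0", "ainf", "k", "t95"),
         estimate = c(x$a0, x$ainf, x$k, x$t95))
}

#' Glance at a plateau fit
#' @param x A `plateau_fit`.
#' @param ... Unused.
#' @return One-row tibble with kinetic parameters and the no-rise flag.
#' @method glance plateau_fit
#' @export
glance.plateau_fit <- function(x, ...) {
  tibble(k = x$k, t95 = x$t95, a0 = x$a0, ainf = x$ainf,
         rss = x$rss, n = nrow(x$data), no_rise = x$no_rise)
}

#' Tidy a redistribution analysis
#' @param x A `redistribution_result`.
#' @param ... Unused.
#' @return The per-slice table.
#' @method tidy redistribution_result
#' @export
tidy.redistribution_result <- function(x, ...) x$table

#' Glance at a redistribution analysis
#' @param x A `redistribution_result`.
#' @param ... Unused.
#' @return One-row tibble: apparent centroid drift vs maximum true
#'   component-centre motion.
#' @method glance redistribution_result
#' @export
glance.redistribution_result <- function(x, ...) {
  tibble(center_lo = x$centers[1], center_hi = x$centers[2],
         centroid_drift = x$centroid_drift,
         max_center_motion = x$max_center_motion,
         n_slices = nrow(x$table))
}
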