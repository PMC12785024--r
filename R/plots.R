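#' Plot a spectrum
#'
#' Wavenumber axis reversed for display, following spectroscopic
#' convention (the data themselves are always stored ascending).
#'
#' @param object An [ir_spectrum()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ir_spectrum
#' @export
autoplot.ir_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wavenumber, y = .data$absorbance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a reaction series
#'
#' @param object An [ir_series()].
#' @param ... Unused.
#' @return A ggplot with one line per time slice, coloured by time.
#' @method autoplot ir_series
#' @export
autoplot.ir_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$wavenumber, y = .data$absorbance,
                               group = .data$time_min, colour = .data$time_min)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_viridis_c(name = "t (min)") +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted window: data, total model, components, residuals
#'
#' @param object A `window_fit` from [fit_window()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot window_fit
#' @export
autoplot.window_fit <- function(object, ...) {
  aug <- augment(object)
  cm <- object$model$components
  comp <- purrr::map_dfr(seq_len(nrow(cm)), function(i) {
    tibble(component = factor(i), wavenumber = aug$wavenumber,
           absorbance = object$model$baseline[1] +
             object$model$baseline[2] * aug$wavenumber +
             voigt_profile(aug$wavenumber, cm$center[i], cm$sigma[i],
                           cm$gamma[i], cm$area[i]))
  })
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$wavenumber)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$absorbance), size = 0.5, alpha = 0.6) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$absorbance, colour = .data$component),
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "black") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(tilde(nu) ~ (cm^-1)), y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' Plot tracked peak-centre trajectories
#'
#' One panel per band: fitted centre against time with 1-sigma error bars.
#'
#' @param traj A `peak_trajectories` tibble from [track_series()].
#' @param bands Optional subset of band ids.
#' @return A ggplot.
#' @export
plot_trajectories <- function(traj, bands = NULL) {
  tb <- as_tibble(traj)
  if (!is.null(bands)) tb <- tb[tb$band_id %in% bands, ]
  ggplot2::ggplot(tb[tb$converged, ],
                  ggplot2::aes(x = .data$time_min, y = .data$center)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$center - .data$center_sd,
                                        ymax = .data$center + .data$center_sd),
                           width = 0, alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~band_id, scales = "free_y") +
    ggplot2::labs(x = "t (min)", y = expression(nu[0] ~ (cm^-1))) +
    ggplot2::theme_minimal()
}

#' @method autoplot peak_trajectories
#' @export
autoplot.peak_trajectories <- function(object, ...) plot_trajectories(object)

#' Plot an exponential-plateau kinetic fit
#'
#' Data, fitted rise, and a dashed vertical line at t95 (the
#' reaction-completion marker).
#'
#' @param object A `plateau_fit` from [fit_plateau()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plateau_fit
#' @export
autoplot.plateau_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$amplitude)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "t (min)", y = expression("Band area" ~ (AU %.% cm^-1))) +
    ggplot2::theme_minimal()
  if (!object$no_rise) {
    p <- p + ggplot2::geom_vline(xintercept = object$t95, linetype = 2)
  }
  p
}

#' Plot an intensity-redistribution analysis
#'
#' Component areas and the apparent centroid against time: the composite
#' band's centroid drifts while the two component centres stay put.
#'
#' @param object A `redistribution_result`.
#' @param ... Unused.
#' @return A ggplot (patchable list of two panels combined with facets).
#' @method autoplot redistribution_result
#' @export
autoplot.redistribution_result <- function(object, ...) {
  tb <- object$table[object$table$converged, ]
  long <- tidyr::pivot_longer(
    tb[, c("time_min", "area_lo", "area_hi", "centroid")],
    cols = c("area_lo", "area_hi", "centroid"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "t (min)") +
    ggplot2::theme_minimal()
}
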