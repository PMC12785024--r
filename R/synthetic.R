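#' Specify one band trajectory of a synthetic scenario
#'
#' Centres and areas evolve by exponential approach sharing the scenario's
#' conversion rate k (or a band-specific `rate`):
#' `center(t) = center_end - (center_end - center_start) * exp(-k t)` and
#' analogously for areas, so a rising product band with
#' `area_start = A0, area_end = A0 + Ainf` follows
#' `A(t) = A0 + Ainf * (1 - exp(-k t))` exactly.
#'
#' @param band_id Band identifier.
#' @param center_start,center_end Centre trajectory endpoints, cm^-1.
#' @param area_start,area_end Area trajectory endpoints, AU*cm^-1 (>= 0).
#' @param sigma,gamma Voigt widths, cm^-1. For `role = "band"` these must
#'   lie inside the fitting bounds (sigma 1-15, gamma 1-20); `"envelope"`
#'   components (broad X-H background features, sigma up to ~120) are
#'   exempt because they are never fitted.
#' @param role `"band"` or `"envelope"`.
#' @param rate Optional band-specific rate (min^-1); default shares the
#'   scenario rate.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(band_id, center_start, center_end = center_start,
                      area_start = 0.3, area_end = area_start,
                      sigma = 3.5, gamma = 3,
                      role = c("band", "envelope"), rate = NULL) {
  role <- match.arg(role)
  if (area_start < 0 || area_end < 0) abort("areas must be >= 0.")
  if (role == "band" &&
      (sigma < 1 || sigma > 15 || gamma < 1 || gamma > 20)) {
    abort(sprintf("band %s widths (sigma=%g, gamma=%g) outside the fitting bounds sigma 1-15, gamma 1-20.",
                  band_id, sigma, gamma))
  }
  structure(list(band_id = band_id,
                 center_start = center_start, center_end = center_end,
                 area_start = area_start, area_end = area_end,
                 sigma = sigma, gamma = gamma, role = role, rate = rate),
            class = "band_spec")
}

scenario_fields <- c("name", "grid", "times", "bands", "rate", "noise_sd",
                     "drift", "metadata")

#' Define a synthetic reaction scenario
#'
#' Carries everything the generator needs: the wavenumber grid, the time
#' grid (default 0-33 min in 1.5 min steps, the acquisition cadence of the
#' assay), the band trajectory specifications, the shared first-order
#' conversion rate, the noise level, and the per-slice linear baseline
#' drift statistics.
#'
#' @param name Scenario name.
#' @param bands List of [band_spec()] objects.
#' @param grid Length-3 numeric `(lo, hi, spacing)` in cm^-1 (spacing 0.25
#'   for static-style, 0.5 for time-resolved-style grids).
#' @param times Length-3 numeric `(t0, t_end, step)` in minutes.
#' @param rate Shared conversion rate k, min^-1.
#' @param noise_sd Additive i.i.d. Gaussian noise SD, AU.
#' @param drift_slope,drift_intercept Half-ranges of the per-slice uniform
#'   draws for the linear baseline drift (AU/cm^-1 and AU).
#' @param metadata Named list (e.g. enzyme/substrate concentrations).
#' @return A list of class `ftir_scenario`.
#' @export
scenario <- function(name, bands,
                     grid = c(400, 4000, 0.5),
                     times = c(0, 33, 1.5),
                     rate = log(20) / 4.5,
                     noise_sd = 2e-4,
                     drift_slope = 1e-6, drift_intercept = 5e-4,
                     metadata = list()) {
  stopifnot(length(grid) == 3, length(times) == 3)
  if (grid[3] <= 0) abort("grid spacing must be positive.")
  if (times[3] <= 0) abort("time step must be positive.")
  if (grid[1] >= grid[2]) abort("grid lo must be below hi.")
  if (rate <= 0) abort("`rate` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  bands <- lapply(bands, function(b) {
    if (!inherits(b, "band_spec")) do.call(band_spec, b) else b
  })
  for (b in bands) {
    if (b$center_start < grid[1] || b$center_start > grid[2] ||
        b$center_end < grid[1] || b$center_end > grid[2]) {
      abort(sprintf("band %s centre trajectory leaves the grid [%g, %g].",
                    b$band_id, grid[1], grid[2]))
    }
  }
  structure(list(name = name, grid = grid, times = times, bands = bands,
                 rate = rate, noise_sd = noise_sd,
                 drift = c(slope = drift_slope, intercept = drift_intercept),
                 metadata = metadata),
            class = "ftir_scenario")
}

#' @export
print.ftir_scenario <- function(x, ...) {
  cat(sprintf("<ftir_scenario> %s: %d bands, grid %g-%g @ %g cm-1, t %g-%g @ %g min, k = %.4g min-1\n",
              x$name, length(x$bands), x$grid[1], x$grid[2], x$grid[3],
              x$times[1], x$times[2], x$times[3], x$rate))
  invisible(x)
}

band_at_time <- function(b, t, k_default) {
  k <- b$rate %||% k_default
  dec <- exp(-k * t)
  list(center = b$center_end - (b$center_end - b$center_start) * dec,
       area = b$area_end - (b$area_end - b$area_start) * dec)
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a static reference spectrum with known ground truth
#'
#' Sums area-parameterised Voigt bands for one species of the reference
#' table (role `"band"` rows), optionally adds a broad X-H envelope
#' (modelled as a wide Voigt centred on the species' X-H feature --
#' realistic background, never fitted), a linear baseline, and i.i.d.
#' Gaussian noise. Deterministic for a given seed.
#'
#' @param species Species name present in the reference table.
#' @param ref_table A [reference_bands()] table.
#' @param grid Length-3 `(lo, hi, spacing)`; default static-acquisition
#'   grid 400-4000 cm^-1 at 0.25 cm^-1.
#' @param areas Named numeric vector of band areas by `band_id`; default
#'   0.5 AU*cm^-1 each.
#' @param noise_sd Noise SD (AU).
#' @param include_envelope Add the broad X-H envelope (ALP and PNP only).
#' @param include_context Also include the species' `role = "context"`
#'   bands.
#' @param seed Optional integer seed.
#' @return A list with `spectrum` (an [ir_spectrum()]) and `truth` (a
#'   tibble of every generating band parameter).
#' @export
generate_static <- function(species, ref_table = reference_bands(),
                            grid = c(400, 4000, 0.25),
                            areas = NULL, noise_sd = 2e-4,
                            include_envelope = TRUE, include_context = FALSE,
                            seed = NULL) {
  roles <- if (include_context) c("band", "context") else "band"
  rows <- ref_table[ref_table$species == species & ref_table$role %in% roles, ]
  nu <- seq(grid[1], grid[2], by = grid[3])
  truth <- tibble(band_id = character(0), center = numeric(0), area = numeric(0),
                  sigma = numeric(0), gamma = numeric(0), role = character(0))
  y <- numeric(length(nu))
  for (i in seq_len(nrow(rows))) {
    cc <- rows$literature_center_cm1[i]
    if (cc < grid[1] || cc > grid[2]) {
      abort(sprintf("band %s at %g cm-1 lies outside the grid.", rows$band_id[i], cc))
    }
    a <- if (!is.null(areas) && rows$band_id[i] %in% names(areas)) {
      areas[[rows$band_id[i]]]
    } else 0.5
    y <- y + voigt_profile(nu, cc, rows$sigma_cm1[i], rows$gamma_cm1[i], a)
    truth <- bind_rows(truth, tibble(band_id = rows$band_id[i], center = cc,
                                     area = a, sigma = rows$sigma_cm1[i],
                                     gamma = rows$gamma_cm1[i], role = "band"))
  }
  if (include_envelope && species %in% c("ALP", "PNP")) {
    env_center <- if (species == "ALP") 3398 else 3400
    if (env_center <= grid[2]) {
      y <- y + voigt_profile(nu, env_center, 120, 20, 12)
      truth <- bind_rows(truth, tibble(band_id = paste0(species, "_xh_envelope"),
                                       center = env_center, area = 12,
                                       sigma = 120, gamma = 20, role = "envelope"))
    }
  }
  y <- with_local_seed(seed, y + rnorm(length(nu), 0, noise_sd))
  list(spectrum = ir_spectrum(nu, y, metadata = list(species = species, synthetic = TRUE)),
       truth = truth)
}

#' Generate a synthetic reaction series with exact ground truth
#'
#' Each slice is the sum of the scenario's bands evaluated at their
#' time-dependent centres and areas, plus a per-slice linear baseline drift
#' (slope and intercept drawn i.i.d. uniform within the scenario's
#' half-ranges) and i.i.d. Gaussian noise. `(scenario, seed)` determines
#' the output bit-for-bit. The truth record carries per-slice true centres
#' and areas, the closed-form net shifts, and `t95 = ln(20)/k`.
#'
#' @param sc An [scenario()].
#' @param seed Optional integer seed.
#' @return A list with `series` (an [ir_series()]) and `truth` (list with
#'   `by_slice`, `shifts`, `t95`, `rate`).
#' @export
generate_series <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "ftir_scenario"))
  nu <- seq(sc$grid[1], sc$grid[2], by = sc$grid[3])
  ts <- seq(sc$times[1], sc$times[2], by = sc$times[3])
  if (length(ts) < 2) abort("scenario time grid must contain at least 2 points.")
  gen <- function() {
    specs <- vector("list", length(ts))
    slices <- vector("list", length(ts))
    for (i in seq_along(ts)) {
      t_rel <- ts[i] - ts[1]
      y <- numeric(length(nu))
      st <- lapply(sc$bands, function(b) {
        v <- band_at_time(b, t_rel, sc$rate)
        tibble(band_id = b$band_id, time_min = ts[i],
               center = v$center, area = v$area,
               sigma = b$sigma, gamma = b$gamma, role = b$role)
      })
      st <- bind_rows(st)
      for (j in seq_len(nrow(st))) {
        if (st$area[j] > 0) {
          y <- y + voigt_profile(nu, st$center[j], st$sigma[j], st$gamma[j], st$area[j])
        }
      }
      slope <- runif(1, -sc$drift["slope"], sc$drift["slope"])
      icpt <- runif(1, -sc$drift["intercept"], sc$drift["intercept"])
      y <- y + icpt + slope * nu + rnorm(length(nu), 0, sc$noise_sd)
      specs[[i]] <- ir_spectrum(nu, y)
      slices[[i]] <- st
    }
    list(specs = specs, by_slice = bind_rows(slices))
  }
  out <- with_local_seed(seed, gen())
  shifts <- bind_rows(lapply(sc$bands, function(b) {
    tibble(band_id = b$band_id,
           center_start = b$center_start, center_end = b$center_end,
           delta_cm1 = b$center_end - b$center_start,
           area_start = b$area_start, area_end = b$area_end,
           rate = b$rate %||% sc$rate, role = b$role)
  }))
  series <- ir_series(out$specs, ts,
                      metadata = list(scenario = sc$name, seed = seed,
                                      metadata = sc$metadata))
  list(series = series,
       truth = list(by_slice = out$by_slice, shifts = shifts,
                    rate = sc$rate, t95 = log(20) / sc$rate,
                    noise_sd = sc$noise_sd))
}

#' Save a scenario to a YAML file
#' @param sc An [scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "ftir_scenario"))
  obj <- list(
    name = sc$name,
    grid = list(lo = sc$grid[1], hi = sc$grid[2], spacing = sc$grid[3]),
    times = list(t0 = sc$times[1], t_end = sc$times[2], step = sc$times[3]),
    rate = sc$rate, noise_sd = sc$noise_sd,
    drift = list(slope = unname(sc$drift["slope"]),
                 intercept = unname(sc$drift["intercept"])),
    metadata = sc$metadata,
    bands = lapply(sc$bands, function(b) {
      out <- b[!vapply(b, is.null, logical(1))]
      class(out) <- NULL
      out
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a scenario from a YAML file
#'
#' The schema is validated strictly: unknown keys or invariant violations
#' (negative spacing, widths outside bounds, centres off-grid) raise an
#' error naming the offending fields.
#'
#' @param path Path to a scenario YAML file.
#' @return An [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) abort(paste0("scenario file not found: ", path))
  obj <- yaml::read_yaml(path)
  unknown <- setdiff(names(obj), scenario_fields)
  if (length(unknown)) {
    abort(paste0("unknown scenario fields: ", paste(unknown, collapse = ", ")))
  }
  need <- setdiff(c("name", "grid", "times", "bands"), names(obj))
  if (length(need)) abort(paste0("scenario file missing fields: ", paste(need, collapse = ", ")))
  band_fields <- c("band_id", "center_start", "center_end", "area_start",
                   "area_end", "sigma", "gamma", "role", "rate")
  bands <- lapply(obj$bands, function(b) {
    unknown_b <- setdiff(names(b), band_fields)
    if (length(unknown_b)) {
      abort(paste0("unknown band fields: ", paste(unknown_b, collapse = ", ")))
    }
    do.call(band_spec, b)
  })
  scenario(
    name = obj$name, bands = bands,
    grid = c(obj$grid$lo, obj$grid$hi, obj$grid$spacing),
    times = c(obj$times$t0, obj$times$t_end, obj$times$step),
    rate = obj$rate %||% (log(20) / 4.5),
    noise_sd = obj$noise_sd %||% 2e-4,
    drift_slope = obj$drift$slope %||% 1e-6,
    drift_intercept = obj$drift$intercept %||% 5e-4,
    metadata = obj$metadata %||% list()
  )
}

packaged_scenario <- function(name) {
  load_scenario(system.file("extdata", "scenarios", paste0(name, ".yaml"),
                            package = "ftirtrack"))
}

#' Packaged reaction scenarios
#'
#' Three ready-made scenarios encoding the tracked-band trajectory
#' endpoints of the PNPP hydrolysis assay at three enzyme loadings:
#' `scenario_high_alp()` (10 uM ALP, 61 mM PNPP: shifts +8, +5, -5, -4
#' cm^-1 and a product rise with k = ln(20)/4.5 min^-1, i.e. t95 = 4.5
#' min), `scenario_mid_alp()` (10 uM ALP, 305 mM PNPP: +0.542, +0.30,
#' -1.7, -3.8 cm^-1) and `scenario_low_alp()` (1 uM ALP, 305 mM PNPP:
#' 0, +0.18, 0, -1 cm^-1). All include the 1606/1617 cm^-1 redistribution
#' pair, the late 1583/1595 doublet, the 1460 cm^-1 control and the
#' 925/1045/847 cm^-1 interfering bands.
#'
#' @return An [scenario()].
#' @export
scenario_high_alp <- function() packaged_scenario("high_alp")

#' @rdname scenario_high_alp
#' @export
scenario_mid_alp <- function() packaged_scenario("mid_alp")

#' @rdname scenario_high_alp
#' @export
scenario_low_alp <- function() packaged_scenario("low_alp")
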