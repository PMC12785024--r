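#' Simulate a scenario to disk
#'
#' Generates the reaction series of a scenario and writes per-slice csv
#' spectra, a `manifest.csv` (columns `time_min,path`) and a `truth.yaml`
#' ground-truth record into `outdir`. Deterministic for a given seed.
#'
#' @param scenario_in An [scenario()] object or path to a scenario YAML.
#' @param seed Integer seed.
#' @param outdir Output directory (created).
#' @return Invisibly, a list with `manifest` and `truth` file paths.
#' @export
run_simulate <- function(scenario_in, seed = 0L, outdir) {
  sc <- if (inherits(scenario_in, "ftir_scenario")) scenario_in else load_scenario(scenario_in)
  gen <- generate_series(sc, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man <- write_series(gen$series, outdir)
  truth_path <- file.path(outdir, "truth.yaml")
  yaml::write_yaml(list(
    scenario = sc$name, seed = seed,
    rate = gen$truth$rate, t95 = gen$truth$t95,
    shifts = lapply(seq_len(nrow(gen$truth$shifts)), function(i) {
      as.list(gen$truth$shifts[i, ])
    })
  ), truth_path)
  invisible(list(manifest = man, truth = truth_path))
}

#' Fit static reference spectra from disk
#'
#' Reads one spectrum per species (`<species>.csv` or `.jdx` files in
#' `input`, or a named list of spectra), fits every reference-table band
#' and writes `fitted_references.csv`.
#'
#' @param input Directory of per-species spectrum files named by species,
#'   or a named list of [ir_spectrum()] objects.
#' @param outdir Output directory.
#' @param ref_table A [reference_bands()] table (or path to one).
#' @return Invisibly, the fitted reference tibble.
#' @export
run_fit_static <- function(input, outdir, ref_table = NULL) {
  if (is.character(ref_table)) ref_table <- reference_bands(ref_table)
  ref_table <- ref_table %||% reference_bands()
  if (is.character(input)) {
    files <- list.files(input, pattern = "\\.(csv|jdx|dx)$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no spectrum files found in ", input))
    spectra <- setNames(lapply(files, read_spectrum),
                        sub("\\.[^.]+$", "", basename(files)))
  } else {
    spectra <- input
    if (length(spectra) == 0) abort("no spectra supplied.")
  }
  refs <- fit_static_references(spectra, ref_table)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(refs, file.path(outdir, "fitted_references.csv"), row.names = FALSE)
  invisible(refs)
}

#' Track a reaction series from disk
#'
#' Reads a series manifest, tracks the configured bands slice by slice,
#' and writes tidy outputs into `outdir`: `trajectories.csv` (per band and
#' time), `summary.csv` (per-band net shifts, columns `band_id, scenario,
#' start_cm1, end_cm1, delta_cm1, delta_sd`), and a plain-text `report.txt`
#' covering the drift-control stability check and the product-band plateau
#' kinetics.
#'
#' @param manifest Path to a series `manifest.csv` (or an [ir_series()]).
#' @param outdir Output directory.
#' @param plan Tracking plan; default [default_track_plan()]. Every plan
#'   band id must be resolvable -- unknown ids error.
#' @param refs Optional [fit_static_references()] tibble or path to a
#'   `fitted_references.csv` used to re-anchor the plan's centres.
#' @param scenario_name Label written into the summary csv.
#' @return Invisibly, a list: `trajectories`, `shifts`, `stability`,
#'   `plateau`.
#' @export
run_track <- function(manifest, outdir, plan = NULL, refs = NULL,
                      scenario_name = NULL) {
  series <- if (inherits(manifest, "ir_series")) manifest else read_series(manifest)
  if (is.character(refs)) {
    refs <- as_tibble(read.table(refs, header = TRUE, sep = ",", stringsAsFactors = FALSE))
  }
  plan <- plan %||% default_track_plan(refs)
  scenario_name <- scenario_name %||% spectrum_meta(series)$scenario %||% "series"
  traj <- track_series(series, plan)
  shifts <- compute_shift(traj)
  shifts <- mutate(shifts, scenario = scenario_name)
  stab <- stability_check(traj)
  prod_id <- if (any(plan$role == "product")) plan$band_id[plan$role == "product"][1] else NULL
  plateau <- NULL
  if (!is.null(prod_id)) {
    tp <- traj[traj$band_id == prod_id & traj$converged, ]
    plateau <- tryCatch(fit_plateau(tp$time_min, tp$area), error = function(e) NULL)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as_tibble(traj), file.path(outdir, "trajectories.csv"), row.names = FALSE)
  write.csv(shifts[, c("band_id", "scenario", "start_cm1", "end_cm1",
                       "delta_cm1", "delta_sd")],
            file.path(outdir, "summary.csv"), row.names = FALSE)
  rep_lines <- c(
    sprintf("ftirtrack tracking report -- scenario: %s", scenario_name),
    sprintf("slices: %d, bands: %d", length(series_times(series)), nrow(plan)),
    "",
    "net shifts (cm-1):",
    sprintf("  %-10s %+8.3f +/- %.3f  (%.2f -> %.2f)",
            shifts$band_id, shifts$delta_cm1, shifts$delta_sd,
            shifts$start_cm1, shifts$end_cm1),
    "",
    sprintf("drift control (%s): %s, max excursion %.3f cm-1 (tol %.2g)",
            stab$band_id, if (stab$pass) "PASS" else "FAIL",
            stab$max_excursion, stab$tol)
  )
  if (!is.null(plateau)) {
    rep_lines <- c(rep_lines,
      if (plateau$no_rise) "product band: no significant rise (no-rise flag)"
      else sprintf("product band plateau: k = %.4g min-1, t95 = %.3f min",
                   plateau$k, plateau$t95))
  }
  writeLines(rep_lines, file.path(outdir, "report.txt"))
  invisible(list(trajectories = traj, shifts = shifts,
                 stability = stab, plateau = plateau))
}

#' Compare tracked runs across conditions
#'
#' Reads the `summary.csv` of each tracked output directory, stacks them,
#' appends the per-band t0 spread, and writes `shift_summary.csv`.
#'
#' @param outdirs Named character vector of [run_track()] output
#'   directories (names label scenarios; defaults to directory basenames).
#' @param out Output csv path.
#' @return Invisibly, the [compare_scenarios()] tibble.
#' @export
run_compare <- function(outdirs, out = NULL) {
  if (is.null(names(outdirs))) names(outdirs) <- basename(outdirs)
  shifts <- lapply(outdirs, function(d) {
    f <- file.path(d, "summary.csv")
    if (!file.exists(f)) abort(paste0("no summary.csv in ", d))
    as_tibble(read.table(f, header = TRUE, sep = ",", stringsAsFactors = FALSE))
  })
  cmp <- compare_scenarios(shifts)
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    write.csv(as_tibble(cmp), out, row.names = FALSE)
    write.csv(t0_spread(cmp), sub("\\.csv$", "_t0spread.csv", out), row.names = FALSE)
  }
  invisible(cmp)
}
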