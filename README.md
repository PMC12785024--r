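# ftirtrack

Voigt peak tracking for time-resolved ATR-FTIR monitoring of enzyme
catalysis.

## The problem

Attenuated total reflection FTIR lets you watch an enzymatic reaction in a
10 µL droplet in real time: as alkaline phosphatase (ALP) hydrolyses
p-nitrophenyl phosphate (PNPP) to p-nitrophenol (PNP) and inorganic
phosphate (Pi), substrate bands fade, product bands grow, and several
nitro/aromatic and fingerprint bands shift by a few cm⁻¹. Turning those
raw absorbance traces into defensible numbers — band centres with
uncertainties, net shifts Δν, reaction-completion times — requires a
disciplined deconvolution workflow, because the interesting bands overlap,
ride on drifting baselines, and move by less than their own widths.

`ftirtrack` implements that workflow for users of time-resolved IR
spectroscopy:

- **Static-reference anchoring.** Peak centres of the pure species (ALP,
  PNPP, PNP, Pi) are fitted freely within broad windows (±25 cm⁻¹ around
  literature values); the fitted positions then constrain the
  time-resolved fits tightly (±5–10 cm⁻¹).
- **Windowed Voigt deconvolution.** Each spectral window is modelled as up
  to three Voigt components, V(ν) = A·Re[w(z)]/(σ√2π) with
  z = (ν−ν₀+iγ)/(σ√2), plus a linear baseline, fitted jointly by bounded
  Levenberg–Marquardt least squares (areas ≥ 0, σ ∈ [1, 15] cm⁻¹,
  γ ∈ [1, 20] cm⁻¹). The Faddeeva function w(z) is evaluated exactly
  (Weideman's rational approximation), not by a pseudo-Voigt shortcut.
- **Initialization by Savitzky–Golay derivatives.** Candidate peaks come
  from lightly smoothed signal maxima plus negative-curvature minima of
  the second derivative, used only to start the fits.
- **Model selection by AIC/BIC.** Gaussian vs Lorentzian vs Voigt
  line-shape families, and one- vs multi-component windows, are compared
  with least-squares information criteria (extra components need
  ΔBIC ≤ −10 *and* residuals above the noise floor).
- **Per-slice independent tracking.** Every time slice is fitted on its
  own; trajectories of centre, area, and width per band follow, with net
  shifts reported as endpoint differences Δν = ν(t_last) − ν(t_first).
- **Kinetics and controls.** The 1077 cm⁻¹ phosphate band area is fitted
  with A(t) = A₀ + A∞(1 − e^(−kt)); completion is reported as
  t95 = ln(20)/k. A designated control band (1460 cm⁻¹ CH₂ scissoring)
  guards against apparent drift; an intensity-redistribution analysis
  distinguishes genuine centre motion from amplitude exchange between
  overlapping components.
- **Synthetic scenarios with exact ground truth.** Because measured
  spectra of this kind are rarely archived, the package ships a generator
  (`scenario_high_alp()`, `scenario_mid_alp()`, `scenario_low_alp()`, or
  your own YAML) that emulates the assay — 400–4000 cm⁻¹ grids, 1.5 min
  cadence over 0–33 min, first-order conversion, noise and baseline
  drift — so every stage of the pipeline can be validated against known
  truth.

## Worked example

Simulate the high-enzyme reaction scenario, track the configured bands,
and summarise:

```r
library(ftirtrack)

sc    <- scenario_high_alp()             # 10 uM ALP / 61 mM PNPP conditions
sim   <- generate_series(sc, seed = 1)   # 23 slices, 0-33 min, known truth
traj  <- track_series(sim$series)        # per-slice windowed Voigt fits
compute_shift(traj)
#> # A tibble: 7 x 6
#>   band_id   start_cm1 end_cm1 delta_cm1 delta_sd n_converged
#> 1 B1_1510       1510.   1518.    7.95     0.0290          23
#> 2 B2_1494       1494.   1499.    4.95     0.0331          23
#> 3 B3_1345       1345.   1340.   -4.98     0.0258          23
#> 4 B4_1294       1294.   1290.   -4.07     0.0284          23
#> 5 ctrl_1460     1460.   1460.    0.0562   0.0393          23
#> 6 ctx_1045      1045.   1045.    0.0252  NA               23
#> 7 pi_1077       1077.   1077.    0.0522  NA               23

pi_band <- dplyr::filter(traj, band_id == "pi_1077", converged)
fit_plateau(pi_band$time_min, pi_band$area)
#> <plateau_fit> A0 = 0.01776, Ainf = 0.5006, k = 0.6707 min-1, t95 = 4.47 min

stability_check(traj)
#> <stability_check> band ctrl_1460: PASS (max excursion 0.124 cm-1, tol 1)
```

The two nitro/aromatic markers blue-shift (+7.95, +4.95 cm⁻¹), the two
substrate-side fingerprint markers red-shift (−4.98, −4.07 cm⁻¹), the
product band rises to 95% of its plateau at t95 ≈ 4.5 min, and the
control band does not move — each number carrying its 1σ fit uncertainty.

`tidy()`, `glance()` and `augment()` methods are provided for fitted
windows, plateau fits and redistribution analyses; `autoplot()` and
`plot_trajectories()` give quick ggplot2 views of spectra, fits and time
courses. Disk-based analyses (manifest + per-slice csv) go through
`run_simulate()`, `run_fit_static()`, `run_track()` and `run_compare()`,
also exposed as a small command-line tool in `inst/cli/ftirtrack`.

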