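---
title: "Methods: windowed Voigt deconvolution and peak tracking for time-resolved ATR-FTIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed Voigt deconvolution and peak tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the tunable parameters,
the synthetic-data generator, and the numerical choices behind
`ftirtrack`, in the spirit of a methods section: everything a user needs
to judge what the package's numbers mean and where they stop being
trustworthy.

## 1. The measurement model

A windowed absorbance trace is modelled as

$$A(\nu) \;=\; b_0 + b_1 \nu \;+\; \sum_{j=1}^{K} V(\nu;\,A_j, \nu_{0j}, \sigma_j, \gamma_j) \;+\; \varepsilon(\nu),
\qquad K \le 3,$$

where $V$ is an area-parameterised Voigt profile — the convolution of a
Gaussian of standard deviation $\sigma$ (inhomogeneous broadening:
environmental distributions in solution) and a Lorentzian of half-width
$\gamma$ (homogeneous broadening: lifetime and interaction effects) — and
$\varepsilon$ is i.i.d. Gaussian noise. Solution-phase IR bands genuinely
carry both broadening mechanisms, which is why pure Gaussian or pure
Lorentzian fits leave structured residuals and poorer AIC/BIC on this
class of data; the package exposes `select_family()` so the comparison
can be re-run on any window rather than assumed.

Conventions worth stating once:

- **$\gamma$ is the Lorentzian HWHM** (the common "Lorentzian $\gamma$"
  convention), not the FWHM.
- **Components are parameterised by area, not apex height.** Area is the
  physically additive quantity and decorrelates better from the widths
  during fitting; apex heights and FWHM
  (Olivero–Longbothum approximation, relative error ~2×10⁻⁴) are derived
  afterwards by `apex_height()` / `voigt_fwhm()`. Where "amplitude" is
  ambiguous in a readout, the tracking tables carry both `area` and
  `height`.
- **The baseline is part of the model.** The linear baseline is fitted
  jointly with the components in every window, never pre-subtracted;
  blank (buffer) subtraction is a separate, earlier step
  (`subtract_blank()`), and difference spectra may legitimately be
  negative.
- **The Voigt evaluator is exact.** $\mathrm{Re}[w(z)]$ is computed with
  Weideman's rational approximation ($N = 64$ terms), which agrees with a
  brute-force numerical convolution of the Gaussian and Lorentzian
  factors to better than $10^{-8}$ of the profile value (this is a test,
  not a claim). No pseudo-Voigt approximation is used anywhere.

## 2. The constraint scheme: static references anchor time-resolved fits

The workflow is deliberately two-stage:

1. **Static reference spectra** of the pure species are fitted with
   centres free within a broad, physically reasonable search range
   around literature values. The packaged reference table uses
   ±25 cm⁻¹ (the middle of the conventional ±20–30 range); it is a
   per-band column, not a constant. A band with no detected candidate of
   at least 5× the noise within its search range is marked *missing*
   rather than failing the run.
2. **Time-resolved series** are then fitted with centres constrained
   tightly around the *fitted* static positions. The default tracking
   tolerance is ±7.5 cm⁻¹ (middle of the 5–10 cm⁻¹ range); the band
   near 1510 cm⁻¹ uses ±10 cm⁻¹ — the upper end of the same stated
   range — because its own reported shift (+8 cm⁻¹) would otherwise sit
   on the constraint boundary, which would bias the endpoint estimate.

Width bounds $\sigma \in [1, 15]$ cm⁻¹ and $\gamma \in [1, 20]$ cm⁻¹ and
non-negative areas are enforced *during* optimisation (box-constrained
Levenberg–Marquardt via `minpack.lm`), never by post-hoc clipping, and
apply to the pure families too.

Each time slice is fitted **independently**: no parameter information
flows between slices except the shared reference constraints. This makes
trajectories honest (a drift cannot be an artefact of warm-starting from
the previous slice) and order-invariant, which the test suite checks by
permuting slice order on disk.

## 3. Initialization and peak detection

Initial parameters come from lightly smoothed spectra: a Savitzky–Golay
filter of order 2 and window 5–9 points (default 7; symmetric filters
need odd lengths, which is how the range 5–10 is realised). Candidates
are the union of

- local maxima of the smoothed signal, with classical topographic
  prominence; and
- negative-curvature minima of the Savitzky–Golay second derivative,
  which resolve shoulders that produce no distinct maximum. For these,
  the component height is reconstructed from the curvature: a Gaussian of
  apex $H$ and width $\sigma$ has $A''(\nu_0) = -H/\sigma^2$, with
  $\sigma$ read off the flanking zero crossings.

Candidates closer than the merge tolerance — default 4 cm⁻¹, the
instrument resolution, below which peaks are not independently
detectable — are merged keeping the larger prominence (ties: lower
wavenumber). The default prominence threshold is $5\hat\sigma$, with
$\hat\sigma$ the robust noise estimate
$1.4826\,\mathrm{MAD}(\Delta A)/\sqrt2$ from a quiet window
(1900–2250 cm⁻¹ by default, the signal-free gap between the fingerprint
region and the X–H stretches). Two guards keep detection sane: a
numerical floor so that smoothing ripple on constant data never counts as
a peak, and a curvature-channel width cap (local $\sigma \le 15$ cm⁻¹,
the largest fittable Gaussian width) so that broad envelope structure is
not reported as a band. Detection output is used **only** to initialise
fits, never as a quantitative result.

## 4. Model complexity: families and component counts

`select_family()` fits Gaussian, Lorentzian and Voigt models from one
initialisation and keeps the lowest BIC
($\mathrm{BIC} = n\ln(\mathrm{RSS}/n) + k\ln n$, the Gaussian-likelihood
least-squares form; AIC analogously with $2k$). Near-ties
($\Delta\mathrm{BIC} < 2$) resolve toward the simpler family (fewer free
width parameters), then toward Gaussian — so on noiseless Gaussian data
the Voigt model's redundant parameter can never win.

`select_components()` starts at $K = \max(1, \text{detected candidates})$
and accepts $K+1$ only if **both** (a) the current residual RMS exceeds
$3\times$ the noise floor and (b) the additional component improves BIC
by at least 10. $K$ never exceeds 3. The paper-style trigger
("derivative inspection or residual analysis indicated partial
overlapping components") is not quantified in prose anywhere we know of;
these two thresholds are our operationalisation and are deliberately
conservative — an extra component must be both *needed* (residuals) and
*decisively supported* (BIC).

## 5. Automated residual review and multi-start policy

Fit quality is verified by residual analysis, automated as follows: a fit
is accepted outright only when its residual RMS is consistent with the
noise floor ($\le 1.25\,\hat\sigma$; a correctly specified model has
expected RMS $\approx \hat\sigma\sqrt{(n-k)/n}$ with ~6% chi
fluctuation at the window sizes used). Otherwise up to three
deterministic restarts are tried, in order: a warm restart if the
iteration cap stopped the optimiser mid-descent; the reference-anchored
centres; and centre jitters of alternating sign (±half the centre
tolerance) combined with width rescaling (×0.6, ×1.6) to escape
broad-component local minima — a weak band's area can otherwise be
absorbed by a bound-pinned wide Lorentzian. The lowest-deviance candidate
wins; convergence status only breaks near-ties. Everything is
deterministic given the data and initial model: there is no random
restart anywhere in the fitting path.

Optimiser settings: parameter and cost tolerances $10^{-10}$, at most
400 iterations per start. Parameter uncertainties are 1σ values from the
local linearisation, $\mathrm{cov} = s^2 (J^\top J)^{-1}$ with
$s^2 = \mathrm{RSS}/(n-k)$; they are reported as `NA` when a parameter
sits on a bound and the information matrix is singular — deliberately,
rather than pretending a boundary solution has a Gaussian error bar.

Component identity across refits is assigned by minimum total
centre-distance matching (permutations enumerated exactly for
$K \le 3$), which prevents label switching along a trajectory.

## 6. Derived summaries

- **Net shifts** are endpoint differences,
  $\Delta\nu = \nu_0(t_\mathrm{last}) - \nu_0(t_\mathrm{first})$ over
  converged slices, with propagated uncertainty
  $\sqrt{s_\mathrm{first}^2 + s_\mathrm{last}^2}$. Positive is a blue
  shift. This matches how concentration-series shifts are conventionally
  quoted ("$\nu_\mathrm{start} \to \nu_\mathrm{end}$"); the alternative —
  the asymptote of a fitted trajectory model — would be smoother but
  model-dependent, and is not used.
- **Completion time** comes from the exponential-plateau fit
  $A(t) = A_0 + A_\infty(1 - e^{-kt})$ to the product-band (1077 cm⁻¹
  phosphate) *area* trajectory, reported as $t_{95} = \ln(20)/k$, the
  95%-of-plateau time. "Effectively complete" has no universal
  definition; 95% is the conventional choice and makes $t_{95}$ a closed
  form in $k$. A fitted rise smaller than twice the amplitude noise (or a
  collapsed rate) yields a `no_rise` flag instead of a number.
  The 1077 cm⁻¹ area is the product readout rather than the ~990 cm⁻¹
  region, which overlaps protein (~925 cm⁻¹) and broad phosphate
  (~847 cm⁻¹) features; the packaged scenarios include those interferers
  precisely so this choice stays testable, and the tracking plan fits the
  neighbouring stable ~1045 cm⁻¹ protein band jointly with 1077 so its
  tail cannot contaminate the product area at early times.
- **Redistribution analysis** fits two Voigt components with centres
  constrained to ±2 cm⁻¹ (tight enough to exclude genuine drift, loose
  enough for fit flexibility) and areas/widths free, and reports the
  product fraction $f(t) = A_\mathrm{hi}/(A_\mathrm{lo}+A_\mathrm{hi})$
  together with the apparent one-peak centroid of the
  baseline-subtracted window. On synthetic data this demonstrates the
  key disambiguation: an apparent centroid drift of ≥5 cm⁻¹ arises from
  pure amplitude exchange while the true component centres never move.
- **Stability check**: the 1460 cm⁻¹ CH₂ scissoring band (present in
  enzyme and product, thickness-sensitive but chemically inert here) is
  fitted in every tracking run and must stay within 1 cm⁻¹ of its
  initial centre; failure flags baseline/film drift masquerading as
  chemistry.

## 7. The synthetic-data generator

Measured droplet spectra for this assay are not publicly archived, so
validation rests on a generator with exact ground truth. A scenario
carries a wavenumber grid (400–4000 cm⁻¹ at 0.5 cm⁻¹ for time-resolved
emulation, 0.25 cm⁻¹ for static), a time grid (0–33 min at 1.5 min, the
acquisition cadence), a band list, a shared first-order rate $k$, a noise
level, and per-slice baseline-drift statistics. Band centres and areas
follow exponential approach,
$\nu_0(t) = \nu_\mathrm{end} - (\nu_\mathrm{end}-\nu_\mathrm{start})e^{-kt}$,
synchronised with the product rise; the *functional form* is a modelling
choice (smooth saturation), stated openly — only the endpoints and the
high-loading rate are anchored to reported values.

The three packaged scenarios encode the reported trajectory endpoints at
three enzyme loadings — high (10 µM ALP / 61 mM PNPP): 1510→1518,
1494→1499, 1345→1340, 1294→1290 with $k = \ln(20)/4.5 \approx
0.666\,\mathrm{min}^{-1}$; mid (10 µM / 305 mM): shifts +0.80, +0.30,
−1.7, −3.8 cm⁻¹; low (1 µM / 305 mM): 0, +0.18, 0, −1 cm⁻¹ — plus the
1606/1617 redistribution pair, the late 1583/1595 doublet, the constant
1460 control, the 925/1045/847 interferers, and a broad X–H envelope
(σ = 120 cm⁻¹, exempt from fitting). One reported pair is internally
inconsistent at the source (an end position of 1510.542 cm⁻¹ alongside
Δν = +0.80 cm⁻¹); the scenario follows the printed shift, so its start
is 1509.742 cm⁻¹.

Values the source does not state are package choices, made once:

| parameter | default | why |
|---|---|---|
| noise SD | 2×10⁻⁴ AU | plausible DTGS/ATR magnitude at 64 scans |
| drift slope | U(±10⁻⁶) AU/cm⁻¹ per slice | slow baseline wander |
| drift intercept | U(±5×10⁻⁴) AU per slice | session-scale offset |
| sharp-band widths | σ = 3.5, γ = 3 cm⁻¹ | inside fit bounds, FWHM ≈ 12.6 cm⁻¹ |
| mid / low rates | 0.25 / 0.08 min⁻¹ | slower apparent kinetics at lower loading; shifts still ≥93% expressed by 33 min |
| band areas | 0.02–0.5 AU·cm⁻¹ | apex SNR ~7–175, spanning weak-band to strong-band regimes |

One generator constraint deserves emphasis: band widths must be
compatible with the constraint scheme they are meant to exercise. The
alkyl C–H reference bands are generated at σ = 5, γ = 3 (FWHM
≈ 18 cm⁻¹) because a band wider than half its ±25 cm⁻¹ search window
cannot be distinguished from background curvature by a
Voigt-plus-linear-baseline model within that window — the window scheme
itself presumes bands narrower than the window.

**What passing tests do and do not show.** The generator reproduces the
*statistical* structure the fitting pipeline must cope with — overlap,
noise, linear drift, weak bands, interfering neighbours — with Gaussian
noise and exactly Voigt bands. Real ATR data additionally contain water-
vapour rotational lines, detector nonlinearity, wavelength-dependent
penetration depth, and model mismatch in the line shapes themselves.
Recovery of ground truth here validates the estimator, not the
spectrometer; tolerances of ±0.3–0.5 cm⁻¹ on recovered shifts should be
read as the *method's* precision under these idealised conditions, a
lower bound on real-data uncertainty.

## 8. Numerical choices, degenerate inputs, tie-breaks

- Spectra are stored strictly ascending in wavenumber; files exported
  high-to-low are sorted on read (plots may reverse the axis, the data
  never do). Duplicated grid points are an error, not silently averaged.
- JCAMP-DX support is deliberately minimal: AFFN `(X++(Y..Y))` only;
  compressed dialects (SQZ/DIF/DUP) error loudly rather than risk
  mis-parsing. Round-trips preserve absorbance to ≤10⁻⁶ AU.
- Resampling is linear interpolation, and extrapolation is an error —
  needed only because static (0.25 cm⁻¹) and time-resolved (0.5 cm⁻¹)
  grids differ.
- Windows must contain ≥8 grid points; fewer than 4 points per free
  parameter warns (below 2 per parameter) rather than failing.
- An all-zero window converges to zero areas at the bound with a ~zero
  baseline. A slice that fails convergence for one window is flagged and
  the trajectory continues; `compute_shift()` refuses bands with fewer
  than two converged endpoints.
- The ±40-FWHM integral property of the Voigt evaluator holds to 0.1%
  only in the Gaussian-dominated regime; a Lorentzian component carries
  tail mass $\approx 2\gamma/(\pi X)$ beyond $\pm X$ (≈0.4% at 40 FWHM
  for a pure Lorentzian), so mixed cases are verified against the exact
  $(-\infty,\infty)$ integral instead.
- Scenario YAML is validated strictly: unknown keys, negative spacing,
  off-grid centres and out-of-bounds widths all raise errors naming the
  offending fields.

## 9. Problem sizes used in the shipped analyses

The packaged end-to-end analyses and the acceptance script track 7 bands
in 5 windows across 23 time slices on a 7201-point grid (one scenario
≈ 10 s on one CPU). Monte Carlo suites use 100 replicates for line-shape
family recovery, 200 random single-band scenarios for centre-recovery
statistics, and 200 seeds for generator noise calibration — sizes chosen
so the whole validation suite completes in a few minutes while keeping
binomial/quantile test statistics meaningful.

## 10. Known limitations

- The two-component redistribution contract assumes the analysis window
  contains only those two components above the baseline. In the full
  high-loading scenario the growing 1583/1595 doublet bleeds into any
  window containing 1606 cm⁻¹ and biases the pair fit; resolving that
  region properly needs the three-component machinery of
  `select_components()`. The redistribution demonstration therefore uses
  the isolated pair construction.
- Weak, heavily overlapped components (apex ≲ 20× noise at ~1 FWHM
  separation) have centre scatter of several tenths of cm⁻¹ per slice;
  max-over-series excursions are max-statistics and should be judged
  against the reported per-slice σ, not against zero.
- No global (all-window simultaneous) fitting, no weighted least
  squares, no Bayesian posteriors, no asymmetric line shapes, no
  enzymological (Michaelis–Menten) parameter estimation — the kinetic
  readout here is a progress marker, not an activity assay.
- Atmospheric compensation beyond blank subtraction, proprietary
  instrument formats, and ATR penetration-depth correction are out of
  scope; exported absorbance is treated as final.
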