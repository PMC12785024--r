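Package: ftirtrack
Title: Voigt Peak Tracking for Time-Resolved ATR-FTIR Catalysis Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring enzymatic reactions with attenuated total
    reflection Fourier-transform infrared (ATR-FTIR) spectroscopy. Provides
    windowed Voigt deconvolution of absorbance spectra anchored to static
    reference spectra, Savitzky-Golay derivative peak detection, AIC/BIC
    line-shape model selection, per-slice independent tracking of band
    centers and areas across a reaction series, intensity-redistribution
    analysis of overlapping bands, exponential-plateau kinetics of product
    bands, and a scenario-driven synthetic spectrum generator with exact
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
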