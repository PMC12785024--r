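#' Packaged reference band table
#'
#' Literature band centres for the four species of the alkaline-phosphatase
#' assay: the enzyme (ALP, 11 bands from its static ATR-FTIR spectrum --
#' Amide A/I/II/III, side-chain C-H, CH2 and carboxylate modes), the
#' substrate p-nitrophenyl phosphate (PNPP, aromatic C=C and NO2 pair), the
#' product p-nitrophenol (PNP) and inorganic phosphate (Pi, whose 1077 cm^-1
#' P-O stretch is the product-formation marker). Two ALP rows (925 and 1045
#' cm^-1) are flagged `role = "context"`: they overlap the phosphate window
#' and are carried as interference context rather than as primary reference
#' bands.
#'
#' @param path Optional path to a user table with the same columns
#'   (`species, band_id, label, literature_center_cm1, search_tol_cm1,
#'   track_tol_cm1, sigma_cm1, gamma_cm1, role`).
#' @return A tibble, one row per band.
#' @export
reference_bands <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_bands.csv", package = "ftirtrack")
  tb <- as_tibble(read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE))
  needed <- c("species", "band_id", "label", "literature_center_cm1",
              "search_tol_cm1", "track_tol_cm1", "sigma_cm1", "gamma_cm1", "role")
  miss <- setdiff(needed, names(tb))
  if (length(miss)) abort(paste0("reference table missing columns: ", paste(miss, collapse = ", ")))
  tb
}
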