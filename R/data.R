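#' Published precision figures of the seven-laboratory trial
#'
#' The consensus values and precision statistics reported for the
#' spICP-MS screening method in its seven-laboratory collaborative trial
#' (robust evaluation, no outlier exclusion): per measurand and test
#' material, the consensus `X_pt`, its uncertainty `U` (twice the
#' standard error), the reproducibility `R` and repeatability `r`
#' standard deviations, and their relative forms in percent. The raw
#' laboratory data behind these figures are not published; the table
#' supports internal-consistency checks
#' ([check_precision_consistency()]) and plausibility comparisons, not
#' reproduction.
#'
#' Values are returned as character strings exactly as printed, so their
#' displayed precision is preserved for rounding-aware checks.
#'
#' @return A tibble with columns `measurand`, `material`, `x_pt`,
#'   `u_xpt`, `R`, `r`, `rsd_R_pct`, `rsd_r_pct` (all character).
#' @export
ilc_reference_precision <- function() {
  path <- system.file("extdata", "ilc_spicpms_precision.csv",
                      package = "nanoscreen", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
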