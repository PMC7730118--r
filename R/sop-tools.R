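#' Sonication energy and energy density
#'
#' Protocol arithmetic for the de-agglomeration step:
#' `energy = delivered acoustic power x duration` and
#' `energy density = energy / suspension volume`. Typical conditions are
#' bath sonication at 2 W for 600 s in 10 mL (120 J/mL) or probe
#' sonication at 18 W for 300--540 s (540--972 J/mL).
#'
#' @param power_W Delivered acoustic power (W).
#' @param duration_s Sonication time (s).
#' @param volume_mL Suspension volume (mL).
#' @return A tibble with `energy_J` and `energy_density_J_per_mL`.
#' @examples
#' sonication_energy(2, 600, 10)   # bath: 1200 J, 120 J/mL
#' sonication_energy(18, 540, 10)  # probe 10 kJ setting: 9720 J, 972 J/mL
#' @export
sonication_energy <- function(power_W, duration_s, volume_mL) {
  if (any(power_W < 0) || any(duration_s < 0)) {
    abort("power and duration must be >= 0")
  }
  if (any(volume_mL <= 0)) abort("volume_mL must be > 0")
  energy <- power_W * duration_s
  tibble(energy_J = energy, energy_density_J_per_mL = energy / volume_mL)
}

#' Suspension mass concentration at protocol precision
#'
#' `mass / volume`, rounded to the number of significant figures used in
#' the preparation tables (default 2), so recorded concentrations
#' reproduce the protocol's printed values exactly.
#'
#' @param mass_mg Sample mass (mg).
#' @param volume_mL Final suspension volume (mL).
#' @param sig_figs Significant figures for rounding.
#' @return Concentration in mg/mL.
#' @examples
#' suspension_concentration(88, 35) # 2.5
#' suspension_concentration(40, 40) # 1.0
#' @export
suspension_concentration <- function(mass_mg, volume_mL, sig_figs = 2) {
  if (any(volume_mL <= 0)) abort("volume_mL must be > 0")
  if (any(mass_mg < 0)) abort("mass_mg must be >= 0")
  signif(mass_mg / volume_mL, sig_figs)
}

#' Validate a sample-preparation / run configuration
#'
#' Pure advisory checks of a run configuration against the screening
#' protocol; never mutates its input. Findings cover:
#' * suspension pH must exceed 6 (TiO2 agglomerates near its isoelectric
#'   point at lower pH);
#' * sonication mode versus material class: bath sonication disperses
#'   confectionery extracts, but pristine E 171 powder requires probe
#'   sonication;
#' * the dilution chain should put the expected detected events per scan
#'   into the 1000--2000 band when enough information is present to
#'   predict it.
#'
#' @param config A named list with (any of) sections `prep`
#'   (`material` = "pristine"/"confectionery", `ph`), `sonication`
#'   (`mode` = "none"/"bath"/"probe"), `instrument` (`flow_mL_min`,
#'   `scan_time_s`, `transport_efficiency`), `dilution`
#'   (`factor`, `suspension_number_concentration_per_mL`).
#' @return A tibble of findings (`level`, `field`, `message`); zero rows
#'   when compliant.
#' @export
validate_sop <- function(config) {
  if (!is.list(config)) abort("config must be a named list")
  findings <- list()
  note <- function(level, field, message) {
    findings[[length(findings) + 1]] <<- tibble(
      level = level, field = field, message = message)
  }
  ph <- config$prep$ph
  if (!is.null(ph)) {
    if (!is.numeric(ph)) abort("prep$ph must be numeric")
    if (ph <= 6) {
      note("warning", "prep.ph", sprintf(
        "pH %.2g is at or below 6: agglomeration risk near the isoelectric point of TiO2",
        ph))
    }
  }
  material <- config$prep$material
  mode <- config$sonication$mode
  if (!is.null(material) && !is.null(mode)) {
    if (identical(material, "pristine") && !identical(mode, "probe")) {
      note("warning", "sonication.mode", sprintf(
        "pristine E 171 requires probe sonication for de-agglomeration; config uses '%s'",
        mode))
    }
    if (identical(material, "confectionery") && identical(mode, "none")) {
      note("warning", "sonication.mode",
           "no sonication configured; bath sonication is needed to disperse confectionery extracts")
    }
  }
  inst <- config$instrument
  dil <- config$dilution
  if (!is.null(inst$flow_mL_min) && !is.null(inst$scan_time_s) &&
      !is.null(inst$transport_efficiency) && !is.null(dil$factor) &&
      !is.null(dil$suspension_number_concentration_per_mL)) {
    conc <- dil$suspension_number_concentration_per_mL / dil$factor
    expected <- conc * ml_min_to_ml_s(inst$flow_mL_min) *
      inst$transport_efficiency * inst$scan_time_s
    if (expected < 1000 || expected > 2000) {
      note("warning", "dilution.factor", sprintf(
        "expected ~%.0f detected events per scan; adjust the dilution to reach the 1000-2000 band",
        expected))
    }
  }
  if (length(findings) == 0) {
    tibble(level = character(), field = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}
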