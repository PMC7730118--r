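#' Describe the analyte/compound relationship of a particle material
#'
#' spICP-MS measures the analyte element; sizing needs the full compound
#' mass and bulk density. For food-grade TiO2 the Ti mass fraction is set
#' to 0.60 and the density to anatase (3.9 g cm^-3), the convention of the
#' screening method this package implements (not the stoichiometric
#' 0.5994 -- fidelity to the operating procedure).
#'
#' @param analyte_mass_fraction Mass fraction of the monitored element in
#'   the particle compound, in (0, 1].
#' @param density_g_cm3 Bulk density of the compound in g cm^-3.
#' @param analyte,compound Labels.
#' @return An `element_compound` list.
#' @export
element_compound <- function(analyte_mass_fraction, density_g_cm3,
                             analyte = "analyte", compound = "compound") {
  if (analyte_mass_fraction <= 0 || analyte_mass_fraction > 1) {
    abort("analyte_mass_fraction must be in (0, 1]")
  }
  if (density_g_cm3 <= 0) abort("density_g_cm3 must be > 0")
  structure(
    list(
      analyte_mass_fraction = analyte_mass_fraction,
      density_g_cm3 = density_g_cm3,
      analyte = analyte,
      compound = compound
    ),
    class = "element_compound"
  )
}

#' @rdname element_compound
#' @export
compound_tio2_anatase <- function() {
  element_compound(0.60, 3.9, analyte = "Ti-48", compound = "TiO2 (anatase)")
}

#' @rdname element_compound
#' @details `compound_gold()` describes the monometallic gold reference
#'   particles used for transport-efficiency determination (mass fraction 1,
#'   density 19.30 g cm^-3).
#' @export
compound_gold <- function() {
  element_compound(1, 19.30, analyte = "Au-197", compound = "Au")
}

#' Fit the dissolved-standard (ionic) calibration line
#'
#' Ordinary least squares of mean counts per dwell against dissolved
#' analyte concentration, e.g. a 5-point curve from 0 to 50 ug/L. The
#' slope converts spike intensities to analyte mass via the transport
#' efficiency and sample flow.
#'
#' @param points Data frame with columns `conc_ug_per_L` and `mean_counts`
#'   (mean counts per dwell). Must contain at least two distinct
#'   concentrations; a blank (0 ug/L) is expected.
#' @return An `ionic_calibration` with fields `slope` (counts per dwell per
#'   ug/L), `intercept`, `r_squared`, `points` and the underlying `lm`.
#' @examples
#' fit_ionic_calibration(data.frame(
#'   conc_ug_per_L = c(0, 5, 10, 25, 50),
#'   mean_counts = c(0.1, 4.3, 8.6, 21.2, 42.5)
#' ))
#' @export
fit_ionic_calibration <- function(points) {
  points <- as_tibble(points)
  if (!all(c("conc_ug_per_L", "mean_counts") %in% names(points))) {
    abort("points must have columns conc_ug_per_L and mean_counts")
  }
  if (nrow(points) < 2) abort("need at least 2 calibration points")
  if (any(points$conc_ug_per_L < 0)) abort("concentrations must be >= 0")
  if (length(unique(points$conc_ug_per_L)) < 2) {
    abort("calibration design is singular: all concentrations equal")
  }
  if (!any(points$conc_ug_per_L == 0)) {
    warn("no blank (0 ug/L) point in the calibration")
  }
  fit <- lm(mean_counts ~ conc_ug_per_L, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("calibration slope must be positive for a valid calibration")
  }
  structure(
    list(
      points = points,
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      model = fit
    ),
    class = "ionic_calibration"
  )
}

#' @export
print.ionic_calibration <- function(x, ...) {
  cat(sprintf(
    "<ionic_calibration> slope %.4g counts/dwell per ug/L, intercept %.4g, r^2 %.5f (%d points)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$points)
  ))
  invisible(x)
}

new_transport_efficiency <- function(eta, method, inputs) {
  if (!is.finite(eta) || eta <= 0) {
    abort(sprintf(
      "transport efficiency is %s; check inputs (%s)",
      format(eta), paste(names(inputs), unlist(inputs), sep = "=",
                         collapse = ", ")
    ))
  }
  if (eta > 1) {
    warn(sprintf("transport efficiency %.3g > 1; clipped to 1", eta))
    eta <- 1
  }
  structure(list(eta = eta, method = method, inputs = inputs),
            class = "transport_efficiency")
}

#' @export
print.transport_efficiency <- function(x, ...) {
  cat(sprintf("<transport_efficiency> eta = %.4g (%.2f%%), method = %s\n",
              x$eta, 100 * x$eta, x$method))
  invisible(x)
}

#' Estimate transport efficiency by the particle-size method
#'
#' Uses a monodisperse reference particle of known diameter and density
#' (typically 63 nm gold): the known particle mass and the ionic response
#' slope predict the counts one particle should generate if every
#' nebulised particle reached the plasma; the ratio against the observed
#' mean per-event intensity is the transport efficiency,
#' `eta = slope x m_ref / (flow x dwell x I_p)` (units reconciled).
#'
#' @param mean_event_counts Mean background-corrected integrated counts per
#'   detected reference-particle event (from [detect_events()]).
#' @param ref_diameter_nm Nominal reference particle diameter in nm.
#' @param cal An [fit_ionic_calibration()] result for the reference analyte.
#' @param flow_mL_min Sample uptake flow in mL/min.
#' @param dwell_time_s Dwell time in seconds.
#' @param ref_density_g_cm3 Reference particle density (gold: 19.30).
#' @return A `transport_efficiency` (fraction in (0, 1]).
#' @export
estimate_te_size <- function(mean_event_counts, ref_diameter_nm, cal,
                             flow_mL_min, dwell_time_s,
                             ref_density_g_cm3 = 19.30) {
  stopifnot(inherits(cal, "ionic_calibration"))
  if (mean_event_counts <= 0) abort("mean_event_counts must be > 0")
  if (ref_diameter_nm <= 0) abort("ref_diameter_nm must be > 0")
  m_ref_fg <- diameter_to_mass(ref_diameter_nm, ref_density_g_cm3)
  q <- ml_min_to_ml_s(flow_mL_min)
  eta <- cal$slope * m_ref_fg /
    (q * dwell_time_s * mean_event_counts * UG_PER_L_TO_FG_PER_ML)
  new_transport_efficiency(
    eta, "size",
    list(ref_diameter_nm = ref_diameter_nm,
         ref_density_g_cm3 = ref_density_g_cm3,
         mean_event_counts = mean_event_counts,
         flow_mL_min = flow_mL_min, dwell_time_s = dwell_time_s,
         slope = cal$slope)
  )
}

#' Estimate transport efficiency by the particle-frequency method
#'
#' `eta = n_events / (reference number concentration x flow x scan time)`.
#' Requires a reference suspension of accurately known number
#' concentration, which is why the size method is usually preferred.
#'
#' @param n_events Number of detected reference-particle events.
#' @param ref_number_conc_per_mL Reference number concentration in mL^-1.
#' @param flow_mL_min Sample uptake flow in mL/min.
#' @param scan_time_s Total acquisition time in seconds.
#' @return A `transport_efficiency`.
#' @export
estimate_te_frequency <- function(n_events, ref_number_conc_per_mL,
                                  flow_mL_min, scan_time_s) {
  if (ref_number_conc_per_mL <= 0 || flow_mL_min <= 0 || scan_time_s <= 0) {
    abort("all inputs must be > 0")
  }
  q <- ml_min_to_ml_s(flow_mL_min)
  eta <- n_events / (ref_number_conc_per_mL * q * scan_time_s)
  if (eta > 1) {
    abort("frequency-method eta > 1: inconsistent inputs")
  }
  new_transport_efficiency(
    eta, "frequency",
    list(n_events = n_events,
         ref_number_conc_per_mL = ref_number_conc_per_mL,
         flow_mL_min = flow_mL_min, scan_time_s = scan_time_s)
  )
}
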