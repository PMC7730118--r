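counts_to_analyte_mass <- function(net_counts, cal, te, flow_mL_min,
                                   dwell_time_s) {
  stopifnot(inherits(cal, "ionic_calibration"),
            inherits(te, "transport_efficiency"))
  q <- ml_min_to_ml_s(flow_mL_min)
  net_counts * q * te$eta * dwell_time_s * UG_PER_L_TO_FG_PER_ML / cal$slope
}

#' Convert detected events to particle masses and diameters
#'
#' The calibration chain of spICP-MS: a spike of net intensity `S` carries
#' analyte mass `m = S x flow x eta x dwell / slope` (the mass of dissolved
#' analyte that would produce the same integrated counts in one dwell);
#' the compound mass follows from the analyte mass fraction and the
#' equivalent spherical diameter from the bulk density.
#'
#' @param events A `particle_events` tibble from [detect_events()] (or any
#'   data frame with a `net_counts` column).
#' @param cal Ionic calibration.
#' @param te Transport efficiency.
#' @param flow_mL_min Sample flow in mL/min.
#' @param dwell_time_s Dwell time in seconds.
#' @param compound An [element_compound()].
#' @return The events tibble with columns `analyte_mass_fg`,
#'   `compound_mass_fg` and `diameter_nm` appended.
#' @export
event_to_masses <- function(events, cal, te, flow_mL_min, dwell_time_s,
                            compound) {
  stopifnot(inherits(compound, "element_compound"))
  events <- as_tibble(events)
  if (!"net_counts" %in% names(events)) {
    abort("events must have a net_counts column")
  }
  if (nrow(events) > 0 && any(events$net_counts <= 0)) {
    abort("net_counts must be positive for sizing")
  }
  m_analyte <- counts_to_analyte_mass(events$net_counts, cal, te,
                                      flow_mL_min, dwell_time_s)
  events$analyte_mass_fg <- m_analyte
  events$compound_mass_fg <- m_analyte / compound$analyte_mass_fraction
  events$diameter_nm <- mass_to_diameter(events$compound_mass_fg,
                                         compound$density_g_cm3)
  events
}

#' Number-based size-distribution quantile (D-value)
#'
#' D-values of the cumulative number-based particle size distribution:
#' `Dx` is the diameter below which x% of particles fall. D0 and D100 are
#' the sample minimum and maximum; interior levels use linear
#' interpolation of order statistics (position `1 + (n-1) x level/100`,
#' i.e. `stats::quantile()` type 7) so D99.5/D99.8 are reproducible
#' across software.
#'
#' @param diameters Numeric vector of particle diameters (nm).
#' @param level Quantile level(s) in percent, in \[0, 100\].
#' @return Diameter(s) in nm.
#' @examples
#' size_quantile(c(10, 20, 30, 40, 50), 50) # 30
#' @export
size_quantile <- function(diameters, level) {
  if (length(diameters) < 1) abort("empty size distribution")
  if (any(level < 0 | level > 100)) abort("level must be in [0, 100]")
  unname(quantile(diameters, level / 100, type = 7, names = FALSE))
}

#' Particles excluded by truncating the distribution at a D-value
#'
#' Reporting e.g. D99.5 instead of the largest detected diameter (D100)
#' excludes isolated large (presumably agglomerated) particles. This is
#' the bookkeeping for how many: `round(n x (100 - level)/100)`, ties
#' half-up.
#'
#' @param n_total Total number of detected particles.
#' @param level D-value level in percent.
#' @return Integer count of excluded particles.
#' @examples
#' excluded_count(2000, 99.5) # 10
#' @export
excluded_count <- function(n_total, level) {
  if (any(n_total < 0)) abort("n_total must be >= 0")
  if (any(level < 0 | level > 100)) abort("level must be in [0, 100]")
  as.integer(floor(n_total * (100 - level) / 100 + 0.5))
}

#' Most frequent diameter (mode) by kernel density estimation
#'
#' Histogram modes depend on the bin width; a Gaussian-kernel density
#' estimate is bin-free and allows reporting the most frequent particle
#' size in a standardised way. Uses Silverman's rule-of-thumb bandwidth,
#' evaluated on a 1 nm grid from 0 to `max + 3 x bandwidth`; with several
#' local maxima the global maximum (highest occurrence frequency) is
#' returned.
#'
#' @param diameters Numeric vector of diameters (nm); at least 10 values.
#' @return The modal diameter in nm, with the bandwidth used attached as
#'   attribute `bandwidth_nm`.
#' @export
kde_mode <- function(diameters) {
  if (length(diameters) < 10) {
    abort("need >= 10 particles for a kernel density mode; inspect a histogram instead")
  }
  bw <- stats::bw.nrd0(diameters)
  hi <- ceiling(max(diameters) + 3 * bw)
  d <- density(diameters, bw = bw, kernel = "gaussian",
               from = 0, to = hi, n = hi + 1L)
  mode_nm <- d$x[which.max(d$y)]
  attr(mode_nm, "bandwidth_nm") <- bw
  mode_nm
}

#' Describe the dilution chain from sample to measured suspension
#'
#' @param steps Data frame with columns `aliquot_mL` and `final_mL`, one
#'   row per dilution step; overall factor is the product of
#'   `final/aliquot`.
#' @param sample_mass_g Mass of sample weighed into the original
#'   suspension (g).
#' @param suspension_volume_mL Volume of the original suspension (mL).
#' @return A `dilution_chain` list with the overall `factor`.
#' @examples
#' # 1:60,000 in two steps
#' dilution_chain(data.frame(aliquot_mL = c(0.1, 0.05), final_mL = c(60, 50)),
#'                sample_mass_g = 0.04, suspension_volume_mL = 40)
#' @export
dilution_chain <- function(steps, sample_mass_g, suspension_volume_mL) {
  steps <- as_tibble(steps)
  if (!all(c("aliquot_mL", "final_mL") %in% names(steps))) {
    abort("steps must have columns aliquot_mL and final_mL")
  }
  if (any(steps$aliquot_mL <= 0) || any(steps$final_mL < steps$aliquot_mL)) {
    abort("each step needs final_mL >= aliquot_mL > 0")
  }
  if (sample_mass_g <= 0 || suspension_volume_mL <= 0) {
    abort("sample_mass_g and suspension_volume_mL must be > 0")
  }
  structure(
    list(
      steps = steps,
      sample_mass_g = sample_mass_g,
      suspension_volume_mL = suspension_volume_mL,
      factor = prod(steps$final_mL / steps$aliquot_mL)
    ),
    class = "dilution_chain"
  )
}

#' Compute the full measurand report of a size distribution
#'
#' Populates every measurand of the screening method: mean and KDE-mode
#' diameter, D0/D10/D50/D99.5/D99.8/D100, the percentage of particles
#' (by number) strictly below 100 nm, the size detection limit, and --
#' when a dilution chain is given -- the particle number concentration of
#' the measured suspension (`n_events / (eta x flow x scan time)`), the
#' total particle number in the original sample and the number of
#' particles per gram of sample.
#'
#' @param diameters Numeric vector of event diameters in nm (e.g. the
#'   `diameter_nm` column of [event_to_masses()] output).
#' @param te Transport efficiency (needed for number concentration).
#' @param flow_mL_min Sample flow in mL/min.
#' @param scan_time_s Acquisition time in seconds.
#' @param size_lod_nm Optional size detection limit to record.
#' @param chain Optional [dilution_chain()]; without it the
#'   sample-referenced concentration fields are `NA` (with a warning).
#' @return A `measurand_report` list.
#' @export
distribution_report <- function(diameters, te = NULL, flow_mL_min = NULL,
                                scan_time_s = NULL, size_lod_nm = NA_real_,
                                chain = NULL) {
  n <- length(diameters)
  if (n > 0 && any(diameters <= 0)) abort("diameters must be positive")
  if (n == 0) {
    rep_base <- list(
      n_events = 0L, mean_nm = NA_real_, mode_nm = NA_real_,
      kde_bandwidth_nm = NA_real_,
      d0_nm = NA_real_, d10_nm = NA_real_, d50_nm = NA_real_,
      d99_5_nm = NA_real_, d99_8_nm = NA_real_, d100_nm = NA_real_,
      pct_below_100 = NA_real_, size_lod_nm = size_lod_nm
    )
  } else {
    qs <- size_quantile(diameters, c(0, 10, 50, 99.5, 99.8, 100))
    mode_nm <- if (n >= 10) kde_mode(diameters) else NA_real_
    rep_base <- list(
      n_events = n,
      mean_nm = mean(diameters),
      mode_nm = as.numeric(mode_nm),
      kde_bandwidth_nm = if (n >= 10) attr(mode_nm, "bandwidth_nm") else NA_real_,
      d0_nm = qs[1], d10_nm = qs[2], d50_nm = qs[3],
      d99_5_nm = qs[4], d99_8_nm = qs[5], d100_nm = qs[6],
      pct_below_100 = 100 * mean(diameters < 100),
      size_lod_nm = size_lod_nm
    )
  }
  conc <- NA_real_
  if (!is.null(te) && !is.null(flow_mL_min) && !is.null(scan_time_s)) {
    q <- ml_min_to_ml_s(flow_mL_min)
    conc <- n / (te$eta * q * scan_time_s)
  }
  total <- NA_real_
  per_g <- NA_real_
  if (!is.null(chain)) {
    stopifnot(inherits(chain, "dilution_chain"))
    if (is.na(conc)) {
      warn("number concentration unavailable; sample-referenced fields are NA")
    } else {
      total <- conc * chain$factor * chain$suspension_volume_mL
      per_g <- total / chain$sample_mass_g
    }
  } else if (!is.na(conc)) {
    warn("no dilution chain given; sample-referenced fields are NA",
         .frequency = "once", .frequency_id = "nanoscreen_no_chain")
  }
  structure(
    c(rep_base, list(
      number_concentration_per_mL = conc,
      total_particles_in_sample = total,
      particles_per_g = per_g
    )),
    class = "measurand_report"
  )
}

#' @export
print.measurand_report <- function(x, ...) {
  cat(sprintf(
    paste0("<measurand_report> n = %d events\n",
           "  mean %.4g nm, mode %.4g nm, D50 %.4g nm, %%<100 nm %.3g\n",
           "  D0 %.4g | D10 %.4g | D99.5 %.4g | D99.8 %.4g | D100 %.4g nm\n",
           "  size LOD %.4g nm; number conc %.4g mL^-1; %.4g particles/g\n"),
    x$n_events, x$mean_nm, x$mode_nm, x$d50_nm, x$pct_below_100,
    x$d0_nm, x$d10_nm, x$d99_5_nm, x$d99_8_nm, x$d100_nm,
    x$size_lod_nm, x$number_concentration_per_mL, x$particles_per_g
  ))
  invisible(x)
}
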