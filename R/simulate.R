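#' Configuration for a synthetic spICP-MS scan
#'
#' Defines the suspension, instrument and material model used by
#' [simulate_scan()]. The defaults emulate a diluted food-grade TiO2
#' suspension measured under typical screening conditions: a lognormal
#' constituent size distribution (median 150 nm, geometric SD 1.4,
#' truncated to 10--1000 nm), a number concentration giving on the order
#' of 1000--2000 detected events in a 60 s scan at 0.17 mL/min and 12%
#' transport efficiency, and a 100 us dwell time. Sensitivity and
#' background are order-of-magnitude instrument choices (the per-lab
#' values of real instruments are rarely reported); together they place
#' the size detection limit near 35 nm.
#'
#' @param median_nm Median of the lognormal constituent diameter model (nm).
#' @param gsd Geometric standard deviation of the size model (> 1 for a
#'   spread; 1 collapses to monodisperse).
#' @param size_bounds_nm Truncation bounds of the size model (nm).
#' @param p_agg Probability that an event is an agglomerate (carries extra
#'   constituent particles).
#' @param lambda_agg Mean number of extra constituents per agglomerated
#'   event (Poisson).
#' @param number_concentration_per_mL Particle number concentration of the
#'   measured suspension (mL^-1).
#' @param flow_mL_min Sample uptake flow (mL/min).
#' @param transport_efficiency Fraction of nebulised sample reaching the
#'   plasma, in (0, 1].
#' @param dwell_time_s Dwell time (s).
#' @param scan_time_s Total acquisition time (s).
#' @param sensitivity_counts_per_fg Detector counts generated per fg of
#'   analyte reaching the plasma.
#' @param background_mean_counts Mean continuous background (counts per
#'   dwell).
#' @param pulse_width_s Duration of a single particle's ion cloud at the
#'   detector; events spread over `ceiling(pulse_width/dwell)` dwells, so
#'   100 us dwells see multi-dwell spikes while 3000 us dwells integrate a
#'   whole particle in one dwell.
#' @param compound An [element_compound()] (defaults to anatase TiO2).
#' @param seed Mandatory integer seed; identical seeds give bit-identical
#'   scans.
#' @return A `scan_sim_config` list.
#' @export
scan_sim_config <- function(median_nm = 150, gsd = 1.4,
                            size_bounds_nm = c(10, 1000),
                            p_agg = 0, lambda_agg = 1,
                            number_concentration_per_mL = 7.5e4,
                            flow_mL_min = 0.17,
                            transport_efficiency = 0.12,
                            dwell_time_s = 1e-4, scan_time_s = 60,
                            sensitivity_counts_per_fg = 250,
                            background_mean_counts = 20,
                            pulse_width_s = 5e-4,
                            compound = compound_tio2_anatase(),
                            seed) {
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory for reproducible simulation")
  }
  if (transport_efficiency <= 0 || transport_efficiency > 1) {
    abort("transport_efficiency must be in (0, 1]")
  }
  if (number_concentration_per_mL < 0 || flow_mL_min < 0 ||
      background_mean_counts < 0 || sensitivity_counts_per_fg < 0 ||
      p_agg < 0 || p_agg > 1 || lambda_agg < 0) {
    abort("rates, concentrations and probabilities must be valid")
  }
  if (median_nm <= 0 || gsd < 1) abort("need median_nm > 0 and gsd >= 1")
  stopifnot(inherits(compound, "element_compound"))
  structure(
    list(
      median_nm = median_nm, gsd = gsd, size_bounds_nm = size_bounds_nm,
      p_agg = p_agg, lambda_agg = lambda_agg,
      number_concentration_per_mL = number_concentration_per_mL,
      flow_mL_min = flow_mL_min,
      transport_efficiency = transport_efficiency,
      dwell_time_s = dwell_time_s, scan_time_s = scan_time_s,
      sensitivity_counts_per_fg = sensitivity_counts_per_fg,
      background_mean_counts = background_mean_counts,
      pulse_width_s = pulse_width_s,
      compound = compound,
      seed = as.integer(seed)
    ),
    class = "scan_sim_config"
  )
}

# draw n diameters from the truncated lognormal constituent model
draw_constituent_diameters <- function(n, config) {
  if (n == 0) return(numeric(0))
  mu <- log(config$median_nm)
  sig <- log(config$gsd)
  if (sig == 0) return(rep(config$median_nm, n))
  lo <- plnorm(config$size_bounds_nm[1], mu, sig)
  hi <- plnorm(config$size_bounds_nm[2], mu, sig)
  qlnorm(runif(n, lo, hi), mu, sig)
}

# deposit per-event analyte masses into a per-dwell expected-signal vector
deposit_events <- function(arrival, analyte_mass_fg, n_dwells, n_split) {
  signal <- numeric(n_dwells)
  if (length(arrival) == 0) return(signal)
  idx <- as.vector(vapply(0:(n_split - 1), function(k) {
    pmin(arrival + k, n_dwells) # clip spill-over into the final dwell
  }, integer(length(arrival))))
  vals <- rep(analyte_mass_fg / n_split, n_split)
  acc <- rowsum(vals, idx)
  signal[as.integer(rownames(acc))] <- acc[, 1]
  signal
}

#' Simulate one spICP-MS scan with known ground truth
#'
#' Particle arrivals per dwell are Poisson with rate
#' `lambda = concentration x flow x transport efficiency x dwell time`;
#' each event is one constituent particle, plus (with probability `p_agg`)
#' a Poisson number of extra constituents that travel as one agglomerate;
#' the event's analyte mass is deposited over
#' `ceiling(pulse_width/dwell)` dwells and detector counts are Poisson
#' around `background + sensitivity x deposited mass`. Events arriving in
#' the same dwell coincide (their masses sum at the detector).
#'
#' @param config A [scan_sim_config()].
#' @return A list with `scan` (a [time_scan()]) and `truth` (a `sim_truth`
#'   list: per-event tibble `events`, per-constituent tibble
#'   `constituents`, and the scalar truths of the material model).
#' @export
simulate_scan <- function(config) {
  stopifnot(inherits(config, "scan_sim_config"))
  q <- ml_min_to_ml_s(config$flow_mL_min)
  lambda <- config$number_concentration_per_mL * q *
    config$transport_efficiency * config$dwell_time_s
  if (lambda > 10) {
    abort(sprintf(
      "expected %.3g events per dwell: unresolvable coincidence regime (max 10)",
      lambda))
  }
  n_dwells <- as.integer(round(config$scan_time_s / config$dwell_time_s))
  withr::with_seed(config$seed, {
    n_events <- rpois(1, lambda * n_dwells)
    arrival <- sort(sample.int(n_dwells, n_events, replace = TRUE))
    extra <- if (n_events > 0) {
      ifelse(runif(n_events) < config$p_agg, rpois(n_events, config$lambda_agg), 0L)
    } else integer(0)
    n_const <- 1L + as.integer(extra)
    d_all <- draw_constituent_diameters(sum(n_const), config)
    ev_id <- rep(seq_len(n_events), n_const)
    const_mass <- diameter_to_mass(d_all, config$compound$density_g_cm3)
    ev_compound_mass <- as.numeric(rowsum(const_mass, ev_id))
    ev_analyte_mass <- ev_compound_mass * config$compound$analyte_mass_fraction
    n_split <- max(1L, as.integer(ceiling(config$pulse_width_s /
                                            config$dwell_time_s)))
    signal <- deposit_events(arrival, ev_analyte_mass, n_dwells, n_split)
    counts <- rpois(n_dwells, config$background_mean_counts +
                      config$sensitivity_counts_per_fg * signal)
  })
  scan <- time_scan(counts, config$dwell_time_s,
                    isotope_label = config$compound$analyte,
                    metadata = list(simulated = TRUE, seed = config$seed))
  truth <- structure(
    list(
      events = tibble(
        event = seq_len(n_events),
        arrival_dwell = arrival,
        n_constituents = n_const,
        compound_mass_fg = if (n_events) ev_compound_mass else numeric(0),
        analyte_mass_fg = if (n_events) ev_analyte_mass else numeric(0),
        esd_nm = if (n_events) {
          mass_to_diameter(ev_compound_mass, config$compound$density_g_cm3)
        } else numeric(0)
      ),
      constituents = tibble(
        event = if (n_events) ev_id else integer(0),
        diameter_nm = d_all
      ),
      n_events = n_events,
      true_number_concentration_per_mL = config$number_concentration_per_mL,
      true_median_nm = config$median_nm,
      config = config
    ),
    class = "sim_truth"
  )
  list(scan = scan, truth = truth)
}

#' Simulate a monodisperse reference-particle scan
#'
#' Emulates the gold reference suspension used to determine transport
#' efficiency: particle diameters are normal around the nominal value
#' (default CV 5%), the analyte mass fraction is 1 and the density that of
#' gold.
#'
#' @param diameter_nm Nominal reference diameter (nm), e.g. 63 for the
#'   usual gold nanospheres.
#' @param diameter_cv Coefficient of variation of the diameter (0 gives
#'   identical particles).
#' @param density_g_cm3 Particle density (gold: 19.30).
#' @param config A [scan_sim_config()] supplying instrument and suspension
#'   parameters (its size model and compound are overridden).
#' @return As [simulate_scan()].
#' @export
simulate_reference_scan <- function(diameter_nm = 63, diameter_cv = 0.05,
                                    density_g_cm3 = 19.30, config) {
  stopifnot(inherits(config, "scan_sim_config"))
  if (diameter_nm <= 0) abort("diameter_nm must be > 0")
  ref_compound <- element_compound(1, density_g_cm3,
                                   analyte = "Au-197", compound = "reference")
  cfg <- config
  cfg$compound <- ref_compound
  cfg$p_agg <- 0
  # monodisperse normal model replaces the lognormal draw
  q <- ml_min_to_ml_s(cfg$flow_mL_min)
  lambda <- cfg$number_concentration_per_mL * q *
    cfg$transport_efficiency * cfg$dwell_time_s
  if (lambda > 10) abort("unresolvable coincidence regime (max 10 per dwell)")
  n_dwells <- as.integer(round(cfg$scan_time_s / cfg$dwell_time_s))
  withr::with_seed(cfg$seed, {
    n_events <- rpois(1, lambda * n_dwells)
    arrival <- sort(sample.int(n_dwells, n_events, replace = TRUE))
    d <- if (diameter_cv > 0) {
      pmax(rnorm(n_events, diameter_nm, diameter_cv * diameter_nm), 1)
    } else rep(diameter_nm, n_events)
    mass <- diameter_to_mass(d, density_g_cm3)
    n_split <- max(1L, as.integer(ceiling(cfg$pulse_width_s / cfg$dwell_time_s)))
    signal <- deposit_events(arrival, mass, n_dwells, n_split)
    counts <- rpois(n_dwells, cfg$background_mean_counts +
                      cfg$sensitivity_counts_per_fg * signal)
  })
  scan <- time_scan(counts, cfg$dwell_time_s, isotope_label = "Au-197",
                    metadata = list(simulated = TRUE, seed = cfg$seed,
                                    reference = TRUE))
  truth <- structure(
    list(
      events = tibble(
        event = seq_len(n_events), arrival_dwell = arrival,
        n_constituents = rep(1L, n_events),
        compound_mass_fg = mass, analyte_mass_fg = mass, esd_nm = d
      ),
      constituents = tibble(event = seq_len(n_events), diameter_nm = d),
      n_events = n_events,
      true_number_concentration_per_mL = cfg$number_concentration_per_mL,
      true_median_nm = diameter_nm,
      config = cfg
    ),
    class = "sim_truth"
  )
  list(scan = scan, truth = truth)
}

#' Simulate ionic calibration points under the scan model
#'
#' Mean counts per dwell at each dissolved-standard concentration, from
#' Poisson counting over `n_dwells` dwells at the configured sensitivity,
#' flow, transport efficiency and background. The background enters the
#' intercept; the slope is `sensitivity x flow x eta x dwell x 1e6`
#' counts per dwell per ug/L in expectation.
#'
#' @param concs_ug_per_L Concentrations of the calibration standards.
#' @param config A [scan_sim_config()].
#' @param n_dwells Dwells averaged per calibration point.
#' @return A tibble with columns `conc_ug_per_L`, `mean_counts`.
#' @export
simulate_ionic_calibration <- function(concs_ug_per_L = c(0, 5, 10, 25, 50),
                                       config, n_dwells = 60000) {
  stopifnot(inherits(config, "scan_sim_config"))
  q <- ml_min_to_ml_s(config$flow_mL_min)
  expected <- config$background_mean_counts +
    config$sensitivity_counts_per_fg * concs_ug_per_L *
      UG_PER_L_TO_FG_PER_ML * q * config$transport_efficiency *
      config$dwell_time_s
  withr::with_seed(config$seed + 1L, {
    mean_counts <- vapply(expected, function(mu) {
      mean(rpois(n_dwells, mu))
    }, numeric(1))
  })
  tibble(conc_ug_per_L = concs_ug_per_L, mean_counts = mean_counts)
}

#' Configuration for a simulated interlaboratory study
#'
#' Laboratories share the material truth but differ in instrument
#' parameters, drawn per lab from the stated ranges. The defaults follow
#' the spread observed across food-control laboratories running this
#' method: transport efficiencies of roughly 5--14%, dwell times of
#' 100 us or 3000 us, flows of about 0.17--0.47 mL/min, and a relative
#' sensitivity bias per lab.
#'
#' @param n_labs Number of laboratories (>= 2).
#' @param replicates Replicates per laboratory (>= 2).
#' @param te_range Transport-efficiency range sampled per lab.
#' @param dwell_choices_s Dwell times sampled per lab (s).
#' @param flow_range_mL_min Flow range sampled per lab (mL/min).
#' @param sensitivity_bias_sd Lognormal SD of the per-lab relative
#'   sensitivity bias (0 = identical instruments).
#' @param material A [scan_sim_config()] describing the shared material
#'   and the baseline instrument.
#' @param seed Integer seed; per-lab seeds are derived from it.
#' @return An `ilc_sim_config` list.
#' @export
ilc_sim_config <- function(n_labs = 7, replicates = 3,
                           te_range = c(0.05, 0.14),
                           dwell_choices_s = c(1e-4, 3e-3),
                           flow_range_mL_min = c(0.17, 0.47),
                           sensitivity_bias_sd = 0.05,
                           material = scan_sim_config(seed = 1),
                           seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  if (n_labs < 2) abort("n_labs must be >= 2")
  if (replicates < 2) abort("replicates must be >= 2")
  structure(
    list(n_labs = as.integer(n_labs), replicates = as.integer(replicates),
         te_range = te_range, dwell_choices_s = dwell_choices_s,
         flow_range_mL_min = flow_range_mL_min,
         sensitivity_bias_sd = sensitivity_bias_sd,
         material = material, seed = as.integer(seed)),
    class = "ilc_sim_config"
  )
}

#' Simulate the scans of an interlaboratory study
#'
#' Draws per-lab instrument parameters, then simulates `replicates` scans
#' per lab of the shared material. Deterministic given the seed; lab
#' seeds are derived as `seed + 1000 x lab + replicate`.
#'
#' @param config An [ilc_sim_config()].
#' @return A tibble with one row per (lab, replicate): lab parameters and
#'   list-columns `scan` and `truth`.
#' @export
simulate_ilc_study <- function(config) {
  stopifnot(inherits(config, "ilc_sim_config"))
  withr::with_seed(config$seed, {
    labs <- tibble(
      lab = seq_len(config$n_labs),
      transport_efficiency = runif(config$n_labs, config$te_range[1],
                                   config$te_range[2]),
      dwell_time_s = sample(config$dwell_choices_s, config$n_labs,
                            replace = TRUE),
      flow_mL_min = runif(config$n_labs, config$flow_range_mL_min[1],
                          config$flow_range_mL_min[2]),
      sensitivity_factor = exp(rnorm(config$n_labs, 0,
                                     config$sensitivity_bias_sd))
    )
  })
  grid <- tidyr::expand_grid(labs, replicate = seq_len(config$replicates))
  sims <- purrr::pmap(grid, function(lab, transport_efficiency, dwell_time_s,
                                     flow_mL_min, sensitivity_factor,
                                     replicate) {
    m <- config$material
    cfg <- scan_sim_config(
      median_nm = m$median_nm, gsd = m$gsd, size_bounds_nm = m$size_bounds_nm,
      p_agg = m$p_agg, lambda_agg = m$lambda_agg,
      number_concentration_per_mL = m$number_concentration_per_mL,
      flow_mL_min = flow_mL_min,
      transport_efficiency = transport_efficiency,
      dwell_time_s = dwell_time_s, scan_time_s = m$scan_time_s,
      sensitivity_counts_per_fg = m$sensitivity_counts_per_fg *
        sensitivity_factor,
      # background scales with the integration window
      background_mean_counts = m$background_mean_counts *
        dwell_time_s / m$dwell_time_s,
      pulse_width_s = m$pulse_width_s, compound = m$compound,
      seed = config$seed + 1000L * lab + replicate
    )
    simulate_scan(cfg)
  })
  grid$scan <- purrr::map(sims, "scan")
  grid$truth <- purrr::map(sims, "truth")
  grid
}

#' Process a simulated interlaboratory study into a measurand table
#'
#' Runs the full per-lab measurement chain on each simulated scan: an
#' ionic calibration and a reference-particle scan under the lab's
#' instrument parameters give the calibration slope and the size-method
#' transport efficiency; events are then detected, sized and summarised.
#'
#' @param study Output of [simulate_ilc_study()].
#' @param config The [ilc_sim_config()] used to generate it.
#' @param k_sigma_detect Detection threshold for spike discrimination
#'   (default 5; the 3-sigma value defines the size LOD, not the spike
#'   filter).
#' @param chain Optional [dilution_chain()] applied to every lab.
#' @return A long tibble (lab, replicate, measurand, unit, value) of class
#'   `ilc_measurands`, 11 measurands per scan.
#' @export
process_ilc_study <- function(study, config, k_sigma_detect = 5,
                              chain = NULL) {
  stopifnot(inherits(config, "ilc_sim_config"))
  lab_params <- dplyr::distinct(
    study, .data$lab, .data$transport_efficiency, .data$dwell_time_s,
    .data$flow_mL_min, .data$sensitivity_factor
  )
  # per-lab calibration + transport efficiency from a reference scan
  lab_cal <- purrr::pmap(lab_params, function(lab, transport_efficiency,
                                              dwell_time_s, flow_mL_min,
                                              sensitivity_factor) {
    m <- config$material
    ref_cfg <- scan_sim_config(
      number_concentration_per_mL = 1e5,
      flow_mL_min = flow_mL_min,
      transport_efficiency = transport_efficiency,
      dwell_time_s = dwell_time_s, scan_time_s = m$scan_time_s,
      sensitivity_counts_per_fg = m$sensitivity_counts_per_fg *
        sensitivity_factor,
      background_mean_counts = m$background_mean_counts *
        dwell_time_s / m$dwell_time_s,
      pulse_width_s = m$pulse_width_s,
      seed = config$seed + 500000L + lab
    )
    cal_pts <- simulate_ionic_calibration(c(0, 1, 2.5, 5, 10), ref_cfg)
    cal <- fit_ionic_calibration(cal_pts)
    ref <- simulate_reference_scan(config = ref_cfg)
    bg <- estimate_background(ref$scan)
    ev <- detect_events(ref$scan, bg, k_sigma = k_sigma_detect)
    te <- estimate_te_size(mean(ev$net_counts), 63, cal, flow_mL_min,
                           dwell_time_s)
    list(lab = lab, cal = cal, te = te)
  })
  names(lab_cal) <- as.character(lab_params$lab)

  rows <- purrr::pmap(study, function(lab, transport_efficiency,
                                      dwell_time_s, flow_mL_min,
                                      sensitivity_factor, replicate,
                                      scan, truth) {
    lc <- lab_cal[[as.character(lab)]]
    bg <- estimate_background(scan)
    ev <- detect_events(scan, bg, k_sigma = k_sigma_detect)
    ev <- event_to_masses(ev, lc$cal, lc$te, flow_mL_min, dwell_time_s,
                          config$material$compound)
    lod <- size_detection_limit(bg, lc$cal, lc$te, flow_mL_min,
                                dwell_time_s, config$material$compound)
    rpt <- distribution_report(ev$diameter_nm, lc$te, flow_mL_min,
                               scan$scan_time_s, size_lod_nm = lod,
                               chain = chain)
    dplyr::mutate(measurand_long(rpt), lab = lab, replicate = replicate,
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ilc_measurands", class(out))
  out
}

# the 11 measurands evaluated in the collaborative trial, in table order
measurand_long <- function(rpt) {
  tibble(
    measurand = c("mean_diameter", "mode_diameter", "pct_below_100",
                  "d10", "d50", "d99_5", "d99_8", "d0", "d100",
                  "total_particles_in_sample", "particles_per_g"),
    unit = c("nm", "nm", "%", "nm", "nm", "nm", "nm", "nm", "nm",
             "#", "#/g"),
    value = c(rpt$mean_nm, rpt$mode_nm, rpt$pct_below_100, rpt$d10_nm,
              rpt$d50_nm, rpt$d99_5_nm, rpt$d99_8_nm, rpt$d0_nm,
              rpt$d100_nm, rpt$total_particles_in_sample,
              rpt$particles_per_g)
  )
}

#' Simulate a balanced lab x replicate precision study
#'
#' Gaussian variance-component model for exercising the interlaboratory
#' statistics: `value = mu + lab effect (SD sd_between) + replicate error
#' (SD sd_within)`.
#'
#' @param n_labs,replicates Design size.
#' @param mu True consensus value.
#' @param sd_between,sd_within Between-lab and within-lab SDs.
#' @param seed Integer seed.
#' @return A long tibble (lab, replicate, value).
#' @export
simulate_precision_study <- function(n_labs = 7, replicates = 3, mu = 150,
                                     sd_between = 10, sd_within = 3, seed) {
  if (missing(seed)) abort("seed is mandatory")
  withr::with_seed(seed, {
    lab_eff <- rnorm(n_labs, 0, sd_between)
    tidyr::expand_grid(lab = seq_len(n_labs),
                       replicate = seq_len(replicates)) |>
      dplyr::mutate(value = mu + lab_eff[.data$lab] +
                      rnorm(dplyr::n(), 0, sd_within))
  })
}
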