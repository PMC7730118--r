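# Shared fixtures: small, fast configurations used across test files.

# an exactly consistent calibration/TE context (no simulation noise):
# slope chosen so a net signal of 1000 counts maps to 1.225 fg analyte at
# eta = 0.12, flow = 0.17 mL/min, dwell = 1e-4 s
exact_context <- function() {
  eta <- 0.12
  flow <- 0.17
  dwell <- 1e-4
  q <- flow / 60
  slope <- 1000 * q * eta * dwell * 1e6 / 1.225
  cal <- fit_ionic_calibration(data.frame(
    conc_ug_per_L = c(0, 10, 20, 30, 50),
    mean_counts = slope * c(0, 10, 20, 30, 50)
  ))
  te <- structure(list(eta = eta, method = "size", inputs = list()),
                  class = "transport_efficiency")
  list(cal = cal, te = te, flow_mL_min = flow, dwell_time_s = dwell,
       compound = compound_tio2_anatase())
}

# small fast scan config (short scan, high concentration) for plumbing
# tests where statistical power is not the point
quick_config <- function(seed = 42, ...) {
  scan_sim_config(
    scan_time_s = 5,
    number_concentration_per_mL = 6e5,
    seed = seed,
    ...
  )
}

# deterministic synthetic TEM table: lognormal Fmin with correlated Fmax
synthetic_tem_table <- function(n = 1200, median_nm = 85, gsd = 1.35,
                                seed = 7) {
  withr::with_seed(seed, {
    fmin <- stats::rlnorm(n, log(median_nm), log(gsd))
    ar <- 1 + stats::rgamma(n, shape = 2, rate = 14)
    tem_particle_table(tibble::tibble(fmin_nm = fmin, fmax_nm = fmin * ar),
                       source_label = "synthetic")
  })
}
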