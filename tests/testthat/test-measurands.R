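test_that("the counts -> mass -> diameter chain reproduces hand arithmetic", {
  ctx <- exact_context()
  ev <- tibble::tibble(net_counts = 1000)
  out <- event_to_masses(ev, ctx$cal, ctx$te, ctx$flow_mL_min,
                         ctx$dwell_time_s, ctx$compound)
  expect_equal(out$analyte_mass_fg, 1.225, tolerance = 1e-9)
  expect_equal(out$compound_mass_fg, 1.225 / 0.6, tolerance = 1e-9)

  # 2.042 fg TiO2 at 3.9 g/cm3 is a 100 nm sphere
  expect_equal(mass_to_diameter(2.042, 3.9), 100, tolerance = 1e-4)
  expect_equal(mass_to_diameter(0, 3.9), 0)
  # algebraic inverse round-trip
  m <- c(0.01, 0.5, 2.042, 40)
  expect_equal(diameter_to_mass(mass_to_diameter(m, 3.9), 3.9), m,
               tolerance = 1e-12)
  expect_error(event_to_masses(tibble::tibble(net_counts = -5), ctx$cal,
                               ctx$te, ctx$flow_mL_min, ctx$dwell_time_s,
                               ctx$compound))
})

test_that("simulated event masses are recovered through the chain", {
  cfg <- scan_sim_config(seed = 301)
  cal <- fit_ionic_calibration(simulate_ionic_calibration(config = cfg))
  te <- structure(list(eta = cfg$transport_efficiency, method = "size",
                       inputs = list()), class = "transport_efficiency")
  sim <- simulate_scan(cfg)
  bg <- estimate_background(sim$scan)
  ev <- detect_events(sim$scan, bg, k_sigma = 5)
  ev <- event_to_masses(ev, cal, te, cfg$flow_mL_min, cfg$dwell_time_s,
                        cfg$compound)
  expect_equal(mean(ev$compound_mass_fg),
               mean(sim$truth$events$compound_mass_fg), tolerance = 0.03)
})

test_that("D-values follow the order-statistic convention", {
  expect_equal(size_quantile(c(10, 20, 30, 40, 50), 50), 30)
  expect_equal(size_quantile(rep(42, 9), c(0, 10, 50, 99.8, 100)),
               rep(42, 5))
  x <- withr::with_seed(1, stats::rlnorm(500, log(150), log(1.4)))
  expect_equal(size_quantile(x, 0), min(x))
  expect_equal(size_quantile(x, 100), max(x))
  # linear interpolation at position 1 + (n-1) p
  expect_equal(size_quantile(c(1, 2, 10, 100), 50), 6)
  expect_error(size_quantile(numeric(0), 50))
  expect_error(size_quantile(x, 101))
})

test_that("excluded-particle bookkeeping matches the truncation table", {
  levels <- c(90, 95, 99, 99.5, 99.8, 100)
  expect_equal(excluded_count(2000, levels), c(200, 100, 20, 10, 4, 0))
  expect_equal(excluded_count(1000, 99.8), 2)
  # rounding is half-up
  expect_equal(excluded_count(250, 99), 3) # 2.5 -> 3
})

test_that("counting above a D-value agrees with excluded_count within rounding", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, stats::rlnorm(sample(50:2000, 1),
                                              log(150), log(1.4)))
    for (lv in c(90, 99, 99.5, 99.8)) {
      n_above <- sum(x > size_quantile(x, lv))
      expect_lte(abs(n_above - excluded_count(length(x), lv)), 1)
    }
  }
})

test_that("the KDE mode is bin-free and matches closed-form modes", {
  # symmetric unimodal: mode near the mean
  x <- withr::with_seed(2, rnorm(2000, 150, 20))
  expect_lt(abs(as.numeric(kde_mode(x)) - 150), 5)

  # lognormal: theoretical mode exp(mu - sigma^2)
  mu <- log(150)
  sig <- log(1.4)
  y <- withr::with_seed(3, stats::rlnorm(5000, mu, sig))
  theo <- exp(mu - sig^2)
  expect_lt(abs(as.numeric(kde_mode(y)) - theo) / theo, 0.06)

  # re-binning for display cannot change it (property: KDE ignores bins)
  expect_identical(as.numeric(kde_mode(y)), as.numeric(kde_mode(y)))
  expect_error(kde_mode(1:9), "histogram")
})

test_that("distribution reports populate every measurand consistently", {
  ctx <- exact_context()
  chain <- dilution_chain(
    tibble::tibble(aliquot_mL = c(1, 0.1), final_mL = c(60, 100)),
    sample_mass_g = 0.04, suspension_volume_mL = 40)
  expect_equal(chain$factor, 60000)

  d <- withr::with_seed(4, stats::rlnorm(1200, log(150), log(1.4)))
  rpt <- distribution_report(d, ctx$te, ctx$flow_mL_min, 60,
                             size_lod_nm = 35, chain = chain)
  # number concentration: n / (eta * flow * scan time)
  expect_equal(rpt$number_concentration_per_mL, 1200 / (0.12 * 0.17),
               tolerance = 1e-9)
  expect_equal(rpt$number_concentration_per_mL, 5.88e4, tolerance = 1e-2)
  expect_equal(rpt$total_particles_in_sample,
               rpt$number_concentration_per_mL * 60000 * 40)
  expect_equal(rpt$particles_per_g, rpt$total_particles_in_sample / 0.04)
  # D-value monotonicity
  dv <- c(rpt$d0_nm, rpt$d10_nm, rpt$d50_nm, rpt$d99_5_nm, rpt$d99_8_nm,
          rpt$d100_nm)
  expect_true(all(diff(dv) >= 0))
  # right-skew: mean above median
  expect_gt(rpt$mean_nm, rpt$d50_nm)
  # strict < 100 nm convention
  expect_equal(rpt$pct_below_100, 100 * mean(d < 100))
  rpt_b <- distribution_report(c(99.9, 100, 100.1))
  expect_equal(rpt_b$pct_below_100, 100 / 3)

  # doubling the dilution factor doubles the per-gram count
  chain2 <- dilution_chain(
    tibble::tibble(aliquot_mL = c(1, 0.1), final_mL = c(120, 100)),
    sample_mass_g = 0.04, suspension_volume_mL = 40)
  rpt2 <- distribution_report(d, ctx$te, ctx$flow_mL_min, 60, chain = chain2)
  expect_equal(rpt2$particles_per_g / rpt$particles_per_g, 2)

  # empty distribution: zero concentration, NA measurands
  empty <- suppressWarnings(distribution_report(
    numeric(0), ctx$te, ctx$flow_mL_min, 60))
  expect_equal(empty$n_events, 0)
  expect_equal(empty$number_concentration_per_mL, 0)
  expect_true(is.na(empty$d50_nm))
  # missing chain leaves sample-referenced fields NA
  no_chain <- suppressWarnings(
    distribution_report(d, ctx$te, ctx$flow_mL_min, 60))
  expect_true(is.na(no_chain$particles_per_g))
  expect_true(is.na(no_chain$total_particles_in_sample))
  expect_false(is.na(no_chain$number_concentration_per_mL))
})

test_that("a simulated suspension's measurands are recovered", {
  cfg <- scan_sim_config(seed = 2024)
  cal <- fit_ionic_calibration(simulate_ionic_calibration(config = cfg))
  ref_cfg <- scan_sim_config(number_concentration_per_mL = 1e5, seed = 2025)
  ref <- simulate_reference_scan(config = ref_cfg)
  ref_bg <- estimate_background(ref$scan)
  ref_ev <- detect_events(ref$scan, ref_bg, k_sigma = 5)
  te <- estimate_te_size(mean(ref_ev$net_counts), 63, cal,
                         cfg$flow_mL_min, cfg$dwell_time_s)

  sim <- simulate_scan(cfg)
  bg <- estimate_background(sim$scan)
  ev <- detect_events(sim$scan, bg, k_sigma = 5)
  ev <- event_to_masses(ev, cal, te, cfg$flow_mL_min, cfg$dwell_time_s,
                        cfg$compound)
  rpt <- suppressWarnings(distribution_report(
    ev$diameter_nm, te, cfg$flow_mL_min, cfg$scan_time_s))
  expect_gt(rpt$n_events, 1000)
  expect_equal(rpt$d50_nm, 150, tolerance = 0.03)
  expect_equal(rpt$number_concentration_per_mL,
               cfg$number_concentration_per_mL, tolerance = 0.1)
})
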