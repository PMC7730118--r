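test_that("identical seeds give bit-identical scans, different seeds differ", {
  a <- simulate_scan(quick_config(seed = 11))
  b <- simulate_scan(quick_config(seed = 11))
  c <- simulate_scan(quick_config(seed = 12))
  expect_identical(a$scan$counts, b$scan$counts)
  expect_identical(a$truth$events, b$truth$events)
  expect_false(identical(a$scan$counts, c$scan$counts))
})

test_that("zero concentration yields background-only scans", {
  cfg <- scan_sim_config(number_concentration_per_mL = 0, scan_time_s = 5,
                         seed = 3)
  sim <- simulate_scan(cfg)
  expect_equal(sim$truth$n_events, 0)
  se <- sqrt(cfg$background_mean_counts / length(sim$scan$counts))
  expect_lt(abs(mean(sim$scan$counts) - cfg$background_mean_counts), 3 * se)
})

test_that("event counts follow the Poisson arrival model", {
  # lambda * n_dwells = 1500 expected events at the default operating point
  cfg <- scan_sim_config(seed = 5)
  q <- cfg$flow_mL_min / 60
  expected <- cfg$number_concentration_per_mL * q *
    cfg$transport_efficiency * cfg$scan_time_s
  expect_equal(expected, 1530, tolerance = 0.01) # the 1000-2000 band
  sim <- simulate_scan(cfg)
  expect_lt(abs(sim$truth$n_events - expected), 3 * sqrt(expected))
})

test_that("coincidence-saturated configurations are refused", {
  cfg <- quick_config()
  cfg$number_concentration_per_mL <- 1e12
  expect_error(simulate_scan(cfg), "coincidence")
})

test_that("expected deposited counts conserve total injected mass", {
  cfg <- quick_config(seed = 21)
  sim <- simulate_scan(cfg)
  injected <- sum(sim$truth$events$analyte_mass_fg)
  n_bg <- length(sim$scan$counts) * cfg$background_mean_counts
  measured <- (sum(sim$scan$counts) - n_bg) / cfg$sensitivity_counts_per_fg
  total_counts <- injected * cfg$sensitivity_counts_per_fg + n_bg
  expect_lt(abs(measured - injected),
            4 * sqrt(total_counts) / cfg$sensitivity_counts_per_fg)
})

test_that("reference scans are monodisperse around the nominal diameter", {
  cfg <- quick_config(seed = 8)
  ref <- simulate_reference_scan(63, diameter_cv = 0, config = cfg)
  expect_equal(unique(ref$truth$events$compound_mass_fg), 2.527,
               tolerance = 1e-3) # (pi/6) d^3 rho for 63 nm gold
  ref_cv <- simulate_reference_scan(63, diameter_cv = 0.05, config = cfg)
  expect_gt(stats::sd(ref_cv$truth$events$esd_nm), 0)
  expect_equal(mean(ref_cv$truth$events$esd_nm), 63, tolerance = 0.02)
})

test_that("agglomerate mixing increases event mass but not constituent size", {
  cfg0 <- quick_config(seed = 31)
  cfg1 <- quick_config(seed = 31, p_agg = 0.4, lambda_agg = 2)
  s0 <- simulate_scan(cfg0)
  s1 <- simulate_scan(cfg1)
  expect_gt(mean(s1$truth$events$n_constituents), 1)
  expect_gt(median(s1$truth$events$esd_nm), median(s0$truth$events$esd_nm))
  # constituent diameters still follow the shared material model
  expect_equal(median(s1$truth$constituents$diameter_nm),
               cfg1$median_nm, tolerance = 0.05)
})

test_that("an ILC simulation emits one scan per lab and replicate", {
  icfg <- ilc_sim_config(
    n_labs = 7, replicates = 3,
    material = scan_sim_config(scan_time_s = 2,
                               number_concentration_per_mL = 6e5, seed = 1),
    seed = 99
  )
  study <- simulate_ilc_study(icfg)
  expect_equal(nrow(study), 21)
  expect_equal(dplyr::n_distinct(study$lab), 7)
  expect_true(all(study$transport_efficiency >= 0.05 &
                    study$transport_efficiency <= 0.14))
  expect_true(all(study$dwell_time_s %in% c(1e-4, 3e-3)))
  # determinism
  study2 <- simulate_ilc_study(icfg)
  expect_identical(study$scan[[1]]$counts, study2$scan[[1]]$counts)
})

test_that("the Gaussian precision-study generator has the declared components", {
  d <- simulate_precision_study(n_labs = 40, replicates = 3, mu = 150,
                                sd_between = 10, sd_within = 3, seed = 4)
  cells <- dplyr::summarise(dplyr::group_by(d, lab),
                            m = mean(value), s = sd(value))
  expect_equal(mean(cells$m), 150, tolerance = 0.05)
  expect_equal(sqrt(mean(cells$s^2)), 3, tolerance = 0.25)
})
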