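test_that("background estimation handles constant and spiked scans", {
  scan <- time_scan(rep(7L, 100), 1e-4)
  bg <- estimate_background(scan)
  expect_equal(bg$mean_counts, 7)
  expect_equal(bg$sd_counts, 0)
  expect_equal(bg$n_iterations, 1L)

  # Poisson(5) background with 100 spikes of 500 counts: every spike dwell
  # excluded and covered by a detected event; the background mean is close
  # to 5 (the iterative cut also trims the Poisson upper tail, so a small
  # downward truncation bias beyond pure sampling error is expected)
  withr::with_seed(14, {
    counts <- rpois(10000, 5)
    spike_at <- sample.int(10000, 100)
    counts[spike_at] <- 500L
  })
  scan2 <- time_scan(counts, 1e-4)
  bg2 <- estimate_background(scan2)
  expect_lt(abs(bg2$mean_counts - 5), 0.1)
  expect_lte(bg2$n_background_dwells, 10000 - 100)
  expect_gte(bg2$n_background_dwells, 10000 - 100 - 500)
  ev <- detect_events(scan2, bg2)
  covered <- unlist(mapply(seq, ev$start, ev$end, SIMPLIFY = FALSE))
  expect_true(all(spike_at %in% covered))

  # on a pure Poisson scan the flagged fraction stays near the
  # theoretical upper-tail mass beyond mu + 3 sigma (truncation during
  # iteration can push it somewhat higher, never by an order of magnitude)
  withr::with_seed(15, pure <- rpois(50000, 20))
  bg3 <- estimate_background(time_scan(pure, 1e-4))
  flagged <- 1 - bg3$n_background_dwells / 50000
  tail_mass <- ppois(20 + 3 * sqrt(20), 20, lower.tail = FALSE)
  expect_lt(flagged, 5 * tail_mass + 0.001)
  expect_lt(abs(bg3$mean_counts - 20), 0.3)

  # too few dwells to characterise a background at all
  expect_error(estimate_background(time_scan(0:8, 1e-4)),
               "background dwells")
})

test_that("event detection merges runs and integrates net counts", {
  bg_counts <- rep(10L, 300)
  bg <- estimate_background(time_scan(bg_counts, 1e-4))
  bg$sd_counts <- 2 # synthetic: threshold 10 + 3*2 = 16

  # no dwell above threshold -> empty result
  ev0 <- detect_events(time_scan(bg_counts, 1e-4), bg)
  expect_equal(nrow(ev0), 0)

  # 50 isolated single-dwell spikes -> 50 events of one dwell each
  counts <- bg_counts
  counts[seq(3, 300, by = 6)] <- 200L
  ev <- detect_events(time_scan(counts, 1e-4), bg)
  expect_equal(nrow(ev), 50)
  expect_true(all(ev$n_dwells == 1))
  expect_equal(ev$net_counts, rep(190, 50))

  # one ion cloud split over 3 contiguous dwells -> exactly one event
  counts2 <- rep(10L, 50)
  counts2[20:22] <- c(80L, 120L, 60L)
  ev2 <- detect_events(time_scan(counts2, 1e-4), bg)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_dwells, 3L)
  expect_equal(ev2$net_counts, 80 + 120 + 60 - 3 * 10)

  # gap bridging merges events split by one sub-threshold dwell
  counts3 <- rep(10L, 50)
  counts3[c(20, 22)] <- 200L
  expect_equal(nrow(detect_events(time_scan(counts3, 1e-4), bg, gap = 0)), 2)
  ev3 <- detect_events(time_scan(counts3, 1e-4), bg, gap = 1)
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$n_dwells, 3L)
})

test_that("event count is monotone non-increasing in k_sigma", {
  sim <- simulate_scan(quick_config(seed = 77))
  bg <- estimate_background(sim$scan)
  ks <- c(3, 5, 8, 12)
  counts <- vapply(ks, function(k) nrow(detect_events(sim$scan, bg, k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recovers the true event count in a clean regime", {
  cfg <- scan_sim_config(seed = 123)
  sim <- simulate_scan(cfg)
  bg <- estimate_background(sim$scan)
  ev <- detect_events(sim$scan, bg, k_sigma = 5)
  expect_lt(abs(nrow(ev) - sim$truth$n_events) / sim$truth$n_events, 0.02)
})

test_that("size detection limit scales and lands where expected", {
  ctx <- exact_context()
  cfg <- scan_sim_config(seed = 55)
  # SOP-scale parameters: simulate, estimate background, compute LOD
  cal_pts <- simulate_ionic_calibration(config = cfg)
  cal <- fit_ionic_calibration(cal_pts)
  sim <- simulate_scan(cfg)
  bg <- estimate_background(sim$scan)
  te <- structure(list(eta = cfg$transport_efficiency, method = "size",
                       inputs = list()), class = "transport_efficiency")
  lod <- size_detection_limit(bg, cal, te, cfg$flow_mL_min,
                              cfg$dwell_time_s, cfg$compound)
  expect_gt(lod, 30)
  expect_lt(lod, 40)

  # doubling sigma_b multiplies the LOD by 2^(1/3)
  bg2 <- bg
  bg2$sd_counts <- 2 * bg$sd_counts
  lod2 <- size_detection_limit(bg2, cal, te, cfg$flow_mL_min,
                               cfg$dwell_time_s, cfg$compound)
  expect_equal(lod2 / lod, 2^(1 / 3), tolerance = 1e-9)

  # zero-variance background degrades to the 1-count equivalent
  bg0 <- bg
  bg0$sd_counts <- 0
  expect_warning(
    lod0 <- size_detection_limit(bg0, ctx$cal, ctx$te, ctx$flow_mL_min,
                                 ctx$dwell_time_s, ctx$compound),
    "1-count")
  one_count <- mass_to_diameter(
    1 * (0.17 / 60) * 0.12 * 1e-4 * 1e6 / ctx$cal$slope / 0.6, 3.9)
  expect_equal(lod0, one_count, tolerance = 1e-9)
})
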