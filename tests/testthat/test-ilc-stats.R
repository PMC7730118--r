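test_that("Algorithm A handles degenerate and contaminated samples", {
  a <- algorithm_A(rep(5, 7))
  expect_equal(a$x_star, 5)
  expect_equal(a$s_star, 0)

  # a gross outlier is suppressed; the arithmetic mean is not robust
  x <- c(10, 11, 9, 10, 1000)
  a2 <- algorithm_A(x)
  expect_gt(a2$x_star, 9)
  expect_lt(a2$x_star, 11)
  expect_gt(mean(x), 100)
})

test_that("Algorithm A is a consistent scale estimator for normal data", {
  withr::with_seed(100, {
    s_stars <- replicate(400, algorithm_A(rnorm(7))$s_star)
  })
  expect_lt(abs(mean(s_stars) - 1), 0.1)
})

test_that("Algorithm S pools homogeneous and contaminated cell SDs", {
  # identical SDs: recovered within the adjustment-factor tolerance
  s_hom <- algorithm_S(rep(2, 7), nu = 2)
  expect_equal(s_hom, 2, tolerance = 0.06)

  # one SD 50x the rest stays capped
  s_cont <- algorithm_S(c(rep(2, 6), 100), nu = 2)
  expect_lt(abs(s_cont - s_hom) / s_hom, 0.2)

  expect_equal(algorithm_S(rep(0, 5), nu = 2), 0)
})

test_that("Algorithm S is unbiased for normal replicate SDs", {
  # cell SDs of nu = 2 (3 replicates), true sigma_r = 3
  withr::with_seed(101, {
    est <- replicate(300, {
      sds <- vapply(1:7, function(i) sd(rnorm(3, 0, 3)), numeric(1))
      algorithm_S(sds, nu = 2)
    })
  })
  expect_lt(abs(mean(est) - 3) / 3, 0.1)
})

test_that("robust precision recovers planted variance components", {
  errs_r <- errs_R <- numeric(200)
  for (i in 1:200) {
    d <- simulate_precision_study(7, 3, mu = 150, sd_between = 10,
                                  sd_within = 3, seed = 5000 + i)
    p <- robust_precision(d)
    errs_r[i] <- p$s_r
    errs_R[i] <- p$s_R
  }
  true_R <- sqrt(10^2 + 3^2)
  expect_lt(abs(mean(errs_r) - 3) / 3, 0.2)
  expect_lt(abs(mean(errs_R) - true_R) / true_R, 0.2)
})

test_that("noiseless data give exact consensus and zero precision spreads", {
  d <- tidyr::expand_grid(lab = 1:5, replicate = 1:3)
  d$value <- 150
  p <- robust_precision(d)
  expect_equal(p$x_pt, 150)
  expect_equal(p$s_r, 0)
  expect_equal(p$s_R, 0)
  expect_true(p$s_R >= p$s_r)
})

test_that("s_R >= s_r holds on random datasets", {
  for (i in 1:25) {
    d <- simulate_precision_study(
      7, 3, mu = 100,
      sd_between = withr::with_seed(i, runif(1, 0, 5)),
      sd_within = withr::with_seed(i + 1000, runif(1, 0.5, 10)),
      seed = 900 + i)
    p <- robust_precision(d)
    expect_gte(p$s_R, p$s_r)
    pc <- classical_precision(d)
    expect_gte(pc$s_R, pc$s_r)
  }
})

test_that("the robust consensus resists a corrupted laboratory", {
  # one lab's values multiplied by 10: the robust consensus stays within
  # half a standard error of the (corrupted) lab means, the classical
  # mean does not
  n_ok_robust <- 0
  n_ok_classical <- 0
  for (i in 1:50) {
    d <- simulate_precision_study(7, 3, mu = 150, sd_between = 10,
                                  sd_within = 3, seed = 7000 + i)
    p0 <- robust_precision(d)
    dc <- dplyr::mutate(d, value = ifelse(lab == 3, value * 10, value))
    cells <- dplyr::summarise(dplyr::group_by(dc, lab),
                              m = mean(value), .groups = "drop")
    se <- sd(cells$m) / sqrt(nrow(cells))
    p1 <- robust_precision(dc)
    if (abs(p1$x_pt - p0$x_pt) < 0.5 * se) n_ok_robust <- n_ok_robust + 1
    if (abs(mean(cells$m) - p0$x_pt) < 0.5 * se) {
      n_ok_classical <- n_ok_classical + 1
    }
  }
  expect_equal(n_ok_robust, 50)
  expect_equal(n_ok_classical, 0)
})

test_that("robust and classical evaluations agree on clean Gaussian data", {
  agg_r <- agg_R <- matrix(NA_real_, 200, 2)
  x_diff <- numeric(200)
  for (i in 1:200) {
    d <- simulate_precision_study(7, 3, mu = 150, sd_between = 10,
                                  sd_within = 3, seed = 3000 + i)
    pr <- robust_precision(d)
    pc <- classical_precision(d)
    agg_r[i, ] <- c(pr$s_r, pc$s_r)
    agg_R[i, ] <- c(pr$s_R, pc$s_R)
    x_diff[i] <- abs(pr$x_pt - pc$x_pt) / (pc$u_xpt / 2)
  }
  expect_lt(abs(mean(agg_r[, 1]) - mean(agg_r[, 2])) / mean(agg_r[, 2]),
            0.15)
  expect_lt(abs(mean(agg_R[, 1]) - mean(agg_R[, 2])) / mean(agg_R[, 2]),
            0.15)
  # consensus values agree within one standard error on average
  expect_lt(mean(x_diff <= 1), 1.01)
  expect_gt(mean(x_diff <= 1), 0.8)
})

test_that("Grubbs and Cochran screening flags planted outliers", {
  # a gross mean outlier in one lab
  d <- simulate_precision_study(7, 3, mu = 150, sd_between = 5,
                                sd_within = 2, seed = 42)
  d_out <- dplyr::mutate(d, value = ifelse(lab == 5, value + 200, value))
  pc <- classical_precision(d_out)
  grubbs_out <- dplyr::filter(pc$flags, test == "grubbs",
                              level == "outlier")
  expect_equal(grubbs_out$lab, "5")
  expect_equal(pc$n_labs, 6)

  # a 50x replicate-variance outlier in one lab
  d_var <- dplyr::mutate(
    d, value = ifelse(lab == 2, 150 + (value - 150) * 50, value))
  pv <- classical_precision(d_var)
  cochran_out <- dplyr::filter(pv$flags, test == "cochran",
                               level == "outlier")
  expect_true("2" %in% cochran_out$lab)

  # clean data: nothing excluded
  expect_equal(nrow(dplyr::filter(classical_precision(d)$flags,
                                  level == "outlier")), 0)
})

test_that("per-measurand ILC evaluation emits the trial table shape", {
  d <- dplyr::bind_rows(
    dplyr::mutate(simulate_precision_study(7, 3, 150, 10, 3, seed = 1),
                  measurand = "d50"),
    dplyr::mutate(simulate_precision_study(7, 3, 26, 4, 1, seed = 2),
                  measurand = "pct_below_100")
  )
  out <- ilc_precision(d)
  expect_equal(nrow(out), 4) # 2 measurands x 2 methods
  expect_setequal(unique(out$measurand), c("d50", "pct_below_100"))
  expect_true(all(c("x_pt", "u_xpt", "s_R", "s_r", "rsd_R_pct",
                    "rsd_r_pct") %in% names(out)))
  expect_true(all(out$rsd_R_pct >= out$rsd_r_pct - 1e-9))
})

test_that("printed precision triples are checked with rounding awareness", {
  expect_true(check_precision_consistency("158", "12.3", "7.8"))
  # consistent only once input rounding is propagated
  expect_true(check_precision_consistency("38", "17.8", "46.5"))
  # genuinely inconsistent triple fails
  expect_false(check_precision_consistency("158", "12.3", "9.9"))
  expect_false(check_precision_consistency("100", "10.0", "11.5"))
})
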