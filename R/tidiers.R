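#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ionic calibration
#'
#' @param x An `ionic_calibration`.
#' @param ... Unused.
#' @return One row per model term, broom-style.
#' @export
tidy.ionic_calibration <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @rdname tidy.ionic_calibration
#' @export
glance.ionic_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
         n_points = nrow(x$points))
}

#' Tidy a measurand report into a long table
#'
#' @param x A `measurand_report`.
#' @param ... Unused.
#' @return A tibble with one row per measurand (`measurand`, `unit`,
#'   `value`).
#' @export
tidy.measurand_report <- function(x, ...) {
  dplyr::bind_rows(
    measurand_long(x),
    tibble(measurand = c("n_events", "size_lod",
                         "number_concentration"),
           unit = c("#", "nm", "#/mL"),
           value = c(x$n_events, x$size_lod_nm,
                     x$number_concentration_per_mL))
  )
}

#' @rdname tidy.measurand_report
#' @export
glance.measurand_report <- function(x, ...) {
  as_tibble(x[c("n_events", "mean_nm", "mode_nm", "d50_nm",
                "pct_below_100", "size_lod_nm",
                "number_concentration_per_mL", "particles_per_g")])
}

#' Tidy precision estimates
#'
#' @param x A `precision_estimates`.
#' @param ... Unused.
#' @return `tidy()`: one row per statistic; `glance()`: one wide row
#'   matching the layout of a collaborative-trial results table.
#' @export
tidy.precision_estimates <- function(x, ...) {
  tibble(
    statistic = c("x_pt", "u_xpt", "s_R", "s_r", "rsd_R_pct", "rsd_r_pct"),
    value = c(x$x_pt, x$u_xpt, x$s_R, x$s_r, x$rsd_R_pct, x$rsd_r_pct)
  )
}

#' @rdname tidy.precision_estimates
#' @export
glance.precision_estimates <- function(x, ...) {
  tibble(
    method = x$method, x_pt = x$x_pt, u_xpt = x$u_xpt,
    s_R = x$s_R, s_r = x$s_r,
    rsd_R_pct = x$rsd_R_pct, rsd_r_pct = x$rsd_r_pct,
    n_labs = x$n_labs, mean_replicates = x$mean_replicates,
    n_outliers = sum(x$flags$level == "outlier"),
    n_stragglers = sum(x$flags$level == "straggler")
  )
}

#' Tidy a TEM summary
#'
#' @param x A `tem_summary`.
#' @param ... Unused.
#' @return The per-measurand statistics tibble.
#' @export
tidy.tem_summary <- function(x, ...) x$stats

#' @rdname tidy.tem_summary
#' @export
glance.tem_summary <- function(x, ...) {
  fmin <- dplyr::filter(x$stats, .data$measurand == "fmin_nm")
  tibble(n_input = x$n_input, n_analysed_fmin = fmin$n_analysed,
         median_fmin_nm = fmin$median, mean_fmin_nm = fmin$mean,
         mode_fmin_nm = fmin$mode, lloq_nm = x$lloq_nm,
         uloq_nm = x$uloq_nm)
}

#' Tidy a screening outcome
#'
#' @param x A `screening_outcome`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.screening_outcome <- function(x, ...) {
  tibble(technique = x$technique, decision = x$decision,
         median_nm = x$median_nm, threshold_nm = x$threshold_nm,
         notes = x$notes)
}
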