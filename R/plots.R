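#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time scan trace
#'
#' Counts per dwell against acquisition time. Long scans are thinned to
#' at most `max_points` dwells (keeping every local spike visible by
#' plotting the maximum of each thinning window).
#'
#' @param object A [time_scan()].
#' @param max_points Maximum number of points drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.time_scan <- function(object, max_points = 20000, ...) {
  counts <- object$counts
  n <- length(counts)
  if (n > max_points) {
    w <- ceiling(n / max_points)
    grp <- (seq_len(n) - 1L) %/% w
    counts <- tapply(counts, grp, max)
    t_s <- (as.numeric(names(counts)) * w + w / 2) * object$dwell_time_s
  } else {
    t_s <- (seq_len(n) - 0.5) * object$dwell_time_s
  }
  ggplot2::ggplot(tibble(time_s = t_s, counts = as.numeric(counts)),
                  ggplot2::aes(.data$time_s, .data$counts)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time [s]", y = "counts per dwell",
                  title = object$isotope_label) +
    ggplot2::theme_minimal()
}

#' Plot a number-based particle size distribution
#'
#' Normalised histogram with the bin-free kernel density estimate
#' overlaid; the KDE mode and, when given, the size detection limit are
#' marked.
#'
#' @param diameters Numeric vector of particle diameters (nm).
#' @param binwidth_nm Histogram bin width (display only; the KDE is
#'   bin-free).
#' @param size_lod_nm Optional size detection limit to mark.
#' @return A ggplot.
#' @export
plot_size_distribution <- function(diameters, binwidth_nm = 10,
                                   size_lod_nm = NULL) {
  df <- tibble(diameter_nm = diameters)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$diameter_nm)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = binwidth_nm, fill = "grey80",
                            colour = "grey40") +
    ggplot2::labs(x = "equivalent spherical diameter [nm]",
                  y = "number density") +
    ggplot2::theme_minimal()
  if (length(diameters) >= 10) {
    m <- kde_mode(diameters)
    p <- p +
      ggplot2::geom_density(bw = attr(m, "bandwidth_nm"), colour = "black") +
      ggplot2::geom_vline(xintercept = as.numeric(m), linetype = "dashed")
  }
  if (!is.null(size_lod_nm)) {
    p <- p + ggplot2::geom_vline(xintercept = size_lod_nm,
                                 colour = "red3", linetype = "dotted")
  }
  p
}

#' Plot laboratory values against the robust consensus
#'
#' Per-laboratory replicate values and cell means for one measurand, with
#' the consensus value and its `+/- 2 s_R` band.
#'
#' @param data Long data frame with `lab`, `value` columns.
#' @param estimates Optional `precision_estimates` (computed with
#'   [robust_precision()] when absent).
#' @param value,lab Column names.
#' @return A ggplot.
#' @export
plot_lab_values <- function(data, estimates = NULL, value = "value",
                            lab = "lab") {
  if (is.null(estimates)) estimates <- robust_precision(data, value, lab)
  df <- tibble(lab = factor(data[[lab]]), value = data[[value]])
  ggplot2::ggplot(df, ggplot2::aes(.data$lab, .data$value)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = estimates$x_pt - 2 * estimates$s_R,
                      ymax = estimates$x_pt + 2 * estimates$s_R,
                      alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = estimates$x_pt, colour = "steelblue4") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 3,
                          colour = "red3") +
    ggplot2::labs(x = "laboratory", y = "value",
                  subtitle = sprintf("X_pt = %.4g, R = %.3g, r = %.3g",
                                     estimates$x_pt, estimates$s_R,
                                     estimates$s_r)) +
    ggplot2::theme_minimal()
}
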