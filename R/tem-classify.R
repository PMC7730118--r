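#' Summarise a TEM per-particle table
#'
#' Median, mean and KDE mode of the minimum Feret diameter, the (maximum)
#' Feret diameter and the aspect ratio of the measured constituent
#' particles, after applying the quantification limits of the imaging
#' protocol: for each diameter measurand, particles outside
#' `[lloq_nm, uloq_nm]` are excluded from that measurand's statistics
#' (the aspect ratio uses rows where both diameters are quantifiable,
#' since its limits are in nm). A warning is issued when fewer than
#' `min_n` particles remain, the conventional floor for a robust
#' number-based distribution.
#'
#' @param table A [tem_particle_table()].
#' @param lloq_nm,uloq_nm Lower/upper limit of quantification in nm
#'   (defaults 11.5 and 478).
#' @param min_n Minimum recommended particle count (default 500).
#' @return A `tem_summary` with a per-measurand statistics tibble.
#' @export
summarize_tem <- function(table, lloq_nm = 11.5, uloq_nm = 478,
                          min_n = 500) {
  stopifnot(inherits(table, "tem_particle_table"))
  if (nrow(table) == 0) abort("empty TEM table")
  in_range <- function(x) x >= lloq_nm & x <= uloq_nm
  sel <- list(
    fmin_nm = in_range(table$fmin_nm),
    fmax_nm = in_range(table$fmax_nm),
    aspect_ratio = in_range(table$fmin_nm) & in_range(table$fmax_nm)
  )
  stats <- purrr::imap(sel, function(keep, col) {
    x <- table[[col]][keep]
    if (length(x) == 0) {
      abort(sprintf("all particles filtered out for %s", col))
    }
    tibble(
      measurand = col,
      n_analysed = length(x),
      n_filtered_out = nrow(table) - length(x),
      median = median(x),
      mean = mean(x),
      mode = if (length(x) >= 10) as.numeric(kde_mode(x)) else NA_real_
    )
  }) |> dplyr::bind_rows()
  if (any(stats$n_analysed < min_n)) {
    warn(sprintf(
      "fewer than %d particles analysed (minimum n = %d); distribution statistics may not be robust",
      min_n, min(stats$n_analysed)))
  }
  structure(
    list(
      stats = stats,
      n_input = nrow(table),
      lloq_nm = lloq_nm, uloq_nm = uloq_nm, min_n = min_n,
      source_label = attr(table, "source_label") %||% "tem"
    ),
    class = "tem_summary"
  )
}

#' @export
print.tem_summary <- function(x, ...) {
  cat(sprintf("<tem_summary> %s: %d particles, LOQ [%.3g, %.3g] nm\n",
              x$source_label, x$n_input, x$lloq_nm, x$uloq_nm))
  print(x$stats)
  invisible(x)
}

#' Classify a material under the 100 nm median criterion
#'
#' A material is a nanomaterial when at least half of its constituent
#' particles (by number) have a minimum external dimension below 100 nm,
#' i.e. when the median minimum Feret diameter is below 100 nm. TEM
#' measures constituent particles directly, so its decision is final
#' either way. spICP-MS cannot resolve agglomerates into constituents and
#' systematically overestimates sizes near its detection limit, so a
#' median below 100 nm is a positive screening result while a median at
#' or above 100 nm is inconclusive and requires electron microscopy as a
#' confirmatory technique. A median of exactly 100 nm is not below the
#' threshold (strict `<`).
#'
#' @param median_nm Median minimum external dimension in nm (minimum
#'   Feret diameter for TEM, equivalent spherical diameter for spICP-MS).
#' @param technique `"tem"` or `"spicpms"`.
#' @return A `screening_outcome` with fields `technique`, `decision`
#'   (`"nanomaterial"`, `"not_nanomaterial"` or
#'   `"inconclusive_requires_tem"`), `median_nm`, `threshold_nm`, `notes`.
#' @export
classify_nano <- function(median_nm, technique = c("tem", "spicpms")) {
  technique <- match.arg(technique)
  if (!is.finite(median_nm) || median_nm <= 0) {
    abort("median_nm must be a positive number")
  }
  is_nano <- median_nm < 100
  decision <- if (technique == "tem") {
    if (is_nano) "nanomaterial" else "not_nanomaterial"
  } else {
    if (is_nano) "nanomaterial" else "inconclusive_requires_tem"
  }
  notes <- if (decision == "inconclusive_requires_tem") {
    paste("spICP-MS median >= 100 nm does not rule out a nanomaterial:",
          "agglomeration and the size detection limit bias the median",
          "upward; confirm with electron microscopy")
  } else ""
  structure(
    list(technique = technique, decision = decision,
         median_nm = median_nm, threshold_nm = 100, notes = notes),
    class = "screening_outcome"
  )
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat(sprintf("<screening_outcome> %s: median %.4g nm -> %s\n",
              x$technique, x$median_nm, x$decision))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Compare spICP-MS and TEM size summaries
#'
#' Side-by-side mean, median and mode from the spICP-MS measurand report
#' (equivalent spherical diameter) and the TEM minimum Feret diameter
#' summary, with their differences. spICP-MS values are expected to be
#' higher (detection-limit truncation plus unresolved agglomerates); rows
#' where spICP-MS is lower are flagged as an unexpected direction.
#'
#' @param sp A `measurand_report` from [distribution_report()].
#' @param tem A `tem_summary` from [summarize_tem()].
#' @return A tibble with columns `measurand`, `spicpms_nm`, `tem_fmin_nm`,
#'   `difference_nm`, `unexpected_direction`.
#' @export
compare_reports <- function(sp, tem) {
  stopifnot(inherits(sp, "measurand_report"), inherits(tem, "tem_summary"))
  fmin <- dplyr::filter(tem$stats, .data$measurand == "fmin_nm")
  out <- tibble(
    measurand = c("mean", "median", "mode"),
    spicpms_nm = c(sp$mean_nm, sp$d50_nm, sp$mode_nm),
    tem_fmin_nm = c(fmin$mean, fmin$median, fmin$mode)
  )
  dplyr::mutate(
    out,
    difference_nm = .data$spicpms_nm - .data$tem_fmin_nm,
    unexpected_direction = .data$difference_nm < 0
  )
}
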