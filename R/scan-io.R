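#' Construct a time-resolved spICP-MS scan
#'
#' A `time_scan` holds the ordered per-dwell detector counts of one
#' single-particle ICP-MS acquisition. Time is always reconstructed as
#' `dwell index x dwell time`; scan files carry no time column because
#' vendor exports disagree on it.
#'
#' @param counts Integer vector of detector counts, one per dwell, in
#'   acquisition order. Must be non-negative whole numbers.
#' @param dwell_time_s Dwell (integration window) time in seconds, e.g.
#'   `1e-4` (100 us) or `3e-3` (3000 us).
#' @param isotope_label Monitored isotope, e.g. `"Ti-48"`.
#' @param metadata Named list of free-form metadata (instrument, date,
#'   dilution factor, ...).
#' @return An object of class `time_scan`.
#' @export
time_scan <- function(counts, dwell_time_s, isotope_label = "Ti-48",
                      metadata = list()) {
  if (length(counts) < 1) abort("counts must contain at least one dwell")
  if (anyNA(counts)) abort("counts must not contain NA")
  if (any(counts < 0)) abort("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort("counts must be whole numbers (detector counts)")
  }
  if (!is.numeric(dwell_time_s) || length(dwell_time_s) != 1 ||
      dwell_time_s <= 0) {
    abort("dwell_time_s must be a single positive number")
  }
  structure(
    list(
      counts = as.integer(round(counts)),
      dwell_time_s = dwell_time_s,
      scan_time_s = length(counts) * dwell_time_s,
      isotope_label = isotope_label,
      metadata = metadata
    ),
    class = "time_scan"
  )
}

#' @export
print.time_scan <- function(x, ...) {
  cat(sprintf(
    "<time_scan> %s: %d dwells x %.6g s = %.4g s; counts mean %.3g, max %d\n",
    x$isotope_label, length(x$counts), x$dwell_time_s, x$scan_time_s,
    mean(x$counts), max(x$counts)
  ))
  invisible(x)
}

#' @export
length.time_scan <- function(x) length(x$counts)

#' Read a time scan from a single-column counts CSV
#'
#' The file holds one numeric counts column (no header needed); an optional
#' leading time column is ignored for computation. The dwell time is always
#' taken from the argument, never from the file.
#'
#' @param path Path to the scan CSV.
#' @param dwell_time_s Dwell time in seconds (overrides anything in the file).
#' @param isotope_label,metadata Passed to [time_scan()].
#' @return A `time_scan`.
#' @export
read_time_scan <- function(path, dwell_time_s, isotope_label = "Ti-48",
                           metadata = list()) {
  if (!file.exists(path)) abort(paste0("scan file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("scan file is empty: ", path))
  first_fields <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first_fields)))
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  fields <- strsplit(body, ",", fixed = TRUE)
  counts <- vapply(seq_along(fields), function(i) {
    f <- trimws(fields[[i]])
    v <- suppressWarnings(as.numeric(f[length(f)])) # last column = counts
    if (is.na(v)) {
      abort(sprintf("non-numeric counts value on line %d of %s",
                    i + offset, path))
    }
    v
  }, numeric(1))
  if (any(counts < 0)) {
    abort(sprintf("negative counts on line(s) %s of %s",
                  paste(which(counts < 0) + offset, collapse = ", "), path))
  }
  time_scan(counts, dwell_time_s, isotope_label, metadata)
}

#' Write a time scan to a single-column counts CSV
#'
#' @param scan A `time_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_time_scan <- function(scan, path) {
  stopifnot(inherits(scan, "time_scan"))
  readr::write_csv(tibble(counts = scan$counts), path)
  invisible(path)
}

#' Read a per-particle TEM measurement table
#'
#' Expects a CSV with a header naming minimum and maximum Feret diameter
#' columns in nm (matched case-insensitively against `fmin`/`fmax`). The
#' aspect ratio `fmax/fmin` is computed when absent.
#'
#' @param path Path to the CSV.
#' @param source_label Label recorded with the table (defaults to the
#'   file name).
#' @return A tibble of class `tem_particle_table` with columns `fmin_nm`,
#'   `fmax_nm`, `aspect_ratio`.
#' @export
read_tem_table <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) abort(paste0("TEM table not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  i_min <- which(grepl("fmin", nm))[1]
  i_max <- which(grepl("fmax", nm))[1]
  if (is.na(i_min) || is.na(i_max)) {
    abort("TEM table must name fmin and fmax columns (nm) in its header")
  }
  tbl <- tibble(
    fmin_nm = as.numeric(raw[[i_min]]),
    fmax_nm = as.numeric(raw[[i_max]])
  )
  tem_particle_table(tbl, source_label = source_label)
}

#' Validate and complete a TEM per-particle table
#'
#' @param data Data frame with columns `fmin_nm` and `fmax_nm` (nm), and
#'   optionally `aspect_ratio`.
#' @param source_label Provenance label stored as an attribute.
#' @return A tibble of class `tem_particle_table`.
#' @export
tem_particle_table <- function(data, source_label = "tem") {
  data <- as_tibble(data)
  if (!all(c("fmin_nm", "fmax_nm") %in% names(data))) {
    abort("data must have fmin_nm and fmax_nm columns")
  }
  if (any(data$fmin_nm <= 0)) {
    abort(sprintf("fmin_nm must be > 0 (rows %s)",
                  paste(which(data$fmin_nm <= 0), collapse = ", ")))
  }
  bad <- which(data$fmax_nm < data$fmin_nm)
  if (length(bad)) {
    abort(sprintf("fmax_nm < fmin_nm on rows %s",
                  paste(bad, collapse = ", ")))
  }
  if (!"aspect_ratio" %in% names(data)) {
    data$aspect_ratio <- data$fmax_nm / data$fmin_nm
  }
  attr(data, "source_label") <- source_label
  class(data) <- c("tem_particle_table", class(data))
  data
}

#' Read an ionic calibration point table
#'
#' CSV with header columns `conc_ug_per_L` and `mean_counts` (mean counts
#' per dwell at each dissolved-standard concentration).
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `conc_ug_per_L`, `mean_counts`.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) abort(paste0("calibration table not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("conc_ug_per_L", "mean_counts")
  if (!all(need %in% names(raw))) {
    abort("calibration table must have columns conc_ug_per_L, mean_counts")
  }
  as_tibble(raw[need])
}

#' Write a report object to CSV or JSON
#'
#' Works for measurand reports, precision estimates and screening outcomes.
#' Field names embed their units (`..._nm`, `..._per_g`). The JSON form
#' round-trips through [read_report()].
#'
#' @param report A `measurand_report`, `precision_estimates` or
#'   `screening_outcome`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_fields(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null",
                         pretty = TRUE)
  } else {
    readr::write_csv(generics::tidy(report), path, na = "")
  }
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return A named list of report fields (class restored when recognised).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(cls)) class(x) <- cls
  x
}

report_fields <- function(report) {
  out <- unclass(report)
  out <- out[!vapply(out, is.function, logical(1))]
  # drop heavyweight embedded objects from the serialised form
  out$model <- NULL
  c(out, list(.class = class(report)[1]))
}
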