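#' Build a pipeline run configuration
#'
#' Collects every stage's parameters in one validated list. The defaults
#' reproduce the screening method's standard operating point: 0.17 mL/min
#' flow, 100 us dwell, 60 s scans, anatase TiO2 constants, 5-sigma spike
#' discrimination with a 3-sigma size-LOD definition.
#'
#' @param mode `"single"` (one simulated suspension measured end-to-end)
#'   or `"ilc"` (a simulated interlaboratory study).
#' @param seed Integer seed governing every random draw of the run.
#' @param material Named list overriding [scan_sim_config()] defaults for
#'   the material/suspension model.
#' @param instrument Named list: `flow_mL_min`, `dwell_time_s`,
#'   `scan_time_s`, `transport_efficiency`, `sensitivity_counts_per_fg`,
#'   `background_mean_counts`.
#' @param detection Named list: `k_sigma` (default 5), `gap` (default 0).
#' @param dilution Optional named list: `steps` (data frame with
#'   `aliquot_mL`, `final_mL`), `sample_mass_g`, `suspension_volume_mL`.
#' @param ilc Named list for ILC mode: `n_labs`, `replicates` and the
#'   per-lab parameter ranges of [ilc_sim_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("single", "ilc"), seed,
                       material = list(), instrument = list(),
                       detection = list(), dilution = NULL, ilc = list()) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("seed is mandatory")
  structure(
    list(mode = mode, seed = as.integer(seed), material = material,
         instrument = instrument, detection = detection,
         dilution = dilution, ilc = ilc),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys match the
#'   arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  x <- yaml::read_yaml(path)
  # YAML 1.1 only recognises exponents with an explicit sign; recover
  # numbers like "6.0e5" that arrive as strings
  x <- rapply(x, function(v) {
    if (is.character(v) && length(v) == 1 &&
        grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", v)) {
      as.numeric(v)
    } else v
  }, how = "replace")
  if (is.null(x$seed)) abort("config must set a seed")
  run_config(
    mode = x$mode %||% "single", seed = x$seed,
    material = x$material %||% list(),
    instrument = x$instrument %||% list(),
    detection = x$detection %||% list(),
    dilution = x$dilution, ilc = x$ilc %||% list()
  )
}

config_to_scan_sim <- function(config, seed_offset = 0L) {
  args <- c(config$material, config$instrument)
  args <- args[names(args) %in% names(formals(scan_sim_config))]
  args$seed <- config$seed + seed_offset
  do.call(scan_sim_config, args)
}

#' Run the screening pipeline end-to-end
#'
#' Executes simulate -> calibrate -> detect -> measure -> classify (or the
#' interlaboratory variant) from one configuration, writing every
#' intermediate artifact under `out_dir` and returning a manifest. Runs
#' are idempotent: the same configuration and seed produce byte-identical
#' outputs.
#'
#' In single mode the stages are: ionic calibration points and a 63 nm
#' reference scan are simulated under the configured instrument, giving
#' the calibration slope and the size-method transport efficiency; a
#' sample scan is simulated, its background estimated, events detected
#' and sized; the measurand report and the screening decision are
#' written. In ILC mode a multi-laboratory study is simulated, processed
#' per lab, and evaluated with the robust and classical interlaboratory
#' statistics.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return A tibble manifest (`stage`, `artifact`, `path`), invisibly
#'   carrying the in-memory results as attribute `results`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("nanoscreen-run-")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, artifact = artifact, path = path)
  }
  k_sigma <- config$detection$k_sigma %||% 5
  gap <- config$detection$gap %||% 0

  if (config$mode == "ilc") {
    base <- config_to_scan_sim(config)
    ilc_args <- config$ilc[names(config$ilc) %in%
                             names(formals(ilc_sim_config))]
    ilc_args$material <- base
    ilc_args$seed <- config$seed
    icfg <- do.call(ilc_sim_config, ilc_args)
    study <- simulate_ilc_study(icfg)
    chain <- build_chain(config$dilution)
    meas <- process_ilc_study(study, icfg, k_sigma_detect = k_sigma,
                              chain = chain)
    meas_path <- file.path(out_dir, "ilc_measurands.csv")
    readr::write_csv(meas, meas_path)
    add("ilc", "measurand table", meas_path)
    prec <- ilc_precision(meas)
    prec_path <- file.path(out_dir, "ilc_precision.csv")
    readr::write_csv(prec, prec_path)
    add("ilc", "precision table", prec_path)
    out <- dplyr::bind_rows(manifest)
    attr(out, "results") <- list(study = study, measurands = meas,
                                 precision = prec)
    return(invisible(out))
  }

  # -- single-suspension mode --
  cfg <- config_to_scan_sim(config)
  cal_pts <- simulate_ionic_calibration(config = cfg)
  cal_path <- file.path(out_dir, "ionic_calibration.csv")
  readr::write_csv(cal_pts, cal_path)
  add("calibrate", "ionic calibration points", cal_path)
  cal <- fit_ionic_calibration(cal_pts)

  ref_cfg <- config_to_scan_sim(config, seed_offset = 7L)
  ref_cfg$number_concentration_per_mL <- 1e5
  ref <- simulate_reference_scan(config = ref_cfg)
  ref_bg <- estimate_background(ref$scan)
  ref_ev <- detect_events(ref$scan, ref_bg, k_sigma = k_sigma, gap = gap)
  te <- estimate_te_size(mean(ref_ev$net_counts), 63, cal,
                         cfg$flow_mL_min, cfg$dwell_time_s)
  te_path <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(
    list(slope = cal$slope, intercept = cal$intercept,
         r_squared = cal$r_squared, eta = te$eta, te_method = te$method),
    te_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("calibrate", "calibration summary", te_path)

  sim <- simulate_scan(cfg)
  scan_path <- file.path(out_dir, "scan.csv")
  write_time_scan(sim$scan, scan_path)
  add("simulate", "sample scan", scan_path)

  bg <- estimate_background(sim$scan)
  ev <- detect_events(sim$scan, bg, k_sigma = k_sigma, gap = gap)
  ev <- event_to_masses(ev, cal, te, cfg$flow_mL_min, cfg$dwell_time_s,
                        cfg$compound)
  ev_path <- file.path(out_dir, "events.csv")
  readr::write_csv(ev, ev_path)
  add("detect", "events table", ev_path)

  lod <- size_detection_limit(bg, cal, te, cfg$flow_mL_min,
                              cfg$dwell_time_s, cfg$compound)
  chain <- build_chain(config$dilution)
  rpt <- distribution_report(ev$diameter_nm, te, cfg$flow_mL_min,
                             sim$scan$scan_time_s, size_lod_nm = lod,
                             chain = chain)
  rpt_path <- file.path(out_dir, "measurand_report.json")
  write_report(rpt, rpt_path, format = "json")
  add("measure", "measurand report", rpt_path)

  outcome <- classify_nano(rpt$d50_nm, technique = "spicpms")
  dec_path <- file.path(out_dir, "screening_outcome.json")
  write_report(outcome, dec_path, format = "json")
  add("classify", "screening decision", dec_path)

  out <- dplyr::bind_rows(manifest)
  attr(out, "results") <- list(
    calibration = cal, transport_efficiency = te, scan = sim$scan,
    truth = sim$truth, background = bg, events = ev, size_lod_nm = lod,
    report = rpt, outcome = outcome
  )
  invisible(out)
}

build_chain <- function(dilution) {
  if (is.null(dilution)) return(NULL)
  steps <- dilution$steps
  if (is.list(steps) && !is.data.frame(steps)) {
    steps <- dplyr::bind_rows(lapply(steps, as_tibble))
  }
  dilution_chain(steps, dilution$sample_mass_g,
                 dilution$suspension_volume_mL)
}
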