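#' Read and write filament traces in the trace CSV dialect
#'
#' One row per centerline point with columns `filament_id`, `strain`
#' (fraction; a `strain_pct` alias is accepted on read and written
#' alongside), `strain_rate_pct_per_s`, `kinesin_nM`, `point_index`, `x_um`,
#' `y_um`. Write-then-read round trips are loss-free to well below 1e-9 um.
#'
#' @param path CSV file path.
#' @return `read_traces()`: an [experiment_dataset()]. `write_traces()`:
#'   the path, invisibly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"strain" %in% names(df) && "strain_pct" %in% names(df)) {
    df$strain <- df$strain_pct / 100
  }
  need <- c("filament_id", "strain", "point_index", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trace file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"kinesin_nM" %in% names(df)) df$kinesin_nM <- NA_real_
  if (!"strain_rate_pct_per_s" %in% names(df)) {
    df$strain_rate_pct_per_s <- NA_real_
  }
  for (col in c("strain", "point_index", "x_um", "y_um")) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
  }
  key <- interaction(df$filament_id, df$strain, drop = TRUE)
  traces <- lapply(split(seq_len(nrow(df)), key), function(rows) {
    sub <- df[rows, ]
    if (any(diff(sub$point_index) <= 0)) {
      bad <- rows[which(diff(sub$point_index) <= 0)[1] + 1]
      stop(sprintf(
        "non-monotonic point_index at row %d (filament %s, strain %g)",
        bad, sub$filament_id[1], sub$strain[1]), call. = FALSE)
    }
    filament_trace(sub$x_um, sub$y_um, strain = sub$strain[1],
                   strain_rate = sub$strain_rate_pct_per_s[1],
                   kinesin_nM = sub$kinesin_nM[1],
                   filament_id = sub$filament_id[1])
  })
  names(traces) <- NULL
  experiment_dataset(traces)
}

#' @rdname read_traces
#' @param dataset An [experiment_dataset()], or a list of
#'   [filament_trace()] objects.
#' @export
write_traces <- function(dataset, path) {
  traces <- if (inherits(dataset, "experiment_dataset")) dataset$traces
            else dataset
  rows <- lapply(traces, function(tr) {
    n <- nrow(tr$points)
    data.frame(
      filament_id = tr$filament_id,
      strain = tr$strain,
      strain_pct = 100 * tr$strain,
      strain_rate_pct_per_s = tr$strain_rate,
      kinesin_nM = tr$kinesin_nM,
      point_index = seq_len(n),
      x_um = tr$points$x, y_um = tr$points$y
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write per-condition summaries, fit reports and simulation results
#'
#' `write_summaries()` writes a summary data frame (e.g. rows from
#' [aggregate_condition()]) as CSV. `write_fit_report()` serializes a fit
#' object (named list of parameters, diagnostics and data frames) as JSON.
#' `write_simulation()` writes a [simulate_ramp()] result as a JSON summary
#' plus, optionally, the relaxed shapes in the trace CSV dialect so that
#' simulator output feeds the trace-measurement pipeline directly.
#'
#' @param summaries A data frame.
#' @param fit A named list (e.g. from [fit_modified_model()]).
#' @param result A `simulation_result`.
#' @param path,json_path,traces_path Output file paths.
#' @return The written path(s), invisibly.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(fit, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
write_simulation <- function(result, json_path, traces_path = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  summary <- list(
    n_steps = length(result$strain_history),
    strain_history = result$strain_history,
    energy = result$energy,
    axial_force = result$axial_force,
    max_amplitude = result$max_amplitude,
    dominant_wavelength = result$dominant_wavelength,
    onset_strain = result$onset_strain,
    model = result$model[c("n_nodes", "node_spacing", "length", "EI",
                           "k_spring", "anchor_spacing", "axial_stiffness",
                           "boundary")]
  )
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(traces_path)) {
    traces <- mapply(function(shape, strain) {
      filament_trace(shape[, 1], shape[, 2], strain = strain,
                     filament_id = "sim")
    }, result$shapes, result$strain_history, SIMPLIFY = FALSE)
    write_traces(traces, traces_path)
  }
  invisible(c(json_path, traces_path))
}

#' Read and validate a run configuration
#'
#' YAML configuration with a `mechanics` section (Young's modulus or
#' softening-model parameters, second moment of area, substrate initial
#' length), optional `analysis`, `fitting` and `simulation` sections, and a
#' `seed`. Mechanical constants are required and must be positive; partial
#' mechanics sections are rejected rather than silently defaulted. A
#' resolved copy can be archived next to every output with
#' [write_run_config()] for provenance.
#'
#' @param path YAML file path.
#' @param config A run-config list.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  mech <- cfg$mechanics
  if (is.null(mech)) stop("config missing `mechanics` section",
                          call. = FALSE)
  for (field in c("youngs_modulus_MPa", "second_moment_m4")) {
    if (is.null(mech[[field]])) {
      stop("config mechanics missing `", field, "`", call. = FALSE)
    }
    check_positive(mech[[field]], field)
  }
  if (is.null(mech$substrate_initial_length_mm)) {
    stop("config mechanics missing `substrate_initial_length_mm`",
         call. = FALSE)
  }
  check_positive(mech$substrate_initial_length_mm,
                 "substrate_initial_length_mm")
  defaults <- list(
    analysis = list(noise_sigma_um = 0.05, window_um = 1,
                    amplitude_floor_um = 0.15, prominence_factor = 3,
                    orientation_tol_deg = 15,
                    wavelength_selection = "critical"),
    fitting = list(softening_family = "hill", shape_exponent = 2,
                   fc_constant = 2),
    seed = 1L
  )
  for (sec in c("analysis", "fitting")) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]],
                                    if (is.null(cfg[[sec]])) list()
                                    else cfg[[sec]])
  }
  if (is.null(cfg$seed)) cfg$seed <- defaults$seed
  if (!cfg$analysis$wavelength_selection %in% c("critical", "transitional")) {
    stop("wavelength_selection must be 'critical' or 'transitional'",
         call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
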