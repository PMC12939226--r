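# CSV/JSON/YAML interfaces: drying curves, quality tables, configuration
# files and simulation exports. All CSV is comma-separated UTF-8 with a
# mandatory header row and '.' decimals.

#' Read drying curves from CSV
#'
#' Expects columns \code{time_h} (or \code{time_min}, converted with a
#' message), \code{moisture_db}, and optionally \code{temp_C}, \code{method}
#' and \code{temperature}. Multiple curves may share one file, distinguished
#' by the \code{method} and \code{temperature} columns.
#'
#' @param path CSV file path.
#' @return a list of \code{\link{drying_curve}} objects.
#' @export
read_drying_curves <- function(path) {
  if (!file.exists(path)) stop_zb("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("time_min" %in% names(df) && !("time_h" %in% names(df))) {
    message("time_min column detected: converting to hours")
    df$time_h <- df$time_min / 60
  }
  if (!all(c("time_h", "moisture_db") %in% names(df)))
    stop_zb("CSV must contain columns time_h (or time_min) and moisture_db")
  if (!("method" %in% names(df))) df$method <- NA_character_
  if (!("temperature" %in% names(df))) df$temperature <- NA_real_
  keys <- unique(df[, c("method", "temperature")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[(df$method %in% keys$method[i]) &
                (df$temperature %in% keys$temperature[i]), ]
    sub <- sub[order(sub$time_h), ]
    drying_curve(sub$time_h, sub$moisture_db,
                 surface_temperature = if ("temp_C" %in% names(sub)) sub$temp_C,
                 method = keys$method[i], temperature = keys$temperature[i])
  })
}

#' Write drying curves to CSV
#'
#' @param curves a \code{\link{drying_curve}} or list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_drying_curves <- function(curves, path) {
  if (inherits(curves, "drying_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cv) {
    out <- data.frame(method = attr(cv, "method"),
                      temperature = attr(cv, "temperature"),
                      time_h = cv$time_h, moisture_db = cv$moisture_db)
    if ("temp_C" %in% names(cv)) out$temp_C <- cv$temp_C
    out
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a quality table from CSV
#'
#' Expects columns \code{method}, \code{temperature} and the four indicator
#' columns (\code{delta_e}, \code{dehiscence_rate}, \code{volatile_oil},
#' \code{amide}); SD columns (suffix \code{_sd}) are carried through when
#' present.
#'
#' @param path CSV file path.
#' @return a \code{\link{quality_table}}.
#' @export
read_quality_table <- function(path) {
  if (!file.exists(path)) stop_zb("file not found: ", path)
  quality_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Load a configuration file
#'
#' Reads a YAML configuration with optional top-level sections
#' \code{properties}, \code{schedule} and \code{simulation}, whose keys are
#' the arguments of \code{\link{material_properties}},
#' \code{\link{pulsation_schedule}} and \code{\link{simulation_config}}. Keys
#' that are omitted fall back to the package defaults (the bundled default
#' configuration reproduces the reference operating-parameter set verbatim).
#'
#' @param path YAML file path; defaults to the bundled configuration.
#' @return list with elements \code{props}, \code{schedule}, \code{config}.
#' @export
zb_load_config <- function(path = zb_default_config()) {
  if (!file.exists(path)) stop_zb("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("properties", "schedule", "simulation"))
  if (length(bad))
    stop_zb("unknown config section(s): ", paste(bad, collapse = ", "))
  props <- do.call(material_properties, raw$properties %||% list())
  schedule <- do.call(pulsation_schedule, raw$schedule %||% list())
  sim_args <- raw$simulation %||% list()
  sim_args$schedule <- schedule
  config <- do.call(simulation_config, sim_args)
  list(props = props, schedule = schedule, config = config)
}

#' Path of the bundled default configuration
#'
#' @return file path of the default YAML configuration shipped with the
#'   package.
#' @export
zb_default_config <- function() {
  system.file("extdata", "default_config.yaml", package = "zbdry",
              mustWork = TRUE)
}

#' Export a simulation result to files
#'
#' Writes the tidy nodal field history
#' (\code{<prefix>_fields.csv}: time_s, node, position_m, temperature_C,
#' moisture_db, MR), the summary series (\code{<prefix>_summary.csv}: time_s,
#' MR_mean, T_surface, T_core, delta_MR, chamber_pressure_kPa) and the run
#' metadata with the energy/mass ledgers (\code{<prefix>_ledger.json}).
#'
#' @param result a \code{\link{simulate_drying}} result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of the three paths written, invisibly.
#' @export
export_simulation <- function(result, dir = ".", prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(result$times)
  N <- ncol(result$temperature)
  fields <- data.frame(
    time_s = rep(result$times, each = N),
    node = rep(seq_len(N), times = n),
    position_m = rep(result$x, times = n),
    temperature_C = as.vector(t(result$temperature)),
    moisture_db = as.vector(t(result$moisture)),
    MR = as.vector(t(result$moisture)) / result$config$initial_moisture)
  f1 <- file.path(dir, paste0(prefix, "_fields.csv"))
  utils::write.csv(fields, f1, row.names = FALSE)
  summary <- data.frame(
    time_s = result$times, MR_mean = result$MR_mean,
    T_surface = result$T_surface, T_core = result$T_core,
    delta_MR = result$delta_MR,
    chamber_pressure_kPa = result$chamber_pressure)
  f2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(summary, f2, row.names = FALSE)
  meta <- list(
    mode = result$config$mode, geometry = result$geometry,
    n_nodes = result$config$n_nodes,
    drying_time_to_target_s = result$drying_time_to_target,
    energy_ledger = result$energy_ledger, mass_ledger = result$mass_ledger)
  f3 <- file.path(dir, paste0(prefix, "_ledger.json"))
  jsonlite::write_json(meta, f3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f1, f2, f3))
}
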