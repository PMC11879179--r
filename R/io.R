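#' Read a survey station table
#'
#' Reads a station CSV and maps its columns, case-insensitively and
#' through common synonyms, onto the canonical layout used throughout the
#' package: `id`, `year`, `lon`, `lat`, `temperature_c`, `nauplii_m3`,
#' `cladocera_m3`, `copepods_m3`, `bluefin_m3`. `id` and a temperature
#' column are mandatory; missing prey columns are reported with a warning
#' and treated as absent, and negative density cells produce a warning
#' naming the offending row and column.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data.frame of stations (possibly zero rows, with a warning).
#' @examples
#' f <- system.file("extdata", "stations_synthetic_example.csv",
#'                  package = "bftforage")
#' read_station_csv(f)
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path)) {
    stop("read_station_csv: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  synonyms <- list(
    id = c("id", "station", "station_id", "st"),
    year = c("year"),
    lon = c("lon", "longitude", "long"),
    lat = c("lat", "latitude"),
    temperature_c = c("temperature_c", "temperature", "temp", "temp_c",
                      "mixed_layer_temperature", "ml_temp", "sst"),
    nauplii_m3 = c("nauplii_m3", "nauplii", "nauplius"),
    cladocera_m3 = c("cladocera_m3", "cladocera", "cladocerans", "cladoceran"),
    copepods_m3 = c("copepods_m3", "copepods", "copepod"),
    bluefin_m3 = c("bluefin_m3", "bluefin", "bluefin_larvae", "tuna_larvae")
  )
  lower <- tolower(trimws(names(raw)))
  out <- list()
  for (canon in names(synonyms)) {
    hit <- which(lower %in% synonyms[[canon]])
    if (length(hit)) out[[canon]] <- raw[[hit[1]]]
  }
  missing_mand <- setdiff(c("id", "temperature_c"), names(out))
  if (length(missing_mand)) {
    stop("read_station_csv: mandatory column(s) missing: ",
         paste(missing_mand, collapse = ", "),
         " (accepted names include e.g. 'station', 'temperature')",
         call. = FALSE)
  }
  dens_cols <- c("nauplii_m3", "cladocera_m3", "copepods_m3")
  absent <- setdiff(dens_cols, names(out))
  if (length(absent)) {
    warning("read_station_csv: prey column(s) missing, treated as absent: ",
            paste(absent, collapse = ", "), call. = FALSE)
    for (cl in absent) out[[cl]] <- rep(NA_real_, nrow(raw))
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("read_station_csv: no data rows in ", path, call. = FALSE)
    return(df)
  }
  for (cl in intersect(c(dens_cols, "bluefin_m3"), names(df))) {
    df[[cl]] <- as.numeric(df[[cl]])
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    for (r in bad) {
      warning("read_station_csv: negative density in row ", r,
              ", column `", cl, "` (station `", df$id[r], "`)", call. = FALSE)
    }
  }
  df$temperature_c <- as.numeric(df$temperature_c)
  df
}

#' Write a station table
#'
#' Writes the canonical station layout as CSV at full double precision.
#'
#' @param stations Data.frame of stations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(stations, path) {
  utils::write.csv(format_full_precision(stations), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Render numeric columns with all 17 significant digits so CSVs round-trip.
format_full_precision <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  df
}

#' Default run configuration
#'
#' The complete, human-readable configuration of a model run: every
#' physiological/optical constant, the stage lengths, the prey traits, the
#' calibration anchor, the diet scenarios, and run metadata (seed,
#' verbosity). Serialise with [write_config()] and load with
#' [read_config()]; the round trip is lossless.
#'
#' @return A named list of class `bft_config`.
#' @export
default_config <- function() {
  p <- model_params()
  cfg <- list(
    params = unclass(p),
    stages = list(F0 = 4.8, F1 = 5.8, F2 = 6.7, F3 = 7.5),
    prey = lapply(default_prey(), unclass),
    sensitivity_nauplius = FALSE,
    anchor = list(stage = "F0", prey = "nauplius", temp = 22,
                  target_density = 4000, target = "max_growth"),
    scenarios = c("nauplii_only", "cladocera_only", "copepods_only", "combined"),
    temps = c(22, 25, 28),
    seed = 1L,
    verbosity = 1L
  )
  class(cfg) <- "bft_config"
  cfg
}

#' Write a run configuration to YAML
#' @param config A `bft_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys (top level, `params`, or prey fields) are rejected with a
#' message naming them, so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file written by [write_config()] (or edited
#'   by hand).
#' @return A `bft_config` list merged over the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("read_config: file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown)) {
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$params)) {
    bad <- setdiff(names(raw$params), names(unclass(model_params())))
    if (length(bad)) {
      stop("read_config: unknown params key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- utils::modifyList(unclass(def), raw)
  class(cfg) <- "bft_config"
  cfg
}

#' Materialise model objects from a configuration
#'
#' @param config A `bft_config` list.
#' @return List with `params` (a `bft_params`), `stages`, `prey`, `anchor`.
#' @export
config_objects <- function(config) {
  pl <- config$params
  pl$resp_conversions <- as.numeric(pl$resp_conversions)
  params <- do.call(model_params, pl[setdiff(names(pl), character())])
  stages <- lapply(names(config$stages), function(code) {
    larval_stage(code, config$stages[[code]], params)
  })
  names(stages) <- names(config$stages)
  prey <- lapply(config$prey, function(p) {
    prey_type(p$name, p$length, p$dry_weight, p$capture_mode)
  })
  if (isTRUE(config$sensitivity_nauplius)) {
    prey$nauplius <- default_prey(sensitivity_nauplius = TRUE)$nauplius
  }
  list(params = params, stages = stages, prey = prey, anchor = config$anchor)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: subcommand, arguments,
#' seed, the calibrated detection constant, the MD5 of the configuration
#' file, package version and timestamp.
#'
#' @param path Output path (plain-text YAML).
#' @param subcommand Name of the operation performed.
#' @param args Named list of effective arguments.
#' @param params The `bft_params` used.
#' @param config_path Optional path of the config file (hashed if given).
#' @param outputs Character vector of files written.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, args, params,
                           config_path = NULL, outputs = character()) {
  man <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("bftforage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    args = args,
    seed = args$seed,
    detection_calib_c = params$detection_calib_c,
    config_md5 = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else NA_character_,
    outputs = outputs
  )
  yaml::write_yaml(man, path, precision = 17)
  invisible(path)
}
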