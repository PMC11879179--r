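#' Critical prey density
#'
#' The single-prey concentration at which a larva exactly meets a growth
#' target: `"maintenance"` (assimilated intake balances metabolism, zero
#' growth) or `"max_growth"` (daily growth reaches the ad-libitum ceiling).
#' Because ingestion is linear in density the threshold has the closed form
#' `N* = i_req / (P * beta * W_prey)`.
#'
#' @param stage A [larval_stage()].
#' @param prey A [prey_type()].
#' @param temp Water temperature in degC.
#' @param target `"max_growth"` or `"maintenance"`.
#' @param params A calibrated [model_params()] object.
#' @return Critical density in m^-3. If the capture probability is zero the
#'   target is unreachable at any density and `Inf` is returned.
#' @examples
#' params <- calibrate_detection()
#' st <- default_stages(params); pr <- default_prey()
#' critical_density(st$F0, pr$nauplius, 22, "max_growth", params) # 4000 (anchor)
#' critical_density(st$F0, pr$cladoceran, 22, "max_growth", params) # ~5
#' @export
critical_density <- function(stage, prey, temp,
                             target = c("max_growth", "maintenance"),
                             params = model_params()) {
  target <- match.arg(target)
  require_calibrated(params)
  i_req <- required_ingestion(stage, temp, target, params)
  det <- detection_distance(prey, stage, light = "day", params = params)
  beta <- search_rate(det, stage, params)
  p_cap <- capture_probability(prey, stage, params)
  if (p_cap <= 0) return(Inf)
  i_req / (p_cap * beta * prey$dry_weight)
}

#' Critical-density table over stages, prey, temperatures and targets
#'
#' Evaluates [critical_density()] on the cartesian grid of the supplied
#' stages, prey types, temperatures and targets.
#'
#' @param stages List of [larval_stage()] objects (default F0-F3).
#' @param prey List of [prey_type()] objects (default nauplius, cladoceran,
#'   copepod).
#' @param temps Numeric vector of temperatures (degC).
#' @param targets Character vector among `"maintenance"`, `"max_growth"`.
#' @param params A calibrated [model_params()] object.
#' @return A long data.frame with columns `stage`, `standard_length_mm`,
#'   `prey`, `temperature_c`, `target`, `critical_density_m3`.
#' @export
critical_density_table <- function(stages = default_stages(params),
                                   prey = default_prey(),
                                   temps = c(22, 25, 28),
                                   targets = c("maintenance", "max_growth"),
                                   params = model_params()) {
  require_calibrated(params)
  grid <- expand.grid(
    stage = seq_along(stages), prey = seq_along(prey),
    temperature_c = temps, target = targets,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    st <- stages[[grid$stage[i]]]
    pr <- prey[[grid$prey[i]]]
    data.frame(
      stage = st$code,
      standard_length_mm = st$standard_length,
      prey = pr$name,
      temperature_c = grid$temperature_c[i],
      target = grid$target[i],
      critical_density_m3 = critical_density(st, pr, grid$temperature_c[i],
                                             grid$target[i], params),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Growth response surface over prey density
#'
#' Realized daily specific growth rate of one stage feeding on one prey
#' type, over a density grid and one or more temperatures: the curves that
#' rise linearly with food, cross zero at the maintenance density and
#' saturate at the temperature's ad-libitum rate.
#'
#' @param stage A [larval_stage()].
#' @param prey A [prey_type()].
#' @param temps Numeric vector of temperatures (degC).
#' @param densities Numeric vector of prey densities (m^-3, >= 0).
#' @param params A calibrated [model_params()] object.
#' @return A data.frame with columns `stage`, `prey`, `temperature_c`,
#'   `density_m3`, `sgr_daily`, `sgr_daily_uncapped`, `sgr_ad_libitum`,
#'   `capped`, `fli`.
#' @export
response_surface <- function(stage, prey, temps, densities,
                             params = model_params()) {
  if (any(densities < 0)) {
    stop("response_surface: densities must be >= 0", call. = FALSE)
  }
  grid <- expand.grid(temperature_c = temps, density_m3 = densities,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    b <- growth_budget(stage, list(prey), grid$density_m3[i],
                       grid$temperature_c[i], params)
    data.frame(
      stage = stage$code, prey = prey$name,
      temperature_c = grid$temperature_c[i],
      density_m3 = grid$density_m3[i],
      sgr_daily = b$sgr_daily,
      sgr_daily_uncapped = b$sgr_daily_uncapped,
      sgr_ad_libitum = b$sgr_ad_libitum,
      capped = b$capped, fli = b$fli,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature_c, out$density_m3), , drop = FALSE]
}

#' Station-level food-limitation assessment
#'
#' Evaluates each survey station under four diet scenarios -- feeding only
#' on nauplii, only on cladocerans, only on copepods, or on the combination
#' of all three -- for each larval stage, using the station's mixed-layer
#' temperature and observed prey concentrations. A stage/scenario is flagged
#' food-limited where the realized daily growth falls short of the
#' ad-libitum rate (FLI < 1).
#'
#' @param stations A data.frame of stations as returned by
#'   [read_station_csv()] or [generate_stations()] (columns `id`,
#'   `temperature_c`, `nauplii_m3`, `cladocera_m3`, `copepods_m3`).
#' @param stages List of [larval_stage()] objects.
#' @param params A calibrated [model_params()] object.
#' @param prey Named list of prey types with elements `nauplius`,
#'   `cladoceran`, `copepod`.
#' @param default_temp Fallback mixed-layer temperature (degC) for stations
#'   with a missing temperature (used with a warning).
#' @return A long data.frame, one row per station x stage x scenario, with
#'   columns `id`, `temperature_c`, `stage`, `scenario`, `sgr_daily`,
#'   `fli`, `limited`, `maintenance_failed` (realized growth negative).
#'   Malformed rows are skipped with a per-row warning.
#' @export
assess_stations <- function(stations, stages = default_stages(params),
                            params = model_params(), prey = default_prey(),
                            default_temp = 24.5) {
  require_calibrated(params)
  need <- c("nauplii_m3", "cladocera_m3", "copepods_m3")
  for (col in need) {
    if (is.null(stations[[col]])) {
      warning("assess_stations: column `", col,
              "` missing; treating that prey as absent", call. = FALSE)
      stations[[col]] <- 0
    }
  }
  scenarios <- list(
    nauplii_only = c("nauplius"),
    cladocera_only = c("cladoceran"),
    copepods_only = c("copepod"),
    combined = c("nauplius", "cladoceran", "copepod")
  )
  dens_col <- c(nauplius = "nauplii_m3", cladoceran = "cladocera_m3",
                copepod = "copepods_m3")

  rows <- list()
  for (i in seq_len(nrow(stations))) {
    st_row <- stations[i, ]
    temp <- st_row$temperature_c
    if (is.null(temp) || is.na(temp)) {
      warning("assess_stations: station `", st_row$id,
              "` has no temperature; using default ", default_temp, " degC",
              call. = FALSE)
      temp <- default_temp
    }
    dens <- vapply(dens_col, function(cl) {
      v <- st_row[[cl]]
      if (is.null(v) || is.na(v)) 0 else v
    }, numeric(1))
    if (any(dens < 0)) {
      warning("assess_stations: station `", st_row$id,
              "` has negative prey density (",
              paste(names(dens)[dens < 0], collapse = ", "),
              "); row skipped", call. = FALSE)
      next
    }
    for (stage in stages) {
      for (sc in names(scenarios)) {
        keep <- scenarios[[sc]]
        b <- growth_budget(stage, prey[keep], unname(dens[keep]), temp, params)
        rows[[length(rows) + 1L]] <- data.frame(
          id = st_row$id, temperature_c = temp,
          stage = stage$code, scenario = sc,
          sgr_daily = b$sgr_daily, fli = b$fli,
          limited = !b$capped,
          maintenance_failed = b$sgr_daily < 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
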