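#' Visual prey detection distance
#'
#' Distance at which a larva detects a prey item. Detection is visual:
#' it grows with prey size and with larval eye development (taken
#' proportional to body length), and is zero in darkness -- the larvae do
#' not feed at night. The single proportionality constant
#' `detection_calib_c` is set by [calibrate_detection()].
#'
#' @param prey A [prey_type()].
#' @param stage A [larval_stage()].
#' @param light `"day"` or `"night"`.
#' @param params A calibrated [model_params()] object.
#' @return Detection distance in m.
#' @export
detection_distance <- function(prey, stage, light = c("day", "night"),
                               params = model_params()) {
  light <- match.arg(light)
  if (light == "night") return(0)
  require_calibrated(params)
  # c [mm^-1] * prey length [mm] * larval length [mm] -> mm -> m
  params$detection_calib_c * prey$length * stage$standard_length / 1000
}

#' Volumetric search rate
#'
#' Volume of water scanned for a prey type per hour. The larva cruises at
#' `swim_bl_per_s` body lengths per second and scans half the visual field
#' (looking upward against the bright sea surface), so
#' `beta = 1/2 * pi * R^2 * V_L` with `R` the detection distance and `V_L`
#' the swimming speed.
#'
#' @param detection_r Detection distance in m (>= 0).
#' @param stage A [larval_stage()].
#' @param params A [model_params()] object (unused beyond validation; the
#'   swimming speed is carried by the stage).
#' @return Search rate in m^3 h^-1.
#' @export
search_rate <- function(detection_r, stage, params = model_params()) {
  if (any(detection_r < 0)) {
    stop("search_rate: `detection_r` must be >= 0", call. = FALSE)
  }
  v_m_h <- swim_speed_m_h(stage)
  0.5 * pi * detection_r^2 * v_m_h
}

swim_speed_m_h <- function(stage) {
  # body lengths s^-1 * SL mm -> mm s^-1 -> m h^-1
  stage$swim_bl_per_s * stage$standard_length / 1000 * 3600
}

#' Capture probability
#'
#' Probability that an encountered prey item is captured. Nauplii are
#' captured with probability 1 at all larval sizes; for the larger
#' cladocerans and copepods the probability increases linearly from 0 at
#' first feeding to 1 at post-flexion. Under the default
#' `capture_mode = "calibration"` every prey is captured with probability 1
#' (the published thresholds are consistent with this mode); the ramp is
#' applied under `capture_mode = "ontogenetic"`.
#'
#' @param prey A [prey_type()].
#' @param stage A [larval_stage()].
#' @param params A [model_params()] object.
#' @return Capture probability in \[0, 1\].
#' @export
capture_probability <- function(prey, stage, params = model_params()) {
  if (params$capture_mode == "calibration") return(1)
  switch(prey$capture_mode,
    always_one = 1,
    ontogenetic_ramp = {
      f <- (stage$standard_length - params$capture_ramp_start) /
        (params$capture_ramp_end - params$capture_ramp_start)
      min(max(f, 0), 1)
    }
  )
}

#' Hourly ingestion of one prey type
#'
#' Ingestion follows a linear (non-saturating) functional response:
#' captures per hour are `P * beta * N` and the ingested mass is captures
#' times prey dry weight. Saturation enters the model only through the
#' ad-libitum growth cap in [growth_budget()].
#'
#' @param prey A [prey_type()].
#' @param density Prey concentration in m^-3 (>= 0).
#' @param stage A [larval_stage()].
#' @param light `"day"` or `"night"`.
#' @param params A calibrated [model_params()] object.
#' @return Named numeric: `count_h` (prey h^-1) and `mg_h` (mg dw h^-1).
#' @export
ingestion_rate <- function(prey, density, stage, light = c("day", "night"),
                           params = model_params()) {
  light <- match.arg(light)
  if (!is.numeric(density) || any(!is.finite(density)) || any(density < 0)) {
    stop("ingestion_rate: `density` must be finite and >= 0", call. = FALSE)
  }
  det <- detection_distance(prey, stage, light = light, params = params)
  beta <- search_rate(det, stage, params)
  p_cap <- capture_probability(prey, stage, params)
  count <- p_cap * beta * density
  c(count_h = count, mg_h = count * prey$dry_weight)
}

#' Calibrate the visual detection constant
#'
#' Solves the detection-distance constant `c` in closed form so that the
#' critical prey density of the anchor configuration equals the anchor
#' density exactly. The default anchor is the published maximum-growth
#' threshold for a pre-flexion (F0) larva feeding only on nauplii at 22
#' degC, 4000 nauplii m^-3; every other threshold the model produces is
#' then an out-of-sample prediction.
#'
#' With `i_req` the required ingestion (mg h^-1) to meet the anchor growth
#' target, the closed form is
#' `c = sqrt(2 * i_req / (pi * V_L * N * W_prey * P)) / (l_prey * L)`.
#'
#' @param stage Anchor larval stage.
#' @param prey Anchor prey type.
#' @param temp Anchor temperature (degC).
#' @param target_density Anchor critical density (m^-3, > 0).
#' @param target `"max_growth"` (density sustaining the ad-libitum rate) or
#'   `"maintenance"` (zero growth).
#' @param params A [model_params()] object; returned with
#'   `detection_calib_c` set.
#' @return The calibrated `bft_params` object.
#' @examples
#' params <- calibrate_detection()
#' params$detection_calib_c # ~7.34 mm^-1
#' @export
calibrate_detection <- function(stage = NULL, prey = NULL, temp = 22,
                                target_density = 4000,
                                target = c("max_growth", "maintenance"),
                                params = model_params()) {
  target <- match.arg(target)
  if (is.null(stage)) stage <- default_stages(params)$F0
  if (is.null(prey)) prey <- default_prey()$nauplius
  if (!is.numeric(target_density) || target_density <= 0 ||
      !is.finite(target_density)) {
    stop("calibrate_detection: `target_density` must be positive", call. = FALSE)
  }
  i_req <- required_ingestion(stage, temp, target, params)
  p_cap <- capture_probability(prey, stage, params)
  if (p_cap <= 0) {
    stop("calibrate_detection: anchor capture probability is zero", call. = FALSE)
  }
  v_m_h <- swim_speed_m_h(stage)
  r_m <- sqrt(2 * i_req / (pi * v_m_h * target_density * prey$dry_weight * p_cap))
  params$detection_calib_c <- r_m * 1000 / (prey$length * stage$standard_length)
  validate_params(params)
  params
}

# Ingestion (mg dw h^-1) needed for a stage to meet a growth target at temp,
# under the configured metabolism accounting.
required_ingestion <- function(stage, temp, target = c("max_growth", "maintenance"),
                               params = model_params()) {
  target <- match.arg(target)
  w <- stage$dry_weight
  r_h <- metabolic_rate(w, temp, params)
  d <- params$daylight_hours
  g_day <- if (target == "max_growth") sgr_max(temp, params) * w else 0
  switch(params$metabolism_accounting,
    daylight = (g_day / d + r_h) / params$alpha,
    full_day = (g_day + 24 * r_h) / (params$alpha * d)
  )
}
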