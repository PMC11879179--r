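#' Model parameters for the larval foraging/bioenergetics model
#'
#' Bundles every physiological and optical constant of the growth budget:
#' assimilation efficiency, the routine-metabolism power law and its unit
#' conversion chain, the Q10 temperature scaling, the temperature-dependent
#' ad-libitum growth ceiling, the length-weight relationship, photoperiod,
#' swimming speed, and the visual detection-distance calibration constant.
#'
#' @param alpha Assimilation efficiency (dimensionless, 0 < alpha <= 1).
#' @param q10 Q10 factor for routine metabolism (dimensionless).
#' @param resp_coef Coefficient of the metabolic power law
#'   (umol O2 h^-1 mg^-resp_exp, measured at `t_ref`).
#' @param resp_exp Mass exponent of the metabolic power law.
#' @param resp_conversions Ordered multiplicative factors converting umol O2
#'   h^-1 to mg dry weight h^-1 (oxycalorific / protein / carbon / dry-weight
#'   chain). Stored as a vector so the chain stays auditable.
#' @param t_ref Reference temperature of the metabolic measurement (degC).
#' @param sgr_slope,sgr_intercept Linear dependence of the ad-libitum specific
#'   growth rate on temperature: `sgr_max = sgr_slope * T - sgr_intercept`
#'   (day^-1); fitted over 22-28 degC.
#' @param lw_coef,lw_exp Length-weight relationship
#'   `W = lw_coef * exp(lw_exp * SL)` (mg dry weight; SL in mm).
#' @param daylight_hours Feeding hours per day; the larvae do not feed in
#'   darkness.
#' @param swim_bl_per_s Larval cruising speed in body lengths per second.
#' @param detection_calib_c Visual detection-distance constant: mm of
#'   detection distance per (mm prey length x mm larval length). `NA` until
#'   set by [calibrate_detection()].
#' @param capture_ramp_start,capture_ramp_end Larval standard lengths (mm)
#'   between which the capture probability for large prey ramps linearly from
#'   0 to 1 (first feeding to post-flexion).
#' @param capture_mode `"calibration"` treats capture probability as 1 for all
#'   prey (the mode under which published thresholds are reproduced);
#'   `"ontogenetic"` applies each prey type's own capture ontogeny.
#' @param metabolism_accounting `"daylight"` accrues metabolic losses only
#'   over the feeding hours when converting the hourly budget to a daily
#'   rate; `"full_day"` additionally charges the (24 - daylight) night hours.
#'
#' @return An object of class `bft_params` (a validated list).
#' @examples
#' p <- model_params()
#' p$alpha
#' prod(p$resp_conversions)
#' @export
model_params <- function(alpha = 0.77,
                         q10 = 2,
                         resp_coef = 0.404,
                         resp_exp = 0.994,
                         resp_conversions = c(32, 0.88, 12 / 34, 100 / (1000 * 45)),
                         t_ref = 26,
                         sgr_slope = 0.0418,
                         sgr_intercept = 0.8355,
                         lw_coef = 0.0008,
                         lw_exp = 0.9052,
                         daylight_hours = 15,
                         swim_bl_per_s = 3,
                         detection_calib_c = NA_real_,
                         capture_ramp_start = 3.0,
                         capture_ramp_end = 7.5,
                         capture_mode = c("calibration", "ontogenetic"),
                         metabolism_accounting = c("daylight", "full_day")) {
  capture_mode <- match.arg(capture_mode)
  metabolism_accounting <- match.arg(metabolism_accounting)
  p <- list(
    alpha = alpha, q10 = q10,
    resp_coef = resp_coef, resp_exp = resp_exp,
    resp_conversions = resp_conversions, t_ref = t_ref,
    sgr_slope = sgr_slope, sgr_intercept = sgr_intercept,
    lw_coef = lw_coef, lw_exp = lw_exp,
    daylight_hours = daylight_hours, swim_bl_per_s = swim_bl_per_s,
    detection_calib_c = detection_calib_c,
    capture_ramp_start = capture_ramp_start,
    capture_ramp_end = capture_ramp_end,
    capture_mode = capture_mode,
    metabolism_accounting = metabolism_accounting
  )
  class(p) <- "bft_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "bft_params"))
  num_pos <- c(
    "q10", "resp_coef", "resp_exp", "t_ref", "sgr_slope", "sgr_intercept",
    "lw_coef", "lw_exp", "daylight_hours", "swim_bl_per_s"
  )
  for (f in num_pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] <= 0) {
      stop("model_params: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha > 1) {
    stop("model_params: `alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(p$resp_conversions)) || any(p$resp_conversions <= 0)) {
    stop("model_params: `resp_conversions` must be positive", call. = FALSE)
  }
  if (p$daylight_hours > 24) {
    stop("model_params: `daylight_hours` cannot exceed 24", call. = FALSE)
  }
  if (!(p$capture_ramp_start < p$capture_ramp_end)) {
    stop("model_params: capture ramp must have start < end", call. = FALSE)
  }
  if (!is.na(p$detection_calib_c) && p$detection_calib_c <= 0) {
    stop("model_params: `detection_calib_c` must be positive when set",
         call. = FALSE)
  }
  invisible(p)
}

is_calibrated <- function(params) {
  !is.na(params$detection_calib_c)
}

require_calibrated <- function(params) {
  if (!is_calibrated(params)) {
    stop("calibration required: `detection_calib_c` is not set; ",
         "run calibrate_detection() first or supply the constant explicitly",
         call. = FALSE)
  }
  invisible(params)
}

#' @export
print.bft_params <- function(x, ...) {
  cat("<bft_params>\n")
  cat(sprintf("  assimilation alpha      : %.3g\n", x$alpha))
  cat(sprintf("  metabolism              : %.4g * W^%.4g * prod(%s) * %.3g^((T - %g)/10)\n",
              x$resp_coef, x$resp_exp,
              paste(signif(x$resp_conversions, 4), collapse = ", "),
              x$q10, x$t_ref))
  cat(sprintf("  ad-libitum SGR (day^-1) : %.4g * T - %.4g\n",
              x$sgr_slope, x$sgr_intercept))
  cat(sprintf("  length-weight (mg)      : %.4g * exp(%.4g * SL)\n",
              x$lw_coef, x$lw_exp))
  cat(sprintf("  photoperiod             : %g h daylight (%s accounting)\n",
              x$daylight_hours, x$metabolism_accounting))
  cat(sprintf("  swimming                : %g body lengths s^-1\n", x$swim_bl_per_s))
  cat(sprintf("  detection constant c    : %s mm^-1 (%s)\n",
              if (is_calibrated(x)) signif(x$detection_calib_c, 5) else "<uncalibrated>",
              x$capture_mode))
  invisible(x)
}
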