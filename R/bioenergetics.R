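#' Larval dry weight from standard length
#'
#' Exponential length-weight relationship for bluefin tuna larvae,
#' `W = lw_coef * exp(lw_exp * SL)`.
#'
#' @param sl Standard length in mm (> 0); vectorised.
#' @param params A [model_params()] object.
#' @return Dry weight in mg.
#' @examples
#' weight_from_length(4.8) # ~0.0617 mg, a pre-flexion larva
#' @export
weight_from_length <- function(sl, params = model_params()) {
  if (!is.numeric(sl) || any(!is.finite(sl)) || any(sl <= 0)) {
    stop("weight_from_length: `sl` must be positive (mm)", call. = FALSE)
  }
  params$lw_coef * exp(params$lw_exp * sl)
}

#' Routine metabolic rate
#'
#' Size- and temperature-dependent routine metabolism. Oxygen consumption
#' scales almost proportionally with larval dry weight
#' (`resp_coef * W^resp_exp`, umol O2 h^-1 at the reference temperature),
#' is converted to mg dry weight h^-1 through the multiplicative conversion
#' chain in `params$resp_conversions`, and scaled with temperature by a Q10
#' law.
#'
#' @param w Larval dry weight in mg (> 0); vectorised.
#' @param temp Water temperature in degC.
#' @param params A [model_params()] object.
#' @return Metabolic loss rate in mg dw h^-1.
#' @examples
#' w <- weight_from_length(4.8)
#' metabolic_rate(w, 22)
#' metabolic_rate(w, 32) / metabolic_rate(w, 22) # = Q10 = 2
#' @export
metabolic_rate <- function(w, temp, params = model_params()) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0)) {
    stop("metabolic_rate: `w` must be positive (mg dw)", call. = FALSE)
  }
  params$resp_coef * w^params$resp_exp * prod(params$resp_conversions) *
    params$q10^((temp - params$t_ref) / 10)
}

#' Ad-libitum specific growth rate
#'
#' The temperature-dependent ceiling on daily specific growth, from
#' temperature-controlled rearing at unlimited food:
#' `sgr_max = sgr_slope * T - sgr_intercept` (day^-1). The linear form was
#' fitted over 22-28 degC; temperatures outside that window extrapolate and
#' trigger a warning.
#'
#' @param temp Water temperature in degC; vectorised.
#' @param params A [model_params()] object.
#' @return Maximum specific growth rate in mg dw mg^-1 day^-1.
#' @examples
#' sgr_max(25) # 0.2095 day^-1
#' @export
sgr_max <- function(temp, params = model_params()) {
  if (any(temp < 22 | temp > 28)) {
    warning("sgr_max: temperature outside the 22-28 degC calibration range; ",
            "the linear ad-libitum growth model is extrapolated", call. = FALSE)
  }
  params$sgr_slope * temp - params$sgr_intercept
}

#' Hourly and daily growth budget of a larva
#'
#' Assembles the full energy budget at the given conditions: per-prey visual
#' detection, search rate, capture probability, encounter and ingestion;
#' total assimilated intake minus routine metabolism gives the hourly
#' daylight specific growth rate `(alpha * i_total - R_h) / W`. The daily
#' rate multiplies the hourly rate by the feeding photoperiod (under
#' `"full_day"` accounting the night hours additionally pay metabolism) and
#' is capped at the ad-libitum ceiling [sgr_max()]. The food limitation
#' index FLI is the realized daily rate divided by the ceiling; FLI = 1
#' means food does not limit growth.
#'
#' @param stage A [larval_stage()].
#' @param prey List of [prey_type()] objects (may be empty: starvation).
#' @param densities Numeric vector of prey concentrations (m^-3), one per
#'   prey, all >= 0.
#' @param temp Water temperature in degC.
#' @param params A calibrated [model_params()] object.
#' @param light `"day"` or `"night"`; at night visual detection, hence
#'   ingestion, is zero.
#'
#' @return An object of class `bft_budget`: a list with `per_prey` (a
#'   data.frame of detection distance m, search rate m^3 h^-1, capture
#'   probability, encounter h^-1, ingestion count h^-1 and mg h^-1 per
#'   prey), the totals `ingestion_mg_h` and `metabolism_mg_h`, the rates
#'   `sgr_hourly` (h^-1), `sgr_daily_uncapped` and `sgr_daily` (day^-1),
#'   `sgr_ad_libitum`, the logical `capped`, and `fli`.
#' @examples
#' params <- calibrate_detection()
#' st <- default_stages(params)
#' pr <- default_prey()
#' growth_budget(st$F0, pr["nauplius"], 500, temp = 25, params = params)
#' @export
growth_budget <- function(stage, prey, densities, temp,
                          params = model_params(), light = c("day", "night")) {
  light <- match.arg(light)
  stopifnot(inherits(stage, "bft_stage"))
  if (inherits(prey, "bft_prey")) prey <- list(prey)
  if (length(prey) != length(densities)) {
    stop("growth_budget: `prey` and `densities` lengths differ", call. = FALSE)
  }
  if (length(densities) && (any(!is.finite(densities)) || any(densities < 0))) {
    stop("growth_budget: prey densities must be finite and >= 0", call. = FALSE)
  }
  require_calibrated(params)

  w <- stage$dry_weight
  r_h <- metabolic_rate(w, temp, params)
  smax <- sgr_max(temp, params)
  d <- params$daylight_hours

  if (length(prey)) {
    per <- do.call(rbind, lapply(seq_along(prey), function(i) {
      pr <- prey[[i]]
      det <- detection_distance(pr, stage, light = light, params = params)
      beta <- search_rate(det, stage, params)
      p_cap <- capture_probability(pr, stage, params)
      enc <- beta * densities[i]
      data.frame(
        prey = pr$name,
        density_m3 = densities[i],
        detection_m = det,
        search_m3_h = beta,
        capture_p = p_cap,
        encounter_h = enc,
        ingestion_count_h = p_cap * enc,
        ingestion_mg_h = p_cap * enc * pr$dry_weight,
        stringsAsFactors = FALSE
      )
    }))
  } else {
    per <- data.frame(
      prey = character(), density_m3 = numeric(), detection_m = numeric(),
      search_m3_h = numeric(), capture_p = numeric(), encounter_h = numeric(),
      ingestion_count_h = numeric(), ingestion_mg_h = numeric(),
      stringsAsFactors = FALSE
    )
  }

  i_total <- sum(per$ingestion_mg_h)
  sgr_h <- (params$alpha * i_total - r_h) / w
  sgr_day_uncapped <- switch(params$metabolism_accounting,
    daylight = sgr_h * d,
    full_day = sgr_h * d - (24 - d) * r_h / w
  )
  capped <- sgr_day_uncapped >= smax
  sgr_day <- min(sgr_day_uncapped, smax)
  fli <- if (smax > 0) min(sgr_day / smax, 1) else NA_real_

  structure(list(
    stage = stage, temp = temp, light = light,
    accounting = params$metabolism_accounting,
    per_prey = per,
    ingestion_mg_h = i_total,
    metabolism_mg_h = r_h,
    sgr_hourly = sgr_h,
    sgr_daily_uncapped = sgr_day_uncapped,
    sgr_daily = sgr_day,
    sgr_ad_libitum = smax,
    capped = capped,
    fli = fli
  ), class = "bft_budget")
}

#' @export
print.bft_budget <- function(x, ...) {
  cat(sprintf("<bft_budget %s @ %.1f degC (%s)>\n",
              x$stage$code, x$temp, x$accounting))
  if (nrow(x$per_prey)) {
    print(cbind(x$per_prey[, c("prey", "density_m3")],
                signif(x$per_prey[, c("search_m3_h", "capture_p",
                                      "ingestion_count_h", "ingestion_mg_h")], 4)))
  }
  cat(sprintf("  ingestion %.4g mg/h, metabolism %.4g mg/h\n",
              x$ingestion_mg_h, x$metabolism_mg_h))
  cat(sprintf("  daily SGR %.4g (uncapped %.4g, ad-libitum %.4g)%s, FLI %.3f\n",
              x$sgr_daily, x$sgr_daily_uncapped, x$sgr_ad_libitum,
              if (x$capped) " [capped]" else "", x$fli))
  invisible(x)
}
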