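#' Distributional profile of one survey year
#'
#' Statistical targets for generating synthetic survey stations: for each
#' zooplankton variable a clipped lognormal matched to the survey mean, SD
#' and observed range (with a configurable number of absence stations), and
#' a truncated normal for the mixed-layer temperature. Abundances are
#' right-skewed in the surveys (ranges far wider than means), hence the
#' lognormal family.
#'
#' The printed survey mean is taken to include absence stations, so the
#' positive component targets `mean / (1 - p_zero)`. The lognormal shape is
#' set from the coefficient of variation; its location is then calibrated
#' numerically so that the *post-clip* expectation matches the target mean
#' (clipping to the observed range would otherwise bias the mean). The
#' temperature location is calibrated the same way under truncation. The SD
#' is matched before clipping and is therefore biased slightly low after it.
#'
#' @param year Label (e.g. `2020`, `2022`, `"synthetic"`).
#' @param temperature List with `mean`, `sd`, `min`, `max` (degC).
#' @param abundances Named list (`nauplii`, `cladocera`, `copepods`,
#'   optionally `bluefin`); each element a list with `mean`, `sd`, `min`,
#'   `max` (m^-3) and `n_zero` (absence stations out of `survey_n`).
#' @param survey_n Number of stations in the real survey; when exactly
#'   `survey_n` stations are generated the absence count is forced, otherwise
#'   absences are drawn with probability `n_zero / survey_n`.
#' @param lon_range,lat_range Bounding box for cosmetic station coordinates
#'   (degrees; Balearic Sea box by default).
#' @return An object of class `bft_year_profile`.
#' @export
year_profile <- function(year, temperature, abundances, survey_n = 17,
                         lon_range = c(0.5, 4.5), lat_range = c(38, 41)) {
  stopifnot(all(c("mean", "sd", "min", "max") %in% names(temperature)))
  for (nm in names(abundances)) {
    a <- abundances[[nm]]
    stopifnot(all(c("mean", "sd", "min", "max") %in% names(a)))
    if (is.null(a$n_zero)) abundances[[nm]]$n_zero <- 0L
    stopifnot(a$mean > 0, a$sd > 0, a$min > 0, a$min < a$max)
  }
  p <- list(year = year, temperature = temperature, abundances = abundances,
            survey_n = survey_n, lon_range = lon_range, lat_range = lat_range)
  class(p) <- "bft_year_profile"
  p
}

#' Default year profiles (2020 and 2022 surveys)
#'
#' Targets from the two Balearic Sea surveys: per-variable abundance mean,
#' SD and range across the 17 zooplankton stations, the number of stations
#' where cladocerans and bluefin larvae were absent (3 and 3 in 2020, 1 and
#' 2 in 2022), and the mixed-layer temperature range (23.1-25.3 degC in
#' 2020, 23.9-25.5 degC in 2022).
#'
#' @return Named list with elements `"2020"` and `"2022"`, each a
#'   [year_profile()].
#' @export
default_profiles <- function() {
  list(
    "2020" = year_profile(
      2020,
      temperature = list(mean = 24.4, sd = 0.7, min = 23.1, max = 25.3),
      abundances = list(
        nauplii = list(mean = 506, sd = 303, min = 169, max = 1244, n_zero = 0L),
        cladocera = list(mean = 653, sd = 1834, min = 1, max = 7272, n_zero = 3L),
        copepods = list(mean = 258, sd = 173, min = 26, max = 773, n_zero = 0L),
        bluefin = list(mean = 0.27, sd = 0.52, min = 0.002, max = 1.7, n_zero = 3L)
      )
    ),
    "2022" = year_profile(
      2022,
      temperature = list(mean = 24.6, sd = 0.5, min = 23.9, max = 25.5),
      abundances = list(
        nauplii = list(mean = 311, sd = 438, min = 43, max = 918, n_zero = 0L),
        cladocera = list(mean = 17, sd = 22, min = 1, max = 74, n_zero = 1L),
        copepods = list(mean = 154, sd = 126, min = 3, max = 494, n_zero = 0L),
        bluefin = list(mean = 1.16, sd = 3.7, min = 0.005, max = 15.28, n_zero = 2L)
      )
    )
  )
}

# Mean of min(max(X, lo), hi) for X ~ lognormal(mu, sigma).
clipped_lnorm_mean <- function(mu, sigma, lo, hi) {
  zlo <- (log(lo) - mu) / sigma
  zhi <- (log(hi) - mu) / sigma
  mid <- exp(mu + sigma^2 / 2) *
    (stats::pnorm(zhi - sigma) - stats::pnorm(zlo - sigma))
  lo * stats::pnorm(zlo) + hi * stats::pnorm(-zhi) + mid
}

# Lognormal parameters whose clipped mean equals `mean`; sdlog from the CV.
clipped_lnorm_params <- function(mean, sd, lo, hi) {
  sigma <- sqrt(log(1 + (sd / mean)^2))
  f <- function(mu) clipped_lnorm_mean(mu, sigma, lo, hi) - mean
  # clipped mean is monotone in mu, bounded in (lo, hi)
  if (mean <= lo || mean >= hi) {
    stop("target mean must lie inside the clip range", call. = FALSE)
  }
  mu <- stats::uniroot(f, lower = log(lo) - 5 * sigma,
                       upper = log(hi) + 5 * sigma, tol = 1e-12)$root
  list(meanlog = mu, sdlog = sigma)
}

# Mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  mu + sigma * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

truncnorm_location <- function(mean, sd, lo, hi) {
  if (mean <= lo || mean >= hi) {
    stop("target mean must lie inside the truncation range", call. = FALSE)
  }
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - mean
  # wider brackets underflow pnorm differences; +-2 sd beyond the range is
  # always enough because the truncated mean then hugs the boundary
  stats::uniroot(f, lower = lo - 2 * sd, upper = hi + 2 * sd, tol = 1e-12)$root
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sigma), stats::pnorm(hi, mu, sigma))
  stats::qnorm(u, mu, sigma)
}

#' Generate synthetic survey stations
#'
#' Draws `n` stations i.i.d. from a [year_profile()]: clipped lognormal
#' abundances (location-calibrated so the expected sample mean, absences
#' included, equals the survey mean), forced or Bernoulli absence stations
#' for zero-inflated variables, truncated-normal mixed-layer temperature,
#' and uniform coordinates in the survey box (the surveys found prey
#' spatially near-homogeneous, so no spatial structure is imposed; bluefin
#' larvae are drawn independently of prey, as observed).
#'
#' @param n Number of stations (>= 1).
#' @param profile A [year_profile()]; default the 2020 survey profile.
#' @param seed Integer seed; generation is fully deterministic given the
#'   seed (mandatory for reproducibility).
#' @return A data.frame with columns `id`, `year`, `lon`, `lat`,
#'   `temperature_c`, `nauplii_m3`, `cladocera_m3`, `copepods_m3`,
#'   `bluefin_m3`.
#' @examples
#' head(generate_stations(17, seed = 42))
#' @export
generate_stations <- function(n, profile = default_profiles()[["2020"]], seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("generate_stations: `n` must be >= 1", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("generate_stations: an integer `seed` is required", call. = FALSE)
  }
  n <- as.integer(n)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  tt <- profile$temperature
  mu_t <- truncnorm_location(tt$mean, tt$sd, tt$min, tt$max)
  out <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    year = profile$year,
    lon = stats::runif(n, profile$lon_range[1], profile$lon_range[2]),
    lat = stats::runif(n, profile$lat_range[1], profile$lat_range[2]),
    temperature_c = rtruncnorm(n, mu_t, tt$sd, tt$min, tt$max),
    stringsAsFactors = FALSE
  )

  col_of <- c(nauplii = "nauplii_m3", cladocera = "cladocera_m3",
              copepods = "copepods_m3", bluefin = "bluefin_m3")
  for (nm in names(profile$abundances)) {
    a <- profile$abundances[[nm]]
    p_zero <- a$n_zero / profile$survey_n
    pos_mean <- if (p_zero > 0) a$mean / (1 - p_zero) else a$mean
    pos_mean <- min(pos_mean, 0.99 * a$max) # keep the calibration solvable
    lp <- clipped_lnorm_params(pos_mean, a$sd, a$min, a$max)
    x <- stats::rlnorm(n, lp$meanlog, lp$sdlog)
    x <- pmin(pmax(x, a$min), a$max)
    if (a$n_zero > 0) {
      zero_idx <- if (n == profile$survey_n) {
        sample.int(n, a$n_zero)
      } else {
        which(stats::runif(n) < p_zero)
      }
      x[zero_idx] <- 0
    }
    out[[col_of[[nm]]]] <- x
  }
  out
}
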