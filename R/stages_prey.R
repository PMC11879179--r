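#' Larval developmental stage
#'
#' A bluefin tuna larva of a given standard length. The dry weight is always
#' derived from the length through the length-weight relationship and cached;
#' it can never be set independently.
#'
#' @param code Stage label; the defaults are `"F0"` (pre-flexion, 4.8 mm),
#'   `"F1"` (first caudal-fin rays, 5.8 mm), `"F2"` (flexion, 6.7 mm) and
#'   `"F3"` (post-flexion, 7.5 mm).
#' @param standard_length Standard length in mm (> 0).
#' @param params A [model_params()] object (supplies the length-weight
#'   coefficients and the default swimming speed).
#' @param swim_bl_per_s Cruising speed in body lengths per second.
#'
#' @return An object of class `bft_stage` with fields `code`,
#'   `standard_length` (mm), `dry_weight` (mg dw) and `swim_bl_per_s`.
#' @examples
#' larval_stage("F0", 4.8)
#' @export
larval_stage <- function(code, standard_length, params = model_params(),
                         swim_bl_per_s = params$swim_bl_per_s) {
  if (!is.numeric(standard_length) || length(standard_length) != 1L ||
      !is.finite(standard_length) || standard_length <= 0) {
    stop("larval_stage: `standard_length` must be a single positive number (mm)",
         call. = FALSE)
  }
  s <- list(
    code = as.character(code),
    standard_length = standard_length,
    dry_weight = weight_from_length(standard_length, params),
    swim_bl_per_s = swim_bl_per_s
  )
  class(s) <- "bft_stage"
  s
}

#' Default developmental stages F0-F3
#'
#' Pre-flexion (F0, 4.8 mm), first caudal-fin rays (F1, 5.8 mm), flexion
#' (F2, 6.7 mm) and post-flexion (F3, 7.5 mm).
#'
#' @param params A [model_params()] object.
#' @return Named list of [larval_stage()] objects.
#' @export
default_stages <- function(params = model_params()) {
  lens <- c(F0 = 4.8, F1 = 5.8, F2 = 6.7, F3 = 7.5)
  stages <- lapply(names(lens), function(code) {
    larval_stage(code, lens[[code]], params)
  })
  names(stages) <- names(lens)
  stages
}

#' @export
print.bft_stage <- function(x, ...) {
  cat(sprintf("<bft_stage %s: SL %.2f mm, W %.4g mg dw, %g BL/s>\n",
              x$code, x$standard_length, x$dry_weight, x$swim_bl_per_s))
  invisible(x)
}

#' Prey type
#'
#' A zooplankton prey category characterised by its length, dry mass and
#' capture-probability ontogeny: nauplii are captured with probability 1 at
#' all larval sizes, while larger cladocerans and copepods become easier to
#' capture as the larva develops from first feeding to post-flexion.
#'
#' @param name Prey label.
#' @param length Prey length in mm (> 0).
#' @param dry_weight Prey dry mass in mg (> 0).
#' @param capture_mode `"always_one"` (captured whenever encountered) or
#'   `"ontogenetic_ramp"` (capture probability ramps linearly with larval
#'   length between the ramp endpoints in [model_params()]).
#'
#' @return An object of class `bft_prey`.
#' @examples
#' prey_type("nauplius", 0.15, 1.1e-4)
#' @export
prey_type <- function(name, length, dry_weight,
                      capture_mode = c("always_one", "ontogenetic_ramp")) {
  capture_mode <- match.arg(capture_mode)
  if (!is.numeric(length) || length <= 0 || !is.finite(length)) {
    stop("prey_type: `length` must be positive (mm)", call. = FALSE)
  }
  if (!is.numeric(dry_weight) || dry_weight <= 0 || !is.finite(dry_weight)) {
    stop("prey_type: `dry_weight` must be positive (mg)", call. = FALSE)
  }
  p <- list(name = as.character(name), length = length,
            dry_weight = dry_weight, capture_mode = capture_mode)
  class(p) <- "bft_prey"
  p
}

#' Default prey types
#'
#' The three prey categories dominating the diet of bluefin tuna larvae in
#' the Western Mediterranean: copepod nauplii (0.15 mm, 0.11 ug dw),
#' cladocerans (0.8 mm, 3.15 ug dw) and copepods (1.0 mm, 11.1 ug dw).
#'
#' @param sensitivity_nauplius If `TRUE`, replace the nauplius with the
#'   alternative larger nauplius (0.3 mm, 0.5 ug dw) used in the sensitivity
#'   scenario.
#' @return Named list of [prey_type()] objects
#'   (`nauplius`, `cladoceran`, `copepod`).
#' @export
default_prey <- function(sensitivity_nauplius = FALSE) {
  naup <- if (sensitivity_nauplius) {
    prey_type("nauplius", 0.3, 5e-4, "always_one")
  } else {
    prey_type("nauplius", 0.15, 1.1e-4, "always_one")
  }
  list(
    nauplius = naup,
    cladoceran = prey_type("cladoceran", 0.8, 3.15e-3, "ontogenetic_ramp"),
    copepod = prey_type("copepod", 1.0, 1.11e-2, "ontogenetic_ramp")
  )
}

#' @export
print.bft_prey <- function(x, ...) {
  cat(sprintf("<bft_prey %s: %.3g mm, %.3g mg dw, %s>\n",
              x$name, x$length, x$dry_weight, x$capture_mode))
  invisible(x)
}
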