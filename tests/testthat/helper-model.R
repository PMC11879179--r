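# Shared fixtures: one calibration for the whole suite, plus an independent
# numeric oracle for critical densities (root-finding on the growth budget,
# never on the closed form).

params_cal <- calibrate_detection()
stages_def <- default_stages(params_cal)
prey_def <- default_prey()

# Critical density by scalar root-finding on the *uncapped* daily SGR curve
# produced by growth_budget(); brackets by doubling, then uniroot.
oracle_critical_density <- function(stage, prey, temp, target, params) {
  goal <- if (target == "max_growth") {
    suppressWarnings(sgr_max(temp, params))
  } else {
    0
  }
  f <- function(n) {
    b <- suppressWarnings(growth_budget(stage, list(prey), n, temp, params))
    b$sgr_daily_uncapped - goal
  }
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-13 * upper)$root
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
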