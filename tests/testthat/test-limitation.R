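test_that("closed-form critical density matches the numeric budget oracle", {
  set.seed(41)
  for (i in 1:100) {
    stage <- larval_stage(sprintf("r%d", i), runif(1, 4, 8.5), params_cal)
    pr <- if (i %% 4 == 0) {
      prey_type("rand", runif(1, 0.1, 1.5), 10^runif(1, -4, -1.5))
    } else {
      prey_def[[sample(3, 1)]]
    }
    temp <- runif(1, 22, 28)
    target <- sample(c("maintenance", "max_growth"), 1)
    closed <- critical_density(stage, pr, temp, target, params_cal)
    numeric <- oracle_critical_density(stage, pr, temp, target, params_cal)
    expect_lt(rel_err(closed, numeric), 1e-9)
  }
})

test_that("critical-density table obeys its ordering invariants", {
  tab <- critical_density_table(stages_def, prey_def, c(22, 25, 28),
                                c("maintenance", "max_growth"), params_cal)
  expect_equal(nrow(tab), 4 * 3 * 3 * 2)
  wide <- reshape(tab[, c("stage", "prey", "temperature_c", "target",
                          "critical_density_m3")],
                  direction = "wide", timevar = "target",
                  idvar = c("stage", "prey", "temperature_c"))
  # growing at the ceiling always needs more food than bare maintenance
  expect_true(all(wide$critical_density_m3.max_growth >
                    wide$critical_density_m3.maintenance))
  # thresholds rise with temperature and with stage for every prey/target
  for (pr in unique(tab$prey)) {
    for (tg in unique(tab$target)) {
      sub <- tab[tab$prey == pr & tab$target == tg, ]
      by_temp <- split(sub$critical_density_m3, sub$stage)
      expect_true(all(vapply(by_temp, function(x) all(diff(x) > 0), logical(1))))
      by_stage <- split(sub, sub$temperature_c)
      expect_true(all(vapply(by_stage, function(d) {
        all(diff(d$critical_density_m3[order(d$standard_length_mm)]) > 0)
      }, logical(1))))
    }
  }
  # F3 needs more than F0 at any fixed temperature and prey
  f3 <- tab[tab$stage == "F3", "critical_density_m3"]
  f0 <- tab[tab$stage == "F0", "critical_density_m3"]
  expect_true(all(f3 / f0 > 1))
})

test_that("cross-prey thresholds follow the W * l^2 law", {
  # with P = 1 the threshold ratio is exactly (W_B l_B^2) / (W_A l_A^2)
  for (temp in c(22, 25, 28)) {
    for (stage in stages_def) {
      n_nau <- critical_density(stage, prey_def$nauplius, temp, "max_growth",
                                params_cal)
      n_cla <- critical_density(stage, prey_def$cladoceran, temp, "max_growth",
                                params_cal)
      n_cop <- critical_density(stage, prey_def$copepod, temp, "max_growth",
                                params_cal)
      ratio_cla <- (1.1e-4 * 0.15^2) / (3.15e-3 * 0.8^2)
      ratio_cop <- (1.1e-4 * 0.15^2) / (1.11e-2 * 1.0^2)
      expect_equal(n_cla / n_nau, ratio_cla, tolerance = 1e-12)
      expect_equal(n_cop / n_nau, ratio_cop, tolerance = 1e-12)
      # cladoceran needs are about three orders of magnitude below nauplii
      expect_gt(n_nau / n_cla, 500)
      expect_lt(n_nau / n_cla, 1500)
    }
  }
})

test_that("capture probability zero yields an infinite-density sentinel", {
  p_ramp <- model_params(capture_mode = "ontogenetic",
                         detection_calib_c = params_cal$detection_calib_c)
  first_feeder <- larval_stage("ff", 2.9, p_ramp)
  expect_identical(
    critical_density(first_feeder, prey_def$copepod, 25, "max_growth", p_ramp),
    Inf)
})

test_that("response surface crosses zero at maintenance and saturates at the ceiling", {
  st <- stages_def$F1
  pr <- prey_def$nauplius
  for (temp in c(22, 25, 28)) {
    n_maint <- critical_density(st, pr, temp, "maintenance", params_cal)
    n_max <- critical_density(st, pr, temp, "max_growth", params_cal)
    dens <- seq(0, 2 * n_max, length.out = 41)
    surf <- response_surface(st, pr, temp, dens, params_cal)
    expect_true(all(diff(surf$sgr_daily) > -1e-12))      # monotone
    expect_lt(surf$sgr_daily[1], 0)                      # starvation at N = 0
    expect_true(all(surf$sgr_daily <= sgr_max(temp, params_cal) + 1e-12))
    at_crit <- response_surface(st, pr, temp, n_max, params_cal)
    expect_lt(rel_err(at_crit$sgr_daily, sgr_max(temp, params_cal)), 1e-9)
    # root of the curve sits at the maintenance threshold
    froot <- function(n) {
      response_surface(st, pr, temp, n, params_cal)$sgr_daily
    }
    root <- stats::uniroot(froot, c(0, n_max), tol = 1e-10 * n_max)$root
    expect_lt(rel_err(root, n_maint), 1e-7)
  }
})

test_that("larger sensitivity nauplius divides thresholds by the trait ratio", {
  prey_sens <- default_prey(sensitivity_nauplius = TRUE)
  ratio <- (5e-4 * 0.3^2) / (1.1e-4 * 0.15^2) # = 18.18...
  expect_equal(ratio, 18.1818181818, tolerance = 1e-9)
  for (stage in stages_def) {
    n_small <- critical_density(stage, prey_def$nauplius, 25, "max_growth",
                                params_cal)
    n_large <- critical_density(stage, prey_sens$nauplius, 25, "max_growth",
                                params_cal)
    expect_equal(n_small / n_large, ratio, tolerance = 1e-12)
    expect_lt(n_large, n_small) # limitation relieved at lower abundance
  }
})

test_that("station assessment reproduces the survey-average diet contrasts", {
  avg_station <- data.frame(
    id = "AVG2020", temperature_c = 24.4,
    nauplii_m3 = 506, cladocera_m3 = 653, copepods_m3 = 258
  )
  res <- assess_stations(avg_station, stages_def, params_cal, prey_def)
  expect_equal(nrow(res), 4 * 4) # stages x scenarios
  nau <- res[res$scenario == "nauplii_only", ]
  cop <- res[res$scenario == "copepods_only", ]
  expect_true(all(nau$limited))     # nauplii alone cannot sustain max growth
  expect_true(all(!cop$limited))    # copepods alone can, at all stages
  expect_true(all(cop$fli == 1))
  # combined diet is at least as good as the best single-prey diet
  for (stg in unique(res$stage)) {
    sub <- res[res$stage == stg, ]
    expect_gte(sub$sgr_daily[sub$scenario == "combined"],
               max(sub$sgr_daily[sub$scenario != "combined"]) - 1e-12)
  }
})

test_that("station assessment handles degenerate rows gracefully", {
  empty <- data.frame(id = "E0", temperature_c = 25,
                      nauplii_m3 = 0, cladocera_m3 = 0, copepods_m3 = 0)
  res <- assess_stations(empty, stages_def, params_cal, prey_def)
  expect_true(all(res$fli < 0))
  expect_true(all(res$maintenance_failed))

  bad <- data.frame(id = c("OK", "NEG"), temperature_c = c(25, 25),
                    nauplii_m3 = c(100, -4), cladocera_m3 = 0, copepods_m3 = 0)
  expect_warning(res2 <- assess_stations(bad, stages_def, params_cal, prey_def),
                 "negative")
  expect_setequal(unique(res2$id), "OK") # bad row skipped, good row kept

  no_temp <- data.frame(id = "NT", temperature_c = NA_real_,
                        nauplii_m3 = 5000, cladocera_m3 = 0, copepods_m3 = 0)
  expect_warning(res3 <- assess_stations(no_temp, stages_def, params_cal,
                                         prey_def, default_temp = 24.5),
                 "default")
  expect_equal(unique(res3$temperature_c), 24.5)

  miss_col <- data.frame(id = "MC", temperature_c = 25, nauplii_m3 = 100)
  w <- capture_warnings(res4 <- assess_stations(miss_col, stages_def,
                                                params_cal, prey_def))
  expect_match(w, "missing", all = TRUE)
  expect_length(w, 2) # cladocera and copepods columns both absent
  expect_equal(nrow(res4), 16)
})
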