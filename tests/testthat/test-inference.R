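test_that("single-record estimators match independent direct evaluation", {
  # unit cases
  expect_equal(bulk_resistivity(1, 1, 1), 1)
  expect_equal(thermal_conductivity(1, 1, 1, 2, 1), 1)

  # independently hand-evaluated: 4.374e5 * 1.539e-8 / 3e-3 = 2.2439 ohm m
  expect_equal(bulk_resistivity(4.374e5, 1.539e-8, 3e-3), 2.2439,
               tolerance = 1e-4)
  expect_equal(ohm_m_to_ohm_cm(2.2439), 224.39)

  # surface resistivity: unit resistance gives the geometric factor itself
  expect_equal(signif(surface_resistivity(1), 3), 84.8)
  expect_equal(surface_resistivity(5.9797), 507.08, tolerance = 3e-3)
  expect_equal(surface_resistivity(2 * 5.9797), 2 * surface_resistivity(5.9797))

  # hand-evaluated heat balance: 30.9 mW across 3 mm and 25 mm^2 at 12 K
  expect_equal(thermal_conductivity(0.0309, 3e-3, 25e-6, 37, 25), 0.309,
               tolerance = 1e-12)
  # invariant under joint scaling of power and gradient
  expect_equal(thermal_conductivity(3 * 0.0309, 3e-3, 25e-6, 25 + 3 * 12, 25),
               0.309, tolerance = 1e-12)

  # scaling laws
  expect_equal(bulk_resistivity(10, 2e-8, 6e-3),
               bulk_resistivity(10, 2e-8, 3e-3) / 2)

  # 1000 random positive inputs against inline formula evaluation
  withr::with_seed(10, {
    r <- runif(1000, 1, 1e6); a <- runif(1000, 1e-9, 1e-6)
    l <- runif(1000, 1e-4, 1e-2); q <- runif(1000, 1e-3, 1)
    dt <- runif(1000, 0.5, 20)
    expect_lt(max(abs(bulk_resistivity(r, a, l) / (r * a / l) - 1)), 1e-12)
    expect_lt(max(abs(surface_resistivity(r) /
                        (2 * pi / log(140 / 130) * r) - 1)), 1e-12)
    expect_lt(max(abs(thermal_conductivity(q, l, a, 25 + dt, 25) /
                        (q * l / (a * dt)) - 1)), 1e-12)
  })

  # monotonicity
  expect_gt(bulk_resistivity(11, 1e-8, 3e-3), bulk_resistivity(10, 1e-8, 3e-3))
  expect_lt(thermal_conductivity(0.03, 3e-3, 25e-6, 37, 25),
            thermal_conductivity(0.03, 3e-3, 25e-6, 31, 25))

  # degenerate inputs
  expect_error(bulk_resistivity(-1, 1, 1), "invalid measurement")
  expect_error(surface_resistivity(0), "invalid measurement")
  expect_error(thermal_conductivity(0.03, 3e-3, 25e-6, 25, 25), "no gradient")
})

test_that("unit conversion commutes with the estimator", {
  # computing in SI then converting equals converting the inputs first
  r <- 4.374e5; a_cm2 <- 1.539e-8 * 1e4; l_cm <- 0.3
  direct_cm <- r * a_cm2 / l_cm
  via_si <- ohm_m_to_ohm_cm(bulk_resistivity(r, 1.539e-8, 3e-3))
  expect_equal(via_si, direct_cm, tolerance = 1e-12)
})

test_that("sink temperature is the mean of valid RTD readings", {
  cal <- rtd_calibration()
  r3 <- temperature_to_resistance(c(30, 30.5, 31), cal)
  expect_equal(sink_temperature(r3, cal), 30.5)
  expect_equal(sink_temperature(rev(r3), cal), 30.5)
  expect_equal(sink_temperature(rep(r3[1], 3), cal), 30)
  expect_warning(t2 <- sink_temperature(c(r3[1:2], NA), cal), "2 of 3")
  expect_equal(t2, 30.25)
  expect_error(sink_temperature(c(NA, NA, NA), cal), "sensor failure")
})

test_that("profiles invert noiseless records exactly at every setpoint", {
  cfg <- study_config(noise_cv = 0, patients_per_preparation = 2, seed = 3)
  study <- generate_study(cfg)
  profiles <- build_profiles(study$measurements, study$truth,
                             chip = cfg$chip, calib = cfg$calib)
  joined <- merge(profiles, study$truth, by = c("sample_id", "group",
                                                "preparation", "patient_id"))
  frac <- (joined$temperature_c - 25) / 12
  expect_lt(max(abs(joined$rho_b_ohm_cm /
                      (joined$rho_b_25 * joined$fold_rho_b^frac) - 1)), 1e-9)
  expect_lt(max(abs(joined$rho_s_ohm_sq /
                      (joined$rho_s_25 * joined$fold_rho_s^frac) - 1)), 1e-9)
  k_true <- joined$k_25 * (1 + (joined$fold_k - 1) * frac)
  expect_lt(max(abs(joined$k_w_m_k / k_true - 1)), 1e-9)

  # the inferred endpoint ratio equals the configured fold factor
  w <- profiles[profiles$temperature_c %in% c(25, 37), ]
  s1 <- w[w$sample_id == w$sample_id[1], ]
  tr1 <- study$truth[study$truth$sample_id == s1$sample_id[1], ]
  expect_equal(s1$rho_b_ohm_cm[s1$temperature_c == 37] /
                 s1$rho_b_ohm_cm[s1$temperature_c == 25],
               tr1$fold_rho_b, tolerance = 1e-9)

  # profile entries are sorted by setpoint and delta T is positive
  expect_true(all(profiles$delta_t_k > 0))
  expect_true(all(tapply(profiles$temperature_c, profiles$sample_id,
                         function(x) !is.unsorted(x))))
})

test_that("profile building handles partial and malformed inputs", {
  cfg <- study_config(noise_cv = 0, patients_per_preparation = 1,
                      repeats_per_block = 1, preparations = "formalin_fixed")
  study <- generate_study(cfg)
  rec <- study$measurements[study$measurements$sample_id ==
                              study$measurements$sample_id[1], ]
  geo <- study$truth[study$truth$sample_id == rec$sample_id[1], ]

  # single setpoint gives a single-entry profile
  p1 <- build_profile(rec[1, ], cfg$chip, cfg$calib, geo)
  expect_equal(nrow(p1), 1)

  # a missing observable flags that parameter but leaves the others intact
  rec_bad <- rec
  rec_bad$r_bulk_ohm[2] <- NA
  p <- build_profile(rec_bad, cfg$chip, cfg$calib, geo)
  expect_true(is.na(p$rho_b_ohm_cm[2]))
  expect_false(anyNA(p$rho_s_ohm_sq))
  expect_false(anyNA(p$k_w_m_k))

  # mixed sample ids are rejected
  rec_mixed <- rec
  rec_mixed$sample_id[1] <- "OTHER"
  expect_error(build_profile(rec_mixed, cfg$chip, cfg$calib, geo),
               "input error")
})
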