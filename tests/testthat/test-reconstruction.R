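test_that("per-beam relative errors split hemispheres and honor the floor", {
  geo <- study_geometry()
  pr <- fake_reading(geo, rep(100, geo$n_diodes))
  meas <- fake_reading(pr$geometry, pr$per_beam * 1.03,
                       kind = "simulated-measurement")
  se <- per_beam_relative_errors(meas, pr, 1, gantry_angle = 0)
  expect_true(all(se$retained))
  expect_equal(unname(se$errors), rep(0.03, geo$n_diodes), tolerance = 1e-12)
  # hemisphere split: gantry 0 enters from +y
  expect_equal(sum(se$hemisphere == "entry"), 33 * 21)
  expect_true(all(geo$positions[se$hemisphere == "entry", 2] > 0))
  # floor exclusion: diodes below 1% of the beam max are dropped, not NaN
  pb <- rep(100, geo$n_diodes)
  pb[1:50] <- 0.5
  pr2 <- fake_reading(geo, pb)
  se2 <- per_beam_relative_errors(fake_reading(geo, cbind(pb * 1.1)), pr2, 1,
                                  gantry_angle = 0)
  expect_equal(se2$n_excluded, 50L)
  expect_true(all(is.na(se2$errors[1:50])))
  expect_false(anyNA(se2$errors[se2$retained]))
})

test_that("smooth interpolation is exact at diodes, for constants and for linear fields", {
  geo <- study_geometry()
  pr <- fake_reading(geo, rep(100, geo$n_diodes))
  # constant error c
  mc <- fake_reading(geo, pr$per_beam * 1.02)
  efc <- smooth_interpolate(per_beam_relative_errors(mc, pr, 1, 0))
  set.seed(2)
  s_q <- runif(200, 0, 2 * pi * geo$radius)
  z_q <- runif(200, -100, 100)
  for (h in c("entry", "exit")) {
    expect_equal(evaluate_error_field(efc, s_q, z_q, h), rep(0.02, 200),
                 tolerance = 1e-9)
  }
  # error linear in z: reproduced at off-diode points
  zlin <- 0.01 + 2e-4 * geo$z
  ml <- fake_reading(geo, pr$per_beam * (1 + zlin))
  efl <- smooth_interpolate(per_beam_relative_errors(ml, pr, 1, 0))
  z_in <- runif(100, -90, 90)
  s_in <- runif(100, 0, 2 * pi * geo$radius)
  for (h in c("entry", "exit")) {
    expect_equal(evaluate_error_field(efl, s_in, z_in, h),
                 0.01 + 2e-4 * z_in, tolerance = 1e-9)
  }
  # exact interpolation at the diode positions themselves
  set.seed(3)
  noisy <- 0.02 * stats::rnorm(geo$n_diodes)
  mn <- fake_reading(geo, pr$per_beam * (1 + noisy))
  sn <- per_beam_relative_errors(mn, pr, 1, 0)
  efn <- smooth_interpolate(sn)
  for (h in c("entry", "exit")) {
    sel <- sn$hemisphere == h
    got <- evaluate_error_field(efn, geo$s[sel], geo$z[sel], h)
    expect_lt(max(abs(got - noisy[sel])), 1e-9)
  }
  # boundedness: no overshoot beyond the sparse value range
  vals <- evaluate_error_field(efn, s_q, z_q, "entry")
  expect_true(all(vals >= min(noisy) - 1e-12 & vals <= max(noisy) + 1e-12))
})

test_that("too few retained diodes is an explicit error", {
  geo <- study_geometry()
  pb <- rep(1e-6, geo$n_diodes)
  pb[geo$positions[, 2] > 0][1:3] <- 100  # 3 usable entry diodes
  pb[geo$positions[, 2] <= 0] <- 100      # exit side fine
  pr <- fake_reading(geo, pb)
  se <- per_beam_relative_errors(fake_reading(geo, cbind(pb)), pr, 1, 0)
  expect_error(smooth_interpolate(se), "fewer than 4")
})

test_that("back-projection satisfies identity, linearity and localization", {
  plan <- study_plans()[[3]]
  pr <- study_planned_readings()[[3]]
  em0 <- error_model(field_size_response = FALSE)
  m0 <- simulate_measurement(pr, plan, em0)
  p0 <- reconstruct_dose(plan, m0, pr)
  # zero errors reproduce the planned dose bit for bit
  expect_identical(p0$values, plan$total_dose$values)
  # uniform +3% in every field scales the whole dose
  m3 <- fake_reading(pr$geometry, pr$per_beam * 1.03,
                     kind = "simulated-measurement")
  p3 <- reconstruct_dose(plan, m3, pr)
  expect_equal(p3$values, 1.03 * plan$total_dose$values, tolerance = 1e-9)
  # error on beam 1 only: perturbed - planned = c x planned beam-1 dose
  mb <- pr
  mb$per_beam[, 1] <- pr$per_beam[, 1] * 1.05
  mb$composite <- rowSums(mb$per_beam)
  mb$kind <- "simulated-measurement"
  pb <- reconstruct_dose(plan, mb, pr)
  delta <- pb$values - plan$total_dose$values
  expected <- 0.05 * plan$normalization_factor * plan$per_beam_dose[[1]]
  expect_equal(delta, expected, tolerance = 1e-9)
  # localization: voxels with zero beam-1 dose are untouched, exactly
  expect_true(all(delta[plan$per_beam_dose[[1]] == 0] == 0))
})

test_that("injected global scales are recovered in isocenter and target mean dose", {
  plan <- study_plans()[[3]]
  pr <- study_planned_readings()[[3]]
  iso_p <- isocenter_dose(plan$total_dose)
  dm_p <- mean_dose(plan$total_dose, plan$rois$target)
  for (s in c(-0.04, -0.02, 0.02, 0.04)) {
    em <- error_model(global_scale = s, field_size_response = FALSE)
    m <- simulate_measurement(pr, plan, em)
    p <- reconstruct_dose(plan, m, pr)
    expect_lt(abs(dose_deviation_pct(predicted_isocenter(p), iso_p) -
                    100 * abs(s)), 0.1)
    expect_lt(abs(dose_deviation_pct(mean_dose(p, plan$rois$target), dm_p) -
                    100 * abs(s)), 0.1)
    # DVH consistency: every metric scales by (1 + s) within half a bin
    mp <- dvh_metrics(plan$total_dose, plan$rois$target, plan$prescription)
    mq <- dvh_metrics(p, plan$rois$target, plan$prescription)
    expect_lt(abs(mq$mean_cgy - (1 + s) * mp$mean_cgy), 0.5)
    expect_lt(abs(mq$d50_cgy - (1 + s) * mp$d50_cgy), 1)
    expect_lt(abs(mq$d95_cgy - (1 + s) * mp$d95_cgy), 1)
  }
})

test_that("field-size response alone under-doses these small-field plans", {
  # every plan's equivalent square is below the calibration zero crossing,
  # so the reconstructed dose must sit below the plan
  plan <- study_plans()[[5]]
  pr <- study_planned_readings()[[5]]
  em <- error_model(field_size_response = TRUE, noise_sd = 0)
  m <- simulate_measurement(pr, plan, em)
  p <- reconstruct_dose(plan, m, pr)
  expect_lt(predicted_isocenter(p), isocenter_dose(plan$total_dose))
  expect_lt(mean_dose(p, plan$rois$target),
            mean_dose(plan$total_dose, plan$rois$target))
})
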