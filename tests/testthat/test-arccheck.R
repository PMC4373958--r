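test_that("helical geometry satisfies the stated constraints", {
  geo <- study_geometry()
  expect_equal(geo$n_diodes, 1386L)
  expect_equal(geo$n_rows * geo$n_cols, 1386L)
  expect_equal(geo$angular_pitch_deg, 360 / 66)
  expect_lt(abs(geo$angular_pitch_deg * geo$n_cols - 360), 0.1)
  r <- sqrt(geo$positions[, 1]^2 + geo$positions[, 2]^2)
  expect_lt(max(abs(r - 105)), 1e-6)
  expect_lte(max(abs(geo$positions[, 3])), geo$cylinder_length / 2)
  # helix: same row, adjacent columns are axially staggered by pitch / n_cols
  z_row1 <- geo$z[geo$row == 1]
  expect_equal(unique(round(diff(z_row1), 9)), 10 / 66, tolerance = 1e-6)
  # unwrap/rewrap round trip
  back <- rewrap_lattice(geo, unwrap_lattice(geo))
  expect_lt(max(abs(back - geo$positions)), 1e-9)
  expect_error(build_geometry(n_diodes = 1000), "multiple")
  expect_error(build_geometry(detector_pitch_mm = 20), "inconsistent")
})

test_that("diode sampling is exact for linear fields and flags outside positions", {
  geo <- study_geometry()
  g <- make_grid(spacing_mm = c(4, 4, 4))
  lin <- linear_dose(g, a = 50, gx = 0.1, gy = -0.05, gz = 0.2)
  plan_stub <- list(grid = g, per_beam_dose = list(lin$values),
                    normalization_factor = 1)
  class(plan_stub) <- "qa_plan"
  rd <- sample_dose_at_diodes(plan_stub, geo)
  expected <- 50 + 0.1 * geo$positions[, 1] - 0.05 * geo$positions[, 2] +
    0.2 * geo$positions[, 3]
  expect_equal(rd$composite, expected, tolerance = 1e-9)
  expect_identical(rd$kind, "planned-reference")
  # zero dose -> all-zero reading
  plan_zero <- plan_stub
  plan_zero$per_beam_dose <- list(array(0, g$shape))
  expect_true(all(sample_dose_at_diodes(plan_zero, geo)$composite == 0))
  # diode outside the grid is an error naming the index
  tiny <- make_grid(c(100, 100, 100), c(4, 4, 4))
  plan_small <- list(grid = tiny, per_beam_dose = list(array(1, tiny$shape)),
                     normalization_factor = 1)
  class(plan_small) <- "qa_plan"
  expect_error(sample_dose_at_diodes(plan_small, geo), "outside")
})

test_that("equivalent square follows 2ab/(a+b)", {
  sq <- matrix(FALSE, 120, 120)
  sq[31:80, 31:80] <- TRUE  # 50 x 50 mm
  expect_equal(equivalent_square_side(fake_aperture(sq)), 5)
  rect <- matrix(FALSE, 120, 120)
  rect[41:80, 21:100] <- TRUE  # 40 x 80 mm
  expect_equal(equivalent_square_side(fake_aperture(rect)),
               2 * 4 * 8 / 12, tolerance = 1e-9)
  expect_error(equivalent_square_side(fake_aperture(matrix(FALSE, 4, 4))),
               "empty")
})

test_that("field-size response interpolates and extrapolates the calibration line", {
  expect_equal(100 * (field_size_response(5) - 1), -1.1)
  expect_equal(100 * (field_size_response(25) - 1), 1.3)
  expect_equal(100 * (field_size_response(15) - 1), 0.1, tolerance = 1e-9)
  # linear extrapolation with the end-segment slope (0.12 %/cm)
  expect_equal(100 * (field_size_response(2.5) - 1), -1.1 - 2.5 * 0.12,
               tolerance = 1e-9)
  expect_equal(100 * (field_size_response(30) - 1), 1.3 + 5 * 0.12,
               tolerance = 1e-9)
  expect_error(field_size_response(0), "positive")
  expect_error(field_size_response(5, data.frame(side_cm = c(25, 5),
                                                 response_pct = c(1, -1))),
               "increasing")
})

test_that("simulated measurements apply the stated error chain", {
  plans <- study_plans()
  readings <- study_planned_readings()
  plan <- plans[[3]]; pr <- readings[[3]]
  # all errors off: bitwise identical to the planned reference
  em0 <- error_model(field_size_response = FALSE)
  m0 <- simulate_measurement(pr, plan, em0)
  expect_identical(m0$per_beam, pr$per_beam)
  # global scale only: every reading is scaled exactly
  em4 <- error_model(global_scale = 0.04, field_size_response = FALSE)
  m4 <- simulate_measurement(pr, plan, em4)
  expect_equal(m4$per_beam, pr$per_beam * 1.04, tolerance = 1e-12)
  # composite / per-beam consistency after any error model
  emx <- error_model(global_scale = 0.02, noise_sd = 0.01, seed = 3)
  mx <- simulate_measurement(pr, plan, emx, replicate = 2)
  expect_identical(mx$composite, rowSums(mx$per_beam))
  # replicates differ but are reproducible
  mx2 <- simulate_measurement(pr, plan, emx, replicate = 2)
  expect_identical(mx$per_beam, mx2$per_beam)
  my <- simulate_measurement(pr, plan, emx, replicate = 3)
  expect_false(identical(mx$per_beam, my$per_beam))
  # a shift that pushes diodes off the grid is an error
  expect_error(simulate_measurement(pr, plan, error_model(
    shift_mm = c(200, 0, 0))), "outside")
})

test_that("reading noise has the configured magnitude across replicates", {
  plans <- study_plans(); readings <- study_planned_readings()
  plan <- plans[[3]]; pr <- readings[[3]]
  em <- error_model(field_size_response = FALSE, noise_sd = 0.01, seed = 42)
  reps <- lapply(1:3, function(r) simulate_measurement(pr, plan, em, r))
  b1 <- sapply(reps, function(m) m$per_beam[, 1])
  keep <- pr$per_beam[, 1] > 0.2 * max(pr$per_beam[, 1])
  rel_sd <- apply(b1[keep, ], 1, stats::sd) / pr$per_beam[keep, 1]
  # E[sample SD, n = 3] = sigma * c4(3) ~ 0.886 * sigma
  expect_gt(mean(rel_sd), 0.007)
  expect_lt(mean(rel_sd), 0.011)
})

test_that("field-size response drives a size-monotone composite error", {
  plans <- study_plans(); readings <- study_planned_readings()
  em <- error_model(field_size_response = TRUE, noise_sd = 0)
  mean_err <- vapply(seq_along(plans), function(i) {
    m <- simulate_measurement(readings[[i]], plans[[i]], em)
    keep <- readings[[i]]$composite > 0.05 * max(readings[[i]]$composite)
    mean(m$composite[keep] / readings[[i]]$composite[keep] - 1)
  }, numeric(1))
  # the mean relative composite error increases with target diameter
  expect_true(all(diff(mean_err) > 0))
  expect_true(all(mean_err < 0))  # all fields are below the calibration zero
})

test_that("delivered dose applies deterministic factors at the grid level", {
  plan <- study_plans()[[2]]
  expect_identical(delivered_dose(plan,
                                  error_model(field_size_response = FALSE))$values,
                   plan$total_dose$values)
  d4 <- delivered_dose(plan, error_model(global_scale = 0.04,
                                         field_size_response = FALSE))
  expect_equal(d4$values, 1.04 * plan$total_dose$values, tolerance = 1e-12)
})
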