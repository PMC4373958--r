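test_that("BEV apertures have the expected extents and clipping behavior", {
  g <- make_grid()
  tgt50 <- cylinder_mask(g, 50, 50)
  ap <- bev_aperture(tgt50, 0)
  hit <- which(ap$mask, arr.ind = TRUE)
  # 50 mm silhouette + 2 x 3 mm margin, within one pixel of discretization
  expect_lt(abs((diff(range(hit[, 1])) + 1) * ap$spacing - 56), 1.6)
  expect_lt(abs((diff(range(hit[, 2])) + 1) * ap$spacing - 56), 1.6)
  # margin 0: aperture equals the projected silhouette (a filled rectangle)
  ap0 <- bev_aperture(tgt50, 0, margin_mm = 0)
  hit0 <- which(ap0$mask, arr.ind = TRUE)
  expect_equal(sum(ap0$mask),
               (diff(range(hit0[, 1])) + 1) * (diff(range(hit0[, 2])) + 1))
  # 9 cm target: 96 mm aperture fits the 100 mm limit without clipping
  tgt90 <- cylinder_mask(g, 90, 50)
  expect_no_warning(ap9 <- bev_aperture(tgt90, 72))
  hit9 <- which(ap9$mask, arr.ind = TRUE)
  w9 <- (diff(range(hit9[, 1])) + 1) * ap9$spacing
  expect_lte(w9, 100)
  expect_lt(abs(w9 - 96), 1.6)
  # an oversized target is clipped with a warning
  big <- cylinder_mask(g, 120, 50)
  expect_warning(apb <- bev_aperture(big, 0), "clip")
  hitb <- which(apb$mask, arr.ind = TRUE)
  expect_lte((diff(range(hitb[, 1])) + 1) * apb$spacing, 100)
})

test_that("beam dose follows the closed-form depth model", {
  g <- make_grid(c(266, 266, 270), c(1, 1, 1))  # x/y centers at half-integers
  tgt <- cylinder_mask(g, 50, 50)
  ap <- bev_aperture(tgt, 0)
  model <- beam_model()
  d <- beam_dose(ap, 0, g, model)
  # two central-axis depths beyond d_max: dose ratio is attenuation times
  # inverse square, in closed form (fluence cancels)
  p1 <- c(0.5, 50.5, 0.5)   # depth 82
  p2 <- c(0.5, -49.5, 0.5)  # depth 182
  d1 <- 133 - p1[2]; d2 <- 133 - p2[2]
  expected <- exp(-model$mu * (d2 - d1)) *
    ((model$sad_mm + d1 - model$d_max_mm) /
       (model$sad_mm + d2 - model$d_max_mm))^2
  expect_equal(trilinear_sample(d, p2) / trilinear_sample(d, p1), expected,
               tolerance = 1e-4)
  # PDD peak: the central-axis dose at the buildup depth is the axis maximum
  axis_y <- seq(-100.5, 117.5, by = 1)
  vals <- trilinear_sample(d, cbind(0.5, axis_y, 0.5))
  expect_equal(max(vals), trilinear_sample(d, c(0.5, 133 - 15, 0.5)),
               tolerance = 2e-2)
  # Gaussian penumbra tail: >= 5 sigma outside the aperture shadow the dose
  # is below 0.1% of the same-depth central-axis dose
  lateral <- trilinear_sample(d, c(28 + 5 * model$sigma_mm + 2, 50.5, 0.5))
  expect_lt(lateral, 1e-3 * trilinear_sample(d, c(0.5, 50.5, 0.5)))
})

test_that("coverage normalization has the documented identities", {
  g <- make_grid(c(60, 60, 60), c(2, 2, 2))
  tgt <- cylinder_mask(g, 30, 30)
  u <- dose_grid(g, array(250, g$shape))
  expect_equal(normalize_to_coverage(u, tgt, 600), 600 / 250)
  # idempotence: renormalizing a normalized dose gives a factor of 1
  f <- normalize_to_coverage(u, tgt, 600)
  u2 <- dose_grid(g, u$values * f)
  expect_lt(abs(normalize_to_coverage(u2, tgt, 600) - 1), 1e-9)
  # linear-gradient dose: the factor is prescription over the 5th-percentile
  lin <- linear_dose(g, a = 100, gz = 1)
  vals <- sort(lin$values[tgt$voxels])
  expect_equal(normalize_to_coverage(lin, tgt, 600),
               600 / vals[ceiling(0.05 * length(vals))])
  expect_error(normalize_to_coverage(dose_grid(g, array(0, g$shape)), tgt,
                                     600), "degenerate")
})

test_that("isocenter dose interpolates exactly on uniform and linear fields", {
  g <- make_grid(c(60, 60, 60), c(2, 2, 2))
  expect_equal(isocenter_dose(dose_grid(g, array(42, g$shape))), 42)
  lin <- linear_dose(g, a = 7, gx = 0.5, gy = -0.25, gz = 1)
  expect_equal(isocenter_dose(lin), 7, tolerance = 1e-12)
})

test_that("plans satisfy additivity, coverage and rotational symmetry", {
  plans <- study_plans()
  for (plan in plans) {
    # dose additivity: total = normalization x sum of per-beam doses, exactly
    expect_identical(plan$total_dose$values,
                     plan$normalization_factor *
                       Reduce(`+`, plan$per_beam_dose))
    # D95(target) = prescription within half a DVH bin
    dvh <- cumulative_dvh(plan$total_dose, plan$rois$target)
    expect_lt(abs(dose_at_volume(dvh, 95) - plan$prescription), 0.5)
    # conformal plans run hot at the center
    expect_gt(isocenter_dose(plan$total_dose), plan$prescription)
  }
  # rotational consistency: per-beam doses are congruent under 72 deg
  # rotation about the cylinder axis
  plan <- plans[[3]]
  set.seed(11)
  n <- 50
  r <- sqrt(runif(n)) * 20
  th <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th), runif(n, -20, 20))
  ref <- trilinear_sample(dose_grid(plan$grid, plan$per_beam_dose[[1]]), pts)
  peak <- max(plan$per_beam_dose[[1]])
  for (b in 2:5) {
    a <- -(b - 1) * 72 * pi / 180  # gantry angles increase clockwise
    rot <- cbind(pts[, 1] * cos(a) - pts[, 2] * sin(a),
                 pts[, 1] * sin(a) + pts[, 2] * cos(a), pts[, 3])
    got <- trilinear_sample(dose_grid(plan$grid, plan$per_beam_dose[[b]]),
                            rot)
    expect_lt(max(abs(got - ref)), 0.02 * peak)
  }
})

test_that("single-beam plans and angle wrapping behave", {
  g <- make_grid(c(120, 120, 120), c(4, 4, 4))
  rois <- roi_set(g, 30, peripheral_spec = list(outer_diameter_mm = 110,
                                                thickness_mm = 10,
                                                length_mm = 50))
  p1 <- compose_plan(30, 400, g, beam_angles = 0, weights = 1, rois = rois)
  expect_identical(p1$total_dose$values,
                   p1$normalization_factor * p1$per_beam_dose[[1]])
  # gantry angles are wrapped modulo 360
  tgt <- rois$target
  ap <- bev_aperture(tgt, 72)
  expect_identical(beam_dose(ap, 72 + 360, g)$values,
                   beam_dose(ap, 72, g)$values)
  expect_error(compose_plan(30, 400, g, beam_angles = c(0, 72),
                            weights = c(0.9, 0.9), rois = rois), "sum to 1")
})
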