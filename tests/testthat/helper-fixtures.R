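# shared fixtures, built lazily once per test run

fixture_env <- new.env(parent = emptyenv())

study_diameters <- c(10, 30, 50, 70, 90)
study_prescriptions <- c(200, 400, 600, 800, 1000)

# the five study plans on the 2 mm grid (the fast profile used throughout the
# suite); identical to build_experiment_plans() at spacing 2
study_plans <- function() {
  if (is.null(fixture_env$plans)) {
    grid <- make_grid(spacing_mm = c(2, 2, 2))
    fixture_env$plans <- lapply(seq_along(study_diameters), function(i) {
      rois <- roi_set(grid, study_diameters[i])
      compose_plan(study_diameters[i], study_prescriptions[i], grid,
                   rois = rois)
    })
  }
  fixture_env$plans
}

study_geometry <- function() {
  if (is.null(fixture_env$geometry)) fixture_env$geometry <- build_geometry()
  fixture_env$geometry
}

study_planned_readings <- function() {
  if (is.null(fixture_env$readings)) {
    fixture_env$readings <- lapply(study_plans(), sample_dose_at_diodes,
                                   geometry = study_geometry())
  }
  fixture_env$readings
}

# smooth positive random field: iterated neighbor-averaging of white noise,
# rescaled to [lo, hi] cGy
smooth_random_field <- function(grid, seed, passes = 8, lo = 20, hi = 120) {
  set.seed(seed)
  a <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  n <- dim(a)
  for (i in seq_len(passes)) {
    a <- (a + a[c(1, 1:(n[1] - 1)), , ] + a[c(2:n[1], n[1]), , ]) / 3
    a <- (a + a[, c(1, 1:(n[2] - 1)), ] + a[, c(2:n[2], n[2]), ]) / 3
    a <- (a + a[, , c(1, 1:(n[3] - 1))] + a[, , c(2:n[3], n[3])]) / 3
  }
  dose_grid(grid, lo + (hi - lo) * (a - min(a)) / diff(range(a)))
}

# dose field linear in the physical coordinates
linear_dose <- function(grid, a = 0, gx = 0, gy = 0, gz = 0) {
  co <- virtualqa:::grid_coords(grid)
  dose_grid(grid, a + gx * co$x + gy * co$y + gz * co$z)
}

# ROI covering the whole grid
full_roi <- function(grid, name = "all") {
  structure(list(name = name, grid = grid,
                 voxels = array(TRUE, grid$shape)), class = "qa_roi")
}

# minimal synthetic reading (constant or supplied per-beam matrix)
fake_reading <- function(geometry, per_beam,
                         kind = "planned-reference") {
  if (is.null(dim(per_beam))) per_beam <- matrix(per_beam, geometry$n_diodes)
  structure(list(geometry = geometry, per_beam = per_beam,
                 composite = rowSums(per_beam), kind = kind),
            class = "qa_reading")
}

# aperture object from an explicit BEV mask (for equivalent-square tests)
fake_aperture <- function(mask, spacing = 1) {
  n <- nrow(mask)
  centers <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
  structure(list(u = centers, v = centers, spacing = spacing, mask = mask,
                 gantry_angle = 0), class = "qa_aperture")
}

voxel_positions <- function(grid, index) {
  arr <- arrayInd(index, grid$shape)
  cbind(grid$origin[1] + (arr[, 1] - 0.5) * grid$spacing[1],
        grid$origin[2] + (arr[, 2] - 0.5) * grid$spacing[2],
        grid$origin[3] + (arr[, 3] - 0.5) * grid$spacing[3])
}
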