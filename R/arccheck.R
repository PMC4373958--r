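#' Helical diode-array geometry
#'
#' Builds a single staggered helical lattice of diodes on a cylinder: `n_cols`
#' angular columns times `n_rows` axial rows (defaults 66 x 21 = 1,386
#' diodes), detector pitch 10 mm both along the helix arc and axially, on a
#' cylinder of 21 cm diameter and length. Consecutive columns are offset
#' axially by `pitch / n_cols` so that following the angle the lattice forms a
#' continuous helix advancing one pitch per revolution.
#'
#' Diodes are ordered column-major: index `= (col - 1) * n_rows + row`. The
#' lattice unwraps to the `(s, z)` plane where `s` is the arc length along the
#' cylinder circumference.
#'
#' @param n_diodes total diode count (default 1386).
#' @param cylinder_diameter_mm detector cylinder diameter (default 210).
#' @param cylinder_length_mm detector cylinder length (default 210).
#' @param detector_pitch_mm arc and axial pitch (default 10).
#' @param n_rows axial rows (default 21).
#' @return an object of class `qa_diode_geometry` with positions and lattice
#'   indices.
#' @export
build_geometry <- function(n_diodes = 1386, cylinder_diameter_mm = 210,
                           cylinder_length_mm = 210, detector_pitch_mm = 10,
                           n_rows = 21) {
  n_cols <- n_diodes / n_rows
  if (n_cols != round(n_cols)) {
    stop("invalid configuration: n_diodes must be a multiple of n_rows",
         call. = FALSE)
  }
  n_cols <- as.integer(n_cols)
  radius <- cylinder_diameter_mm / 2
  arc_pitch <- 2 * pi * radius / n_cols
  if (abs(arc_pitch - detector_pitch_mm) > 0.5) {
    stop("invalid configuration: circumference / n_cols (", round(arc_pitch, 3),
         " mm) is inconsistent with the detector pitch", call. = FALSE)
  }
  if ((n_rows - 1) * detector_pitch_mm + detector_pitch_mm >
      cylinder_length_mm + 1e-9) {
    stop("invalid configuration: rows do not fit the cylinder length",
         call. = FALSE)
  }
  col <- rep(seq_len(n_cols), each = n_rows)       # 1-based
  row <- rep(seq_len(n_rows), times = n_cols)
  angular_pitch <- 360 / n_cols
  angle_deg <- (col - 1) * angular_pitch
  phi <- angle_deg * pi / 180
  z <- (row - 1 - (n_rows - 1) / 2) * detector_pitch_mm +
    ((col - 0.5) / n_cols - 0.5) * detector_pitch_mm
  positions <- cbind(x = radius * sin(phi), y = radius * cos(phi), z = z)
  structure(list(n_diodes = as.integer(n_diodes), n_rows = as.integer(n_rows),
                 n_cols = n_cols, radius = radius,
                 cylinder_length = cylinder_length_mm,
                 pitch = detector_pitch_mm, arc_pitch = arc_pitch,
                 angular_pitch_deg = angular_pitch,
                 positions = positions, row = row, col = col,
                 angle_deg = angle_deg, s = radius * phi, z = z),
            class = "qa_diode_geometry")
}

#' @export
print.qa_diode_geometry <- function(x, ...) {
  cat(sprintf("<qa_diode_geometry> %d diodes (%d cols x %d rows), R = %g mm, angular pitch %.2f deg\n",
              x$n_diodes, x$n_cols, x$n_rows, x$radius, x$angular_pitch_deg))
  invisible(x)
}

#' Unwrap diode positions to the (s, z) plane
#'
#' @param geometry a `qa_diode_geometry`.
#' @return matrix with columns `s` (arc length, mm) and `z` (mm).
#' @export
unwrap_lattice <- function(geometry) {
  cbind(s = geometry$s, z = geometry$z)
}

#' Map unwrapped (s, z) coordinates back to 3D cylinder positions
#'
#' @param geometry a `qa_diode_geometry`.
#' @param sz matrix with columns `s`, `z`.
#' @return n x 3 matrix of positions.
#' @export
rewrap_lattice <- function(geometry, sz) {
  phi <- sz[, 1] / geometry$radius
  cbind(x = geometry$radius * sin(phi), y = geometry$radius * cos(phi),
        z = sz[, 2])
}

#' Sample a plan's per-beam doses at the diode positions
#'
#' Trilinear interpolation of each per-beam dose at each diode position,
#' scaled by the plan normalization factor so readings are in absolute cGy;
#' the composite is the per-beam sum.
#'
#' @param plan a `qa_plan`.
#' @param geometry a `qa_diode_geometry`.
#' @return an object of class `qa_reading` with `per_beam` (n_diodes x
#'   n_beams), `composite`, and `kind = "planned-reference"`.
#' @export
sample_dose_at_diodes <- function(plan, geometry) {
  check_positions_inside(geometry$positions, plan$grid)
  nb <- length(plan$per_beam_dose)
  per_beam <- matrix(0, nrow = geometry$n_diodes, ncol = nb)
  for (b in seq_len(nb)) {
    per_beam[, b] <- plan$normalization_factor *
      trilinear_sample(dose_grid(plan$grid, plan$per_beam_dose[[b]]),
                       geometry$positions)
  }
  structure(list(geometry = geometry, per_beam = per_beam,
                 composite = rowSums(per_beam), kind = "planned-reference"),
            class = "qa_reading")
}

check_positions_inside <- function(positions, grid) {
  b <- grid_bounds(grid)
  out <- which(positions[, 1] < b$lower[1] | positions[, 1] > b$upper[1] |
                 positions[, 2] < b$lower[2] | positions[, 2] > b$upper[2] |
                 positions[, 3] < b$lower[3] | positions[, 3] > b$upper[3])
  if (length(out)) {
    stop("diode position(s) outside the dose grid: index ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Equivalent square side of an aperture
#'
#' Standard equivalent-square rule `side = 2ab / (a + b)` applied to the
#' aperture bounding-box side lengths.
#'
#' @param aperture a `qa_aperture`.
#' @return side in cm.
#' @export
equivalent_square_side <- function(aperture) {
  hit <- which(aperture$mask, arr.ind = TRUE)
  if (nrow(hit) == 0) stop("empty aperture", call. = FALSE)
  a <- (diff(range(hit[, 1])) + 1) * aperture$spacing
  b <- (diff(range(hit[, 2])) + 1) * aperture$spacing
  2 * a * b / (a + b) / 10
}

#' Field-size-dependent diode response
#'
#' Piecewise-linear interpolation of the relative diode response through the
#' calibration points, linearly extrapolated outside them with the end-segment
#' slopes. The default calibration runs through -1.1% at a 5 cm equivalent
#' square and +1.3% at 25 cm.
#'
#' @param side_cm equivalent square side(s) in cm.
#' @param calibration data frame with columns `side_cm` (strictly increasing)
#'   and `response_pct`.
#' @return multiplicative response factor(s) `1 + error`.
#' @export
field_size_response <- function(side_cm,
                                calibration = data.frame(
                                  side_cm = c(5, 25),
                                  response_pct = c(-1.1, 1.3))) {
  if (any(side_cm <= 0)) stop("field side must be positive", call. = FALSE)
  xs <- calibration$side_cm
  ys <- calibration$response_pct
  if (is.unsorted(xs, strictly = TRUE)) {
    stop("calibration points must be strictly increasing in field size",
         call. = FALSE)
  }
  resp <- stats::approx(xs, ys, xout = pmin(pmax(side_cm, xs[1]),
                                            xs[length(xs)]))$y
  lo <- side_cm < xs[1]
  hi <- side_cm > xs[length(xs)]
  if (any(lo)) {
    slope <- (ys[2] - ys[1]) / (xs[2] - xs[1])
    resp[lo] <- ys[1] + slope * (side_cm[lo] - xs[1])
  }
  if (any(hi)) {
    n <- length(xs)
    slope <- (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1])
    resp[hi] <- ys[n] + slope * (side_cm[hi] - xs[n])
  }
  1 + resp / 100
}

#' Measurement error model
#'
#' Controls the synthetic measurement: a global calibration scale, the
#' field-size-dependent diode response, a rigid setup shift (the detector is
#' displaced by `shift_mm`, so readings re-sample the planned dose at
#' `position - shift`), and zero-mean multiplicative Gaussian reading noise.
#'
#' @param global_scale fractional calibration error (e.g. 0.04 for +4%).
#' @param field_size_response logical, apply the per-beam field-size response.
#' @param fs_calibration calibration points for [field_size_response()].
#' @param shift_mm rigid translation triple, mm.
#' @param noise_sd fractional reading-noise standard deviation (>= 0).
#' @param seed integer RNG seed; replicate `r` of a measurement uses
#'   `seed + r`.
#' @return an object of class `qa_error_model`.
#' @export
error_model <- function(global_scale = 0, field_size_response = TRUE,
                        fs_calibration = data.frame(side_cm = c(5, 25),
                                                    response_pct = c(-1.1, 1.3)),
                        shift_mm = c(0, 0, 0), noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(global_scale = global_scale,
                 field_size_response = isTRUE(field_size_response),
                 fs_calibration = fs_calibration,
                 shift_mm = rep_len(as.numeric(shift_mm), 3L),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "qa_error_model")
}

# per-beam deterministic error factors: global scale x field-size response
beam_error_factors <- function(plan, em) {
  fs <- if (em$field_size_response) {
    vapply(plan$beams,
           function(b) field_size_response(b$eq_square_cm, em$fs_calibration),
           numeric(1))
  } else rep(1, length(plan$beams))
  (1 + em$global_scale) * fs
}

#' Simulate a diode measurement of a plan
#'
#' For each beam `b` and diode `i`:
#' `reading = planned(position - shift) * (1 + global_scale) *
#' field_size_response(equivalent square of beam b) * (1 + eps)`, with
#' `eps ~ N(0, noise_sd)` independent per diode, beam and replicate. The
#' composite is re-summed from the per-beam readings. Deterministic given
#' `em$seed` and `replicate`; with the error model entirely off the result is
#' identical to the planned reference (same sampling path).
#'
#' @param planned the planned-reference `qa_reading` from
#'   [sample_dose_at_diodes()].
#' @param plan the `qa_plan` the reference was sampled from.
#' @param em a `qa_error_model`.
#' @param replicate replicate number (>= 1); the RNG stream uses
#'   `em$seed + replicate`.
#' @return a `qa_reading` with `kind = "simulated-measurement"`.
#' @export
simulate_measurement <- function(planned, plan, em, replicate = 1L) {
  if (!identical(planned$kind, "planned-reference")) {
    stop("planned must be a planned-reference reading", call. = FALSE)
  }
  geometry <- planned$geometry
  nb <- length(plan$per_beam_dose)
  shifted <- any(em$shift_mm != 0)
  if (shifted) {
    pos <- sweep(geometry$positions, 2, em$shift_mm)
    check_positions_inside(pos, plan$grid)
    per_beam <- matrix(0, geometry$n_diodes, nb)
    for (b in seq_len(nb)) {
      per_beam[, b] <- plan$normalization_factor *
        trilinear_sample(dose_grid(plan$grid, plan$per_beam_dose[[b]]), pos)
    }
  } else {
    per_beam <- planned$per_beam
  }
  fac <- beam_error_factors(plan, em)
  per_beam <- sweep(per_beam, 2, fac, `*`)
  if (em$noise_sd > 0) {
    eps <- with_seed(em$seed + as.integer(replicate), {
      matrix(stats::rnorm(length(per_beam), sd = em$noise_sd),
             nrow = nrow(per_beam))
    })
    per_beam <- per_beam * (1 + eps)
  }
  structure(list(geometry = geometry, per_beam = per_beam,
                 composite = rowSums(per_beam),
                 kind = "simulated-measurement", replicate = replicate),
            class = "qa_reading")
}

# evaluate an expression under a fixed seed, restoring the RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Ground-truth delivered 3D dose under an error model
#'
#' The deterministic part of the error model applied at the dose-grid level:
#' each per-beam dose is rigidly shifted (re-sampled at `position - shift`)
#' and scaled by its global and field-size factors; the total is the
#' normalized sum. This is the dose a point detector (ion-chamber analog)
#' would sample.
#'
#' @param plan a `qa_plan`.
#' @param em a `qa_error_model`.
#' @return a `qa_dose`.
#' @export
delivered_dose <- function(plan, em) {
  fac <- beam_error_factors(plan, em)
  nb <- length(plan$per_beam_dose)
  shifted <- any(em$shift_mm != 0)
  per_beam <- vector("list", nb)
  if (shifted) {
    co <- grid_coords(plan$grid)
    pts <- cbind(co$x - em$shift_mm[1], co$y - em$shift_mm[2],
                 co$z - em$shift_mm[3])
  }
  for (b in seq_len(nb)) {
    vals <- if (shifted) {
      array(trilinear_sample(dose_grid(plan$grid, plan$per_beam_dose[[b]]),
                             pts), plan$grid$shape)
    } else plan$per_beam_dose[[b]]
    per_beam[[b]] <- vals * fac[b]
  }
  dose_grid(plan$grid, plan$normalization_factor * Reduce(`+`, per_beam))
}
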