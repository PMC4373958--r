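#' Per-beam relative diode errors
#'
#' For one beam, computes `measured / planned - 1` at every diode whose
#' planned per-beam dose exceeds an exclusion floor (default 1% of the beam's
#' maximum planned diode dose; ratios below it are unstable). Diodes are
#' partitioned into the beam's entry hemisphere (facing the source, i.e. the
#' dot product of the diode position with the beam direction is negative) and
#' exit hemisphere.
#'
#' @param measured simulated-measurement `qa_reading`.
#' @param planned planned-reference `qa_reading` on the same geometry.
#' @param beam beam index (column of the readings).
#' @param gantry_angle the beam's gantry angle in degrees.
#' @param floor_frac exclusion floor as a fraction of the beam's maximum
#'   planned diode dose.
#' @return an object of class `qa_sparse_errors`: per-diode `errors` (NA where
#'   excluded), logical `retained`, `hemisphere` (`"entry"`/`"exit"`), and the
#'   number of excluded diodes.
#' @export
per_beam_relative_errors <- function(measured, planned, beam, gantry_angle,
                                     floor_frac = 0.01) {
  geometry <- planned$geometry
  if (!identical(dim(measured$per_beam), dim(planned$per_beam))) {
    stop("readings do not share a geometry/beam layout", call. = FALSE)
  }
  pb <- planned$per_beam[, beam]
  floor <- floor_frac * max(pb)
  retained <- pb > floor
  errors <- rep(NA_real_, length(pb))
  errors[retained] <- measured$per_beam[retained, beam] / pb[retained] - 1
  ax <- beam_axes(gantry_angle)
  dot <- geometry$positions[, 1] * ax$d[1] + geometry$positions[, 2] * ax$d[2]
  hemisphere <- ifelse(dot < 0, "entry", "exit")
  structure(list(beam = beam, gantry_angle = gantry_angle %% 360,
                 errors = errors, retained = retained,
                 hemisphere = hemisphere, n_excluded = sum(!retained),
                 geometry = geometry),
            class = "qa_sparse_errors")
}

# contiguous arc of lattice columns (0-based) belonging to one hemisphere
hemisphere_columns <- function(geometry, gantry_angle, hemisphere) {
  ax <- beam_axes(gantry_angle)
  phi <- (seq_len(geometry$n_cols) - 1) * geometry$angular_pitch_deg * pi / 180
  dot <- sin(phi) * ax$d[1] + cos(phi) * ax$d[2]
  flags <- if (hemisphere == "entry") dot < 0 else dot >= 0
  n <- geometry$n_cols
  starts <- which(flags & !flags[c(n, seq_len(n - 1))])
  if (length(starts) != 1) {
    stop("hemisphere columns are not a contiguous arc", call. = FALSE)
  }
  m <- sum(flags)
  c0 <- starts - 1L  # 0-based
  if (!all(flags[(c0 + seq_len(m) - 1L) %% n + 1L])) {
    stop("hemisphere columns are not a contiguous arc", call. = FALSE)
  }
  list(c0 = c0, m = m)
}

# Build one hemisphere's interpolation table on the sheared helix lattice.
# In sheared coordinates (alpha = s / arc_pitch, rho = (z - stagger(alpha)) /
# pitch + (n_rows - 1)/2) the staggered helix is a perfect rectangular integer
# lattice, so bilinear interpolation there is exact at the diodes, bounded by
# the sparse values, and exact for fields linear in (s, z). Cells without a
# retained value (excluded diodes, helix wrap edge) inherit the nearest
# retained value before interpolation.
build_hemisphere_field <- function(sparse, hemisphere) {
  geometry <- sparse$geometry
  arc <- hemisphere_columns(geometry, sparse$gantry_angle, hemisphere)
  n_rows <- geometry$n_rows
  n_cols <- geometry$n_cols
  # virtual rows run from -1 to n_rows - 1 so that every actual diode of a
  # helix-wrapped column (axially shifted by one pitch) still has a slot
  E <- matrix(NA_real_, arc$m, n_rows + 1L)
  usable <- sparse$retained & sparse$hemisphere == hemisphere
  if (sum(usable) < 4) {
    stop("fewer than 4 retained diodes in the ", hemisphere,
         " hemisphere; consider a larger exclusion floor or another beam",
         call. = FALSE)
  }
  for (j in seq_len(arc$m)) {
    cu <- arc$c0 + j - 1L          # unwrapped 0-based column
    cc <- cu %% n_cols             # actual column
    w <- cu %/% n_cols             # helix wrap count (0 or 1)
    for (t in seq_len(n_rows + 1L)) {  # matrix slot; virtual row rv = t - 2
      ra <- t - 1L + w             # actual row (1-based)
      if (ra >= 1L && ra <= n_rows) {
        i <- cc * n_rows + ra      # diode index, column-major
        if (usable[i]) E[j, t] <- sparse$errors[i]
      }
    }
  }
  # nearest-retained fill in the sheared metric (alpha in arc-pitch units,
  # rho in pitch units; both scaled to mm)
  if (anyNA(E)) {
    filled <- which(!is.na(E), arr.ind = TRUE)
    holes <- which(is.na(E), arr.ind = TRUE)
    fx <- filled[, 1] * geometry$arc_pitch
    fy <- filled[, 2] * geometry$pitch
    for (h in seq_len(nrow(holes))) {
      dx <- fx - holes[h, 1] * geometry$arc_pitch
      dy <- fy - holes[h, 2] * geometry$pitch
      k <- which.min(dx^2 + dy^2)
      E[holes[h, 1], holes[h, 2]] <- E[filled[k, 1], filled[k, 2]]
    }
  }
  list(E = E, c0 = arc$c0, m = arc$m, geometry = geometry)
}

# evaluate a hemisphere field at unwrapped surface points (vectorized)
eval_hemisphere_field <- function(field, s, z) {
  geo <- field$geometry
  a <- s / geo$arc_pitch
  a_rel <- (a - field$c0) %% geo$n_cols
  past_end <- a_rel > field$m - 1
  if (any(past_end)) {
    to_end <- a_rel - (field$m - 1)
    to_start <- geo$n_cols - a_rel
    a_rel[past_end] <- ifelse(to_end[past_end] <= to_start[past_end],
                              field$m - 1, 0)
  }
  a_abs <- field$c0 + a_rel
  stagger <- ((a_abs + 0.5) / geo$n_cols - 0.5) * geo$pitch
  rho <- (z - stagger) / geo$pitch + (geo$n_rows - 1) / 2
  rho <- pmin(pmax(rho, -1), geo$n_rows - 1)
  bilinear_matrix(field$E, 0, -1, 1, a_rel, rho)
}

#' Smooth error surface from sparse diode errors
#'
#' Interpolates a beam's sparse relative errors into a continuous function
#' over the unwrapped detector cylinder surface, separately for the entry and
#' exit hemispheres. Interpolation is piecewise bilinear on the sheared helix
#' lattice (exact at retained diodes, bounded by the sparse value range, exact
#' for fields linear in the surface coordinates), with periodic angular wrap
#' and nearest-value extrapolation outside the lattice span.
#'
#' @param sparse a `qa_sparse_errors` from [per_beam_relative_errors()].
#' @return an object of class `qa_error_field` evaluable with
#'   [evaluate_error_field()].
#' @export
smooth_interpolate <- function(sparse) {
  structure(list(entry = build_hemisphere_field(sparse, "entry"),
                 exit = build_hemisphere_field(sparse, "exit"),
                 gantry_angle = sparse$gantry_angle, beam = sparse$beam,
                 geometry = sparse$geometry),
            class = "qa_error_field")
}

#' Evaluate a smooth error field on the cylinder surface
#'
#' @param ef a `qa_error_field`.
#' @param s arc-length coordinate(s), mm.
#' @param z axial coordinate(s), mm.
#' @param hemisphere `"entry"` or `"exit"`.
#' @return interpolated relative error(s).
#' @export
evaluate_error_field <- function(ef, s, z, hemisphere = "entry") {
  eval_hemisphere_field(ef[[match.arg(hemisphere, c("entry", "exit"))]], s, z)
}

#' Back-project per-beam errors into the planned dose
#'
#' The open analog of a planned-dose-perturbation workflow: for every voxel
#' `v` and beam `b`, the ray through `v` along the beam direction pierces the
#' detector cylinder at an entry and an exit point; the voxel's relative error
#' is the depth-weighted blend `e_b(v) = (1 - w) * entry error + w * exit
#' error`, with `w` the fractional depth of `v` along the entry-to-exit
#' chord. Each per-beam dose is scaled by `1 + e_b(v)` and the perturbed total
#' re-assembled with the plan's normalization. Voxels outside the detector
#' cylinder take the error at the nearest surface point (its hemisphere
#' decides entry vs exit).
#'
#' With all sparse errors zero the perturbed dose reproduces the planned dose
#' bit for bit.
#'
#' @param plan a `qa_plan`.
#' @param error_fields list of `qa_error_field`, one per beam.
#' @return a `qa_dose` with attribute `provenance`.
#' @export
perturb_plan <- function(plan, error_fields) {
  nb <- length(plan$per_beam_dose)
  if (length(error_fields) != nb) {
    stop("need one error field per beam", call. = FALSE)
  }
  geo <- error_fields[[1]]$geometry
  R <- geo$radius
  co <- grid_coords(plan$grid)
  perturbed <- vector("list", nb)
  for (b in seq_len(nb)) {
    ef <- error_fields[[b]]
    ax <- beam_axes(ef$gantry_angle)
    pb <- plan$per_beam_dose[[b]]
    # the fluence has compact support, so only voxels with nonzero beam dose
    # can change; zeros stay exact zeros
    nz <- which(pb != 0)
    x <- co$x[nz]; y <- co$y[nz]; z <- co$z[nz]
    r2 <- x^2 + y^2
    inside <- r2 < R^2
    e <- numeric(length(nz))
    # chord through the detector cylinder (beams are axial: z constant)
    vd <- x[inside] * ax$d[1] + y[inside] * ax$d[2]
    sq <- sqrt(pmax(vd^2 - (r2[inside] - R^2), 0))
    te <- -vd - sq
    tx <- -vd + sq
    phi_e <- atan2(x[inside] + te * ax$d[1], y[inside] + te * ax$d[2])
    phi_x <- atan2(x[inside] + tx * ax$d[1], y[inside] + tx * ax$d[2])
    s_e <- R * (phi_e %% (2 * pi))
    s_x <- R * (phi_x %% (2 * pi))
    w <- -te / (tx - te)
    e_in <- eval_hemisphere_field(ef$entry, s_e, z[inside])
    e_out <- eval_hemisphere_field(ef$exit, s_x, z[inside])
    e[inside] <- (1 - w) * e_in + w * e_out
    if (any(!inside)) {
      # nearest surface point for voxels outside the detector cylinder
      phi_n <- atan2(x[!inside], y[!inside])
      s_n <- R * (phi_n %% (2 * pi))
      dot_n <- x[!inside] * ax$d[1] + y[!inside] * ax$d[2]
      en <- numeric(sum(!inside))
      is_entry <- dot_n < 0
      if (any(is_entry)) {
        en[is_entry] <- eval_hemisphere_field(ef$entry, s_n[is_entry],
                                              z[!inside][is_entry])
      }
      if (any(!is_entry)) {
        en[!is_entry] <- eval_hemisphere_field(ef$exit, s_n[!is_entry],
                                               z[!inside][!is_entry])
      }
      e[!inside] <- en
    }
    pb[nz] <- pb[nz] * (1 + e)
    perturbed[[b]] <- pb
  }
  out <- dose_grid(plan$grid,
                   plan$normalization_factor * Reduce(`+`, perturbed))
  attr(out, "provenance") <- list(target_diameter = plan$target_diameter,
                                  prescription = plan$prescription)
  out
}

#' Predicted dose at the isocenter of a perturbed dose
#'
#' @param perturbed a `qa_dose` from [perturb_plan()].
#' @return dose in cGy.
#' @export
predicted_isocenter <- function(perturbed) {
  isocenter_dose(perturbed)
}

#' Full reconstruction: measured reading to perturbed 3D dose
#'
#' Convenience wrapper running [per_beam_relative_errors()],
#' [smooth_interpolate()] and [perturb_plan()] over all beams.
#'
#' @param plan a `qa_plan`.
#' @param measured simulated-measurement `qa_reading`.
#' @param planned planned-reference `qa_reading`.
#' @param floor_frac exclusion floor fraction (see
#'   [per_beam_relative_errors()]).
#' @return the perturbed `qa_dose`.
#' @export
reconstruct_dose <- function(plan, measured, planned, floor_frac = 0.01) {
  fields <- lapply(seq_along(plan$beams), function(b) {
    smooth_interpolate(per_beam_relative_errors(
      measured, planned, b, plan$beams[[b]]$gantry_angle, floor_frac))
  })
  perturb_plan(plan, fields)
}
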