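#' Closed-form beam model parameters
#'
#' The planner replaces a commissioned pencil-beam engine with a smooth
#' closed-form model: `dose(voxel) = fluence(u, v) * PDD(depth) *
#' (SAD / (SAD + depth - d_max))^2`, where the fluence is the beam aperture
#' convolved with a 2D Gaussian of standard deviation `sigma_mm` (penumbra),
#' and the percentage depth dose rises linearly from 0.5 at the phantom entry
#' surface to 1.0 at `d_max_mm`, then decays as `exp(-mu * (depth - d_max))`.
#'
#' @param mu effective linear attenuation coefficient, 1/mm.
#' @param sigma_mm penumbra Gaussian sigma, mm.
#' @param d_max_mm buildup depth, mm.
#' @param sad_mm source-axis distance, mm.
#' @return a list of model parameters.
#' @export
beam_model <- function(mu = 0.005, sigma_mm = 3, d_max_mm = 15, sad_mm = 1000) {
  stopifnot(mu > 0, sigma_mm > 0, d_max_mm > 0, sad_mm > 0)
  list(mu = mu, sigma_mm = sigma_mm, d_max_mm = d_max_mm, sad_mm = sad_mm)
}

# unit beam direction (travel) and in-plane BEV axis for a gantry angle.
# Gantry 0 has the source on +y, beam travelling along -y; angles increase
# clockwise when viewed from +z. Angles outside [0, 360) are wrapped.
beam_axes <- function(gantry_angle) {
  th <- (gantry_angle %% 360) * pi / 180
  list(d = c(-sin(th), -cos(th), 0),   # direction of travel
       u = c(cos(th), -sin(th), 0),    # BEV in-plane axis
       theta = th)
}

#' Beam's-eye-view aperture from a target mask
#'
#' Parallel (non-divergent) projection of the target voxel centers onto the
#' BEV plane at the isocenter, dilated isotropically by the MLC margin and
#' clipped to the field-size limit (with a warning when clipping occurs).
#'
#' @param target a `qa_roi`.
#' @param gantry_angle gantry angle in degrees.
#' @param margin_mm isotropic MLC margin (default 3 mm).
#' @param field_limit_mm maximal field side (default 100 mm, a 10 x 10 cm
#'   field).
#' @param spacing_mm BEV pixel spacing (default 1 mm).
#' @return an object of class `qa_aperture`: boolean matrix `mask` on BEV
#'   pixel centers `u`, `v`.
#' @export
bev_aperture <- function(target, gantry_angle, margin_mm = 3,
                         field_limit_mm = 100, spacing_mm = 1) {
  idx <- which(target$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("target mask is empty", call. = FALSE)
  g <- target$grid
  px <- g$origin[1] + (idx[, 1] - 0.5) * g$spacing[1]
  py <- g$origin[2] + (idx[, 2] - 0.5) * g$spacing[2]
  pz <- g$origin[3] + (idx[, 3] - 0.5) * g$spacing[3]
  ax <- beam_axes(gantry_angle)
  u <- px * ax$u[1] + py * ax$u[2]
  v <- pz
  half <- field_limit_mm / 2 + margin_mm + 12  # pad for penumbra tails
  ncell <- ceiling(2 * half / spacing_mm)
  centers <- (seq_len(ncell) - 0.5) * spacing_mm - ncell * spacing_mm / 2
  bin <- function(w) pmin(pmax(floor((w + ncell * spacing_mm / 2) /
                                       spacing_mm) + 1, 1), ncell)
  mask <- matrix(FALSE, ncell, ncell)
  mask[cbind(bin(u), bin(v))] <- TRUE
  if (margin_mm > 0) {
    r <- ceiling(margin_mm / spacing_mm)
    off <- expand.grid(di = -r:r, dj = -r:r)
    off <- off[(off$di^2 + off$dj^2) * spacing_mm^2 <= margin_mm^2 + 1e-9, ]
    hit <- which(mask, arr.ind = TRUE)
    dil <- matrix(FALSE, ncell, ncell)
    for (t in seq_len(nrow(off))) {
      i <- hit[, 1] + off$di[t]
      j <- hit[, 2] + off$dj[t]
      ok <- i >= 1 & i <= ncell & j >= 1 & j <= ncell
      dil[cbind(i[ok], j[ok])] <- TRUE
    }
    mask <- dil
  }
  outside <- abs(centers) > field_limit_mm / 2
  if (any(mask[outside, ]) || any(mask[, outside])) {
    warning("aperture exceeds the field-size limit; clipping to ",
            field_limit_mm, " mm", call. = FALSE)
    mask[outside, ] <- FALSE
    mask[, outside] <- FALSE
  }
  structure(list(u = centers, v = centers, spacing = spacing_mm, mask = mask,
                 gantry_angle = gantry_angle %% 360,
                 margin_mm = margin_mm, field_limit_mm = field_limit_mm),
            class = "qa_aperture")
}

# 1D convolution along the first dimension with zero padding
conv1 <- function(m, k) {
  hw <- (length(k) - 1L) / 2L
  nr <- nrow(m)
  pad <- rbind(matrix(0, hw, ncol(m)), m, matrix(0, hw, ncol(m)))
  out <- matrix(0, nr, ncol(m))
  for (t in seq_along(k)) out <- out + k[t] * pad[(t - 1L) + seq_len(nr), ,
                                                  drop = FALSE]
  out
}

# aperture fluence: separable Gaussian blur of the binary aperture
aperture_fluence <- function(aperture, sigma_mm) {
  sp <- aperture$spacing
  hw <- max(1L, ceiling(4 * sigma_mm / sp))
  k <- stats::dnorm((-hw:hw) * sp, sd = sigma_mm)
  k <- k / sum(k)
  f <- conv1(aperture$mask * 1, k)
  t(conv1(t(f), k))
}

# bilinear interpolation on a matrix with regularly spaced centers; zero
# outside the matrix span
bilinear_matrix <- function(m, u0, v0, spacing, u, v) {
  nu <- nrow(m); nv <- ncol(m)
  fu <- (u - u0) / spacing
  fv <- (v - v0) / spacing
  inside <- fu > -0.5 & fu < nu - 0.5 & fv > -0.5 & fv < nv - 0.5
  i0 <- pmin(pmax(floor(fu), 0), nu - 2L)
  j0 <- pmin(pmax(floor(fv), 0), nv - 2L)
  tu <- pmin(pmax(fu - i0, 0), 1)
  tv <- pmin(pmax(fv - j0, 0), 1)
  at <- function(i, j) m[1 + i + nu * j]
  val <- (at(i0, j0) * (1 - tu) + at(i0 + 1, j0) * tu) * (1 - tv) +
    (at(i0, j0 + 1) * (1 - tu) + at(i0 + 1, j0 + 1) * tu) * tv
  val * inside
}

#' Dose of a single beam on the voxel grid
#'
#' Evaluates the closed-form beam model (see [beam_model()]) for one gantry
#' angle. The homogeneous phantom is modeled as a water cylinder coaxial with
#' the grid (radius = half the smaller in-plane grid extent, matching the
#' cylindrical detector phantom); depth is measured along the beam direction
#' from the entry point on the curved phantom surface. The dose is zero
#' outside the phantom cylinder (the grid corners). With the phantom
#' rotation-symmetric about the cylinder axis, the per-beam doses of an
#' axially symmetric target are congruent under gantry rotation.
#'
#' @param aperture a `qa_aperture`.
#' @param gantry_angle gantry angle in degrees (wrapped modulo 360).
#' @param grid a `qa_grid`.
#' @param model parameters from [beam_model()].
#' @param coords optional precomputed [grid_coords()] (internal reuse).
#' @return a `qa_dose` with the (relative, unweighted) beam dose.
#' @export
beam_dose <- function(aperture, gantry_angle, grid, model = beam_model(),
                      coords = NULL) {
  if (is.null(coords)) coords <- grid_coords(grid)
  ax <- beam_axes(gantry_angle)
  b <- grid_bounds(grid)
  rp <- min(b$upper[1], b$upper[2])  # phantom cylinder radius
  r2 <- coords$x^2 + coords$y^2
  inside <- r2 <= rp^2
  vd <- coords$x * ax$d[1] + coords$y * ax$d[2]
  depth <- vd + sqrt(pmax(vd^2 - (r2 - rp^2), 0))
  u <- coords$x * ax$u[1] + coords$y * ax$u[2]
  fl <- bilinear_matrix(aperture_fluence(aperture, model$sigma_mm),
                        aperture$u[1], aperture$v[1], aperture$spacing,
                        u, coords$z)
  pdd <- ifelse(depth < model$d_max_mm,
                0.5 + 0.5 * depth / model$d_max_mm,
                exp(-model$mu * (depth - model$d_max_mm)))
  invsq <- (model$sad_mm / (model$sad_mm + depth - model$d_max_mm))^2
  dose_grid(grid, fl * pdd * invsq * inside)
}

#' Normalization factor for target coverage
#'
#' Returns the scale factor that makes the dose covering `coverage_pct` of the
#' target volume equal to the prescription: `factor = prescription /
#' D_coverage(target)`, where the coverage dose is the exact voxel percentile.
#'
#' @param dose a `qa_dose` (unscaled plan dose).
#' @param target target `qa_roi`.
#' @param prescription_cgy prescription dose in cGy.
#' @param coverage_pct coverage goal in percent (default 95, so D95 =
#'   prescription after scaling).
#' @return scalar normalization factor.
#' @export
normalize_to_coverage <- function(dose, target, prescription_cgy,
                                  coverage_pct = 95) {
  vals <- dose$values[target$voxels]
  if (length(vals) == 0) stop("target mask is empty", call. = FALSE)
  dcov <- stats::quantile(vals, probs = 1 - coverage_pct / 100, type = 1,
                          names = FALSE)
  if (!is.finite(dcov) || dcov <= 0) {
    stop("degenerate input: no positive dose at the coverage percentile",
         call. = FALSE)
  }
  prescription_cgy / dcov
}

#' Compose a five-field conformal plan
#'
#' Builds per-beam apertures and doses, sums them with the given weights, and
#' scales the sum so that D95 of the target equals the prescription.
#'
#' @param target_diameter_mm target diameter in mm.
#' @param prescription_cgy prescription in cGy.
#' @param grid a `qa_grid`.
#' @param beam_angles gantry angles in degrees (default the five-field
#'   arrangement 0, 72, 144, 216, 288).
#' @param weights relative beam weights; default equal. Must sum to 1 (within
#'   1e-9; they are renormalized exactly).
#' @param margin_mm MLC margin (default 3).
#' @param field_limit_mm field-size limit (default 100).
#' @param model beam model parameters.
#' @param rois optional precomputed [roi_set()] for this diameter.
#' @param coverage_pct coverage goal (default 95).
#' @return an object of class `qa_plan` with per-beam doses (weighted,
#'   unnormalized), the normalization factor, the normalized `total_dose`,
#'   beam metadata (aperture, equivalent square) and the ROI set.
#' @export
compose_plan <- function(target_diameter_mm, prescription_cgy, grid,
                         beam_angles = c(0, 72, 144, 216, 288),
                         weights = NULL, margin_mm = 3, field_limit_mm = 100,
                         model = beam_model(), rois = NULL,
                         coverage_pct = 95) {
  if (is.null(rois)) rois <- roi_set(grid, target_diameter_mm)
  nb <- length(beam_angles)
  if (is.null(weights)) weights <- rep(1 / nb, nb)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("beam weights must sum to 1", call. = FALSE)
  }
  weights <- weights / sum(weights)
  coords <- grid_coords(grid)
  beams <- vector("list", nb)
  per_beam <- vector("list", nb)
  for (b in seq_len(nb)) {
    ap <- bev_aperture(rois$target, beam_angles[b], margin_mm = margin_mm,
                       field_limit_mm = field_limit_mm)
    d <- beam_dose(ap, beam_angles[b], grid, model, coords = coords)
    per_beam[[b]] <- d$values * weights[b]
    beams[[b]] <- list(gantry_angle = beam_angles[b] %% 360, aperture = ap,
                       weight = weights[b],
                       eq_square_cm = equivalent_square_side(ap))
  }
  raw_total <- Reduce(`+`, per_beam)
  factor <- normalize_to_coverage(dose_grid(grid, raw_total), rois$target,
                                  prescription_cgy, coverage_pct)
  structure(list(target_diameter = target_diameter_mm,
                 prescription = prescription_cgy,
                 grid = grid, beams = beams, per_beam_dose = per_beam,
                 normalization_factor = factor,
                 total_dose = dose_grid(grid, factor * raw_total),
                 rois = rois, model = model),
            class = "qa_plan")
}

#' @export
print.qa_plan <- function(x, ...) {
  cat(sprintf(paste0("<qa_plan> target %g mm, prescription %g cGy, %d beams,",
                     " norm factor %.4g\n"),
              x$target_diameter, x$prescription, length(x$beams),
              x$normalization_factor))
  invisible(x)
}

#' Dose at the isocenter
#'
#' Trilinear interpolation of a dose grid at the isocenter (0, 0, 0).
#'
#' @param dose a `qa_dose`.
#' @return dose in cGy.
#' @export
isocenter_dose <- function(dose) {
  as.numeric(trilinear_sample(dose, c(0, 0, 0)))
}
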