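#' Build a voxel grid specification
#'
#' The grid covers the phantom box and is centered on the isocenter, which sits
#' at the physical origin (0, 0, 0). Voxel (i, j, k) (1-based) has its center at
#' `origin + (c(i, j, k) - 0.5) * spacing`, where `origin` is the lower corner
#' of the grid. The voxel count per axis is `ceiling(extent / spacing)`, so the
#' grid always covers at least the requested extent.
#'
#' Axis convention (used throughout the package): x and y span the axial plane,
#' z is the cranio-caudal axis; target and detector cylinders share the z axis;
#' beams rotate about z.
#'
#' @param extent_mm physical extent per axis in mm (default the
#'   265 x 265 x 270 mm phantom box).
#' @param spacing_mm voxel spacing per axis in mm.
#' @return an object of class `qa_grid` with fields `origin`, `spacing`,
#'   `shape`.
#' @export
make_grid <- function(extent_mm = c(265, 265, 270), spacing_mm = c(1, 1, 1)) {
  extent_mm <- rep_len(as.numeric(extent_mm), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(extent_mm)) || any(extent_mm <= 0)) {
    stop("extent_mm must be positive and finite", call. = FALSE)
  }
  # small epsilon so exact multiples do not gain a voxel from float noise
  shape <- as.integer(ceiling(extent_mm / spacing_mm - 1e-9))
  origin <- -shape * spacing_mm / 2
  structure(list(origin = origin, spacing = spacing_mm, shape = shape),
            class = "qa_grid")
}

#' @export
print.qa_grid <- function(x, ...) {
  cat(sprintf("<qa_grid> %d x %d x %d voxels, spacing %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# voxel-center coordinates along one axis
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

# full per-voxel coordinate vectors (array order: x fastest, then y, then z)
grid_coords <- function(grid) {
  cx <- axis_centers(grid, 1L)
  cy <- axis_centers(grid, 2L)
  cz <- axis_centers(grid, 3L)
  n <- grid$shape
  list(
    x = rep(cx, times = n[2] * n[3]),
    y = rep(rep(cy, each = n[1]), times = n[3]),
    z = rep(cz, each = n[1] * n[2])
  )
}

grid_bounds <- function(grid) {
  list(lower = grid$origin, upper = grid$origin + grid$shape * grid$spacing)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(a$shape == b$shape)
}

#' Wrap a scalar field into a dose grid
#'
#' @param grid a `qa_grid`.
#' @param values numeric array (or vector) of per-voxel dose in cGy, matching
#'   the grid shape.
#' @return an object of class `qa_dose`.
#' @export
dose_grid <- function(grid, values) {
  if (length(values) != prod(grid$shape)) {
    stop("values length does not match grid shape", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("dose values must be finite", call. = FALSE)
  dim(values) <- grid$shape
  structure(list(grid = grid, values = values), class = "qa_dose")
}

#' Trilinear interpolation of a dose grid at arbitrary points
#'
#' Values are interpolated between the 8 surrounding voxel centers; outside the
#' span of voxel centers the field is clamped to the edge value.
#'
#' @param dose a `qa_dose`.
#' @param points numeric n x 3 matrix (or length-3 vector) of positions in mm.
#' @return numeric vector of interpolated doses.
#' @export
trilinear_sample <- function(dose, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  g <- dose$grid
  v <- dose$values
  n <- g$shape
  f1 <- (points[, 1] - g$origin[1]) / g$spacing[1] - 0.5
  f2 <- (points[, 2] - g$origin[2]) / g$spacing[2] - 0.5
  f3 <- (points[, 3] - g$origin[3]) / g$spacing[3] - 0.5
  i0 <- pmin(pmax(floor(f1), 0), max(n[1] - 2L, 0L))
  j0 <- pmin(pmax(floor(f2), 0), max(n[2] - 2L, 0L))
  k0 <- pmin(pmax(floor(f3), 0), max(n[3] - 2L, 0L))
  tx <- pmin(pmax(f1 - i0, 0), 1)
  ty <- pmin(pmax(f2 - j0, 0), 1)
  tz <- pmin(pmax(f3 - k0, 0), 1)
  i1 <- pmin(i0 + 1, n[1] - 1L)
  j1 <- pmin(j0 + 1, n[2] - 1L)
  k1 <- pmin(k0 + 1, n[3] - 1L)
  nx <- n[1]; nxy <- n[1] * n[2]
  at <- function(i, j, k) v[1 + i + nx * j + nxy * k]
  c00 <- at(i0, j0, k0) * (1 - tx) + at(i1, j0, k0) * tx
  c10 <- at(i0, j1, k0) * (1 - tx) + at(i1, j1, k0) * tx
  c01 <- at(i0, j0, k1) * (1 - tx) + at(i1, j0, k1) * tx
  c11 <- at(i0, j1, k1) * (1 - tx) + at(i1, j1, k1) * tx
  (c00 * (1 - ty) + c10 * ty) * (1 - tz) + (c01 * (1 - ty) + c11 * ty) * tz
}

#' Volume of a boolean mask in cc
#'
#' Count of true voxels times voxel volume, reported in cubic centimeters.
#'
#' @param mask a `qa_roi`.
#' @return volume in cc.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$voxels) * prod(mask$grid$spacing) / 1000
}
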