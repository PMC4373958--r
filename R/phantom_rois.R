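#' Cylindrical ROI mask
#'
#' A voxel belongs to the cylinder iff its center lies inside it
#' (center-inclusion rule, no partial-volume weighting): radial distance from
#' the cylinder axis `<= diameter/2` and axial distance from the cylinder
#' midplane `<= length/2`.
#'
#' @param grid a `qa_grid`.
#' @param diameter_mm cylinder diameter in mm.
#' @param length_mm cylinder length in mm.
#' @param axis cylinder axis, one of `"x"`, `"y"`, `"z"` (default the
#'   cranio-caudal z axis).
#' @param center cylinder center in mm (default the isocenter).
#' @param name ROI label.
#' @return an object of class `qa_roi` with fields `name`, `grid`, `voxels`.
#' @export
cylinder_mask <- function(grid, diameter_mm, length_mm, axis = "z",
                          center = c(0, 0, 0), name = "roi") {
  radial_mask(grid, r_min = -Inf, r_max = diameter_mm / 2,
              length_mm = length_mm, axis = axis, center = center,
              name = name, check_fit = TRUE)
}

#' Annular (donut) ROI mask
#'
#' Voxel centers with radial distance in `(inner_radius, inner_radius +
#' thickness]` and the same axial rule as [cylinder_mask()]. The half-open
#' radial interval makes an annulus exactly disjoint from the cylinder it
#' surrounds.
#'
#' @inheritParams cylinder_mask
#' @param inner_diameter_mm inner diameter in mm.
#' @param thickness_mm radial thickness in mm (must be > 0).
#' @return a `qa_roi`.
#' @export
annulus_mask <- function(grid, inner_diameter_mm, thickness_mm, length_mm,
                         axis = "z", center = c(0, 0, 0), name = "roi") {
  if (!is.finite(thickness_mm) || thickness_mm <= 0) {
    stop("thickness_mm must be > 0 (zero thickness gives an empty mask)",
         call. = FALSE)
  }
  radial_mask(grid, r_min = inner_diameter_mm / 2,
              r_max = inner_diameter_mm / 2 + thickness_mm,
              length_mm = length_mm, axis = axis, center = center,
              name = name, check_fit = TRUE)
}

# shared cylinder/annulus construction: r_min < r <= r_max (r_min = -Inf gives
# a solid cylinder with r <= r_max)
radial_mask <- function(grid, r_min, r_max, length_mm, axis, center, name,
                        check_fit = TRUE) {
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop("axis must be one of 'x', 'y', 'z'", call. = FALSE)
  if (!is.finite(r_max) || r_max <= 0) {
    stop("diameter must be positive", call. = FALSE)
  }
  if (!is.finite(length_mm) || length_mm <= 0) {
    stop("length_mm must be positive", call. = FALSE)
  }
  cross <- setdiff(1:3, ax)
  if (check_fit) {
    b <- grid_bounds(grid)
    lo <- center; hi <- center
    lo[cross] <- lo[cross] - r_max; hi[cross] <- hi[cross] + r_max
    lo[ax] <- lo[ax] - length_mm / 2; hi[ax] <- hi[ax] + length_mm / 2
    if (any(lo < b$lower - 1e-9) || any(hi > b$upper + 1e-9)) {
      stop("cylinder does not fit inside the grid", call. = FALSE)
    }
  }
  ca <- axis_centers(grid, cross[1]) - center[cross[1]]
  cb <- axis_centers(grid, cross[2]) - center[cross[2]]
  cc <- axis_centers(grid, ax) - center[ax]
  r2 <- outer(ca^2, cb^2, `+`)
  r_min2 <- if (is.finite(r_min) && r_min > 0) r_min^2 else -Inf
  in_plane <- (r2 <= r_max^2) & (r2 > r_min2)
  axial <- abs(cc) <= length_mm / 2
  vox <- array(FALSE, grid$shape)
  # place the in-plane disc on every slab within the axial extent
  perm <- order(c(cross, ax))
  slab <- aperm(array(in_plane, c(length(ca), length(cb), 1L)), perm)
  idx <- list(seq_len(grid$shape[1]), seq_len(grid$shape[2]),
              seq_len(grid$shape[3]))
  for (k in which(axial)) {
    idx_k <- idx
    idx_k[[ax]] <- k
    vox[idx_k[[1]], idx_k[[2]], idx_k[[3]]] <- slab
  }
  structure(list(name = name, grid = grid, voxels = vox), class = "qa_roi")
}

#' @export
print.qa_roi <- function(x, ...) {
  cat(sprintf("<qa_roi> '%s': %d voxels, %.2f cc\n", x$name, sum(x$voxels),
              mask_volume_cc(x)))
  invisible(x)
}

#' Target / adjacent-OAR / peripheral-OAR mask triple
#'
#' Builds the three study ROIs for one target size: the cylindrical target, a
#' 1 cm thick annular "adjacent OAR" directly surrounding it, and a 1 cm thick
#' peripheral rim annulus whose geometry is fixed by `peripheral_spec` and
#' identical for every target size.
#'
#' @param grid a `qa_grid`.
#' @param target_diameter_mm target diameter in mm (>= grid spacing).
#' @param peripheral_spec list with `outer_diameter_mm` (default 210, the
#'   detector cylinder), `thickness_mm` (default 10) and `length_mm`
#'   (default 50).
#' @param adjacent_thickness_mm thickness of the adjacent annulus (default 10).
#' @param length_mm common length of target and OARs (default 50).
#' @return named list of `qa_roi`: `target`, `adjacent`, `peripheral`.
#' @export
roi_set <- function(grid, target_diameter_mm,
                    peripheral_spec = list(outer_diameter_mm = 210,
                                           thickness_mm = 10,
                                           length_mm = 50),
                    adjacent_thickness_mm = 10, length_mm = 50) {
  if (target_diameter_mm < max(grid$spacing)) {
    stop("target diameter below grid spacing", call. = FALSE)
  }
  target <- cylinder_mask(grid, target_diameter_mm, length_mm, name = "target")
  adjacent <- annulus_mask(grid, target_diameter_mm, adjacent_thickness_mm,
                           length_mm, name = "adjacent")
  per <- peripheral_spec
  peripheral <- annulus_mask(grid,
                             inner_diameter_mm = per$outer_diameter_mm -
                               2 * per$thickness_mm,
                             thickness_mm = per$thickness_mm,
                             length_mm = per$length_mm, name = "peripheral")
  if (any(adjacent$voxels & peripheral$voxels)) {
    stop("adjacent OAR overlaps the peripheral rim: invalid configuration",
         call. = FALSE)
  }
  list(target = target, adjacent = adjacent, peripheral = peripheral)
}
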