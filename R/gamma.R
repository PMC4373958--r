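#' Gamma evaluation criteria
#'
#' Global-normalization gamma criteria: dose tolerance as a percentage of the
#' normalization dose (by default the maximum of the planned reference
#' distribution), distance-to-agreement in mm, and a low-dose threshold below
#' which points are not evaluated (applied to the reference dose at the
#' evaluation point).
#'
#' @param dose_tol_pct dose tolerance, % of the normalization dose.
#' @param dta_mm distance-to-agreement, mm.
#' @param threshold_pct low-dose threshold, % of the normalization dose.
#' @return an object of class `qa_gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol_pct = 3, dta_mm = 3, threshold_pct = 5) {
  stopifnot(dose_tol_pct > 0, dta_mm > 0, threshold_pct > 0)
  structure(list(dose_tol_pct = dose_tol_pct, dta_mm = dta_mm,
                 threshold_pct = threshold_pct, normalization = "global"),
            class = "qa_gamma_criteria")
}

criteria_label <- function(criteria) {
  sprintf("%g%%/%gmm", criteria$dose_tol_pct, criteria$dta_mm)
}

# DTA search offsets within a ball, sorted by distance (zero offset first)
gamma_offsets <- function(ndim, radius, step) {
  k <- ceiling(radius / step)
  v <- (-k:k) * step
  off <- as.matrix(do.call(expand.grid, rep(list(v), ndim)))
  dimnames(off) <- NULL
  d2 <- rowSums(off^2)
  keep <- d2 <= radius^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(offsets = off[ord, , drop = FALSE], d2 = d2[ord])
}

check_gamma_search <- function(criteria, search_radius, fine_step) {
  if (fine_step > criteria$dta_mm + 1e-12) {
    stop("fine_step exceeds the DTA: the search would undersample the ",
         "distance-to-agreement; refuse", call. = FALSE)
  }
  if (search_radius < 3 * criteria$dta_mm - 1e-9) {
    stop("search_radius must be at least 3 x DTA", call. = FALSE)
  }
  invisible(TRUE)
}

new_gamma_result <- function(gamma, evaluable, criteria, norm_dose,
                             index = NULL, geometry = NULL) {
  n_ev <- sum(evaluable)
  passing <- if (n_ev > 0) 100 * sum(gamma[evaluable] <= 1) / n_ev else NA_real_
  structure(list(gamma = gamma, evaluable = evaluable,
                 passing_rate = passing, n_evaluable = n_ev,
                 criteria = criteria, norm_dose = norm_dose, index = index,
                 geometry = geometry),
            class = "qa_gamma")
}

#' @export
print.qa_gamma <- function(x, ...) {
  cat(sprintf("<qa_gamma> %s: %d evaluable points, passing rate %s\n",
              criteria_label(x$criteria), x$n_evaluable,
              if (is.na(x$passing_rate)) "undefined (no evaluable points)"
              else sprintf("%.2f%%", x$passing_rate)))
  invisible(x)
}

#' 3D gamma map of an evaluated dose grid against a reference grid
#'
#' Computes the gamma index of Low et al. at each evaluation voxel:
#' `gamma(p) = min over reference positions r within the search radius of
#' sqrt(|r - p|^2 / dta^2 + (D_ref(r) - D_eval(p))^2 / tol_abs^2)`, with
#' `tol_abs = dose_tol_pct/100 * norm_dose`. The reference is interpolated
#' trilinearly on a fine step (default `dta / 3`) within a search ball
#' (default radius `3 * dta`). Points whose reference dose falls below the
#' threshold are not evaluable. Gamma values at or below 1 pass (boundary
#' inclusive).
#'
#' @param eval_dose the evaluated `qa_dose` (e.g. the perturbed dose).
#' @param reference the reference `qa_dose` (the planned dose), on the same
#'   grid.
#' @param criteria a `qa_gamma_criteria`.
#' @param roi optional `qa_roi` restricting the evaluation points (default:
#'   all voxels).
#' @param norm_dose normalization dose; default `max(reference)`.
#' @param search_radius_mm DTA search radius (default `3 * dta`; must be at
#'   least that).
#' @param fine_step_mm reference interpolation step (default `dta / 3`; a step
#'   above the DTA is refused).
#' @return a `qa_gamma` with per-point gamma values (aligned with `index`,
#'   the voxel indices evaluated), the evaluable mask and the passing rate.
#' @export
gamma_map_grid <- function(eval_dose, reference, criteria = gamma_criteria(),
                           roi = NULL, norm_dose = NULL,
                           search_radius_mm = 3 * criteria$dta_mm,
                           fine_step_mm = criteria$dta_mm / 3) {
  stopifnot(inherits(eval_dose, "qa_dose"), inherits(reference, "qa_dose"))
  if (!same_grid(eval_dose$grid, reference$grid)) {
    stop("evaluated and reference doses must share a grid", call. = FALSE)
  }
  check_gamma_search(criteria, search_radius_mm, fine_step_mm)
  if (is.null(norm_dose)) norm_dose <- max(reference$values)
  g <- reference$grid
  idx <- if (is.null(roi)) seq_len(prod(g$shape)) else which(roi$voxels)
  if (length(idx) == 0) stop("empty evaluation set", call. = FALSE)
  arr <- arrayInd(idx, g$shape)
  pos <- cbind(g$origin[1] + (arr[, 1] - 0.5) * g$spacing[1],
               g$origin[2] + (arr[, 2] - 0.5) * g$spacing[2],
               g$origin[3] + (arr[, 3] - 0.5) * g$spacing[3])
  de <- eval_dose$values[idx]
  ref_at <- reference$values[idx]
  evaluable <- ref_at >= criteria$threshold_pct / 100 * norm_dose
  gamma <- rep(NA_real_, length(idx))
  if (any(evaluable)) {
    off <- gamma_offsets(3L, search_radius_mm, fine_step_mm)
    gamma[evaluable] <- gamma_points_cpp(
      reference$values, g$shape, g$origin, g$spacing,
      pos[evaluable, , drop = FALSE], de[evaluable],
      off$offsets, off$d2 / criteria$dta_mm^2,
      criteria$dose_tol_pct / 100 * norm_dose)
  }
  new_gamma_result(gamma, evaluable, criteria, norm_dose, index = idx)
}

#' 2D gamma map of diode readings on the unwrapped cylinder surface
#'
#' The evaluated points are the diode composite readings; the reference is
#' the planned 3D dose restricted to the detector cylinder surface. Distance
#' is measured on the unwrapped `(arc length, z)` surface with periodic wrap
#' in the angular direction; a surface offset `(ds, dz)` looks the reference
#' up at the corresponding 3D cylinder point by trilinear interpolation.
#'
#' By default the normalization dose is the maximum of the planned 3D dose
#' (global normalization "with respect to the maximum 3D dose"); it is
#' configurable via `norm_dose`, e.g. the maximum planned diode reading.
#'
#' @param measured a `qa_reading` (the evaluated distribution).
#' @param reference the planned composite `qa_dose`.
#' @param geometry the `qa_diode_geometry`.
#' @inheritParams gamma_map_grid
#' @return a `qa_gamma` with one gamma value per diode.
#' @export
gamma_map_diode <- function(measured, reference, geometry,
                            criteria = gamma_criteria(), norm_dose = NULL,
                            search_radius_mm = 3 * criteria$dta_mm,
                            fine_step_mm = criteria$dta_mm / 3) {
  stopifnot(inherits(measured, "qa_reading"), inherits(reference, "qa_dose"))
  check_gamma_search(criteria, search_radius_mm, fine_step_mm)
  if (is.null(norm_dose)) norm_dose <- max(reference$values)
  ref_at <- trilinear_sample(reference, geometry$positions)
  evaluable <- ref_at >= criteria$threshold_pct / 100 * norm_dose
  gamma <- rep(NA_real_, geometry$n_diodes)
  if (any(evaluable)) {
    off <- gamma_offsets(2L, search_radius_mm, fine_step_mm)
    g <- reference$grid
    gamma[evaluable] <- gamma_cylinder_cpp(
      reference$values, g$shape, g$origin, g$spacing, geometry$radius,
      geometry$s[evaluable], geometry$z[evaluable],
      measured$composite[evaluable],
      off$offsets, off$d2 / criteria$dta_mm^2,
      criteria$dose_tol_pct / 100 * norm_dose)
  }
  new_gamma_result(gamma, evaluable, criteria, norm_dose,
                   geometry = geometry)
}

#' Passing rate of a gamma result, optionally over a subset
#'
#' `100 * |evaluable points in the subset with gamma <= 1| / |evaluable points
#' in the subset|`. Gamma exactly 1 passes. An empty evaluable subset is an
#' error, never 0% or 100%.
#'
#' @param result a `qa_gamma`.
#' @param subset optional logical or integer subset of the result's points
#'   (e.g. a lattice subset); default all.
#' @return passing rate in percent.
#' @export
passing_rate <- function(result, subset = NULL) {
  sel <- rep(FALSE, length(result$gamma))
  if (is.null(subset)) sel[] <- TRUE else sel[subset] <- TRUE
  ev <- result$evaluable & sel
  if (!any(ev)) {
    stop("no evaluable points in the requested subset", call. = FALSE)
  }
  100 * sum(result$gamma[ev] <= 1) / sum(ev)
}

#' Brute-force gamma at a single point (validation oracle)
#'
#' Exhaustive minimization over a dense ball of reference positions,
#' implemented independently of the gamma engine (plain vectorized R with its
#' own interpolation path and offset enumeration). Upper-bounds the true gamma
#' within a step-dependent tolerance; at the engine's own fine step (the
#' default) it validates the engine's search and early-exit logic, and smaller
#' steps tighten the continuum bound.
#'
#' @param point length-3 position of the evaluation point, mm.
#' @param eval_dose_value the evaluated dose at that point, cGy.
#' @param reference the reference `qa_dose`.
#' @param criteria a `qa_gamma_criteria`.
#' @param norm_dose normalization dose; default `max(reference)`.
#' @param search_radius_mm search-ball radius (default `3 * dta`).
#' @param step_mm dense search step (default `dta / 3`, the engine's fine
#'   step).
#' @return the gamma value.
#' @export
brute_force_gamma_point <- function(point, eval_dose_value, reference,
                                    criteria = gamma_criteria(),
                                    norm_dose = NULL,
                                    search_radius_mm = 3 * criteria$dta_mm,
                                    step_mm = criteria$dta_mm / 3) {
  if (is.null(norm_dose)) norm_dose <- max(reference$values)
  k <- ceiling(search_radius_mm / step_mm)
  v <- (-k:k) * step_mm
  off <- as.matrix(expand.grid(v, v, v))
  d2 <- rowSums(off^2)
  keep <- d2 <= search_radius_mm^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ref_vals <- trilinear_sample(reference, sweep(off, 2, -as.numeric(point)))
  tol_abs <- criteria$dose_tol_pct / 100 * norm_dose
  sqrt(min(d2 / criteria$dta_mm^2 +
             ((ref_vals - eval_dose_value) / tol_abs)^2))
}
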