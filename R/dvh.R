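#' Cumulative dose-volume histogram
#'
#' Exact voxel-counting cumulative DVH (no partial-volume weighting): the
#' volume fraction at each bin edge is the percentage of ROI voxels receiving
#' at least that dose. The curve starts at 100% at zero dose, is monotone
#' non-increasing, and reaches 0% above the maximum dose.
#'
#' @param dose a `qa_dose`.
#' @param roi a `qa_roi`.
#' @param bin_width_cgy bin width in cGy (default 1).
#' @return an object of class `qa_dvh` with `bin_edges` and `volume_fraction`
#'   (percent).
#' @export
cumulative_dvh <- function(dose, roi, bin_width_cgy = 1) {
  vals <- dose$values[roi$voxels]
  if (length(vals) == 0) stop("empty ROI", call. = FALSE)
  stopifnot(bin_width_cgy > 0)
  edges <- seq(0, max(vals) + bin_width_cgy, by = bin_width_cgy)
  sv <- sort(vals)
  n <- length(sv)
  # count of voxels with dose >= edge
  ge <- n - findInterval(edges - 1e-9 * bin_width_cgy, sv)
  structure(list(bin_edges = edges, volume_fraction = 100 * ge / n,
                 bin_width = bin_width_cgy, roi = roi$name),
            class = "qa_dvh")
}

#' Dose covering a volume fraction (Dx)
#'
#' The largest dose at which the cumulative volume fraction is still at least
#' `volume_pct`, linearly interpolated between bin edges. D95 and D50 are
#' `dose_at_volume(dvh, 95)` and `dose_at_volume(dvh, 50)`.
#'
#' @param dvh a `qa_dvh`.
#' @param volume_pct volume percentage in (0, 100].
#' @return dose in cGy.
#' @export
dose_at_volume <- function(dvh, volume_pct) {
  if (volume_pct <= 0 || volume_pct > 100) {
    stop("volume_pct must be in (0, 100]", call. = FALSE)
  }
  V <- dvh$volume_fraction
  d <- dvh$bin_edges
  k <- max(which(V >= volume_pct))
  if (k == length(V) || V[k] == volume_pct) return(d[k])
  # V[k] > volume_pct > V[k + 1]
  d[k] + (V[k] - volume_pct) / (V[k] - V[k + 1]) * (d[k + 1] - d[k])
}

#' Mean dose over an ROI
#'
#' @param dose a `qa_dose`.
#' @param roi a `qa_roi`.
#' @return arithmetic mean dose over the ROI voxels, cGy.
#' @export
mean_dose <- function(dose, roi) {
  vals <- dose$values[roi$voxels]
  if (length(vals) == 0) stop("empty ROI", call. = FALSE)
  mean(vals)
}

#' DVH scalar metrics for one ROI
#'
#' Mean dose, D50 and D95, each in cGy and as a percentage of the
#' prescription.
#'
#' @param dose a `qa_dose`.
#' @param roi a `qa_roi`.
#' @param prescription_cgy prescription dose, cGy.
#' @param bin_width_cgy DVH bin width (default 1).
#' @return named list with `mean_cgy`, `d50_cgy`, `d95_cgy` and the matching
#'   `_pct` fields.
#' @export
dvh_metrics <- function(dose, roi, prescription_cgy, bin_width_cgy = 1) {
  dvh <- cumulative_dvh(dose, roi, bin_width_cgy)
  m <- mean_dose(dose, roi)
  d50 <- dose_at_volume(dvh, 50)
  d95 <- dose_at_volume(dvh, 95)
  list(mean_cgy = m, d50_cgy = d50, d95_cgy = d95,
       mean_pct = 100 * m / prescription_cgy,
       d50_pct = 100 * d50 / prescription_cgy,
       d95_pct = 100 * d95 / prescription_cgy)
}

#' Dose deviation percentage
#'
#' `100 * |a - b| / b`: the absolute relative deviation of a measured or
#' predicted dose from the planned dose, in percent (sign discarded).
#'
#' @param predicted_or_measured dose a, cGy.
#' @param planned dose b, cGy (must be > 0).
#' @return deviation in percent.
#' @export
dose_deviation_pct <- function(predicted_or_measured, planned) {
  if (any(planned <= 0)) stop("planned dose must be positive", call. = FALSE)
  100 * abs(predicted_or_measured - planned) / planned
}
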