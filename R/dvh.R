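#' Voxel dose grid
#'
#' A regular 3-D grid of absorbed dose values. The axis order is (z, y, x),
#' spacing is the voxel edge length in millimetres per axis, and `origin` is
#' the physical coordinate of the centre of voxel `[1, 1, 1]` in millimetres.
#'
#' @param values Numeric 3-D array of absorbed dose in Gy. All values must be
#'   finite and non-negative.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm (z, y, x),
#'   strictly positive.
#' @param origin Numeric length-3 vector, physical coordinate (mm) of the first
#'   voxel centre.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(values) < 1L)) {
    stop("grid must have at least one voxel per axis", call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("dose values must be finite and >= 0", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive lengths (mm)", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "dose_grid"
  )
}

#' Binary structure mask
#'
#' Marks the voxels of a [dose_grid()] occupied by an anatomical structure.
#' Voxels are wholly in or out (voxel-centre convention); there is no
#' partial-volume weighting.
#'
#' @param occupancy Logical 3-D array, congruent with the paired dose grid.
#' @param name Structure label (e.g. `"ptv"`, `"rectum"`).
#' @param role Either `"target"` or `"oar"`; decides the default direction of
#'   metrics defined on the structure downstream.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, name, role = c("target", "oar")) {
  role <- match.arg(role)
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L) {
    stop("`occupancy` must be a 3-D array", call. = FALSE)
  }
  occupancy <- array(as.logical(occupancy), dim = dim(occupancy))
  if (anyNA(occupancy)) stop("mask occupancy must be TRUE/FALSE", call. = FALSE)
  structure(
    list(occupancy = occupancy, name = as.character(name), role = role),
    class = "structure_mask"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm, dose ",
      signif(min(x$values), 4), "-", signif(max(x$values), 4), " Gy\n", sep = "")
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> ", x$name, " (", x$role, "), ",
      sum(x$occupancy), " voxels\n", sep = "")
  invisible(x)
}

#' Volume of one voxel in cubic centimetres
#' @param grid A [dose_grid()].
#' @return Voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  prod(grid$spacing) / 1000
}

check_congruent <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$occupancy))) {
    stop("mask '", mask$name, "' is not congruent with the dose grid (",
         paste(dim(mask$occupancy), collapse = "x"), " vs ",
         paste(dim(grid$values), collapse = "x"), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cumulative dose-volume histogram
#'
#' Computes the cumulative DVH of a structure: the fraction of structure
#' volume receiving at least each dose level. Bin edges run from 0 Gy to the
#' maximum in-structure dose padded up to a bin edge; the curve is the exact
#' empirical exceedance function of the voxel dose multiset (no smoothing).
#'
#' @param grid A [dose_grid()].
#' @param mask A [structure_mask()] congruent with `grid` and non-empty.
#' @param bin_width Dose bin width in Gy. The default 0.01 Gy is finer than
#'   any difference the downstream summaries report.
#' @return An object of class `dvh_curve` with fields `dose_edges` (Gy,
#'   strictly increasing), `cum_volume_fraction` (0-1, non-increasing, equal
#'   to 1 at 0 Gy) and `total_volume_cc`.
#' @export
compute_cumulative_dvh <- function(grid, mask, bin_width = 0.01) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  check_congruent(grid, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("`bin_width` must be a single positive dose (Gy)", call. = FALSE)
  }
  doses <- grid$values[mask$occupancy]
  n <- length(doses)
  if (n == 0L) {
    stop("structure '", mask$name, "' is empty: cannot compute a DVH",
         call. = FALSE)
  }
  dmax <- max(doses)
  top <- ceiling(dmax / bin_width - 1e-9) * bin_width
  edges <- seq(0, max(top, bin_width), by = bin_width)
  sorted <- sort(doses)
  # exceedance count: voxels with dose >= edge (tolerance guards fp edges)
  cum <- (n - findInterval(edges - 1e-9 * max(1, dmax), sorted)) / n
  structure(
    list(
      dose_edges = edges,
      cum_volume_fraction = cum,
      total_volume_cc = n * voxel_volume_cc(grid),
      bin_width = bin_width
    ),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", length(x$dose_edges), " edges to ",
      max(x$dose_edges), " Gy, volume ", signif(x$total_volume_cc, 5),
      " cc\n", sep = "")
  invisible(x)
}

#' Dose to the hottest x% of a structure (Dx%)
#'
#' Minimum dose received by the hottest `x` percent of the structure volume,
#' under the step-function (empirical) quantile convention: the returned dose
#' is the largest DVH edge whose exceedance volume still covers the requested
#' fraction. No interpolation between voxel doses is performed.
#'
#' @param curve A `dvh_curve` from [compute_cumulative_dvh()].
#' @param x Percent of structure volume, in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_relative_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 100) {
    stop("`x` must be a volume percentage in (0, 100]", call. = FALSE)
  }
  frac <- x / 100
  ok <- curve$cum_volume_fraction >= frac - 1e-12
  max(curve$dose_edges[ok])
}

#' Dose to the hottest x cc of a structure (Dxcc)
#'
#' Minimum dose received by the hottest `x` cubic centimetres. `x = 0` returns
#' the maximum in-structure dose; `x` at or beyond the total structure volume
#' returns the minimum dose.
#'
#' @param curve A `dvh_curve`.
#' @param x Absolute volume in cc, `x >= 0`.
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(curve, x) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop("`x` must be a non-negative volume in cc", call. = FALSE)
  }
  if (x == 0) {
    return(max(curve$dose_edges[curve$cum_volume_fraction > 1e-12]))
  }
  frac <- min(x / curve$total_volume_cc, 1)
  ok <- curve$cum_volume_fraction >= frac - 1e-12
  max(curve$dose_edges[ok])
}

#' Volume receiving at least a dose threshold (VxGy / Vx%)
#'
#' Percent of the structure volume receiving at least `threshold` Gy. The
#' relative-dose variant Vx% is obtained by converting x% of the per-fraction
#' prescription to Gy first (see [relative_dose_threshold()]).
#'
#' @param curve A `dvh_curve`.
#' @param threshold Dose threshold in Gy, `>= 0`.
#' @return Volume percentage in \[0, 100\].
#' @export
volume_at_dose <- function(curve, threshold) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("`threshold` must be a non-negative dose (Gy)", call. = FALSE)
  }
  idx <- which(curve$dose_edges >= threshold - 1e-9)
  if (length(idx) == 0L) return(0)
  100 * curve$cum_volume_fraction[idx[1L]]
}
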