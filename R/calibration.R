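# Ex-vivo fat calibration: ellipsoidal ROI statistics and the fat density
# window derived from them.

#' Define an ellipsoidal region of interest
#'
#' @param center world coordinates (z, y, x) of the ellipsoid centre, mm.
#' @param semi_axes semi-axis lengths (z, y, x), mm; all > 0.
#' @return An `ellipsoid_roi` with the nominal (continuous) volume
#'   `4/3 * pi * a * b * c` attached.
#' @export
ellipsoid_roi <- function(center, semi_axes) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be 3 finite world coordinates (mm)")
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) || any(semi_axes <= 0))
    stop("`semi_axes` must be 3 positive values (mm)")
  structure(list(center = center, semi_axes = semi_axes,
                 nominal_volume_mm3 = 4 / 3 * pi * prod(semi_axes)),
            class = "ellipsoid_roi")
}

#' @export
print.ellipsoid_roi <- function(x, ...) {
  cat(sprintf("ellipsoid_roi: centre (%s) mm, semi-axes (%s) mm, nominal %.4g mm^3\n",
              paste(format(x$center), collapse = ", "),
              paste(format(x$semi_axes), collapse = ", "),
              x$nominal_volume_mm3))
  invisible(x)
}

#' Voxels belonging to an ellipsoidal ROI
#'
#' A voxel belongs to the ROI iff its centre satisfies the ellipsoid
#' inequality (sum of squared normalised offsets <= 1). Membership is by
#' voxel-centre inclusion, not partial-volume weighting.
#'
#' @param vol a `ct_volume`.
#' @param roi an `ellipsoid_roi`.
#' @return Integer matrix with one row per member voxel and columns
#'   `z`, `y`, `x` (1-based indices). Errors if the ROI lies entirely
#'   outside the volume.
#' @export
roi_voxels <- function(vol, roi) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  if (!inherits(roi, "ellipsoid_roi")) stop("`roi` must be an ellipsoid_roi")
  d <- dim(vol$data)
  ax <- lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
  # candidate index ranges from the bounding box
  rng <- lapply(1:3, function(k) {
    which(ax[[k]] >= roi$center[k] - roi$semi_axes[k] &
          ax[[k]] <= roi$center[k] + roi$semi_axes[k])
  })
  if (any(lengths(rng) == 0L)) stop("ROI lies entirely outside the volume")
  z2 <- ((ax[[1]][rng[[1]]] - roi$center[1]) / roi$semi_axes[1])^2
  y2 <- ((ax[[2]][rng[[2]]] - roi$center[2]) / roi$semi_axes[2])^2
  x2 <- ((ax[[3]][rng[[3]]] - roi$center[3]) / roi$semi_axes[3])^2
  inside <- outer(outer(z2, y2, "+"), x2, "+") <= 1
  if (!any(inside)) stop("ROI lies entirely outside the volume")
  w <- which(inside, arr.ind = TRUE)
  out <- cbind(z = rng[[1]][w[, 1]], y = rng[[2]][w[, 2]], x = rng[[3]][w[, 3]])
  out[order(out[, "x"], out[, "y"], out[, "z"]), , drop = FALSE]
}

#' ROI voxel statistics
#'
#' Voxel count, mean HU and (sample) SD over the member voxels of an
#' ellipsoidal ROI.
#'
#' @param vol a `ct_volume`.
#' @param roi an `ellipsoid_roi`.
#' @return list of class `roi_stats` with `n_voxels`, `mean_hu`, `sd_hu`.
#' @export
roi_stats <- function(vol, roi) {
  idx <- roi_voxels(vol, roi)
  lin <- idx[, 1] + dim(vol$data)[1] * ((idx[, 2] - 1) +
          dim(vol$data)[2] * (idx[, 3] - 1))
  vals <- vol$data[lin]
  structure(list(n_voxels = nrow(idx),
                 mean_hu = mean(vals),
                 sd_hu = if (length(vals) > 1) sd(vals) else 0),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("roi_stats: n = %d, mean = %.2f HU, sd = %.2f HU\n",
              x$n_voxels, x$mean_hu, x$sd_hu))
  invisible(x)
}

#' Calibrate the pure-fat HU value from ellipsoidal ROIs
#'
#' Computes per-ROI mean HU on an ex-vivo fat scan and averages the ROI
#' means (unweighted). Every ROI must contain strictly more than
#' `min_voxels` voxels. The reported value is rounded to the nearest
#' integer HU, matching how such calibration constants are presented; the
#' unrounded value is retained and used downstream.
#'
#' @param vol a `ct_volume` of the ex-vivo fat block.
#' @param rois list of `ellipsoid_roi`.
#' @param min_voxels strict lower bound on per-ROI voxel count.
#' @return A `fat_calibration`: `value_hu` (rounded), `value_hu_unrounded`,
#'   `per_roi` (data.frame: roi, n_voxels, mean_hu, sd_hu), `min_voxels`.
#' @export
calibrate_fat_hu <- function(vol, rois, min_voxels = 400) {
  if (inherits(rois, "ellipsoid_roi")) rois <- list(rois)
  if (length(rois) < 1L) stop("need at least one ROI")
  stats <- lapply(rois, function(r) roi_stats(vol, r))
  ns <- vapply(stats, `[[`, numeric(1), "n_voxels")
  bad <- which(ns <= min_voxels)
  if (length(bad))
    stop(sprintf("ROI %d has %d voxels; more than %d are required",
                 bad[1], ns[bad[1]], min_voxels))
  means <- vapply(stats, `[[`, numeric(1), "mean_hu")
  sds <- vapply(stats, `[[`, numeric(1), "sd_hu")
  value <- mean(means)
  structure(list(value_hu = round(value),
                 value_hu_unrounded = value,
                 per_roi = data.frame(roi = seq_along(rois), n_voxels = ns,
                                      mean_hu = means, sd_hu = sds),
                 min_voxels = min_voxels),
            class = "fat_calibration")
}

#' @export
print.fat_calibration <- function(x, ...) {
  cat(sprintf("fat_calibration: %d HU (unrounded %.3f) from %d ROIs (> %d voxels each)\n",
              x$value_hu, x$value_hu_unrounded, nrow(x$per_roi), x$min_voxels))
  print(x$per_roi, row.names = FALSE)
  invisible(x)
}

#' Define an inclusive HU density window
#'
#' @param lo,hi inclusive window bounds in HU, `lo < hi`.
#' @return A `density_window`.
#' @export
density_window <- function(lo, hi) {
  lo <- as.numeric(lo)[1]
  hi <- as.numeric(hi)[1]
  if (!is.finite(lo) || !is.finite(hi)) stop("window bounds must be finite")
  if (lo >= hi) stop(sprintf("invalid density window: lo (%g) must be < hi (%g)", lo, hi))
  structure(list(lo = lo, hi = hi), class = "density_window")
}

#' @export
print.density_window <- function(x, ...) {
  cat(sprintf("density_window: [%g, %g] HU (inclusive)\n", x$lo, x$hi))
  invisible(x)
}

#' The fat density window
#'
#' The in-situ fat window \[-115, +50\] HU: lower bound from the ex-vivo
#' pure-fat calibration, upper bound a fixed constant.
#' @return A `density_window`.
#' @export
fat_window <- function() density_window(-115, 50)

#' The whole-body density window
#'
#' The whole-body window \[-1000, +2500\] HU used to delineate the fish
#' against background air.
#' @return A `density_window`.
#' @export
body_window <- function() density_window(-1000, 2500)

#' Build the fat window from a calibrated value
#'
#' @param calibrated calibrated pure-fat HU value (numeric, or a
#'   `fat_calibration`, whose unrounded value is used).
#' @param upper fixed upper bound in HU (default +50). The upper bound is a
#'   constant, not calibrated: only the lower bound derives from the ex-vivo
#'   measurement.
#' @return A `density_window` `[calibrated, upper]`.
#' @export
build_fat_window <- function(calibrated, upper = 50) {
  if (inherits(calibrated, "fat_calibration"))
    calibrated <- calibrated$value_hu_unrounded
  density_window(calibrated, upper)
}
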