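# Whole-body isocontour, bed exclusion, and density-window segmentation.

dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(a, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[axis]
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    res <- array(FALSE, d)
    ids <- list(1:d[1], 1:d[2], 1:d[3])
    ids_src <- ids; ids_src[[axis]] <- src
    ids_dst <- ids; ids_dst[[axis]] <- dst
    res[ids_dst[[1]], ids_dst[[2]], ids_dst[[3]]] <-
      a[ids_src[[1]], ids_src[[2]], ids_src[[3]]]
    res
  }
  for (axis in 1:3) out <- out | shift(m, axis, 1L) | shift(m, axis, -1L)
  out
}

#' Bed mask from an empty-bed scan
#'
#' Thresholds the empty-bed reference scan (voxels with HU strictly above
#' `threshold` are bed) and dilates the result by one voxel
#' (6-neighbourhood) so that blurred bed edges are also excluded. The bed is
#' removed from the body by mask exclusion, not by HU subtraction, so it
#' cannot corrupt HU quantitation.
#'
#' @param empty `ct_volume` of the empty scanner bed, congruent in shape
#'   with the specimen scan it will be applied to.
#' @param threshold HU threshold separating bed from air (default -900).
#' @return A `voxel_mask` labelled "bed".
#' @export
bed_mask_from_empty_scan <- function(empty, threshold = -900) {
  if (!inherits(empty, "ct_volume")) stop("`empty` must be a ct_volume")
  m <- empty$data > threshold
  if (any(m)) m <- dilate6(m)
  voxel_mask(m, label = "bed")
}

#' Seeded 3D body isocontour
#'
#' Delineates the whole fish as the 6-connected component, containing
#' `seed_point`, of voxels whose HU lies inside the body density window.
#' Because the nominal body window's lower bound (-1000 HU) equals the air
#' value, naive thresholding would flood the background; an effective
#' lower bound breaks the air connection while the nominal window is still
#' reported in the result's metadata. The default (-480 HU) is the midpoint
#' between air and lean tissue — the half-maximum edge criterion — which
#' leaves the contour unbiased under partial-volume blur: a more air-side
#' bound systematically swallows the blur shell around the body. Voxels in
#' `exclude` (typically the bed mask) are never part of the component.
#'
#' A QC flag is raised when the component is smaller than a voxel-count
#' floor. The floor default (33,564 voxels) refers to full scanner
#' resolution (`reference_spacing` = 0.125 mm) and is rescaled by the cube
#' of the spacing ratio for reduced or desk-scale volumes.
#'
#' @param vol a `ct_volume`.
#' @param seed_point voxel index (z, y, x), 1-based, inside the specimen.
#' @param window body `density_window` (default [body_window()]).
#' @param exclude optional `voxel_mask` of voxels to exclude (e.g. bed).
#' @param effective_lo effective lower HU bound used for region growing.
#' @param qc_floor minimum expected component size at `reference_spacing`.
#' @param reference_spacing spacing (mm) at which `qc_floor` is defined.
#' @return A `voxel_mask` labelled "body" with attribute `qc` (list:
#'   `n_voxels`, `floor`, `below_floor`, `window`, `effective_lo`).
#' @export
body_isocontour <- function(vol, seed_point, window = body_window(),
                            exclude = NULL, effective_lo = -480,
                            qc_floor = 33564, reference_spacing = 0.125) {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  if (!inherits(window, "density_window")) stop("`window` must be a density_window")
  d <- dim(vol$data)
  seed_point <- as.integer(seed_point)
  if (length(seed_point) != 3L || any(seed_point < 1L) || any(seed_point > d))
    stop("`seed_point` is outside the volume")
  lo <- max(window$lo, effective_lo)
  cand <- vol$data >= lo & vol$data <= window$hi
  if (!is.null(exclude)) {
    check_congruent(vol, exclude, "exclude mask")
    cand <- cand & !exclude$data
  }
  seed_hu <- vol$data[seed_point[1], seed_point[2], seed_point[3]]
  lin0 <- (seed_point[1] - 1L) + d[1] * ((seed_point[2] - 1L) + d[2] * (seed_point[3] - 1L))
  if (!cand[seed_point[1], seed_point[2], seed_point[3]])
    stop(sprintf("seed voxel HU (%.1f) is outside the effective body window [%g, %g] or excluded",
                 seed_hu, lo, window$hi))
  comp <- array(.flood_fill_6(as.vector(cand), d, lin0), d)
  n <- sum(comp)
  floor_scaled <- qc_floor * (reference_spacing / mean(vol$spacing))^3
  mask <- voxel_mask(comp, label = "body")
  attr(mask, "qc") <- list(n_voxels = n, floor = floor_scaled,
                           below_floor = n < floor_scaled,
                           window = c(window$lo, window$hi),
                           effective_lo = effective_lo)
  mask
}

#' Density-window segmentation
#'
#' Selects the voxels whose HU lies inside an inclusive density window,
#' optionally restricted to a region (`within`, typically the body mask).
#' Both window endpoints are included.
#'
#' @param vol a `ct_volume`.
#' @param window a `density_window`.
#' @param within optional `voxel_mask` restricting the segmentation.
#' @param label label for the returned mask.
#' @return A `voxel_mask`.
#' @export
segment_window <- function(vol, window, within = NULL, label = "fat") {
  if (!inherits(vol, "ct_volume")) stop("`vol` must be a ct_volume")
  if (!inherits(window, "density_window")) stop("`window` must be a density_window")
  m <- vol$data >= window$lo & vol$data <= window$hi
  if (!is.null(within)) {
    check_congruent(vol, within, "`within` mask")
    m <- m & within$data
  }
  voxel_mask(m, label = label)
}

#' Segment one specimen end to end
#'
#' Convenience wrapper combining bed exclusion, body isocontour and fat
#' window segmentation for a single volume, enforcing the containment
#' invariants (fat inside body, fat disjoint from bed).
#'
#' @param vol a `ct_volume`.
#' @param seed_point voxel index (z, y, x) inside the specimen.
#' @param fat_win fat `density_window`.
#' @param body_win body `density_window`.
#' @param empty optional empty-bed `ct_volume` for bed exclusion.
#' @param bed_threshold HU threshold for the bed mask.
#' @param effective_lo effective body lower bound (HU).
#' @param qc_floor,reference_spacing see [body_isocontour()].
#' @return list of class `segmentation_result`: `body_mask`, `fat_mask`,
#'   `bed_mask`, `qc`.
#' @export
segment_specimen <- function(vol, seed_point, fat_win = fat_window(),
                             body_win = body_window(), empty = NULL,
                             bed_threshold = -900, effective_lo = -480,
                             qc_floor = 33564, reference_spacing = 0.125) {
  bed <- if (!is.null(empty)) {
    check_congruent(vol, list(data = empty$data), "empty-bed scan")
    bed_mask_from_empty_scan(empty, threshold = bed_threshold)
  } else voxel_mask(array(FALSE, dim(vol$data)), "bed")
  body <- body_isocontour(vol, seed_point, window = body_win, exclude = bed,
                          effective_lo = effective_lo, qc_floor = qc_floor,
                          reference_spacing = reference_spacing)
  fat <- segment_window(vol, fat_win, within = body)
  qc <- attr(body, "qc")
  qc$fat_n_voxels <- n_voxels(fat)
  qc$window_overlap_warning <- fat_win$hi >= 40  # lean tissue plausibly inside
  structure(list(body_mask = body, fat_mask = fat, bed_mask = bed, qc = qc),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: body %d voxels, fat %d voxels, bed %d voxels\n",
              n_voxels(x$body_mask), n_voxels(x$fat_mask), n_voxels(x$bed_mask)))
  if (isTRUE(x$qc$below_floor))
    cat(sprintf("  QC: body component below floor (%d < %.0f)\n",
                x$qc$n_voxels, x$qc$floor))
  invisible(x)
}
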