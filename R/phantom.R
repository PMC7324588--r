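# Digital fish phantoms with known ground truth.
#
# The fish is a stylised ellipsoid lying along the x axis, containing a
# swim-bladder gas lumen, a spine, an eye, and fat depots (subcutaneous
# shell, visceral ellipsoid, optional head depot). A homogeneous bed slab
# sits under the ventral surface. Geometry is deterministic given the spec;
# randomness enters only through voxel noise, so ground-truth labels are
# exact. Tissue boundaries are placed by quantiles of ellipsoidal radius
# fields, which makes the labelled body volume and fat fraction match their
# targets to within one voxel.

TISSUE_CODES <- c(background_air = 0L, soft_tissue = 1L, fat = 2L, bone = 3L,
                  swimbladder_air = 4L, bed = 5L, eye = 6L)

#' Default tissue attenuation model
#'
#' Mean and standard deviation of Hounsfield units per tissue compartment.
#' The fat mean (-115 HU) is the ex-vivo pure-fat calibration constant; air
#' is -1000 HU by definition of the HU scale. The remaining tissue means are
#' package parameters chosen to be plausible for a teleost, not measured
#' values. Note that the default soft-tissue mean (+40 HU) lies inside the
#' fat density window's upper bound (+50 HU): this is deliberate, so that
#' window segmentation is imperfect in the same way it is on real fish,
#' where lean-tissue densities overlap the window. Analyses that need clean
#' tissue separation raise `soft_tissue` to +80 HU.
#'
#' @return data.frame with columns `tissue`, `mean_hu`, `sd_hu`, `code`.
#' @export
tissue_table <- function() {
  data.frame(
    tissue  = c("background_air", "soft_tissue", "fat", "bone",
                "swimbladder_air", "bed", "eye"),
    mean_hu = c(-1000, 40, -115, 1500, -1000, 300, 10),
    sd_hu   = c(15, 15, 15, 15, 15, 15, 15),
    code    = as.integer(c(0, 1, 2, 3, 4, 5, 6)),
    stringsAsFactors = FALSE)
}

#' Specify a digital fish phantom
#'
#' @param shape grid dimension (nz, ny, nx).
#' @param spacing isotropic voxel spacing in mm. Desk-scale phantoms default
#'   to a coarse 2 mm grid that preserves realistic whole-fish volumes (tens
#'   of cm^3) within memory and runtime reach; the segmentation logic is
#'   scale-free.
#' @param condition one of "control", "fed", "starved" (cohort parameter
#'   presets live in [make_cohort()]; for a single phantom the condition is
#'   descriptive metadata).
#' @param total_volume_cm3 target true body volume (swim-bladder lumen
#'   excluded), cm^3.
#' @param length_cm fish length in cm; sets the body semi-axis along x.
#' @param target_fat_fraction target fat volume as % of body volume, in
#'   (0, 100).
#' @param depots named numeric vector of fat-depot shares (must include
#'   names among "subcutaneous", "visceral", "head"); normalised to sum 1.
#' @param tissues tissue model data.frame as from [tissue_table()].
#' @param noise_sd if non-NULL, overrides `sd_hu` for every tissue (HU).
#' @param blur_sigma Gaussian blur sigma in voxels applied after noise, as a
#'   partial-volume surrogate.
#' @param bed_thickness_mm thickness of the scanner-bed slab.
#' @param dorsoventral_aspect ratio of the z to y body semi-axis.
#' @param seed integer seed fixing the noise realisation.
#' @return A `phantom_spec` list.
#' @export
fish_phantom_spec <- function(shape = c(64, 64, 112), spacing = 2,
                              condition = "control",
                              total_volume_cm3 = 33.792,
                              length_cm = 12.566,
                              target_fat_fraction = 48.737,
                              depots = c(subcutaneous = 0.45, visceral = 0.55),
                              tissues = tissue_table(),
                              noise_sd = NULL,
                              blur_sigma = 0.6,
                              bed_thickness_mm = 4,
                              dorsoventral_aspect = 1.45,
                              seed = 1L) {
  condition <- match.arg(condition, c("control", "fed", "starved"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) stop("`shape` must be 3 dims >= 16")
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (!(target_fat_fraction > 0 && target_fat_fraction < 100))
    stop("`target_fat_fraction` must be in (0, 100)")
  if (is.null(names(depots)) || !all(names(depots) %in% c("subcutaneous", "visceral", "head")))
    stop("`depots` must be named among subcutaneous/visceral/head")
  if (any(depots < 0) || sum(depots) <= 0) stop("depot shares must be non-negative")
  if (!is.null(noise_sd) && (!is.numeric(noise_sd) || noise_sd < 0))
    stop("`noise_sd` must be >= 0")
  if (!is.numeric(blur_sigma) || blur_sigma < 0) stop("`blur_sigma` must be >= 0")
  if (!is.null(noise_sd)) tissues$sd_hu <- noise_sd
  spec <- list(shape = shape, spacing = spacing, condition = condition,
               total_volume_cm3 = total_volume_cm3, length_cm = length_cm,
               target_fat_fraction = target_fat_fraction,
               depots = depots / sum(depots), tissues = tissues,
               blur_sigma = blur_sigma, bed_thickness_mm = bed_thickness_mm,
               dorsoventral_aspect = dorsoventral_aspect,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec (%s): %s voxels at %.3g mm, body %.2f cm^3, fat %.2f%%, seed %d\n",
              x$condition, paste(x$shape, collapse = "x"), x$spacing,
              x$total_volume_cm3, x$target_fat_fraction, x$seed))
  invisible(x)
}

# Normalised squared ellipsoid radius field over the grid, in mm world
# coordinates. centre/semi are (z, y, x) in mm.
ellipsoid_field <- function(coords, centre, semi) {
  z2 <- ((coords$z - centre[1]) / semi[1])^2
  y2 <- ((coords$y - centre[2]) / semi[2])^2
  x2 <- ((coords$x - centre[3]) / semi[3])^2
  outer(outer(z2, y2, "+"), x2, "+")
}

grid_coords <- function(shape, spacing) {
  list(z = (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing,
       y = (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing,
       x = (seq_len(shape[3]) - (shape[3] + 1) / 2) * spacing)
}

# Deterministic label map for a spec. Returns list(labels, counts, rho, ...).
phantom_geometry <- function(spec) {
  shape <- spec$shape
  sp <- spec$spacing
  co <- grid_coords(shape, sp)
  voxvol <- sp^3

  bx <- spec$length_cm * 10 / 2
  prod_zy <- spec$total_volume_cm3 * 1000 / (4 / 3 * pi * bx)
  if (prod_zy <= 0) stop("invalid body volume/length combination")
  by <- sqrt(prod_zy / spec$dorsoventral_aspect)
  bz <- spec$dorsoventral_aspect * by
  semi <- c(bz, by, bx)
  extent <- shape * sp
  if (2 * bx > 0.95 * extent[3] || 2 * by > 0.9 * extent[2] ||
      2 * bz + spec$bed_thickness_mm > 0.8 * extent[1])
    stop("body ellipsoid does not fit the grid; enlarge `shape` or `spacing`")

  rho <- ellipsoid_field(co, c(0, 0, 0), semi)

  # swim-bladder lumen: dorsal, mid-body
  bladder <- ellipsoid_field(co, c(0.30 * bz, 0, 0.05 * bx),
                             c(0.30 * bz, 0.45 * by, 0.28 * bx)) <= 1

  # body surface placed so that body voxels (lumen excluded) hit the target
  # count exactly (to one voxel)
  target_n <- round(spec$total_volume_cm3 * 1000 / voxvol)
  candidates <- !bladder
  rho_c <- rho[candidates]
  if (target_n > length(rho_c)) stop("body volume exceeds the grid")
  r_cut <- sort(rho_c, partial = target_n)[target_n]
  if (r_cut > 1.35 || r_cut < 0.7)
    stop("body surface calibration failed; inconsistent volume/length")
  body <- candidates & (rho <= r_cut)
  if (sum(body) > target_n) {  # grid symmetry can tie several surface voxels
    idx <- which(body)
    body[idx[order(rho[idx])][-seq_len(target_n)]] <- FALSE
  }
  # drop surface voxels only diagonally attached, so the body is a single
  # 6-connected component (what a seeded isocontour can recover)
  seed_lin <- which(body)[which.min(rho[body])] - 1L
  body <- array(.flood_fill_6(as.vector(body), shape, seed_lin), shape)

  labels <- array(TISSUE_CODES[["background_air"]], shape)
  labels[body] <- TISSUE_CODES[["soft_tissue"]]
  labels[bladder & (rho <= r_cut)] <- TISSUE_CODES[["swimbladder_air"]]

  # spine: elongated ellipsoid along x, slightly dorsal
  spine <- ellipsoid_field(co, c(0.12 * bz, 0, 0),
                           c(0.15 * bz, 0.15 * bz, 0.88 * bx)) <= 1
  labels[body & spine] <- TISSUE_CODES[["bone"]]

  # eye: sphere near the head (positive x)
  eye <- ellipsoid_field(co, c(0.15 * bz, 0, 0.86 * bx), rep(0.2 * bz, 3)) <= 1
  labels[body & eye & labels != TISSUE_CODES[["bone"]]] <- TISSUE_CODES[["eye"]]

  n_body <- sum(body)
  # fat depots carved out of soft tissue
  soft <- labels == TISSUE_CODES[["soft_tissue"]]
  needed <- round(spec$target_fat_fraction / 100 * n_body)
  if (needed > sum(soft))
    stop("fat depots cannot fit inside the body at the requested fraction")
  shares <- spec$depots
  n_per <- round(shares * needed)
  n_per[length(n_per)] <- needed - sum(n_per[-length(n_per)])

  fat <- array(FALSE, shape)
  remaining <- soft
  for (depot in names(shares)) {
    k <- n_per[[depot]]
    if (k <= 0) next
    field <- switch(depot,
      subcutaneous = -rho,  # largest rho first = outermost soft voxels
      visceral = ellipsoid_field(co, c(-0.38 * bz, 0, 0.15 * bx),
                                 c(0.55 * bz, 0.65 * by, 0.45 * bx)),
      head = ellipsoid_field(co, c(0, 0, 0.75 * bx),
                             c(0.5 * bz, 0.5 * by, 0.2 * bx)))
    vals <- field[remaining]
    if (k > length(vals))
      stop("fat depot '", depot, "' cannot fit inside the body")
    cut <- sort(vals, partial = k)[k]
    sel <- remaining & (field <= cut)
    # ties could overshoot by a few voxels; trim deterministically
    if (sum(sel) > k) {
      idx <- which(sel)
      sel[idx[order(field[idx])][-seq_len(k)]] <- FALSE
    }
    fat <- fat | sel
    remaining <- remaining & !sel
  }
  labels[fat] <- TISSUE_CODES[["fat"]]

  # bed slab under the ventral surface, separated from the fish by a
  # one-voxel air gap (the tissue paper of the scanning protocol)
  zmin <- min(which(apply(body, 1, any)))
  nb <- max(1L, round(spec$bed_thickness_mm / sp))
  if (zmin - nb - 1L < 1L) stop("no room for the bed slab below the body")
  bed_layers <- seq.int(zmin - nb - 1L, zmin - 2L)
  bg <- labels == TISSUE_CODES[["background_air"]]
  bed_sel <- array(FALSE, shape)
  bed_sel[bed_layers, , ] <- TRUE
  labels[bed_sel & bg] <- TISSUE_CODES[["bed"]]

  n_fat <- sum(labels == TISSUE_CODES[["fat"]])
  list(labels = labels, semi = semi, r_cut = r_cut, bed_layers = bed_layers,
       n_body = n_body, n_fat = n_fat, voxvol = voxvol)
}

render_hu <- function(labels, tissues, blur_sigma, spacing) {
  mu <- tissues$mean_hu[match(as.vector(labels), tissues$code)]
  sdv <- tissues$sd_hu[match(as.vector(labels), tissues$code)]
  hu <- mu + rnorm(length(mu)) * sdv
  dim(hu) <- dim(labels)
  if (blur_sigma > 0)
    hu <- array(.gauss_blur_3d(hu, dim(labels), blur_sigma), dim(labels))
  ct_volume(hu, spacing = spacing)
}

#' Generate a digital fish phantom
#'
#' Rasterises the tissue label map for a [fish_phantom_spec()], assigns each
#' voxel its tissue mean plus Gaussian noise, and applies a Gaussian blur as
#' a partial-volume surrogate. Ground truth is computed from the unblurred
#' label map, so true volumes are exact voxel counts times the voxel volume.
#' The true body volume excludes the swim-bladder gas lumen (gas is
#' radiologically indistinguishable from background air).
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `volume` (a `ct_volume`), `truth` (a
#'   `ground_truth`: label array, true volumes in cm^3, true fat fraction in
#'   %), and `spec`.
#' @export
make_fish_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  geo <- phantom_geometry(spec)
  vol <- with_seed(spec$seed,
                   render_hu(geo$labels, spec$tissues, spec$blur_sigma, spec$spacing))
  truth <- structure(list(
    labels = geo$labels,
    body_volume_cm3 = geo$n_body * geo$voxvol / 1000,
    fat_volume_cm3 = geo$n_fat * geo$voxvol / 1000,
    fat_fraction_pct = 100 * geo$n_fat / geo$n_body,
    n_body = geo$n_body, n_fat = geo$n_fat,
    bed_layers = geo$bed_layers), class = "ground_truth")
  list(volume = vol, truth = truth, spec = spec)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: body %.3f cm^3 (%d voxels), fat %.3f cm^3 (%.3f%%)\n",
              x$body_volume_cm3, x$n_body, x$fat_volume_cm3, x$fat_fraction_pct))
  invisible(x)
}

#' Generate the matching empty-bed scan
#'
#' Same grid and bed geometry as the phantom from `spec`, with the fish
#' removed — the reference scan used to exclude bed voxels from the body
#' isocontour. Uses an independent noise realisation (seed offset by 1).
#'
#' @param spec a `phantom_spec`.
#' @return A `ct_volume`.
#' @export
make_empty_bed_scan <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  geo <- phantom_geometry(spec)
  labels <- array(TISSUE_CODES[["background_air"]], spec$shape)
  bed_sel <- array(FALSE, spec$shape)
  bed_sel[geo$bed_layers, , ] <- TRUE
  labels[bed_sel] <- TISSUE_CODES[["bed"]]
  with_seed(spec$seed + 1L,
            render_hu(labels, spec$tissues, spec$blur_sigma, spec$spacing))
}

#' Generate an ex-vivo fat-block phantom
#'
#' A rectangular block of pure fat surrounded by background air, emulating
#' dissected visceral fat imaged on its own for calibration of the pure-fat
#' HU value. No blur is applied: calibration ROIs are drawn well inside the
#' block, where partial-volume effects are absent anyway.
#'
#' @param mean_hu fat mean attenuation (HU).
#' @param sd_hu voxel noise SD (HU).
#' @param shape grid dimension (nz, ny, nx).
#' @param spacing isotropic voxel spacing in mm (default the scanner's
#'   native 0.125 mm).
#' @param seed integer noise seed.
#' @param block_fraction fraction of each grid axis occupied by the block.
#' @return A `ct_volume` with an extra `block_semi` element giving the block
#'   half-extent (mm) around the world origin.
#' @export
make_exvivo_fat_phantom <- function(mean_hu = -115, sd_hu = 15,
                                    shape = c(48, 48, 48), spacing = 0.125,
                                    seed = 1L, block_fraction = 0.6) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("`shape` too small for a fat block")
  if (sd_hu < 0) stop("`sd_hu` must be >= 0")
  if (!(block_fraction > 0 && block_fraction < 1))
    stop("`block_fraction` must be in (0, 1)")
  co <- grid_coords(shape, spacing)
  semi <- shape * spacing / 2 * block_fraction
  inz <- abs(co$z) <= semi[1]
  iny <- abs(co$y) <= semi[2]
  inx <- abs(co$x) <= semi[3]
  block <- outer(outer(inz, iny, "&"), inx, "&")
  vol <- with_seed(as.integer(seed), {
    hu <- array(-1000, shape)
    hu[block] <- mean_hu + rnorm(sum(block)) * sd_hu
    ct_volume(hu, spacing = spacing)
  })
  vol$block_semi <- semi
  vol
}

cohort_params <- function(condition) {
  switch(condition,
    control = list(volume = c(33.792, 1.164), fat = c(48.737, 4.917),
                   weight = c(26.385, 1.950), size = c(12.566, 0.625)),
    fed     = list(volume = c(71.289, 0.655), fat = c(44.618, 1.331),
                   weight = c(53.000, 6.931), size = c(16.000, 1.000)),
    starved = list(volume = c(37.101, 2.077), fat = c(49.172, 3.080),
                   weight = c(19.660, 2.200), size = c(12.416, 1.625)))
}

# Gaussian truncated to [mean - 3 sd, mean + 3 sd] and to positive values:
# cohort fish are size-graded, and bounded draws guarantee every drawn fish
# fits its grid.
rtrunc_pos <- function(n, mean, sd) {
  lo <- max(.Machine$double.eps, mean - 3 * sd)
  hi <- mean + 3 * sd
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate a phantom cohort
#'
#' Draws per-fish body volume, fat fraction, weight and length from
#' condition-specific Gaussians (defaults are the biometric means and SDs of
#' the fed, starved and baseline control groups), truncated to positive, and
#' builds one phantom per fish. Per-fish phantom seeds are derived
#' deterministically from `base_seed`.
#'
#' @param condition "control", "fed" or "starved".
#' @param n number of fish (>= 2).
#' @param base_seed integer master seed for the cohort.
#' @param params optional override of the condition parameter list (elements
#'   `volume`, `fat`, `weight`, `size`, each `c(mean, sd)`).
#' @param ... further arguments passed to [fish_phantom_spec()] (for
#'   example `noise_sd`, `blur_sigma`, `tissues`, `shape`, `spacing`).
#' @return list of per-fish lists: `volume`, `truth`, `spec`, `meta`
#'   (id, condition, weight_g, length_cm).
#' @export
make_cohort <- function(condition = c("control", "fed", "starved"), n = 6,
                        base_seed = 1L, params = NULL, ...) {
  condition <- match.arg(condition)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2")
  p <- params %||% cohort_params(condition)
  draws <- with_seed(as.integer(base_seed), list(
    volume = rtrunc_pos(n, p$volume[1], p$volume[2]),
    fat    = pmin(pmax(rtrunc_pos(n, p$fat[1], p$fat[2]), 1), 95),
    weight = rtrunc_pos(n, p$weight[1], p$weight[2]),
    size   = rtrunc_pos(n, p$size[1], p$size[2])))
  lapply(seq_len(n), function(i) {
    spec <- fish_phantom_spec(condition = condition,
                              total_volume_cm3 = draws$volume[i],
                              length_cm = draws$size[i],
                              target_fat_fraction = draws$fat[i],
                              seed = as.integer(base_seed) + i, ...)
    ph <- make_fish_phantom(spec)
    ph$meta <- list(id = sprintf("%s_%02d", condition, i),
                    condition = condition,
                    weight_g = draws$weight[i],
                    length_cm = draws$size[i])
    ph
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
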