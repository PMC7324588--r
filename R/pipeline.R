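# End-to-end orchestration: generate or ingest volumes, calibrate, reduce,
# segment, quantify, compare, report. Fully deterministic under the
# configured seed.

#' Default calibration ROIs for an ex-vivo fat block
#'
#' Places `n` spherical ROIs well inside the fat block of an ex-vivo
#' phantom (or around the world origin if the volume carries no block
#' metadata), spread along the block diagonal so they sample different
#' noise realisations.
#'
#' @param vol a `ct_volume`, ideally from [make_exvivo_fat_phantom()].
#' @param n number of ROIs.
#' @param semi_mm ROI semi-axes in mm (default 0.6 mm spheres, which hold
#'   >400 voxels at 0.125 mm spacing).
#' @return list of `ellipsoid_roi`.
#' @export
default_calibration_rois <- function(vol, n = 6, semi_mm = c(0.6, 0.6, 0.6)) {
  semi_mm <- if (length(semi_mm) == 1L) rep(semi_mm, 3L) else semi_mm
  block <- vol$block_semi %||% (dim(vol$data) * vol$spacing / 2 * 0.5)
  reach <- pmax(block - semi_mm - 2 * vol$spacing, 0)
  lapply(seq_len(n), function(i) {
    u <- (i - (n + 1) / 2) / max(n - 1, 1) * 1.6   # in (-0.8, 0.8)
    ellipsoid_roi(center = u * reach * c(1, -1, 1) ^ i, semi_axes = semi_mm)
  })
}

#' Pick a body seed voxel automatically
#'
#' Chooses a deterministic seed for the body isocontour: among voxels with
#' clearly soft-tissue-like HU (default \[-50, 150\]), the voxel closest to
#' their centroid. Robust to the seed landing in gas lumina or background.
#'
#' @param vol a `ct_volume`.
#' @param hu_range HU interval regarded as unambiguous tissue.
#' @return voxel index (z, y, x), 1-based.
#' @export
auto_seed_point <- function(vol, hu_range = c(-50, 150)) {
  m <- vol$data >= hu_range[1] & vol$data <= hu_range[2]
  # drop one-voxel-thin shells (partial-volume transition bands at, e.g.,
  # the air/bed edge sweep through tissue HU): erode once if possible
  eroded <- m & !dilate6(!m)
  if (any(eroded)) m <- eroded
  cand <- which(m)
  if (length(cand) == 0L) stop("no voxels in the tissue HU range; cannot place a seed")
  d <- dim(vol$data)
  idx <- arrayInd(cand, d)
  ctr <- colMeans(idx)
  best <- which.min((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2 + (idx[, 3] - ctr[3])^2)
  as.integer(idx[best, ])
}

#' Build a pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis in one validated
#' list. Defaults follow the published protocol where a printed value
#' exists (body window -1000..+2500 HU, fat upper bound +50 HU, ROI floor
#' >400 voxels, QC floor 33,564 voxels at 0.125 mm, alpha 0.05); the fat
#' window's lower bound is calibrated at run time, never hard-coded.
#'
#' @param mode "phantom" (generate cohorts) or "files" (read volumes).
#' @param conditions phantom cohorts to generate (any of "control", "fed",
#'   "starved"); the first two are compared when there are at least two.
#' @param n_per_group specimens per cohort (>= 2).
#' @param phantom_args list of extra arguments for [make_cohort()] /
#'   [fish_phantom_spec()] (e.g. `noise_sd`, `blur_sigma`, `tissues`,
#'   `shape`, `spacing`).
#' @param files for `mode = "files"`: list with `volumes` (paths),
#'   optional `conditions` (one per volume), optional `empty` (empty-bed
#'   scan path), optional `format`.
#' @param reduction_factor integer mean-pooling factor applied before
#'   segmentation (1 = no reduction).
#' @param calibration list: `mean_hu`, `sd_hu`, `shape`, `spacing`,
#'   `n_rois`, `roi_semi_mm`, `min_voxels` for the ex-vivo stage.
#' @param fat_upper fixed upper bound of the fat window (HU).
#' @param body_lo,body_hi printed body window (HU).
#' @param effective_lo effective lower bound used for region growing (HU).
#' @param use_bed whether to build and exclude a bed mask.
#' @param bed_threshold HU threshold for the empty-bed scan.
#' @param qc_floor,reference_spacing body-size QC floor and the spacing it
#'   refers to.
#' @param alpha significance level for group comparison.
#' @param seed master seed; all stage seeds derive from it.
#' @param seed_point optional explicit body seed voxel (z, y, x) for
#'   file-mode volumes; NULL for automatic placement.
#' @param output_dir directory for CSV/NIfTI/manifest outputs; NULL writes
#'   nothing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("phantom", "files"),
                            conditions = c("fed", "starved"),
                            n_per_group = 6,
                            phantom_args = list(),
                            files = NULL,
                            reduction_factor = 1,
                            calibration = list(),
                            fat_upper = 50,
                            body_lo = -1000, body_hi = 2500,
                            effective_lo = -480,
                            use_bed = TRUE,
                            bed_threshold = -900,
                            qc_floor = 33564,
                            reference_spacing = 0.125,
                            alpha = 0.05,
                            seed = 1L,
                            seed_point = NULL,
                            output_dir = NULL) {
  cal <- utils::modifyList(
    list(mean_hu = -115, sd_hu = 15, shape = c(48, 48, 48), spacing = 0.125,
         n_rois = 6, roi_semi_mm = 0.6, min_voxels = 400),
    calibration)
  cfg <- list(mode = match.arg(mode), conditions = conditions,
              n_per_group = n_per_group, phantom_args = phantom_args,
              files = files, reduction_factor = reduction_factor,
              calibration = cal, fat_upper = fat_upper,
              body_lo = body_lo, body_hi = body_hi,
              effective_lo = effective_lo, use_bed = use_bed,
              bed_threshold = bed_threshold, qc_floor = qc_floor,
              reference_spacing = reference_spacing, alpha = alpha,
              seed = as.integer(seed), seed_point = seed_point,
              output_dir = output_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of the configuration and returns the problems
#' found (an empty character vector when the configuration is valid);
#' nothing is raised.
#'
#' @param config a `pipeline_config`.
#' @return character vector of problems, each naming the offending field.
#' @export
validate_config <- function(config) {
  p <- character(0)
  add <- function(msg) p <<- c(p, msg)
  if (!config$mode %in% c("phantom", "files")) add("mode: must be 'phantom' or 'files'")
  if (config$mode == "phantom") {
    if (length(config$conditions) < 1L ||
        !all(config$conditions %in% c("control", "fed", "starved")))
      add("conditions: must be among control/fed/starved")
    if (!is.numeric(config$n_per_group) || config$n_per_group < 2)
      add("n_per_group: must be >= 2")
  } else {
    if (is.null(config$files) || is.null(config$files$volumes) ||
        length(config$files$volumes) < 1L)
      add("files: volumes must list at least one path")
    else if (!all(file.exists(config$files$volumes)))
      add(paste0("files: missing volume file(s): ",
                 paste(config$files$volumes[!file.exists(config$files$volumes)],
                       collapse = ", ")))
    if (!is.null(config$files$empty) && !file.exists(config$files$empty))
      add("files: empty-bed scan file does not exist")
  }
  rf <- config$reduction_factor
  if (!is.numeric(rf) || length(rf) != 1L || is.na(rf) || rf < 1 || rf != round(rf))
    add("reduction_factor: must be a positive integer")
  if (!is.numeric(config$fat_upper)) add("fat_upper: must be numeric")
  if (config$body_lo >= config$body_hi)
    add("body window: lo must be < hi")
  if (config$effective_lo >= config$body_hi)
    add("effective_lo: must be below the body window's upper bound")
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    add("alpha: must be in (0, 1)")
  if (!is.numeric(config$seed) || is.na(config$seed))
    add("seed: must be an integer")
  if (!is.numeric(config$calibration$min_voxels) || config$calibration$min_voxels < 1)
    add("calibration$min_voxels: must be >= 1")
  if (config$calibration$mean_hu >= config$fat_upper)
    add("fat window: calibrated lower bound would be >= upper bound")
  p
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' The file holds any subset of the arguments of [pipeline_config()];
#' unspecified fields take their defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647   # djb2 mod Mersenne prime
  sprintf("%08x", h)
}

reduce_seed_point <- function(seed_point, factor, dims) {
  sp <- pmax(1L, as.integer(floor((seed_point - 1L) / factor) + 1L))
  pmin(sp, dims)
}

segment_and_quantify <- function(vol, empty, config, id, meta, truth = NULL) {
  f <- as.integer(config$reduction_factor)
  rvol <- reduce_volume(vol, f)
  rempty <- if (!is.null(empty)) reduce_volume(empty, f) else NULL
  seed_point <- if (!is.null(config$seed_point))
    reduce_seed_point(as.integer(config$seed_point), f, dim(rvol$data))
  else auto_seed_point(rvol)
  seg <- segment_specimen(
    rvol, seed_point,
    fat_win = config$fat_win,
    body_win = density_window(config$body_lo, config$body_hi),
    empty = rempty, bed_threshold = config$bed_threshold,
    effective_lo = config$effective_lo, qc_floor = config$qc_floor,
    reference_spacing = config$reference_spacing)
  rec <- specimen_volumetrics(seg, rvol$spacing, id = id, meta = meta)
  if (!is.null(truth)) {
    rec$true_total_cm3 <- truth$body_volume_cm3
    rec$true_fat_cm3 <- truth$fat_volume_cm3
    rec$true_fat_fraction_pct <- truth$fat_fraction_pct
  }
  list(record = rec, seg = seg, volume = rvol)
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow: ex-vivo fat calibration, phantom cohort
#' generation (or volume ingestion), optional image reduction, bed
#' exclusion, body isocontour, fat window segmentation, per-specimen
#' volumetrics, cohort summaries and, with two or more cohorts, Student's
#' t-tests per parameter. Re-running with the same configuration
#' reproduces every number bit for bit.
#'
#' @param config a `pipeline_config`.
#' @return A `ctfat_report`: `calibration` (`fat_calibration`),
#'   `fat_window`, `records` (per-specimen data.frame), `summaries` (per
#'   condition), `comparison` (or NULL), `segmentations`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))

  # calibration stage
  cal_cfg <- config$calibration
  exvivo <- make_exvivo_fat_phantom(mean_hu = cal_cfg$mean_hu,
                                    sd_hu = cal_cfg$sd_hu,
                                    shape = cal_cfg$shape,
                                    spacing = cal_cfg$spacing,
                                    seed = config$seed + 101L)
  rois <- default_calibration_rois(exvivo, n = cal_cfg$n_rois,
                                   semi_mm = cal_cfg$roi_semi_mm)
  calibration <- calibrate_fat_hu(exvivo, rois, min_voxels = cal_cfg$min_voxels)
  config$fat_win <- build_fat_window(calibration, upper = config$fat_upper)

  # specimens
  results <- list()
  if (config$mode == "phantom") {
    for (k in seq_along(config$conditions)) {
      cond <- config$conditions[k]
      cohort <- do.call(make_cohort,
                        c(list(condition = cond, n = config$n_per_group,
                               base_seed = config$seed + 1000L * k),
                          config$phantom_args))
      for (ph in cohort) {
        empty <- if (config$use_bed) make_empty_bed_scan(ph$spec) else NULL
        results[[ph$meta$id]] <- segment_and_quantify(
          ph$volume, empty, config, id = ph$meta$id, meta = ph$meta,
          truth = ph$truth)
      }
    }
  } else {
    paths <- config$files$volumes
    conds <- config$files$conditions %||% rep(NA_character_, length(paths))
    if (length(conds) == 1L) conds <- rep(conds, length(paths))
    empty <- if (!is.null(config$files$empty))
      read_volume(config$files$empty, format = config$files$format %||% NULL)
    else NULL
    for (i in seq_along(paths)) {
      vol <- read_volume(paths[i], format = config$files$format %||% NULL)
      id <- sub("\\.(nii(\\.gz)?|mha|mhd)$", "", basename(paths[i]), ignore.case = TRUE)
      results[[id]] <- segment_and_quantify(
        vol, empty, config, id = id, meta = list(condition = conds[i]))
    }
  }

  records <- do.call(rbind, lapply(results, `[[`, "record"))
  rownames(records) <- NULL
  by_cond <- split(records, records$condition, drop = TRUE)
  summaries <- lapply(by_cond, function(r) if (nrow(r) >= 2) summarize_cohort(r) else NULL)
  summaries <- Filter(Negate(is.null), summaries)
  comparison <- NULL
  cond_order <- unique(records$condition)
  cond_order <- cond_order[!is.na(cond_order)]
  if (length(cond_order) >= 2 &&
      all(cond_order[1:2] %in% names(summaries)))
    comparison <- compare_cohorts(summaries[[cond_order[1]]],
                                  summaries[[cond_order[2]]],
                                  alpha = config$alpha)

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  manifest <- list(
    package = "ctfat",
    version = as.character(utils::packageVersion("ctfat")),
    seed = config$seed,
    config_hash = config_hash(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE,
                                              digits = NA, force = TRUE)),
    reduction_factor = config$reduction_factor,
    fat_window = c(config$fat_win$lo, config$fat_win$hi),
    calibration_hu = calibration$value_hu,
    n_specimens = nrow(records),
    complete = TRUE)

  report <- structure(list(calibration = calibration,
                           fat_window = config$fat_win,
                           records = records,
                           summaries = summaries,
                           comparison = comparison,
                           segmentations = lapply(results, `[[`, "seg"),
                           volumes = lapply(results, `[[`, "volume"),
                           manifest = manifest,
                           config = config),
                      class = "ctfat_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$calibration$per_roi,
            file.path(dir, "calibration.csv"), row.names = FALSE)
  write.csv(report$records, file.path(dir, "volumetrics.csv"), row.names = FALSE)
  for (cond in names(report$summaries))
    write.csv(report$summaries[[cond]]$table,
              file.path(dir, sprintf("cohort_summary_%s.csv", cond)),
              row.names = FALSE)
  if (!is.null(report$comparison)) {
    tab <- report$comparison$table
    tab$flag <- ifelse(tab$significant, "*", "")
    write.csv(tab, file.path(dir, "ttests.csv"), row.names = FALSE)
  }
  for (id in names(report$segmentations)) {
    seg <- report$segmentations[[id]]
    lab <- array(0, dim(seg$body_mask$data))
    lab[seg$body_mask$data] <- 1
    lab[seg$fat_mask$data] <- 2
    lab[seg$bed_mask$data] <- 3
    vol <- report$volumes[[id]]
    write_volume(ct_volume(lab, spacing = vol$spacing, origin = vol$origin),
                 file.path(dir, sprintf("labels_%s.nii.gz", id)))
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ctfat_report <- function(x, ...) {
  cat("ctfat_report\n")
  cat(sprintf("  calibration : %d HU (unrounded %.3f)\n",
              x$calibration$value_hu, x$calibration$value_hu_unrounded))
  cat(sprintf("  fat window  : [%.3f, %g] HU\n", x$fat_window$lo, x$fat_window$hi))
  cat(sprintf("  specimens   : %d\n", nrow(x$records)))
  for (cond in names(x$summaries)) {
    tab <- x$summaries[[cond]]$table
    ff <- tab[tab$parameter == "fat_fraction_pct", ]
    tv <- tab[tab$parameter == "total_volume_cm3", ]
    cat(sprintf("  %-10s: total %.3f ± %.3f cm^3, fat %.3f ± %.3f %%\n",
                cond, tv$mean, tv$sd, ff$mean, ff$sd))
  }
  if (!is.null(x$comparison)) {
    sig <- x$comparison$table$parameter[x$comparison$table$significant]
    cat(sprintf("  significant : %s (alpha = %g)\n",
                if (length(sig)) paste(sig, collapse = ", ") else "none",
                x$comparison$alpha))
  }
  invisible(x)
}

#' @export
summary.ctfat_report <- function(object, ...) {
  print(object)
  cat("\nPer-specimen volumetrics:\n")
  print(object$records, row.names = FALSE)
  if (!is.null(object$comparison)) {
    cat("\nGroup comparison:\n")
    print(object$comparison)
  }
  invisible(object)
}
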