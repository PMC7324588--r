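# Voxel volumetrics and cohort summary tables.

#' Volume of a mask in cm^3
#'
#' @param mask a `voxel_mask` (or logical array).
#' @param spacing voxel spacing in mm (1 or 3 values).
#' @return `count * prod(spacing) / 1000`, in cm^3.
#' @export
mask_volume_cm3 <- function(mask, spacing) {
  n <- if (inherits(mask, "voxel_mask")) n_voxels(mask) else sum(mask)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  n * prod(spacing) / 1000
}

#' Fat fraction in percent
#'
#' @param fat_cm3 fat volume, cm^3.
#' @param total_cm3 total body volume, cm^3 (> 0).
#' @return `100 * fat_cm3 / total_cm3`.
#' @export
fat_fraction_pct <- function(fat_cm3, total_cm3) {
  if (any(total_cm3 <= 0)) stop("`total_cm3` must be > 0")
  if (any(fat_cm3 < 0)) stop("`fat_cm3` must be >= 0")
  if (any(fat_cm3 > total_cm3)) stop("`fat_cm3` cannot exceed `total_cm3`")
  100 * fat_cm3 / total_cm3
}

#' Per-specimen volumetrics record
#'
#' Collects total body volume, fat volume and fat fraction for one
#' specimen from its segmentation masks.
#'
#' @param seg a `segmentation_result` (or a list with `body_mask`,
#'   `fat_mask`, optional `qc`).
#' @param spacing voxel spacing in mm.
#' @param id specimen identifier.
#' @param meta optional list of biometric metadata (`weight_g`,
#'   `length_cm`, `condition`).
#' @return One-row data.frame of class `volumetrics_record`.
#' @export
specimen_volumetrics <- function(seg, spacing, id = "specimen", meta = NULL) {
  total <- mask_volume_cm3(seg$body_mask, spacing)
  fat <- mask_volume_cm3(seg$fat_mask, spacing)
  rec <- data.frame(
    id = id,
    condition = meta$condition %||% NA_character_,
    weight_g = meta$weight_g %||% NA_real_,
    length_cm = meta$length_cm %||% NA_real_,
    total_volume_cm3 = total,
    fat_volume_cm3 = fat,
    fat_fraction_pct = fat_fraction_pct(fat, total),
    body_voxels = n_voxels(seg$body_mask),
    fat_voxels = n_voxels(seg$fat_mask),
    qc_below_floor = isTRUE(seg$qc$below_floor),
    stringsAsFactors = FALSE)
  class(rec) <- c("volumetrics_record", class(rec))
  rec
}

cohort_parameters <- c("weight_g", "length_cm", "total_volume_cm3",
                       "fat_volume_cm3", "fat_fraction_pct")

#' Summarise a cohort of volumetrics records
#'
#' Mean and sample SD (n - 1 denominator) per biometric parameter across
#' specimens. The cohort fat fraction is the mean of the per-specimen
#' percentages, not the ratio of summed volumes: normalising each specimen
#' to its own total volume first makes the summary independent of absolute
#' body size.
#'
#' @param records data.frame of per-specimen records (rows from
#'   [specimen_volumetrics()], stacked), or a list of such records.
#' @return A `cohort_summary`: data.frame with `parameter`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_cohort <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (nrow(records) < 2L) stop("need at least 2 records to summarise a cohort")
  pars <- intersect(cohort_parameters, names(records))
  pars <- pars[vapply(pars, function(p) !all(is.na(records[[p]])), logical(1))]
  out <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(records[[p]]), numeric(1)),
    sd = vapply(pars, function(p) sd(records[[p]]), numeric(1)),
    n = nrow(records),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out, records = records), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary (n = %d): mean ± SD\n", x$table$n[1]))
  with(x$table, for (i in seq_along(parameter))
    cat(sprintf("  %-18s %8.3f ± %.3f\n", parameter[i], mean[i], sd[i])))
  invisible(x)
}
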