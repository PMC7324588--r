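# Shared fixtures, all generated in code.

# Tissue model with lean tissue moved clearly outside the fat window, for
# tests that need clean fat/soft separation.
clean_tissues <- function() {
  tis <- tissue_table()
  tis$mean_hu[tis$tissue %in% c("soft_tissue", "eye")] <- 80
  tis
}

# Control-sized fish on a grid small enough for fast unit tests.
test_fish_spec <- function(seed = 1, ...) {
  fish_phantom_spec(shape = c(48, 48, 96), spacing = 2, seed = seed, ...)
}

# Small fish on a fine grid: the reference for resolution-sensitive
# properties (reduction robustness), where boundary voxels are a small
# fraction of the body.
fine_fish_spec <- function(seed = 1, ...) {
  fish_phantom_spec(shape = c(64, 64, 144), spacing = 0.5,
                    total_volume_cm3 = 8, length_cm = 6, seed = seed, ...)
}

# Brute-force oracle for window segmentation: triple loop, inclusive ends.
brute_force_window <- function(data, lo, hi, within = NULL) {
  d <- dim(data)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    ok <- data[z, y, x] >= lo && data[z, y, x] <= hi
    if (!is.null(within)) ok <- ok && within[z, y, x]
    out[z, y, x] <- ok
  }
  out
}

# Brute-force 6-neighbourhood binary dilation.
brute_force_dilate6 <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!m[z, y, x]) next
    out[z, y, x] <- TRUE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      zz <- z + s[1]; yy <- y + s[2]; xx <- x + s[3]
      if (zz >= 1 && zz <= d[1] && yy >= 1 && yy <= d[2] && xx >= 1 && xx <= d[3])
        out[zz, yy, xx] <- TRUE
    }
  }
  out
}
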