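# Programmatic fixtures shared across the suite.

# Random foreground mask of mixed morphology: a few balls, one or two tubes,
# plus sparse salt voxels; deterministic under seed.
random_blob_tube_mask <- function(shape = c(24, 24, 24), seed = 1) {
  set.seed(seed)
  ext <- shape  # 1 um voxels
  m <- array(FALSE, shape)
  for (i in seq_len(3)) {
    ctr <- matrix(runif(3, 0.2, 0.8) * ext, 1)
    m <- m | rasterize_tube(ctr, runif(1, 3, 8), shape, 1)
  }
  for (i in seq_len(2)) {
    p1 <- runif(3) * ext
    p2 <- runif(3) * ext
    m <- m | rasterize_tube(rbind(p1, p2), runif(1, 2, 5), shape, 1)
  }
  salt <- sample(length(m), round(0.01 * length(m)))
  m[salt] <- TRUE
  m
}

# Exhaustive nearest-zero-set distance (independent of the package's
# transform): per zero voxel, running minimum over the whole volume.
exhaustive_distance <- function(zero_set, spacing = c(1, 1, 1), pad = FALSE) {
  d <- dim(zero_set)
  if (pad) {
    zp <- array(TRUE, d + 2L)
    zp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- zero_set
    full <- exhaustive_distance(zp, spacing, pad = FALSE)
    return(full[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)])
  }
  zi <- which(zero_set, arr.ind = TRUE)
  gz <- slice.index(zero_set, 1)
  gy <- slice.index(zero_set, 2)
  gx <- slice.index(zero_set, 3)
  best <- array(Inf, d)
  for (r in seq_len(nrow(zi))) {
    d2 <- ((gz - zi[r, 1]) * spacing[1])^2 +
      ((gy - zi[r, 2]) * spacing[2])^2 +
      ((gx - zi[r, 3]) * spacing[3])^2
    best <- pmin(best, d2)
  }
  array(sqrt(best), d)
}

# A small probe-bearing phantom spec that fits desk-size test volumes
# (geometry shrunk relative to the defaults; intensity model unchanged).
small_probe_spec <- function(seed = 1, noise_sd = 8, shape = c(24, 72, 72),
                             inflation = 1.5) {
  phantom_spec(
    shape = shape, seed = seed,
    vessel_params = list(n_vessels = 40L, target_fraction = 0.023,
                         diameter_range_um = c(3, 10), tortuosity_um = 4),
    cell_params = list(density_per_mm3 = 1e5, radius_range_um = c(2.5, 4)),
    probe_params = list(present = TRUE, width_um = 30, thickness_um = 6,
                        n_tracks = 3L, track_width_um = 4),
    calc_params = list(n_blobs = 2L, radius_range_um = c(3, 5),
                       distance_range_um = c(4, 12)),
    cavity_params = list(margin_y_um = 5, margin_x_um = 4),
    intensity_model = list(noise_sd = noise_sd),
    artifact_params = list(axis = "y", band_halfwidth_um = 10,
                           inflation = inflation))
}

small_config <- function(exclusion_um = 12) {
  pipeline_config(phantom = small_probe_spec(),
                  segmentation = segmentation_config(
                    exclusion_distance_um = exclusion_um))
}
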