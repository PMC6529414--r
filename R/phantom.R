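#' Specification for a synthetic probe-in-cortex phantom
#'
#' Defines a synthetic reconstructed-tomogram-like volume with voxel-level
#' ground truth: dark tortuous blood vessels, cell-like blobs, a flat probe
#' shaft carrying saturated metal tracks, bright calcification blobs near the
#' probe, a low-intensity cavity sheath along the shaft, Gaussian noise and a
#' directional streak band emulating the metal-induced missing-wedge
#' artifact. All randomness is drawn from a single seeded generator in a
#' fixed order (cells, vessels, calcifications, intensity noise, artifact
#' noise), so two runs with an identical spec are voxel-identical.
#'
#' Defaults emulate the study conditions at a desk-tractable scale: vessels
#' occupy ~2.3% of the volume with diameters 3-20 um, the probe shaft is
#' 380 um wide and 12 um thick, and the 8-bit class means are cavity 40,
#' vessel 60, cell 90, tissue 120, calcification 220, metal 255 (saturated)
#' with noise SD 8.
#'
#' @param shape integer voxel counts `(z, y, x)`.
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @param seed integer RNG seed fixing all randomness.
#' @param vessel_params list: `n_vessels` (maximum count), `diameter_range_um`,
#'   `diameter_meanlog`/`diameter_sdlog` (lognormal diameter draw, clipped to
#'   the range), `tortuosity_um` (SD of centerline jitter),
#'   `target_fraction` (vessels are added until this volume fraction is
#'   reached, or `NULL` to place exactly `n_vessels`).
#' @param cell_params list: `density_per_mm3`, `radius_range_um`.
#' @param probe_params list: `present`, `width_um`, `thickness_um`,
#'   `n_tracks`, `track_width_um`. The shaft runs the full z extent, its
#'   width along y and thickness along x.
#' @param calc_params list: `n_blobs`, `radius_range_um`,
#'   `distance_range_um` (center distance from the shaft plane).
#' @param cavity_params list: `margin_y_um`, `margin_x_um` (elliptical sheath
#'   semi-axes are shaft half-width/half-thickness plus these margins).
#' @param intensity_model list: `means` (named per-class grayscale means),
#'   `noise_sd`, `bit_depth`.
#' @param artifact_params list: `axis` ("z", "y" or "x"),
#'   `band_halfwidth_um`, `inflation` (multiplier on the noise SD inside the
#'   band; `<= 1` disables the artifact).
#' @return object of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(48L, 420L, 420L),
                         voxel_size_um = c(1, 1, 1),
                         seed = 1L,
                         vessel_params = list(),
                         cell_params = list(),
                         probe_params = list(),
                         calc_params = list(),
                         cavity_params = list(),
                         intensity_model = list(),
                         artifact_params = list()) {
  merge_defaults <- function(x, def) {
    bad <- setdiff(names(x), names(def))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    def[names(x)] <- x
    def
  }
  vessel_params <- merge_defaults(vessel_params, list(
    n_vessels = 400L, diameter_range_um = c(3, 20),
    diameter_meanlog = log(5), diameter_sdlog = 0.35,
    tortuosity_um = 8, target_fraction = 0.023))
  cell_params <- merge_defaults(cell_params, list(
    density_per_mm3 = 1e5, radius_range_um = c(2.5, 5)))
  probe_params <- merge_defaults(probe_params, list(
    present = TRUE, width_um = 380, thickness_um = 12,
    n_tracks = 12L, track_width_um = 8))
  calc_params <- merge_defaults(calc_params, list(
    n_blobs = 3L, radius_range_um = c(5, 15), distance_range_um = c(20, 150)))
  cavity_params <- merge_defaults(cavity_params, list(
    margin_y_um = 20, margin_x_um = 12))
  intensity_model <- merge_defaults(intensity_model, list(
    means = c(cavity = 40, vessel = 60, cell = 90, tissue = 120,
              calcification = 220, metal = 255),
    noise_sd = 8, bit_depth = 8L))
  artifact_params <- merge_defaults(artifact_params, list(
    axis = "y", band_halfwidth_um = 46, inflation = 1.5))

  shape <- as.integer(shape)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive voxel counts", call. = FALSE)
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  maxval <- 2^intensity_model$bit_depth - 1
  if (any(intensity_model$means < 0) || any(intensity_model$means > maxval))
    stop("class means must lie within the output bit-depth range", call. = FALSE)
  if (intensity_model$noise_sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (!artifact_params$axis %in% c("z", "y", "x"))
    stop("artifact axis must be one of 'z', 'y', 'x'", call. = FALSE)

  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 seed = as.integer(seed),
                 vessel_params = vessel_params, cell_params = cell_params,
                 probe_params = probe_params, calc_params = calc_params,
                 cavity_params = cavity_params,
                 intensity_model = intensity_model,
                 artifact_params = artifact_params),
            class = "phantom_spec")
}

#' Write a phantom spec to YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$intensity_model$means <- as.list(x$intensity_model$means)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a phantom spec from a YAML or JSON file
#'
#' @param path file path; `.yml`/`.yaml` is parsed with [yaml::read_yaml()],
#'   anything else with [jsonlite::read_json()].
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(x$intensity_model$means))
    x$intensity_model$means <- unlist(x$intensity_model$means)
  do.call(phantom_spec, x)
}

#' Rasterize a tube around a polyline
#'
#' A voxel is marked iff its center lies within `diameter_um / 2` (inclusive)
#' of the polyline; a zero-length polyline therefore gives a digital ball.
#' Tubes thinner than the smallest voxel pitch still mark the chain of voxels
#' nearest the polyline, so no track is lost to undersampling.
#'
#' @param centerline numeric matrix, one `(z, y, x)` point per row, in
#'   micrometres (voxel `(i,j,k)` has its center at `((i-0.5)*dz, ...)`).
#' @param diameter_um tube diameter, micrometres (`>= 0`).
#' @param shape voxel counts `(z, y, x)`.
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @return logical 3D array.
#' @export
rasterize_tube <- function(centerline, diameter_um, shape, voxel_size_um) {
  centerline <- rbind(centerline)
  storage.mode(centerline) <- "double"
  if (nrow(centerline) < 1L) stop("centerline needs at least one point",
                                  call. = FALSE)
  if (diameter_um < 0) stop("diameter must be >= 0", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  m <- cpp_rasterize_tube(as.integer(shape), voxel_size_um, centerline,
                          diameter_um)
  if (!any(m)) warning("centerline lies entirely outside the volume; ",
                       "returning an empty mask")
  array(m, as.integer(shape))
}

# one random point on a given face of the [0, ext] box
face_point <- function(face, ext) {
  p <- runif(3) * ext
  axis <- ((face - 1L) %/% 2L) + 1L
  p[axis] <- if (face %% 2L == 1L) 0 else ext[axis]
  p
}

#' Generate a synthetic probe-in-cortex phantom
#'
#' Builds the ground-truth label volume (painted in priority order
#' metal > calcification > cavity > vessel > cell > tissue), renders
#' grayscale intensities from the class means plus Gaussian noise, applies
#' the missing-wedge streak band if a probe is present, and returns the
#' rendered grid, the labels and a ground-truth manifest.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_volume`: list with `grid` (a
#'   [voxel_grid]), `labels` (a [label_volume]) and `manifest` (ground truth:
#'   per-vessel centerlines and diameters, exact per-class voxel counts and
#'   fractions, probe bounding geometry, seed).
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   shape = c(24, 40, 40), seed = 7,
#'   vessel_params = list(n_vessels = 3, target_fraction = NULL),
#'   probe_params = list(present = FALSE),
#'   calc_params = list(n_blobs = 0)))
#' ph$manifest$class_fractions
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  classes <- tomo_classes()
  shape <- spec$shape
  vs <- spec$voxel_size_um
  ext <- shape * vs
  n_total <- prod(shape)
  set.seed(spec$seed)

  labels <- array(classes[["tissue"]], shape)

  # --- cells (lowest structure priority) ---------------------------------
  n_cells <- round(spec$cell_params$density_per_mm3 * prod(ext) / 1e9)
  if (n_cells > 0) {
    rr <- spec$cell_params$radius_range_um
    centers <- matrix(runif(3 * n_cells), ncol = 3) %*% diag(ext)
    radii <- runif(n_cells, rr[1], rr[2])
    for (i in seq_len(n_cells)) {
      idx <- cpp_tube_indices(shape, vs, centers[i, , drop = FALSE],
                              2 * radii[i])
      labels[idx] <- classes[["cell"]]
    }
  }

  # --- vessels ------------------------------------------------------------
  vp <- spec$vessel_params
  vessel_mask <- logical(n_total)
  vessel_count <- 0L
  vessels <- list()
  i <- 0L
  repeat {
    frac <- vessel_count / n_total
    if (!is.null(vp$target_fraction) && frac >= vp$target_fraction) break
    if (i >= vp$n_vessels) break
    i <- i + 1L
    faces <- sample.int(6L, 2L)
    p1 <- face_point(faces[1], ext)
    p2 <- face_point(faces[2], ext)
    k <- 8L
    tt <- seq_len(k) / (k + 1)
    mid <- outer(1 - tt, p1) + outer(tt, p2) +
      matrix(rnorm(3L * k, 0, vp$tortuosity_um), ncol = 3)
    pts <- rbind(p1, mid, p2)
    pts <- pmin(pmax(pts, 0), matrix(ext, nrow(pts), 3, byrow = TRUE))
    d <- min(max(rlnorm(1, vp$diameter_meanlog, vp$diameter_sdlog),
                 vp$diameter_range_um[1]), vp$diameter_range_um[2])
    idx <- cpp_tube_indices(shape, vs, pts, d)
    vessel_count <- vessel_count + sum(!vessel_mask[idx])
    vessel_mask[idx] <- TRUE
    vessels[[i]] <- tibble::tibble(vessel = i, diameter_um = d,
                                   n_points = nrow(pts))
  }
  labels[vessel_mask] <- classes[["vessel"]]

  # --- probe: cavity sheath, then saturated metal tracks ------------------
  pp <- spec$probe_params
  probe_info <- list(present = isTRUE(pp$present))
  metal_mask <- NULL
  if (isTRUE(pp$present)) {
    if (pp$width_um > ext[2] || pp$thickness_um > ext[3])
      stop("probe shaft (", pp$width_um, " x ", pp$thickness_um,
           " um) does not fit in the volume extent (",
           ext[2], " x ", ext[3], " um)", call. = FALSE)
    cy <- ext[2] / 2
    cx <- ext[3] / 2
    yc <- (seq_len(shape[2]) - 0.5) * vs[2]
    xc <- (seq_len(shape[3]) - 0.5) * vs[3]

    ay <- pp$width_um / 2 + spec$cavity_params$margin_y_um
    ax <- pp$thickness_um / 2 + spec$cavity_params$margin_x_um
    cav2d <- outer(((yc - cy) / ay)^2, ((xc - cx) / ax)^2, `+`) <= 1
    cav3d <- aperm(array(cav2d, c(shape[2], shape[3], shape[1])), c(3, 1, 2))
    labels[cav3d] <- classes[["cavity"]]

    nt <- pp$n_tracks
    ty <- cy - pp$width_um / 2 + (seq_len(nt) - 0.5) * pp$width_um / nt
    in_track_y <- vapply(yc, function(y) any(abs(y - ty) <= pp$track_width_um / 2),
                         logical(1))
    in_track_x <- abs(xc - cx) <= pp$thickness_um / 2
    met2d <- outer(in_track_y, in_track_x, `&`)
    met3d <- aperm(array(met2d, c(shape[2], shape[3], shape[1])), c(3, 1, 2))
    # calcifications are painted after the cavity but below metal, so place
    # them before overwriting with metal below
    cp <- spec$calc_params
    if (cp$n_blobs > 0) {
      for (b in seq_len(cp$n_blobs)) {
        r <- runif(1, cp$radius_range_um[1], cp$radius_range_um[2])
        dist <- runif(1, cp$distance_range_um[1], cp$distance_range_um[2])
        side <- sample(c(-1, 1), 1)
        ctr <- c(runif(1, r, max(ext[1] - r, r)),
                 runif(1, cy - pp$width_um / 3, cy + pp$width_um / 3),
                 cx + side * (pp$thickness_um / 2 + dist))
        ctr <- pmin(pmax(ctr, r), ext - r)
        idx <- cpp_tube_indices(shape, vs, matrix(ctr, 1), 2 * r)
        labels[idx] <- classes[["calcification"]]
      }
    }
    labels[met3d] <- classes[["metal"]]
    metal_mask <- met3d
    iy <- range(which(in_track_y)); ix <- range(which(in_track_x))
    probe_info <- list(present = TRUE, width_um = pp$width_um,
                       thickness_um = pp$thickness_um,
                       bbox = list(z = c(1L, shape[1]), y = as.integer(iy),
                                   x = as.integer(ix)))
  }

  lv <- label_volume(labels, classes, vs)

  # --- grayscale rendering and artifact -----------------------------------
  grid <- render_intensities(lv, spec$intensity_model, seed = spec$seed + 1L)
  ap <- spec$artifact_params
  if (isTRUE(pp$present) && ap$inflation > 1 &&
      spec$intensity_model$noise_sd > 0) {
    grid <- apply_missing_wedge_artifact(
      grid, metal_mask, axis = ap$axis,
      band_halfwidth_um = ap$band_halfwidth_um, inflation = ap$inflation,
      noise_sd = spec$intensity_model$noise_sd, seed = spec$seed + 2L)
  }

  cnt <- label_counts(lv)
  manifest <- list(
    seed = spec$seed,
    shape = shape,
    voxel_size_um = vs,
    class_counts = cnt,
    class_fractions = setNames(cnt$voxels / n_total, cnt$class),
    vessels = if (length(vessels)) do.call(rbind, vessels) else
      tibble::tibble(vessel = integer(), diameter_um = numeric(),
                     n_points = integer()),
    vessel_fraction = sum(vessel_mask) / n_total,
    probe = probe_info)

  structure(list(grid = grid, labels = lv, manifest = manifest),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat("<phantom_volume>\n")
  print(x$grid)
  cat(sprintf("  vessel fraction (ground truth): %.3f%%\n",
              100 * x$manifest$vessel_fraction))
  cat(sprintf("  probe present: %s\n", x$manifest$probe$present))
  invisible(x)
}

#' Render grayscale intensities from a label volume
#'
#' Each voxel takes its class mean plus Gaussian noise, rounded half-up and
#' clipped to the bit-depth range. The contrast polarity of the tomograms is
#' enforced: metal (saturated) > calcification > tissue > cell >= vessel >
#' cavity; violating models are rejected.
#'
#' @param labels a [label_volume].
#' @param intensity_model list with `means` (named numeric, one per class
#'   name in the label table), `noise_sd` (>= 0) and `bit_depth`.
#' @param seed optional integer seed.
#' @return a [voxel_grid].
#' @export
render_intensities <- function(labels, intensity_model, seed = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  means <- intensity_model$means
  sd <- intensity_model$noise_sd
  bit <- intensity_model$bit_depth %||% 8L
  maxval <- 2^bit - 1
  need <- names(labels$classes)
  if (!all(need %in% names(means)))
    stop("intensity model lacks a class mean for: ",
         paste(setdiff(need, names(means)), collapse = ", "), call. = FALSE)
  if (sd < 0) stop("noise SD must be >= 0", call. = FALSE)
  ge <- function(a, b) means[[a]] >= means[[b]]
  gt <- function(a, b) means[[a]] > means[[b]]
  if (!(gt("metal", "calcification") && gt("calcification", "tissue") &&
        gt("tissue", "cell") && ge("cell", "vessel") && gt("vessel", "cavity")))
    stop("intensity ordering violated: need metal > calcification > tissue > ",
         "cell >= vessel > cavity", call. = FALSE)
  if (means[["metal"]] != maxval)
    stop("metal class mean must equal the saturation value (", maxval, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  lut <- rep(NA_real_, max(labels$classes))
  lut[labels$classes] <- means[names(labels$classes)]
  v <- lut[labels$labels]
  if (sd > 0) v <- v + rnorm(length(v), 0, sd)
  v <- floor(pmin(pmax(v, 0), maxval) + 0.5)
  voxel_grid(array(v, dim(labels$labels)), labels$voxel_size_um, bit)
}

#' Apply a missing-wedge-like streak band around the probe
#'
#' Emulates the directional artifact caused by X-ray absorption along
#' metal-rich directions: within the band of voxels sharing an axis line with
#' any probe voxel (expanded by `band_halfwidth_um` in the perpendicular
#' plane), the noise SD is multiplied by `inflation` (independent Gaussian
#' noise of SD `noise_sd * sqrt(inflation^2 - 1)` is added) and alternating
#' bright/dark streaks of amplitude `(inflation - 1) * noise_sd` are
#' superimposed, constant along the artifact axis. Outside the band the
#' volume is unchanged; `inflation <= 1` is the identity.
#'
#' @param grid a [voxel_grid].
#' @param probe_mask logical 3D array of probe (metal) voxels.
#' @param axis artifact axis, one of `"z"`, `"y"`, `"x"`.
#' @param band_halfwidth_um band expansion in the perpendicular plane (um).
#' @param inflation noise SD multiplier inside the band.
#' @param noise_sd baseline noise SD of the volume (grayscale units).
#' @param seed optional integer seed.
#' @return a [voxel_grid].
#' @export
apply_missing_wedge_artifact <- function(grid, probe_mask, axis = "y",
                                         band_halfwidth_um = 46,
                                         inflation = 1.5, noise_sd = 8,
                                         seed = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (inflation <= 1) return(grid)
  if (is.null(probe_mask) || !any(probe_mask))
    stop("probe mask must be nonempty when inflation > 0", call. = FALSE)
  ax <- match(axis, c("z", "y", "x"))
  if (is.na(ax)) stop("axis must be 'z', 'y' or 'x'", call. = FALSE)
  d <- dim(grid$data)
  others <- setdiff(1:3, ax)

  fp <- apply(probe_mask, others, any)
  if (band_halfwidth_um > 0) {
    d2 <- cpp_edt_sq(as.vector(fp), c(1L, dim(fp)),
                     c(1, grid$voxel_size_um[others]), FALSE)
    fp <- matrix(sqrt(d2) <= band_halfwidth_um, dim(fp)[1], dim(fp)[2])
  }
  # broadcast the 2D footprint back to 3D with the artifact axis last, then
  # permute the axes home
  band <- array(fp, c(dim(fp), d[ax]))
  perm <- integer(3)
  perm[c(others, ax)] <- 1:3
  band <- aperm(band, perm)

  stripe2d <- outer(seq_len(dim(fp)[1]), seq_len(dim(fp)[2]),
                    function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  stripe <- aperm(array(stripe2d, c(dim(fp), d[ax])), perm)

  if (!is.null(seed)) set.seed(seed)
  idx <- which(band)
  amp <- (inflation - 1) * noise_sd
  sd_extra <- noise_sd * sqrt(inflation^2 - 1)
  v <- grid$data
  v[idx] <- v[idx] + amp * stripe[idx] + rnorm(length(idx), 0, sd_extra)
  maxval <- 2^grid$bit_depth - 1
  v <- floor(pmin(pmax(v, 0), maxval) + 0.5)
  voxel_grid(array(v, d), grid$voxel_size_um, grid$bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
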