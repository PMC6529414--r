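#' Segmentation configuration
#'
#' Grayscale windows for each tissue class, component-cleanup settings and
#' the artifact-exclusion geometry. The defaults match the default phantom
#' intensity model (cavity 40, vessel 60, cell 90, tissue 120, calcification
#' 220, metal saturated at 255, noise SD 8); for real tomograms the windows
#' are the analyst's choice, mirroring the manual grayscale thresholding the
#' workflow replaces.
#'
#' @param t_metal scalar; voxels `>= t_metal` are probe metal.
#' @param t_calc `(lo, hi)` calcification window; must lie below `t_metal`.
#' @param t_vessel `(lo, hi)` dark vessel window.
#' @param t_cell `(lo, hi)` cell window.
#' @param t_cavity `(lo, hi)` cavity window.
#' @param min_component_voxels connected components smaller than this are
#'   removed when cleaning class masks.
#' @param connectivity 6, 18 or 26.
#' @param exclusion_distance_um distance from the probe within which voxels
#'   are excluded from vessel/cell quantification (default 46).
#' @param exclusion_mode `"radial"` (distance to any probe voxel) or
#'   `"directional"` (additionally restricted to the two half-spaces beyond
#'   the probe's bounding slab along `artifact_axis`).
#' @param artifact_axis axis for the directional mode (`"z"`, `"y"`, `"x"`).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(t_metal = 240,
                                t_calc = c(170, 239),
                                t_vessel = c(44, 76),
                                t_cell = c(77, 105),
                                t_cavity = c(24, 43),
                                min_component_voxels = 10L,
                                connectivity = 26L,
                                exclusion_distance_um = 46,
                                exclusion_mode = c("radial", "directional"),
                                artifact_axis = "y") {
  exclusion_mode <- match.arg(exclusion_mode)
  for (w in list(t_calc, t_vessel, t_cell, t_cavity))
    if (length(w) != 2L || w[1] > w[2])
      stop("class windows must be (lo, hi) with lo <= hi", call. = FALSE)
  if (t_metal <= t_calc[2])
    stop("`t_metal` must lie above the calcification window", call. = FALSE)
  if (exclusion_distance_um < 0)
    stop("`exclusion_distance_um` must be >= 0", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  structure(list(t_metal = t_metal, t_calc = t_calc, t_vessel = t_vessel,
                 t_cell = t_cell, t_cavity = t_cavity,
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = as.integer(connectivity),
                 exclusion_distance_um = exclusion_distance_um,
                 exclusion_mode = exclusion_mode,
                 artifact_axis = artifact_axis),
            class = "segmentation_config")
}

#' Read a segmentation config from YAML
#'
#' @param path YAML file whose keys match [segmentation_config()] arguments.
#' @return a `segmentation_config`.
#' @export
read_segmentation_config <- function(path) {
  do.call(segmentation_config, yaml::read_yaml(path))
}

as_mask_array <- function(x) {
  if (inherits(x, "voxel_grid")) x <- x$data
  x
}

#' Threshold a volume into a binary mask
#'
#' A voxel is selected iff `lo <= value <= hi` (inclusive at both ends, so
#' masks are monotone in the window).
#'
#' @param grid a [voxel_grid] (or 3D array).
#' @param window numeric `(lo, hi)` with `lo <= hi`.
#' @return logical 3D array.
#' @export
segment_by_threshold <- function(grid, window) {
  v <- as_mask_array(grid)
  if (length(window) != 2L || window[1] > window[2])
    stop("window must be (lo, hi) with lo <= hi", call. = FALSE)
  v >= window[1] & v <= window[2]
}

#' Label connected components of a binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all neighbours).
#' @return integer 3D array; background 0, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  array(cpp_label_components(mask, dim(mask), as.integer(connectivity)),
        dim(mask))
}

#' Remove small connected components from a mask
#'
#' @param mask logical 3D array.
#' @param min_component_voxels components with fewer voxels are dropped
#'   (1 leaves the mask unchanged).
#' @param connectivity 6, 18 or 26.
#' @return logical 3D array, a subset of `mask`.
#' @export
clean_mask <- function(mask, min_component_voxels, connectivity = 26L) {
  if (min_component_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component_voxels)
  array(lab %in% keep & mask, dim(mask))
}

#' Fill enclosed holes in a binary mask
#'
#' Background components (6-connected) that do not touch the volume boundary
#' are enclosed by the foreground and are filled. Used on the vessel mask
#' before sphere-fitting: interior holes punched by voxel noise would
#' otherwise collapse the local thickness, since an inscribed sphere may not
#' contain any background voxel center.
#'
#' @param mask logical 3D array.
#' @return logical 3D array, a superset of `mask`.
#' @export
fill_holes <- function(mask) {
  if (all(mask)) return(mask)
  bg <- !mask
  lab <- label_components(bg, 6L)
  d <- dim(mask)
  boundary <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                       lab[, , c(1, d[3])]))
  boundary <- setdiff(boundary, 0L)
  enclosed <- bg & !array(lab %in% boundary, d)
  mask | enclosed
}

#' Linear contrast enhancement by percentile windowing
#'
#' Rescales the `[p_lo, p_hi]` percentile range of the volume linearly to
#' the full bit-depth range (round-half-up, clipped). A constant volume is
#' returned unchanged with a warning.
#'
#' @param grid a [voxel_grid].
#' @param percentiles numeric `(p_lo, p_hi)` in `[0, 100]`, `p_lo < p_hi`.
#' @return a [voxel_grid] at the input bit depth.
#' @export
enhance_contrast <- function(grid, percentiles = c(0.1, 99.9)) {
  stopifnot(inherits(grid, "voxel_grid"))
  p <- percentiles
  if (length(p) != 2L || p[1] < 0 || p[2] > 100 || p[1] >= p[2])
    stop("percentiles must satisfy 0 <= p_lo < p_hi <= 100", call. = FALSE)
  w <- unname(quantile(grid$data, p / 100, names = FALSE))
  if (w[1] == w[2]) {
    warning("volume is constant over the requested percentile range; ",
            "returning it unchanged")
    return(grid)
  }
  maxval <- 2^grid$bit_depth - 1
  v <- round_half_up(maxval * (pmin(pmax(grid$data, w[1]), w[2]) - w[1]) /
                       (w[2] - w[1]))
  voxel_grid(array(v, dim(grid$data)), grid$voxel_size_um, grid$bit_depth)
}

#' Classify the high-contrast phases: probe metal and calcification
#'
#' Probe metal is the cleaned mask of voxels at or above `t_metal`;
#' calcification is the cleaned `t_calc` window minus the probe mask, so the
#' two are disjoint by construction.
#'
#' @param grid a [voxel_grid].
#' @param t_metal metal threshold (values `>= t_metal` are metal).
#' @param t_calc calcification window `(lo, hi)`, below `t_metal`.
#' @param min_component_voxels,connectivity passed to [clean_mask()].
#' @param probe_expected if `TRUE`, warn when no metal voxels are found.
#' @return list with logical arrays `probe` and `calcification`.
#' @export
classify_high_contrast <- function(grid, t_metal, t_calc,
                                   min_component_voxels = 10L,
                                   connectivity = 26L,
                                   probe_expected = FALSE) {
  if (t_metal <= t_calc[2])
    stop("`t_metal` must lie above the calcification window", call. = FALSE)
  v <- as_mask_array(grid)
  probe <- clean_mask(v >= t_metal, min_component_voxels, connectivity)
  if (probe_expected && !any(probe))
    warning("a probe was declared present but no metal voxels were found; ",
            "the exclusion mask will be empty")
  calc <- clean_mask(segment_by_threshold(v, t_calc) & !probe,
                     min_component_voxels, connectivity)
  list(probe = probe, calcification = calc)
}

# voxels within one (possibly diagonal) step of the mask
dilate1 <- function(mask) {
  d2 <- cpp_edt_sq(as.vector(mask), dim(mask), c(1, 1, 1), FALSE)
  array(d2 <= 3, dim(mask))
}

#' Segment the cavity sheath along the probe shaft
#'
#' Candidate voxels are those in the `t_cavity` grayscale window; only
#' connected components touching the probe (within a one-voxel dilation) are
#' kept, so unrelated low-intensity blobs are not mistaken for the cavity.
#'
#' @param grid a [voxel_grid].
#' @param probe_mask logical 3D array of probe voxels (may be empty).
#' @param t_cavity cavity window `(lo, hi)`.
#' @param connectivity 6, 18 or 26.
#' @return logical 3D array (possibly empty).
#' @export
segment_cavity <- function(grid, probe_mask, t_cavity, connectivity = 26L) {
  cand <- segment_by_threshold(grid, t_cavity) & !probe_mask
  if (!any(probe_mask) || !any(cand))
    return(array(FALSE, dim(as_mask_array(grid))))
  lab <- label_components(cand, connectivity)
  near <- dilate1(probe_mask)
  keep <- setdiff(unique(lab[near]), 0L)
  array(lab %in% keep, dim(lab))
}

#' Build the artifact-exclusion mask around the probe
#'
#' Radial mode selects all voxels whose center-to-center distance to the
#' nearest probe voxel is at most `distance_um` (the probe itself included).
#' Directional mode intersects that set with the two half-spaces beyond the
#' probe's bounding slab along `axis` (the probe again included), matching
#' an artifact confined to the two sides of the shaft.
#'
#' @param probe_mask logical 3D array (empty mask gives an empty result).
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @param distance_um exclusion distance (default 46).
#' @param mode `"radial"` or `"directional"`.
#' @param axis artifact axis for directional mode.
#' @return logical 3D array.
#' @export
build_exclusion_mask <- function(probe_mask, voxel_size_um, distance_um = 46,
                                 mode = c("radial", "directional"),
                                 axis = "y") {
  mode <- match.arg(mode)
  if (distance_um < 0) stop("`distance_um` must be >= 0", call. = FALSE)
  d <- dim(probe_mask)
  if (!any(probe_mask)) return(array(FALSE, d))
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  d2 <- cpp_edt_sq(as.vector(probe_mask), d, voxel_size_um, FALSE)
  excl <- array(sqrt(d2) <= distance_um, d)
  if (mode == "directional") {
    ax <- match(axis, c("z", "y", "x"))
    if (is.na(ax)) stop("axis must be 'z', 'y' or 'x'", call. = FALSE)
    pos <- which(probe_mask, arr.ind = TRUE)[, ax]
    coord <- slice.index(probe_mask, ax)
    halves <- coord < min(pos) | coord > max(pos)
    excl <- excl & (halves | probe_mask)
  }
  excl
}

#' Build the analysis domain for tissue quantification
#'
#' The domain is the whole volume minus probe, cavity and exclusion mask;
#' vessel and cell statistics are computed only inside it, while probe and
#' calcification statistics use the full volume.
#'
#' @param probe_mask,cavity_mask,exclusion_mask logical 3D arrays of a
#'   common shape (`NULL` counts as empty).
#' @param shape required if all three masks are `NULL`.
#' @return logical 3D array; errors if the domain would be empty.
#' @export
build_analysis_domain <- function(probe_mask = NULL, cavity_mask = NULL,
                                  exclusion_mask = NULL, shape = NULL) {
  masks <- Filter(Negate(is.null),
                  list(probe_mask, cavity_mask, exclusion_mask))
  if (!length(masks)) {
    if (is.null(shape)) stop("supply at least one mask or `shape`",
                             call. = FALSE)
    return(array(TRUE, shape))
  }
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("masks must share one shape", call. = FALSE)
  domain <- array(TRUE, d)
  for (m in masks) domain <- domain & !m
  if (!any(domain)) stop("analysis domain is empty", call. = FALSE)
  domain
}

#' Segment a grayscale volume into the full class label volume
#'
#' Applies the class windows in priority order (metal, calcification,
#' cavity, vessel, cell; everything else is tissue), cleans each mask by
#' connected-component size, and derives the artifact-exclusion mask and the
#' analysis domain.
#'
#' @param grid a [voxel_grid].
#' @param config a [segmentation_config()].
#' @param probe_expected warn if no metal is found although a probe was
#'   declared present.
#' @return list with `labels` (a [label_volume]), `masks` (named list of
#'   per-class logical arrays), `exclusion` and `domain` (logical arrays).
#' @export
segment_volume <- function(grid, config = segmentation_config(),
                           probe_expected = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(config, "segmentation_config"))
  v <- grid$data
  mc <- config$min_component_voxels
  cn <- config$connectivity
  classes <- tomo_classes()

  hc <- classify_high_contrast(grid, config$t_metal, config$t_calc,
                               mc, cn, probe_expected)
  metal <- hc$probe
  calc <- hc$calcification
  cavity <- segment_cavity(grid, metal, config$t_cavity, cn) & !metal & !calc
  vessel <- clean_mask(segment_by_threshold(v, config$t_vessel) &
                         !metal & !calc & !cavity, mc, cn)
  cell <- clean_mask(segment_by_threshold(v, config$t_cell) &
                       !metal & !calc & !cavity & !vessel, mc, cn)

  labels <- array(classes[["tissue"]], dim(v))
  labels[cell] <- classes[["cell"]]
  labels[vessel] <- classes[["vessel"]]
  labels[cavity] <- classes[["cavity"]]
  labels[calc] <- classes[["calcification"]]
  labels[metal] <- classes[["metal"]]

  exclusion <- build_exclusion_mask(metal, grid$voxel_size_um,
                                    config$exclusion_distance_um,
                                    config$exclusion_mode,
                                    config$artifact_axis)
  domain <- build_analysis_domain(metal, cavity, exclusion)

  list(labels = label_volume(labels, classes, grid$voxel_size_um),
       masks = list(metal = metal, calcification = calc, cavity = cavity,
                    vessel = vessel, cell = cell),
       exclusion = exclusion,
       domain = domain)
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of one shape.
#' @param domain optional logical array restricting the comparison.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b, domain = NULL) {
  if (!is.null(domain)) {
    a <- a & domain
    b <- b & domain
  }
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
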