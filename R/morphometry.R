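#' Distance and thickness map containers
#'
#' A `distance_map` holds per-voxel nonnegative distances (micrometres) to a
#' reference voxel set (zero exactly on the reference set); a
#' `thickness_map` holds per-voxel local diameters from maximal inscribed
#' spheres (zero outside the foreground).
#'
#' @param values numeric 3D array (micrometres).
#' @param reference short description of the reference set.
#' @param voxel_size_um per-axis voxel size.
#' @param mask foreground mask the thickness was computed on.
#' @return object of class `distance_map` / `thickness_map`.
#' @name map-containers
NULL

new_distance_map <- function(values, reference, voxel_size_um) {
  structure(list(values = values, reference = reference,
                 voxel_size_um = voxel_size_um),
            class = "distance_map")
}

new_thickness_map <- function(values, mask, voxel_size_um) {
  structure(list(values = values, mask = mask,
                 voxel_size_um = voxel_size_um),
            class = "thickness_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> to %s; %s voxels; range [%.3g, %.3g] um\n",
              x$reference, paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.thickness_map <- function(x, ...) {
  fg <- x$values[x$mask]
  cat(sprintf("<thickness_map> %s voxels; %d foreground; diameters [%.3g, %.3g] um\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              if (length(fg)) min(fg) else NA, if (length(fg)) max(fg) else NA))
  invisible(x)
}

map_values <- function(map) {
  if (is.list(map) && !is.null(map$values)) map$values else map
}

check_spacing <- function(voxel_size_um) {
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  stopifnot(length(voxel_size_um) == 3L, all(voxel_size_um > 0))
  voxel_size_um
}

#' Euclidean distance transform of a foreground mask
#'
#' For every foreground voxel, the Euclidean center-to-center distance (in
#' micrometres, anisotropy-aware) to the nearest background voxel center;
#' background voxels get 0. Everything outside the volume counts as
#' background (one-layer padding), so an isolated foreground voxel at the
#' volume edge still has a finite distance.
#'
#' @param mask logical 3D array (foreground).
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @return a `distance_map`.
#' @export
edt_to_background <- function(mask, voxel_size_um) {
  vs <- check_spacing(voxel_size_um)
  d2 <- cpp_edt_sq(as.vector(!mask), dim(mask), vs, TRUE)
  new_distance_map(array(sqrt(d2), dim(mask)), "background", vs)
}

#' Distance of every voxel to a target set
#'
#' For every voxel in the volume, the Euclidean distance (micrometres) to
#' the nearest target voxel center; zero on the target itself. No padding is
#' applied: only actual target voxels attract.
#'
#' @param target_mask logical 3D array; must be nonempty.
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @param reference description stored in the result (default "target").
#' @return a `distance_map`.
#' @export
distance_to_set <- function(target_mask, voxel_size_um,
                            reference = "target") {
  if (!any(target_mask))
    stop("target set is empty: distances (and their median) are undefined",
         call. = FALSE)
  vs <- check_spacing(voxel_size_um)
  d2 <- cpp_edt_sq(as.vector(target_mask), dim(target_mask), vs, FALSE)
  new_distance_map(array(sqrt(d2), dim(target_mask)), reference, vs)
}

#' Local thickness by maximal inscribed spheres
#'
#' The local thickness of a foreground voxel p is the diameter of the
#' largest sphere that contains p and fits entirely inside the foreground
#' (Hildebrand-Ruegsegger): `2 * max{ EDT(x) : ||p - x|| < EDT(x) }` over
#' foreground centers x, with the EDT of [edt_to_background()] (outside the
#' volume counts as background) and open-ball containment. The accelerated
#' implementation is exactly equivalent to the literal evaluation in
#' [local_thickness_bruteforce()].
#'
#' Note the convention bias: distances are center-to-center, so a tube of
#' true diameter d rasterized on a 1 um grid reports thickness in
#' `[d, d + 2]` um (about one voxel pitch high).
#'
#' @param mask logical 3D array (foreground).
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @return a `thickness_map` (diameters in micrometres, 0 outside the
#'   foreground).
#' @export
local_thickness <- function(mask, voxel_size_um) {
  vs <- check_spacing(voxel_size_um)
  v <- cpp_local_thickness(mask, dim(mask), vs)
  new_thickness_map(array(v, dim(mask)), mask, vs)
}

#' Brute-force local thickness (reference implementation)
#'
#' Literal evaluation of the maximal-inscribed-sphere definition: for every
#' foreground voxel the EDT is found by exhaustive nearest-background search
#' (including the padding layer) and its open sphere is painted at twice
#' that radius; per-voxel maxima are returned. Quadratic cost - intended for
#' small volumes (roughly up to 32^3) as the oracle for [local_thickness()].
#'
#' @inheritParams local_thickness
#' @return a `thickness_map`.
#' @export
local_thickness_bruteforce <- function(mask, voxel_size_um) {
  vs <- check_spacing(voxel_size_um)
  v <- cpp_local_thickness_bruteforce(mask, dim(mask), vs)
  new_thickness_map(array(v, dim(mask)), mask, vs)
}

#' Physical volume of a structure mask
#'
#' @param mask logical 3D array.
#' @param voxel_size_um per-axis voxel size, micrometres.
#' @return volume in cubic micrometres (voxel count times voxel volume).
#' @export
structure_volume <- function(mask, voxel_size_um) {
  vs <- check_spacing(voxel_size_um)
  sum(mask) * prod(vs)
}

#' Volume fraction of a structure within a domain
#'
#' @param structure_mask,domain_mask logical 3D arrays of one shape; the
#'   structure is intersected with the domain.
#' @return `|structure n domain| / |domain|`, a fraction in `[0, 1]`.
#' @export
volume_fraction <- function(structure_mask, domain_mask) {
  nd <- sum(domain_mask)
  if (nd == 0) stop("domain is empty", call. = FALSE)
  sum(structure_mask & domain_mask) / nd
}

#' Histogram of a distance or thickness map over a domain
#'
#' Values are binned into half-open bins `[k*w, (k+1)*w)` starting at zero;
#' counts sum to the domain voxel count.
#'
#' @param map a `distance_map`, `thickness_map` or numeric 3D array.
#' @param domain_mask logical array selecting contributing voxels (`NULL`
#'   for all).
#' @param bin_width_um bin width in micrometres (> 0).
#' @return object of class `tomo_histogram`: list with `bin_edges` (length
#'   `nbins + 1`), `counts` and `domain` description.
#' @export
map_histogram <- function(map, domain_mask = NULL, bin_width_um = 1) {
  if (bin_width_um <= 0) stop("bin width must be > 0", call. = FALSE)
  v <- map_values(map)
  v <- if (is.null(domain_mask)) as.vector(v) else v[domain_mask]
  if (!length(v)) {
    return(structure(list(bin_edges = c(0, bin_width_um),
                          counts = 0L, domain = "empty domain"),
                     class = "tomo_histogram"))
  }
  idx <- pmin(floor(v / bin_width_um), floor(max(v) / bin_width_um)) + 1L
  nbins <- max(idx)
  counts <- tabulate(idx, nbins = nbins)
  structure(list(bin_edges = seq(0, nbins) * bin_width_um,
                 counts = counts,
                 domain = sprintf("%d voxels", length(v))),
            class = "tomo_histogram")
}

#' @export
print.tomo_histogram <- function(x, ...) {
  cat(sprintf("<tomo_histogram> %d bins of %.3g um; %d voxels (%s)\n",
              length(x$counts), diff(x$bin_edges[1:2]), sum(x$counts),
              x$domain))
  invisible(x)
}

#' @rdname tomomorph-generics
#' @export
tidy.tomo_histogram <- function(x, ...) {
  tibble::tibble(bin_lo = head(x$bin_edges, -1),
                 bin_hi = tail(x$bin_edges, -1),
                 count = x$counts)
}

#' @rdname tomomorph-generics
#' @param ... unused.
#' @export
autoplot.tomo_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_edges[1:2]),
                      fill = "grey35") +
    ggplot2::labs(x = "value (µm)", y = "voxels") +
    ggplot2::theme_minimal()
}

#' Median of a map over a domain
#'
#' @param map a `distance_map`, `thickness_map` or numeric 3D array.
#' @param domain_mask logical array selecting voxels (`NULL` for all); must
#'   select at least one voxel.
#' @return median in micrometres; for even counts, the mean of the two
#'   central order statistics.
#' @export
median_of_map <- function(map, domain_mask = NULL) {
  v <- map_values(map)
  v <- if (is.null(domain_mask)) as.vector(v) else v[domain_mask]
  if (!length(v)) stop("domain is empty: median undefined", call. = FALSE)
  median(v)
}
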