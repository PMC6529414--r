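#' Grayscale voxel volume with physical voxel size
#'
#' The basic container for a reconstructed tomogram (or a rendered phantom):
#' a 3D scalar array in `(z, y, x)` axis order together with the per-axis
#' physical voxel size in micrometres and the nominal bit depth.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`; values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param voxel_size_um numeric length-3 `(dz, dy, dx)` in micrometres (a
#'   scalar is recycled to an isotropic size); all entries must be positive.
#' @param bit_depth 8 or 16. Default 8.
#' @return An object of class `voxel_grid`: a list with elements `data`,
#'   `voxel_size_um` and `bit_depth`.
#' @examples
#' g <- voxel_grid(array(100, c(4, 4, 4)), voxel_size_um = 0.876)
#' g
#' @export
voxel_grid <- function(data, voxel_size_um, bit_depth = 8L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 3 positive values (dz, dy, dx)",
         call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  maxval <- 2^bit_depth - 1
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > maxval)
    stop(sprintf("values outside [0, %d] for %d-bit data", maxval, bit_depth),
         call. = FALSE)
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 bit_depth = bit_depth),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), %d-bit\n",
              d[1], d[2], d[3], x$bit_depth))
  cat(sprintf("  voxel size: %.4g x %.4g x %.4g um; extent %.4g x %.4g x %.4g um\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              d[1] * x$voxel_size_um[1], d[2] * x$voxel_size_um[2],
              d[3] * x$voxel_size_um[3]))
  cat(sprintf("  intensity range: [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Physical volume of one voxel
#'
#' @param voxel_size_um per-axis voxel size in micrometres (or a
#'   `voxel_grid`/`label_volume`, whose size is used).
#' @return voxel volume in cubic micrometres.
#' @export
voxel_volume_um3 <- function(voxel_size_um) {
  if (is.list(voxel_size_um) && !is.null(voxel_size_um$voxel_size_um))
    voxel_size_um <- voxel_size_um$voxel_size_um
  prod(voxel_size_um)
}

#' Canonical tissue class table
#'
#' Integer codes used for label volumes throughout the pipeline, ordered by
#' painting priority from lowest (tissue, the default class) to highest
#' (probe metal, which overrides everything it overlaps).
#'
#' @return named integer vector mapping class name to label code.
#' @export
tomo_classes <- function() {
  c(tissue = 1L, cell = 2L, vessel = 3L, cavity = 4L,
    calcification = 5L, metal = 6L)
}

#' Per-voxel class labels aligned to a voxel grid
#'
#' @param labels 3D integer array of class codes, axis order `(z, y, x)`.
#' @param classes named integer vector mapping class name to code; every
#'   value occurring in `labels` must be listed. Default [tomo_classes()].
#' @param voxel_size_um per-axis voxel size in micrometres.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, classes = tomo_classes(), voxel_size_um) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  present <- unique(as.vector(labels))
  if (!all(present %in% classes))
    stop("labels contain codes absent from the class table: ",
         paste(setdiff(present, classes), collapse = ", "), call. = FALSE)
  structure(list(labels = labels, classes = classes,
                 voxel_size_um = voxel_size_um),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x)\n", d[1], d[2], d[3]))
  cnt <- label_counts(x)
  for (i in seq_len(nrow(cnt)))
    cat(sprintf("  %-14s %12d voxels (%.3f%%)\n", cnt$class[i], cnt$voxels[i],
                100 * cnt$voxels[i] / prod(d)))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Extract a binary mask for one class
#'
#' @param lv a [label_volume].
#' @param class class name (must appear in the class table).
#' @return logical 3D array.
#' @export
label_mask <- function(lv, class) {
  stopifnot(inherits(lv, "label_volume"))
  if (!class %in% names(lv$classes))
    stop("unknown class: ", class, call. = FALSE)
  lv$labels == lv$classes[[class]]
}

#' Voxel counts per class
#'
#' @param lv a [label_volume].
#' @return tibble with columns `class`, `code`, `voxels`.
#' @export
label_counts <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  tab <- tabulate(lv$labels, nbins = max(lv$classes))
  tibble::tibble(class = names(lv$classes),
                 code = unname(lv$classes),
                 voxels = tab[lv$classes])
}
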