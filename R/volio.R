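#' Read a TIFF volume stack
#'
#' Accepts either a multi-page TIFF or a directory of numbered single-slice
#' TIFFs (sorted by file name). Slices must share one shape; 8- and 16-bit
#' grayscale data are supported. The physical voxel size is taken from the
#' JSON sidecar written by [write_stack()] when present, otherwise from the
#' `voxel_size` override.
#'
#' @param path multi-page TIFF file or directory of 2D TIFF slices.
#' @param voxel_size voxel size override `(dz, dy, dx)` (scalar recycled),
#'   in the unit given by `unit`. Required when no sidecar exists.
#' @param unit `"um"` (default) or `"nm"`.
#' @return a [voxel_grid].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, voxel_size = NULL, unit = c("um", "nm")) {
  unit <- match.arg(unit)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF slices found in ", path, call. = FALSE)
    pages <- lapply(files, tiff::readTIFF, as.is = TRUE, info = TRUE)
    meta_path <- file.path(path, "stack.meta.json")
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    meta_path <- paste0(path, ".meta.json")
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("slices have inconsistent shapes", call. = FALSE)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  nz <- length(pages)
  arr <- array(0L, c(nz, shapes[1, 1], shapes[2, 1]))
  for (i in seq_len(nz)) arr[i, , ] <- pages[[i]]

  vs <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    vs <- as.numeric(meta$voxel_size_um)
    if (!is.null(meta$bit_depth)) bits <- as.integer(meta$bit_depth)
  }
  if (!is.null(voxel_size)) {
    vs <- as.numeric(voxel_size)
    if (unit == "nm") vs <- vs / 1000
  }
  if (is.null(vs))
    stop("voxel size unavailable: no metadata sidecar and no `voxel_size` ",
         "override supplied", call. = FALSE)
  voxel_grid(arr, vs, as.integer(bits))
}

#' Write a voxel grid as a multi-page TIFF stack
#'
#' Slices along z are written as TIFF pages at the grid's bit depth; the
#' voxel size and bit depth are recorded in a JSON sidecar
#' (`<path>.meta.json`) so that [read_stack()] round-trips losslessly.
#'
#' @param grid a [voxel_grid].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  maxval <- 2^grid$bit_depth - 1
  pages <- lapply(seq_len(dim(grid$data)[1]),
                  function(i) grid$data[i, , ] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = grid$bit_depth)
  jsonlite::write_json(list(voxel_size_um = grid$voxel_size_um,
                            bit_depth = grid$bit_depth,
                            shape = dim(grid$data)),
                       paste0(path, ".meta.json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

# round-half-up quantization to the integer grid
round_half_up <- function(x) floor(x + 0.5)

#' Bin a volume by block averaging
#'
#' Non-overlapping `factor^3` blocks are replaced by their arithmetic mean
#' (rounded half-up back to the integer grid); trailing partial blocks are
#' discarded. The voxel size is multiplied by `factor` on every axis, so a
#' factor-2 binning of 0.438 um data yields the 0.876 um grid, and of
#' 0.57424 um data the 1.14848 um grid.
#'
#' @param grid a [voxel_grid].
#' @param factor integer binning factor `>= 1`.
#' @return a [voxel_grid] with `floor(dim / factor)` voxels per axis.
#' @export
bin_volume <- function(grid, factor) {
  stopifnot(inherits(grid, "voxel_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  d <- dim(grid$data)
  if (any(factor > d))
    stop("binning factor ", factor, " exceeds a volume dimension (",
         paste(d, collapse = "x"), ")", call. = FALSE)
  if (factor == 1L) return(grid)
  m <- d %/% factor
  acc <- array(0, m)
  for (oz in seq_len(factor)) for (oy in seq_len(factor)) for (ox in seq_len(factor)) {
    acc <- acc + grid$data[seq(oz, by = factor, length.out = m[1]),
                           seq(oy, by = factor, length.out = m[2]),
                           seq(ox, by = factor, length.out = m[3])]
  }
  out <- round_half_up(acc / factor^3)
  voxel_grid(out, grid$voxel_size_um * factor, grid$bit_depth)
}

#' Windowed conversion to 8-bit
#'
#' Maps `v` to `round(255 * (clip(v, lo, hi) - lo) / (hi - lo))` with
#' round-half-up, a monotone non-decreasing mapping. When no window is
#' supplied, the 0.1st-99.9th percentile range of the volume is used.
#'
#' @param grid a [voxel_grid].
#' @param window numeric `(lo, hi)` with `lo < hi`, in input grayscale units.
#' @return an 8-bit [voxel_grid].
#' @export
convert_to_8bit <- function(grid, window = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(window))
    window <- unname(quantile(grid$data, c(0.001, 0.999), names = FALSE))
  lo <- window[1]; hi <- window[2]
  if (!(lo < hi)) stop("window must satisfy lo < hi", call. = FALSE)
  v <- round_half_up(255 * (pmin(pmax(grid$data, lo), hi) - lo) / (hi - lo))
  voxel_grid(array(v, dim(grid$data)), grid$voxel_size_um, 8L)
}

# +90 degree rotation about one axis: the two remaining axes (u, v), in
# (z, y, x) order, map as new[a, b] = old[b, n_u + 1 - a]
rotate90_axis <- function(arr, axis) {
  uv <- setdiff(1:3, axis)
  perm <- seq_len(3)
  perm[uv] <- rev(uv)
  out <- aperm(arr, perm)
  idx <- list(seq_len(dim(out)[1]), seq_len(dim(out)[2]), seq_len(dim(out)[3]))
  idx[[uv[1]]] <- rev(idx[[uv[1]]])
  do.call(`[`, c(list(out), idx, list(drop = FALSE)))
}

#' Reorient and crop a volume
#'
#' Supports axis-aligned 90-degree rotations (applied in sequence) followed
#' by cropping; the voxel-size tuple is permuted along with the axes.
#'
#' @param grid a [voxel_grid].
#' @param rotations character vector; each element is an axis name
#'   (`"z"`, `"y"`, `"x"`) about which a +90 degree rotation is applied.
#' @param crop optional list with elements `z`, `y`, `x`, each `(lo, hi)`
#'   1-based inclusive index ranges (missing axes are kept whole), applied
#'   after the rotations.
#' @return a [voxel_grid].
#' @export
reorient <- function(grid, rotations = character(0), crop = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- grid$data
  vs <- grid$voxel_size_um
  for (axname in rotations) {
    axis <- match(axname, c("z", "y", "x"))
    if (is.na(axis)) stop("unknown rotation axis: ", axname, call. = FALSE)
    arr <- rotate90_axis(arr, axis)
    uv <- setdiff(1:3, axis)
    vs[uv] <- vs[rev(uv)]
  }
  if (!is.null(crop)) {
    d <- dim(arr)
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    for (k in 1:3) {
      nm <- c("z", "y", "x")[k]
      if (!is.null(crop[[nm]])) {
        rng <- as.integer(crop[[nm]])
        if (length(rng) != 2L || rng[1] < 1L || rng[2] > d[k] ||
            rng[1] > rng[2])
          stop("crop range out of bounds on axis ", nm, call. = FALSE)
        idx[[k]] <- rng[1]:rng[2]
      }
    }
    arr <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  voxel_grid(arr, vs, grid$bit_depth)
}
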