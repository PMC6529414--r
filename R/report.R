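#' Pipeline configuration
#'
#' A single object capturing every input, threshold and seed of the
#' end-to-end analysis, so a run is fully reproducible from its config. The
#' input is either a phantom spec (synthetic volume with ground truth) or a
#' TIFF stack on disk.
#'
#' @param phantom a [phantom_spec()], or `NULL` when reading from disk.
#' @param input_path TIFF stack path (used when `phantom` is `NULL`).
#' @param voxel_size_um voxel size override for `input_path`.
#' @param bin_factor optional integer block-binning factor applied first.
#' @param window_8bit optional `(lo, hi)` window; when the loaded volume is
#'   16-bit it is converted to 8-bit with this window (percentile default).
#' @param segmentation a [segmentation_config()].
#' @param histogram_bin_um histogram bin width, micrometres.
#' @param distance_excludes_vessels if `TRUE`, the nearest-vessel distance
#'   statistics are computed over non-vessel domain voxels only; default
#'   `FALSE` (vessel voxels contribute distance 0).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = NULL, input_path = NULL,
                            voxel_size_um = NULL, bin_factor = NULL,
                            window_8bit = NULL,
                            segmentation = segmentation_config(),
                            histogram_bin_um = 1,
                            distance_excludes_vessels = FALSE) {
  if (is.null(phantom) && is.null(input_path))
    stop("supply either a phantom spec or an input path", call. = FALSE)
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  structure(list(phantom = phantom, input_path = input_path,
                 voxel_size_um = voxel_size_um, bin_factor = bin_factor,
                 window_8bit = window_8bit, segmentation = segmentation,
                 histogram_bin_um = histogram_bin_um,
                 distance_excludes_vessels = distance_excludes_vessels),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Top-level keys match [pipeline_config()] arguments; the `phantom` and
#' `segmentation` blocks are passed to [phantom_spec()] and
#' [segmentation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$phantom)) {
    if (!is.null(x$phantom$intensity_model$means))
      x$phantom$intensity_model$means <- unlist(x$phantom$intensity_model$means)
    x$phantom <- do.call(phantom_spec, x$phantom)
  }
  if (!is.null(x$segmentation))
    x$segmentation <- do.call(segmentation_config, x$segmentation)
  do.call(pipeline_config, x)
}

#' Run the full morphometry pipeline
#'
#' Executes the stages in order: volume acquisition (phantom generation or
#' TIFF reading, optional binning and 8-bit conversion), segmentation into
#' the class label volume plus exclusion mask and analysis domain, and
#' morphometry (volumes, volume fractions, vessel-diameter histogram by
#' maximal inscribed spheres, nearest-vessel distance histogram and median
#' over the analysis domain, calcification volume and
#' calcification-to-probe distance statistics over the full volume).
#' Deterministic given the config (including the phantom seed).
#'
#' @param config a [pipeline_config()].
#' @return a `morphometry_report`; see [tidy()] and [glance()] methods.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  grid <- stage("volio", {
    if (!is.null(config$phantom)) {
      ph <- generate_phantom(config$phantom)
      truth <- ph$manifest
      ph$grid
    } else {
      read_stack(config$input_path, voxel_size = config$voxel_size_um)
    }
  })
  grid <- stage("volio", {
    g <- grid
    if (!is.null(config$bin_factor) && config$bin_factor > 1)
      g <- bin_volume(g, config$bin_factor)
    if (g$bit_depth == 16L) g <- convert_to_8bit(g, config$window_8bit)
    g
  })

  probe_declared <- !is.null(config$phantom) &&
    isTRUE(config$phantom$probe_params$present)
  seg <- stage("segment",
               segment_volume(grid, config$segmentation,
                              probe_expected = probe_declared))

  vs <- grid$voxel_size_um
  voxvol <- prod(vs)
  n_total <- prod(dim(grid$data))
  bw <- config$histogram_bin_um
  masks <- seg$masks
  domain <- seg$domain

  rep_ <- stage("morphometry", {
    vessel <- masks$vessel
    n_domain <- sum(domain)

    # per-class volumes; vessel/cell fractions are taken inside the domain,
    # probe metal and calcification over the full volume
    cls <- names(masks)
    vol_tbl <- tibble::tibble(
      class = cls,
      voxels = vapply(masks, sum, numeric(1)),
      volume_um3 = vapply(masks, function(m) sum(m) * voxvol, numeric(1)),
      fraction = vapply(cls, function(cl) {
        if (cl %in% c("vessel", "cell")) {
          sum(masks[[cl]] & domain) / n_domain
        } else {
          sum(masks[[cl]]) / n_total
        }
      }, numeric(1)),
      domain = ifelse(cls %in% c("vessel", "cell"),
                      "analysis domain", "full volume"))

    excluded <- list(volume_um3 = sum(seg$exclusion) * voxvol,
                     fraction = sum(seg$exclusion) / n_total)

    if (any(vessel)) {
      # sphere fitting is run on the hole-filled mask: interior voxels lost
      # to noise are not "surrounding space" and must not puncture the
      # inscribed spheres; reported masks and fractions stay unfilled
      th <- local_thickness(fill_holes(vessel), vs)
      diam_hist <- map_histogram(th, vessel & domain, bw)
      dmap <- distance_to_set(vessel, vs, reference = "nearest vessel")
      dist_domain <- if (isTRUE(config$distance_excludes_vessels))
        domain & !vessel else domain
      dist_hist <- map_histogram(dmap, dist_domain, bw)
      dist_median <- median_of_map(dmap, dist_domain)
      diam_median <- median_of_map(th, vessel & domain)
    } else {
      diam_hist <- dist_hist <- NULL
      dist_median <- diam_median <- NA_real_
    }

    if (any(masks$calcification) && any(masks$metal)) {
      pmap <- distance_to_set(masks$metal, vs, reference = "probe")
      calc_hist <- map_histogram(pmap, masks$calcification, bw)
      calc_median <- median_of_map(pmap, masks$calcification)
    } else {
      calc_hist <- NULL
      calc_median <- NA_real_
    }

    list(volumes = vol_tbl, excluded = excluded,
         histograms = list(vessel_diameter = diam_hist,
                           vessel_distance = dist_hist,
                           calc_probe_distance = calc_hist),
         medians = list(vessel_diameter_um = diam_median,
                        vessel_distance_um = dist_median,
                        calc_probe_distance_um = calc_median))
  })

  structure(list(
    volumes = rep_$volumes,
    excluded = rep_$excluded,
    histograms = rep_$histograms,
    medians = rep_$medians,
    investigated_volume_um3 = n_total * voxvol,
    truth = if (!is.null(truth))
      list(vessel_fraction = truth$vessel_fraction,
           class_fractions = as.list(truth$class_fractions)) else NULL,
    provenance = list(config_hash = rlang::hash(config),
                      seed = if (!is.null(config$phantom))
                        config$phantom$seed else NA_integer_,
                      input = config$input_path %||% "phantom",
                      histogram_bin_um = bw)),
    class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>\n")
  cat(sprintf("  investigated volume: %.4g um^3\n", x$investigated_volume_um3))
  cat(sprintf("  excluded volume: %.4g um^3 (%.1f%%)\n",
              x$excluded$volume_um3, 100 * x$excluded$fraction))
  v <- x$volumes
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-14s %.4g um^3 (%.2f%% of %s)\n", v$class[i],
                v$volume_um3[i], 100 * v$fraction[i], v$domain[i]))
  cat(sprintf("  median vessel diameter: %.2f um\n",
              x$medians$vessel_diameter_um))
  cat(sprintf("  median nearest-vessel distance: %.2f um\n",
              x$medians$vessel_distance_um))
  cat(sprintf("  median calcification-probe distance: %.2f um\n",
              x$medians$calc_probe_distance_um))
  invisible(x)
}

#' Percent change of a value relative to a reference
#'
#' @param reference nonzero reference value.
#' @param value new value.
#' @return `100 * (value - reference) / reference`, full precision; use
#'   [round_percent()] for the headline integer form.
#' @examples
#' percent_change(10.7, 17.2)  # +60.7..., rounds to 61
#' @export
percent_change <- function(reference, value) {
  if (reference == 0) stop("reference must be nonzero", call. = FALSE)
  100 * (value - reference) / reference
}

#' Round a percentage to the nearest integer, ties away from zero
#'
#' @param x numeric percentage.
#' @return integer-valued numeric.
#' @export
round_percent <- function(x) sign(x) * floor(abs(x) + 0.5)

report_scalars <- function(r) {
  v <- setNames(r$volumes$fraction, paste0(r$volumes$class, "_fraction"))
  c(as.list(v),
    list(excluded_fraction = r$excluded$fraction,
         excluded_volume_um3 = r$excluded$volume_um3,
         investigated_volume_um3 = r$investigated_volume_um3),
    r$medians)
}

#' Write a morphometry report to JSON and CSV
#'
#' Writes `<path>` (JSON, machine-readable, full precision) plus two CSV
#' companions `<stem>_volumes.csv` and `<stem>_histograms.csv`.
#'
#' @param report a `morphometry_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_report()], [compare_reports()]
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "morphometry_report"))
  ser <- list(volumes = report$volumes,
              excluded = report$excluded,
              medians = report$medians,
              investigated_volume_um3 = report$investigated_volume_um3,
              histograms = lapply(report$histograms, function(h)
                if (is.null(h)) NULL else
                  list(bin_edges = h$bin_edges, counts = h$counts,
                       domain = h$domain)),
              truth = report$truth,
              provenance = report$provenance)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  stem <- sub("\\.json$", "", path)
  write.csv(report$volumes, paste0(stem, "_volumes.csv"), row.names = FALSE)
  hdf <- do.call(rbind, lapply(names(report$histograms), function(nm) {
    h <- report$histograms[[nm]]
    if (is.null(h)) return(NULL)
    cbind(histogram = nm, tidy(h))
  }))
  if (!is.null(hdf))
    write.csv(hdf, paste0(stem, "_histograms.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a morphometry report written by [write_report()]
#'
#' @param path JSON path.
#' @return a `morphometry_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$volumes <- tibble::as_tibble(x$volumes)
  x$histograms <- lapply(x$histograms, function(h) {
    if (is.null(h)) return(NULL)
    structure(list(bin_edges = as.numeric(h$bin_edges),
                   counts = as.integer(h$counts), domain = h$domain),
              class = "tomo_histogram")
  })
  x$medians <- lapply(x$medians, function(m) m %||% NA_real_)
  structure(x, class = "morphometry_report")
}

#' Compare two morphometry reports
#'
#' @param a,b `morphometry_report` objects (or JSON paths).
#' @return tibble with one row per scalar metric: values, delta, percent
#'   change relative to `a` (full precision and rounded). Histogram count
#'   deltas (requiring identical bin widths; shorter histograms are
#'   zero-padded) are attached as attribute `"histogram_deltas"`.
#' @export
compare_reports <- function(a, b) {
  if (is.character(a)) a <- read_report(a)
  if (is.character(b)) b <- read_report(b)
  sa <- report_scalars(a)
  sb <- report_scalars(b)
  keys <- intersect(names(sa), names(sb))
  va <- unlist(sa[keys])
  vb <- unlist(sb[keys])
  pc <- ifelse(is.na(va) | is.na(vb) | va == 0, NA_real_,
               100 * (vb - va) / va)
  out <- tibble::tibble(metric = keys, a = unname(va), b = unname(vb),
                        delta = unname(vb - va),
                        percent_change = unname(pc),
                        percent_change_rounded = round_percent(unname(pc)))
  hd <- list()
  for (nm in intersect(names(a$histograms), names(b$histograms))) {
    ha <- a$histograms[[nm]]; hb <- b$histograms[[nm]]
    if (is.null(ha) || is.null(hb)) next
    wa <- diff(ha$bin_edges[1:2]); wb <- diff(hb$bin_edges[1:2])
    if (!isTRUE(all.equal(wa, wb)))
      stop("histogram '", nm, "' has mismatched bin edges", call. = FALSE)
    n <- max(length(ha$counts), length(hb$counts))
    ca <- c(ha$counts, rep(0L, n - length(ha$counts)))
    cb <- c(hb$counts, rep(0L, n - length(hb$counts)))
    hd[[nm]] <- tibble::tibble(bin_lo = (seq_len(n) - 1) * wa,
                               bin_hi = seq_len(n) * wa,
                               count_a = ca, count_b = cb,
                               delta = cb - ca)
  }
  attr(out, "histogram_deltas") <- hd
  out
}

#' @rdname tomomorph-generics
#' @export
tidy.morphometry_report <- function(x, ...) x$volumes

#' @rdname tomomorph-generics
#' @export
glance.morphometry_report <- function(x, ...) {
  vf <- x$volumes$fraction[x$volumes$class == "vessel"]
  tibble::tibble(
    vessel_fraction = if (length(vf)) vf else NA_real_,
    median_vessel_diameter_um = x$medians$vessel_diameter_um,
    median_vessel_distance_um = x$medians$vessel_distance_um,
    median_calc_probe_distance_um = x$medians$calc_probe_distance_um,
    excluded_fraction = x$excluded$fraction,
    investigated_volume_um3 = x$investigated_volume_um3,
    config_hash = x$provenance$config_hash)
}

#' @rdname tomomorph-generics
#' @param which which histogram to plot: `"vessel_diameter"`,
#'   `"vessel_distance"` or `"calc_probe_distance"`.
#' @export
autoplot.morphometry_report <- function(object, which = "vessel_diameter",
                                        ...) {
  h <- object$histograms[[which]]
  if (is.null(h)) stop("histogram '", which, "' is absent from this report",
                       call. = FALSE)
  lab <- c(vessel_diameter = "vessel diameter (µm)",
           vessel_distance = "distance to nearest vessel (µm)",
           calc_probe_distance = "calcification-probe distance (µm)")[which]
  autoplot(h) + ggplot2::labs(x = lab)
}
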