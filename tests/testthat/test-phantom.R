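test_that("degenerate spec yields a uniform tissue volume", {
  spec <- phantom_spec(shape = c(8, 10, 12), seed = 1,
                       vessel_params = list(n_vessels = 0L,
                                            target_fraction = NULL),
                       cell_params = list(density_per_mm3 = 0),
                       probe_params = list(present = FALSE),
                       calc_params = list(n_blobs = 0L),
                       intensity_model = list(noise_sd = 0))
  ph <- generate_phantom(spec)
  expect_true(all(ph$labels$labels == tomo_classes()[["tissue"]]))
  expect_true(all(ph$grid$data == 120))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- small_probe_spec(seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$grid$data, b$grid$data)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- generate_phantom(small_probe_spec(seed = 43))
  expect_false(identical(a$grid$data, c$grid$data))
})

test_that("manifest per-class voxel counts equal label counts exactly", {
  ph <- generate_phantom(small_probe_spec(seed = 5))
  cnt <- label_counts(ph$labels)
  expect_identical(ph$manifest$class_counts$voxels, cnt$voxels)
  expect_equal(sum(cnt$voxels), prod(dim(ph$labels)))
  # exactly one class per voxel by construction; metal never overlaps vessel
  expect_equal(sum(label_mask(ph$labels, "metal") &
                     label_mask(ph$labels, "vessel")), 0)
})

test_that("a probe wider than the volume is rejected with a sizing error", {
  spec <- phantom_spec(shape = c(8, 20, 20),
                       probe_params = list(present = TRUE, width_um = 380))
  expect_error(generate_phantom(spec), "does not fit")
})

test_that("rasterized straight tube matches the in-plane offset enumeration", {
  # radius 2 um, 1 um voxels: every slice holds the 13 offsets dx^2+dy^2 <= 4
  m <- rasterize_tube(rbind(c(0, 10.5, 10.5), c(20, 10.5, 10.5)),
                      diameter_um = 4, shape = c(20, 21, 21),
                      voxel_size_um = 1)
  expect_equal(unique(apply(m, 1, sum)), 13)
  off <- expand.grid(dy = -2:2, dx = -2:2)
  expect_equal(sum(off$dy^2 + off$dx^2 <= 4), 13)
})

test_that("zero-diameter tube reduces to the nearest-voxel chain", {
  m <- rasterize_tube(rbind(c(2.5, 0, 2.5), c(2.5, 5, 2.5)),
                      diameter_um = 0, shape = c(5, 5, 5), voxel_size_um = 1)
  expect_equal(sum(m), 5)
  expect_true(all(which(m, arr.ind = TRUE)[, c(1, 3)] == 3))
})

test_that("zero-length ball-ended segment gives the exact digital ball", {
  b <- rasterize_tube(rbind(c(10.5, 10.5, 10.5)), diameter_um = 8,
                      shape = c(21, 21, 21), voxel_size_um = 1)
  off <- expand.grid(-5:5, -5:5, -5:5)
  expect_equal(sum(b), sum(rowSums(off^2) <= 16))
})

test_that("rasterized cylinder volume is within 10% of pi r^2 L", {
  m <- rasterize_tube(rbind(c(0, 10.5, 10.5), c(200, 10.5, 10.5)),
                      diameter_um = 8, shape = c(200, 21, 21),
                      voxel_size_um = 1)
  analytic <- pi * 4^2 * 200
  expect_lt(abs(sum(m) - analytic) / analytic, 0.10)
})

test_that("centerline outside the volume warns and returns an empty mask", {
  expect_warning(
    m <- rasterize_tube(rbind(c(100, 100, 100), c(120, 100, 100)),
                        diameter_um = 2, shape = c(10, 10, 10),
                        voxel_size_um = 1),
    "outside")
  expect_false(any(m))
})

test_that("zero-noise rendering reproduces class means; metal saturates", {
  lab <- array(tomo_classes()[["tissue"]], c(4, 4, 4))
  lab[1, , ] <- tomo_classes()[["metal"]]
  lab[2, , ] <- tomo_classes()[["vessel"]]
  lv <- label_volume(lab, voxel_size_um = 1)
  model <- list(means = c(cavity = 40, vessel = 60, cell = 90, tissue = 120,
                          calcification = 220, metal = 255),
                noise_sd = 0, bit_depth = 8L)
  g <- render_intensities(lv, model)
  expect_true(all(g$data[1, , ] == 255))
  expect_true(all(g$data[2, , ] == 60))
  expect_true(all(g$data[3:4, , ] == 120))
})

test_that("intensity models violating the contrast polarity are rejected", {
  lv <- label_volume(array(1L, c(2, 2, 2)), voxel_size_um = 1)
  bad <- list(means = c(cavity = 40, vessel = 130, cell = 90, tissue = 120,
                        calcification = 220, metal = 255),
              noise_sd = 0, bit_depth = 8L)
  expect_error(render_intensities(lv, bad), "ordering")
  nosat <- list(means = c(cavity = 40, vessel = 60, cell = 90, tissue = 120,
                          calcification = 220, metal = 250),
                noise_sd = 0, bit_depth = 8L)
  expect_error(render_intensities(lv, nosat), "saturation")
})

test_that("noise realizations differ by seed but share class means", {
  lab <- array(tomo_classes()[["tissue"]], c(20, 40, 40))
  lab[, 1:20, ] <- tomo_classes()[["vessel"]]
  lv <- label_volume(lab, voxel_size_um = 1)
  model <- list(means = c(cavity = 40, vessel = 60, cell = 90, tissue = 120,
                          calcification = 220, metal = 255),
                noise_sd = 8, bit_depth = 8L)
  g1 <- render_intensities(lv, model, seed = 1)
  g2 <- render_intensities(lv, model, seed = 2)
  expect_false(identical(g1$data, g2$data))
  for (g in list(g1, g2)) {
    n <- sum(lab == tomo_classes()[["vessel"]])
    se <- 8 / sqrt(n)
    expect_lt(abs(mean(g$data[lab == tomo_classes()[["vessel"]]]) - 60), 3 * se)
    expect_lt(abs(mean(g$data[lab == tomo_classes()[["tissue"]]]) - 120), 3 * se)
  }
})

test_that("missing-wedge artifact modifies only the probe band", {
  ph <- generate_phantom(small_probe_spec(seed = 3, inflation = 1.5))
  spec <- small_probe_spec(seed = 3, inflation = 1.5)
  # identity when inflation is switched off
  base <- generate_phantom(small_probe_spec(seed = 3, inflation = 0))
  met <- label_mask(base$labels, "metal")
  g0 <- apply_missing_wedge_artifact(base$grid, met, axis = "y",
                                     band_halfwidth_um = 10, inflation = 0,
                                     noise_sd = 8, seed = 9)
  expect_identical(g0$data, base$grid$data)

  # half-width 0: only axis lines through probe voxels may change
  g1 <- apply_missing_wedge_artifact(base$grid, met, axis = "y",
                                     band_halfwidth_um = 0, inflation = 2,
                                     noise_sd = 8, seed = 9)
  fp <- apply(met, c(1, 3), any)
  line_mask <- aperm(array(fp, c(dim(fp), dim(met)[2])), c(1, 3, 2))
  expect_identical(g1$data[!line_mask], base$grid$data[!line_mask])
  expect_false(identical(g1$data[line_mask], base$grid$data[line_mask]))

  # SNR (class-mean difference / tissue noise SD) is lower inside the band
  lab <- base$labels
  tis <- label_mask(lab, "tissue")
  ves <- label_mask(lab, "vessel")
  band <- aperm(array(
    matrix(sqrt(tomomorph:::cpp_edt_sq(as.vector(fp), c(1L, dim(fp)),
                                       c(1, 1, 1), FALSE)) <= 10,
           dim(fp)[1], dim(fp)[2]) , c(dim(fp), dim(met)[2])), c(1, 3, 2))
  g2 <- apply_missing_wedge_artifact(base$grid, met, axis = "y",
                                     band_halfwidth_um = 10, inflation = 2,
                                     noise_sd = 8, seed = 9)
  snr <- function(g, region) {
    (mean(g$data[tis & region]) - mean(g$data[ves & region])) /
      sd(g$data[tis & region])
  }
  expect_lt(snr(g2, band), snr(g2, !band))
})

test_that("phantom spec round-trips through YAML", {
  spec <- small_probe_spec(seed = 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  expect_equal(spec2$probe_params, spec$probe_params)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec2)
  expect_identical(a$grid$data, b$grid$data)
})
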