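test_that("distance to a single-voxel set follows Euclidean geometry", {
  m <- array(FALSE, c(3, 3, 3))
  m[2, 2, 2] <- TRUE
  dm <- distance_to_set(m, 1)
  expect_equal(dm$values[1, 2, 2], 1)          # face neighbour
  expect_equal(dm$values[1, 1, 2], sqrt(2))    # edge neighbour
  expect_equal(dm$values[1, 1, 1], sqrt(3))    # corner
  expect_equal(dm$values[2, 2, 2], 0)

  m2 <- array(FALSE, c(8, 8, 8))
  m2[1, 1, 1] <- TRUE
  dm2 <- distance_to_set(m2, 1)
  expect_equal(dm2$values[4, 5, 1], 5)         # 3-4-5 triangle
  expect_true(all(distance_to_set(array(TRUE, c(3, 3, 3)), 1)$values == 0))
  expect_error(distance_to_set(array(FALSE, c(3, 3, 3)), 1), "empty")
})

test_that("EDT to background uses the padding convention", {
  m <- array(TRUE, c(5, 5, 5))
  d <- edt_to_background(m, 1)
  expect_equal(d$values[1, 1, 1], 1)  # outside counts as background
  expect_equal(d$values[3, 3, 3], 3)

  iso <- array(FALSE, c(5, 5, 5)); iso[3, 3, 3] <- TRUE
  expect_equal(edt_to_background(iso, 1)$values[3, 3, 3], 1)
  expect_true(all(edt_to_background(iso, 1)$values[!iso] == 0))
})

test_that("anisotropic spacings weight each axis by its pitch", {
  # background one step along the 2 um axis and two steps along a 1 um axis
  m <- array(TRUE, c(1, 5, 3))
  m[1, 1, 2] <- FALSE  # two steps along y (1 um)
  m[1, 3, 1] <- FALSE  # one step along x (2 um)
  dm <- distance_to_set(!m, c(5, 1, 2))
  expect_equal(dm$values[1, 3, 2], 2)
})

test_that("distance transforms match exhaustive search on random masks", {
  for (seed in 1:6) {
    m <- random_blob_tube_mask(c(12, 12, 12), seed)
    if (!any(m) || all(m)) next
    sp <- if (seed %% 2 == 0) c(1, 1, 2) else c(1, 1, 1)
    expect_equal(edt_to_background(m, sp)$values,
                 exhaustive_distance(!m, sp, pad = TRUE),
                 tolerance = 1e-12)
    expect_equal(distance_to_set(m, sp)$values,
                 exhaustive_distance(m, sp, pad = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("adding target voxels never increases any distance", {
  m <- random_blob_tube_mask(c(14, 14, 14), 7)
  extra <- m
  set.seed(8)
  extra[sample(which(!m), 30)] <- TRUE
  d1 <- distance_to_set(m, 1)$values
  d2 <- distance_to_set(extra, 1)$values
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("local thickness handles the canonical analytic phantoms", {
  # isolated voxel: EDT 1, covers itself -> diameter 2
  s <- array(FALSE, c(5, 5, 5)); s[3, 3, 3] <- TRUE
  expect_equal(local_thickness(s, 1)$values[3, 3, 3], 2)

  # 5-voxel slab: mid-layer EDT 3 covers |dz| <= 2 -> 6 um on all layers
  sl <- array(FALSE, c(13, 21, 21)); sl[5:9, , ] <- TRUE
  th <- local_thickness(sl, 1)
  expect_true(all(th$values[5:9, 5:17, 5:17] == 6))
  expect_true(all(th$values[!sl] == 0))

  # digital ball of radius 4: thickness at center = 2 * exhaustive EDT
  b <- rasterize_tube(rbind(c(10.5, 10.5, 10.5)), 8, c(21, 21, 21), 1)
  edt_center <- exhaustive_distance(!b, c(1, 1, 1), pad = TRUE)[11, 11, 11]
  expect_equal(local_thickness(b, 1)$values[11, 11, 11], 2 * edt_center)
})

test_that("accelerated local thickness equals the brute-force definition", {
  for (seed in 1:8) {
    m <- random_blob_tube_mask(c(16, 16, 16), seed + 100)
    sp <- if (seed %% 2 == 0) c(1, 1, 2) else c(1, 1, 1)
    a <- local_thickness(m, sp)$values
    b <- local_thickness_bruteforce(m, sp)$values
    expect_identical(a, b)
  }
})

test_that("thickness dominates twice the EDT and grows under dilation", {
  m <- random_blob_tube_mask(c(16, 16, 16), 200)
  th <- local_thickness(m, 1)$values
  edt <- edt_to_background(m, 1)$values
  expect_true(all(th[m] >= 2 * edt[m]))
  expect_true(all(th[m] > 0))

  grown <- m | rasterize_tube(rbind(c(8, 8, 8)), 8, c(16, 16, 16), 1)
  th2 <- local_thickness(grown, 1)$values
  expect_true(all(th2[m] >= th[m]))
})

test_that("brute-force thickness on an empty mask is all zero", {
  out <- local_thickness_bruteforce(array(FALSE, c(4, 4, 4)), 1)
  expect_true(all(out$values == 0))
})

test_that("structure volumes scale with the voxel volume", {
  m <- array(TRUE, c(10, 10, 10))
  expect_equal(structure_volume(m, 1), 1000)
  expect_equal(structure_volume(m, 0.876), 1000 * 0.876^3)
  expect_equal(structure_volume(array(FALSE, c(2, 2, 2)), 1), 0)
})

test_that("volume fractions behave as set arithmetic", {
  dom <- array(FALSE, c(5, 5, 5)); dom[1:5, 1:5, 1:5] <- TRUE
  s <- array(FALSE, c(5, 5, 5)); s[1:8] <- TRUE
  expect_equal(volume_fraction(s, dom), 8 / 125)  # 6.4%
  expect_equal(volume_fraction(dom, dom), 1)
  expect_error(volume_fraction(s, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("zero-noise phantom vessel fraction equals manifest truth exactly", {
  ph <- generate_phantom(small_probe_spec(seed = 31, noise_sd = 0))
  seg <- segment_volume(ph$grid,
                        segmentation_config(exclusion_distance_um = 12,
                                            min_component_voxels = 1L))
  full <- array(TRUE, dim(ph$grid$data))
  expect_equal(volume_fraction(seg$masks$vessel, full),
               unname(ph$manifest$class_fractions["vessel"]))
})

test_that("histograms bin half-open from zero and conserve counts", {
  z <- array(0, c(3, 3, 3))
  h <- map_histogram(z, NULL, 1)
  expect_equal(h$counts, 27L)
  expect_equal(h$bin_edges, c(0, 1))

  pm <- array(FALSE, c(10, 10, 60)); pm[, , seq(11, 60, by = 20)] <- TRUE
  dm <- distance_to_set(pm, 1)
  h2 <- map_histogram(dm, NULL, 1)
  expect_equal(h2$counts, c(3L, rep(6L, 9), 3L) * 100L)
  expect_equal(sum(h2$counts), length(dm$values))

  empty <- map_histogram(dm, array(FALSE, c(10, 10, 60)), 1)
  expect_true(all(empty$counts == 0))
  expect_error(map_histogram(dm, NULL, 0), "bin width")
})

test_that("medians use the even-count convention", {
  expect_equal(median_of_map(array(c(1, 2, 3), c(3, 1, 1))), 2)
  expect_equal(median_of_map(array(c(1, 2, 3, 4), c(4, 1, 1))), 2.5)
  pm <- array(FALSE, c(10, 10, 60)); pm[, , seq(11, 60, by = 20)] <- TRUE
  expect_equal(median_of_map(distance_to_set(pm, 1)), 5)
  expect_error(median_of_map(array(1, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
})

test_that("tube diameters are recovered with at most the one-voxel bias", {
  for (d in c(4, 8)) {
    m <- rasterize_tube(rbind(c(0, 20.5, 20.5), c(40, 20.5, 20.5)), d,
                        c(40, 41, 41), 1)
    th <- local_thickness(m, 1)
    vals <- th$values[m]
    mode_val <- as.numeric(names(which.max(table(vals))))
    expect_gte(mode_val, d)
    expect_lte(mode_val, d + 2)
  }
})
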