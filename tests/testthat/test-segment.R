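zero_noise_phantom <- function(seed = 21) {
  generate_phantom(small_probe_spec(seed = seed, noise_sd = 0))
}

test_that("threshold windows are inclusive and monotone", {
  set.seed(10)
  g <- voxel_grid(array(sample(0:255, 6^3, TRUE), c(6, 6, 6)), 1)
  expect_equal(segment_by_threshold(g, c(255, 255)), g$data == 255)
  expect_true(all(segment_by_threshold(g, c(0, 255))))
  m1 <- segment_by_threshold(g, c(50, 100))
  m2 <- segment_by_threshold(g, c(40, 120))
  expect_true(all(m2[m1]))  # larger window gives a superset
  expect_equal(segment_by_threshold(g, c(80, 80)), g$data == 80)
})

test_that("thresholding a zero-noise phantom recovers the window classes", {
  ph <- zero_noise_phantom()
  m <- segment_by_threshold(ph$grid, c(50, 70))  # only vessel mean (60) inside
  expect_equal(m, label_mask(ph$labels, "vessel"))
})

test_that("clean_mask removes components below the size threshold", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:5, 1, 1] <- TRUE               # size 5
  m[8:10, 1:5, 1:4] <- TRUE          # size 60
  out <- clean_mask(m, 10)
  expect_equal(sum(out), 60)
  expect_true(all(!out | m))
  expect_identical(clean_mask(m, 1), m)
})

test_that("corner-touching voxels join under 26- but not 6-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
  expect_equal(max(label_components(m, 18)), 2)  # corner contact only
})

test_that("fill_holes closes enclosed pockets but not boundary-connected ones", {
  m <- array(FALSE, c(9, 9, 9))
  m[3:7, 3:7, 3:7] <- TRUE
  m[5, 5, 5] <- FALSE          # enclosed single-voxel hole
  m[5, 5, 3] <- FALSE          # notch on the cube face: 6-connected outwards?
  filled <- fill_holes(m)
  expect_true(filled[5, 5, 5])
  # the face voxel removed above sits on the cube surface, so its void is
  # connected to the outside background and must not be filled
  expect_false(filled[5, 5, 3])
  expect_true(all(filled[m]))
  expect_identical(fill_holes(array(TRUE, c(3, 3, 3))), array(TRUE, c(3, 3, 3)))
})

test_that("contrast enhancement rescales and leaves degenerate input alone", {
  g <- voxel_grid(array(rep(c(10, 20), 32), c(4, 4, 4)), 1)
  out <- enhance_contrast(g, c(0, 100))
  expect_setequal(unique(as.vector(out$data)), c(0, 255))

  full <- voxel_grid(array(seq(0, 255, length.out = 64) |> round(), c(4, 4, 4)), 1)
  expect_equal(enhance_contrast(full, c(0, 100))$data, full$data)

  const <- voxel_grid(array(7, c(4, 4, 4)), 1)
  expect_warning(out2 <- enhance_contrast(const, c(0, 100)), "constant")
  expect_identical(out2$data, const$data)
})

test_that("high-contrast classification separates probe metal and calcification", {
  ph <- zero_noise_phantom()
  hc <- classify_high_contrast(ph$grid, 240, c(170, 239))
  expect_equal(hc$probe, label_mask(ph$labels, "metal"))
  expect_equal(hc$calcification, label_mask(ph$labels, "calcification"))
  expect_equal(sum(hc$probe & hc$calcification), 0)

  # no voxel reaches the metal threshold: everything in the window is
  # calcification and the probe mask is empty
  g <- voxel_grid(array(200, c(4, 4, 4)), 1)
  hc2 <- classify_high_contrast(g, 240, c(170, 239), min_component_voxels = 1)
  expect_false(any(hc2$probe))
  expect_true(all(hc2$calcification))
  expect_warning(classify_high_contrast(g, 240, c(170, 239),
                                        probe_expected = TRUE), "no metal")
})

test_that("cavity segmentation keeps only probe-adjacent components", {
  ph <- zero_noise_phantom()
  probe <- label_mask(ph$labels, "metal")
  cav <- segment_cavity(ph$grid, probe, c(24, 56))
  expect_equal(cav & !probe, label_mask(ph$labels, "cavity"),
               ignore_attr = TRUE)

  # a low-intensity blob far from the probe is not cavity
  g <- array(120, c(10, 20, 20))
  g[5, 2:3, 2:3] <- 40                  # far blob
  g[5, 10, 10] <- 255                   # probe voxel
  g[5, 10, 11] <- 40                    # adjacent candidate
  vg <- voxel_grid(g, 1)
  pm <- array(g == 255, dim(g))
  cav2 <- segment_cavity(vg, pm, c(24, 56))
  expect_true(cav2[5, 10, 11])
  expect_false(any(cav2[, 1:5, 1:5]))

  # no probe -> empty cavity
  expect_false(any(segment_cavity(vg, array(FALSE, dim(g)), c(24, 56))))
})

test_that("radial exclusion mask matches the offset enumeration", {
  pm <- array(FALSE, c(6, 21, 21))
  pm[, 11, 11] <- TRUE  # single-voxel column along z
  ex <- build_exclusion_mask(pm, 1, distance_um = 2, mode = "radial")
  expect_equal(unique(apply(ex, 1, sum)), 13)  # dx^2+dy^2 <= 4

  expect_equal(build_exclusion_mask(pm, 1, distance_um = 0), pm)
  expect_true(all(build_exclusion_mask(pm, 1, distance_um = 1000)))
  expect_false(any(build_exclusion_mask(array(FALSE, c(3, 3, 3)), 1, 5)))
})

test_that("directional exclusion keeps only the two half-spaces plus probe", {
  pm <- array(FALSE, c(4, 11, 11))
  pm[, 5:7, 6] <- TRUE  # slab spanning y = 5..7
  ex <- build_exclusion_mask(pm, 1, distance_um = 3, mode = "directional",
                             axis = "y")
  expect_true(all(ex[pm]))
  inplane <- which(ex[1, , ], arr.ind = TRUE)
  lateral <- inplane[, 1] >= 5 & inplane[, 1] <= 7
  expect_true(all(inplane[lateral, 2] == 6))  # inside the slab only the probe
  rad <- build_exclusion_mask(pm, 1, distance_um = 3, mode = "radial")
  expect_true(all(rad[ex]))  # directional is a subset of radial
})

test_that("analysis domain is the complement of probe, cavity and exclusion", {
  ph <- zero_noise_phantom()
  seg <- segment_volume(ph$grid, segmentation_config(exclusion_distance_um = 12))
  union_masks <- seg$masks$metal | seg$masks$cavity | seg$exclusion
  expect_equal(sum(seg$domain), prod(dim(ph$grid$data)) - sum(union_masks))
  expect_error(build_analysis_domain(array(TRUE, c(2, 2, 2))), "empty")
  expect_true(all(build_analysis_domain(shape = c(2, 2, 2))))
})

test_that("segmentation masks are pairwise disjoint", {
  ph <- generate_phantom(small_probe_spec(seed = 22, noise_sd = 8))
  seg <- segment_volume(ph$grid, segmentation_config(exclusion_distance_um = 12))
  total <- Reduce(`+`, lapply(seg$masks, function(m) as.integer(m)))
  expect_true(all(total <= 1))
})

test_that("zero-noise segmentation recovers every class exactly", {
  # component cleanup is a noise-robustness device; without noise it is
  # disabled so that fragments left where classes overlap are kept
  ph <- zero_noise_phantom()
  seg <- segment_volume(ph$grid,
                        segmentation_config(exclusion_distance_um = 12,
                                            min_component_voxels = 1L))
  for (cl in c("metal", "calcification", "cavity", "vessel", "cell")) {
    expect_equal(dice_coefficient(seg$masks[[cl]], label_mask(ph$labels, cl)),
                 1, info = cl)
  }
  expect_equal(label_mask(seg$labels, "tissue"),
               label_mask(ph$labels, "tissue"))
})
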