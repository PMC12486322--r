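# Centre of mass, alignment, projections, spans, densities, offsets

mask_from_voxels <- function(vox, shape = c(6, 6, 6),
                             voxel_size = c(2, 1, 1)) {
  m <- array(FALSE, shape)
  for (v in vox) m[v[1], v[2], v[3]] <- TRUE
  binary_mask(m, voxel_size)
}

test_that("centre of mass averages positive-voxel coordinates", {
  single <- mask_from_voxels(list(c(4, 7, 2)), shape = c(8, 8, 8))
  expect_equal(unname(centre_of_mass(single)$voxel), c(4, 7, 2))
  # a full cube centred at (5,5,5)
  m <- array(FALSE, c(9, 9, 9)); m[4:6, 4:6, 4:6] <- TRUE
  expect_equal(unname(centre_of_mass(binary_mask(m))$voxel), c(5, 5, 5))
  # L-shape {(1,1,1),(1,1,2),(1,2,1)} (1-based) -> (1, 4/3, 4/3)
  l <- mask_from_voxels(list(c(1, 1, 1), c(1, 1, 2), c(1, 2, 1)))
  expect_equal(unname(centre_of_mass(l)$voxel), c(1, 4 / 3, 4 / 3))
  # micrometre form scales by the per-axis voxel size
  expect_equal(unname(centre_of_mass(l)$um), c(0, 1 / 3, 1 / 3))
  expect_error(centre_of_mass(mask_from_voxels(list())), "no positive")
})

test_that("alignment centres the cloud inside the window and preserves counts", {
  single <- mask_from_voxels(list(c(2, 2, 2)), shape = c(6, 6, 6))
  out <- align_to_centre(single, c(5, 5, 5))
  expect_equal(dim(out$mask), c(5L, 5L, 5L))
  expect_true(out$mask[3, 3, 3])
  expect_equal(sum(out$mask), 1)
  # identity: window = full shape, cloud already centred
  m <- array(FALSE, c(7, 7, 7)); m[3:5, 3:5, 3:5] <- TRUE
  bm <- binary_mask(m)
  expect_identical(align_to_centre(bm, c(7, 7, 7))$mask, m)
  # blob near a boundary: count preserved, clipped side zero-padded
  edge <- mask_from_voxels(list(c(1, 1, 1), c(1, 1, 2), c(2, 1, 1)),
                           shape = c(6, 6, 6))
  al <- align_to_centre(edge, c(6, 6, 6))
  expect_equal(sum(al$mask), 3)
})

test_that("summed projections conserve the positive-voxel count", {
  # a 3-voxel dorsoventral column projects to a single pixel of value 3
  col <- mask_from_voxels(list(c(2, 4, 5), c(3, 4, 5), c(4, 4, 5)))
  p <- summed_projection(col, "DV")
  expect_equal(sum(p == 3), 1)
  expect_equal(sum(p), 3)
  expect_equal(p[4, 5], 3L)
  # empty mask projects to zeros
  expect_true(all(summed_projection(mask_from_voxels(list()), "ML") == 0))
  # conservation on random masks, against the brute-force oracle
  for (seed in 1:5) {
    bm <- random_mask(c(6, 6, 6), 0.4, seed = seed)
    for (ax in c("DV", "RC", "ML")) {
      p <- summed_projection(bm, ax)
      expect_equal(sum(p), sum(bm$mask))
      expect_equal(unclass(p),
                   brute_projection(bm$mask, c(DV = 1, RC = 2, ML = 3)[[ax]]),
                   ignore_attr = TRUE)
    }
  }
  expect_error(summed_projection(col, "XY"))
})

test_that("spans of a solid box follow the thresholded bounding rectangles", {
  m <- array(FALSE, c(20, 40, 60))
  m[6:15, 11:30, 16:45] <- TRUE          # 10 x 20 x 30 voxel box
  bm <- binary_mask(m, voxel_size = c(2, 1, 1))
  sp <- measure_spans(bm)
  expect_equal(sp, c(ML = 30, RC = 20, DV = 20))
})

test_that("moving two blobs apart stretches only the ML span", {
  base <- array(FALSE, c(12, 30, 40))
  blob <- function(x0) {
    m <- base
    m[5:8, 13:18, x0:(x0 + 5)] <- TRUE
    m
  }
  near <- binary_mask(blob(10) | blob(18), voxel_size = c(2, 1, 1))
  far <- binary_mask(blob(10) | blob(28), voxel_size = c(2, 1, 1))
  s_near <- measure_spans(near); s_far <- measure_spans(far)
  expect_gt(s_far[["ML"]], s_near[["ML"]])
  expect_equal(s_far[["RC"]], s_near[["RC"]])
  expect_equal(s_far[["DV"]], s_near[["DV"]])
})

test_that("areal density of a solid box equals its depth along the collapsed axis", {
  m <- array(FALSE, c(20, 40, 60))
  m[6:15, 11:30, 16:45] <- TRUE
  bm <- binary_mask(m, voxel_size = c(2, 1, 1))   # 1 um x 1 um DV pixels
  expect_equal(areal_density(bm, "DV"), 10)
  # translation leaves the density unchanged
  m2 <- array(FALSE, c(20, 40, 60))
  m2[8:17, 5:24, 20:49] <- TRUE
  expect_equal(areal_density(binary_mask(m2, voxel_size = c(2, 1, 1)), "DV"),
               10)
})

test_that("COM is translation-equivariant; spans, densities and counts invariant", {
  set.seed(31)
  m <- array(FALSE, c(10, 12, 14))
  m[3:6, 3:8, 3:9] <- array(runif(4 * 6 * 7) < 0.5, c(4, 6, 7))
  shift <- c(2, 3, 4)
  m2 <- array(FALSE, c(10, 12, 14))
  m2[(3:6) + shift[1], (3:8) + shift[2], (3:9) + shift[3]] <-
    m[3:6, 3:8, 3:9]
  a <- binary_mask(m, voxel_size = c(2, 1, 1))
  b <- binary_mask(m2, voxel_size = c(2, 1, 1))
  expect_equal(centre_of_mass(b)$voxel - centre_of_mass(a)$voxel,
               c(z = 2, y = 3, x = 4))
  expect_equal(measure_spans(a), measure_spans(b))
  for (ax in c("DV", "ML", "RC"))
    expect_equal(areal_density(a, ax), areal_density(b, ax))
  expect_equal(sum(a$mask), sum(b$mask))
})

test_that("morphometry agrees with the brute-force oracle on random masks", {
  for (seed in 1:30) {
    shp <- sample(4:8, 3, replace = TRUE)
    bm <- random_mask(shp, runif(1, 0.1, 0.6), seed = seed + 100)
    if (sum(bm$mask) == 0) next
    expect_equal(unname(centre_of_mass(bm)$voxel), brute_com(bm$mask))
    expect_equal(measure_spans(bm),
                 brute_spans(bm$mask, bm$voxel_size))
    for (ax in c("DV", "RC", "ML"))
      expect_equal(areal_density(bm, ax),
                   brute_density(bm$mask, bm$voxel_size,
                                 c(DV = 1, RC = 2, ML = 3)[[ax]]))
  }
})

test_that("focus offsets are distances to the annotated borders", {
  l <- mask_from_voxels(list(c(3, 4, 5)), shape = c(8, 8, 8))
  # borders at zero: offsets equal the COM coordinates in um
  off <- focus_offsets(l, border_annotation(0, 0))
  expect_equal(off, c(ML = 4, DV = 4))   # x = (5-1)*1, z = (3-1)*2
  # shifting the cloud +10 um laterally changes the ML offset by 10 um
  l2 <- mask_from_voxels(list(c(3, 4, 15)), shape = c(8, 8, 20))
  off2 <- focus_offsets(l2, border_annotation(0, 0))
  expect_equal(off2[["ML"]] - off[["ML"]], 10)
  expect_error(focus_offsets(l, NULL), "border_annotation")
})

test_that("planar shift and percent change reproduce the derived field metrics", {
  expect_equal(planar_shift(0, 0), 0)
  expect_equal(round(planar_shift(18.75, 1.42), 1), 18.8)
  expect_equal(round(planar_shift(14.00, 13.54), 1), 19.5)
  expect_error(planar_shift(NA, 1), "finite")
  expect_equal(round(percent_change(167.9, 191.6)), 14)
  expect_equal(round(percent_change(30.8, 24.0)), -22)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "non-zero")
})

test_that("terminal_field_metrics bundles all per-specimen measurements", {
  m <- array(FALSE, c(20, 40, 60))
  m[6:15, 11:30, 16:45] <- TRUE
  bm <- binary_mask(m, voxel_size = c(2, 1, 1))
  met <- terminal_field_metrics(bm, border_annotation(0, 0))
  expect_equal(met$voxel_count, 6000)
  expect_equal(met$spans_um, c(ML = 30, RC = 20, DV = 20))
  expect_equal(met$density_vox_um2[["DV"]], 10)
  expect_equal(met$offsets_um[["ML"]], 29.5)  # x centre (30.5-1)*1
  expect_equal(met$offsets_um[["DV"]], 19)    # z centre (10.5-1)*2
})
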