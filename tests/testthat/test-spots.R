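box_spot <- function(dims, z, ys, xs, value = 100) {
  arr <- array(0, dims)
  arr[z, ys, xs] <- value
  arr
}

test_that("an empty channel yields no spots and a zero particle count", {
  arr <- array(0, c(8, 32, 32))
  cfg <- analysis_config(spot_threshold = "fixed:10")
  expect_equal(nrow(detect_spots(arr, cfg, voxel_spacing())), 0L)
  expect_equal(mip_count(arr, cfg, voxel_spacing()), 0L)
})

test_that("spot geometry follows directly from the definitions", {
  # 5x5 footprint over 7 planes at dz = 0.25: area 25 * 0.09^2, extent 1.75
  arr <- box_spot(c(12, 32, 32), z = 3:9, ys = 10:14, xs = 10:14)
  cfg <- analysis_config(spot_threshold = "fixed:50")
  spots <- detect_spots(arr, cfg, voxel_spacing())
  expect_equal(nrow(spots), 1L)
  expect_equal(spots$xy_area_um2, 25 * 0.09^2)
  expect_equal(spots$z_extent_um, 7 * 0.25)
  expect_false(spots$edge_touching)
  expect_equal(spots$y_um, 11.5 * 0.09)  # centroid of rows 10:14

  # same footprint over 5 planes (1.25 um) fails the 1.5 um height criterion
  short <- box_spot(c(12, 32, 32), z = 3:7, ys = 10:14, xs = 10:14)
  expect_equal(nrow(detect_spots(short, cfg, voxel_spacing())), 0L)

  # a spot reaching the top plane is kept but flagged
  edge <- box_spot(c(12, 32, 32), z = 1:7, ys = 10:14, xs = 10:14)
  expect_true(detect_spots(edge, cfg, voxel_spacing())$edge_touching)
})

test_that("detected component counts match the flood-fill oracle", {
  set.seed(55)
  cfg6 <- analysis_config(spot_threshold = "fixed:0.5", connectivity = 6,
                          min_xy_area = 0, min_z_height = 1e-9)
  cfg26 <- analysis_config(spot_threshold = "fixed:0.5", connectivity = 26,
                           min_xy_area = 0, min_z_height = 1e-9)
  for (i in 1:15) {
    d <- sample(4:12, 3, replace = TRUE)
    mask <- array(rbinom(prod(d), 1, 0.2), d)
    expect_equal(nrow(detect_spots(mask, cfg6, voxel_spacing())),
                 max(flood_fill_oracle(mask, 6)))
    expect_equal(nrow(detect_spots(mask, cfg26, voxel_spacing())),
                 max(flood_fill_oracle(mask, 26)))
  }
})

test_that("axial overlap counts majority-covered spot planes", {
  sp <- voxel_spacing()
  vox <- as.matrix(expand.grid(z = 2:9, y = 10:14, x = 10:14))
  full <- binary_mask(array(1L, c(12, 32, 32)), sp)
  none <- binary_mask(array(0L, c(12, 32, 32)), sp)
  expect_equal(axial_overlap(vox, full), 1)
  expect_equal(axial_overlap(vox, none), 0)
  # mask positive on 6 of the 8 spot planes -> 0.75
  part <- array(0L, c(12, 32, 32))
  part[2:7, , ] <- 1L
  expect_equal(axial_overlap(vox, binary_mask(part, sp)), 0.75)
  # a plane covering less than half the footprint does not count
  half <- array(0L, c(12, 32, 32))
  half[2:7, , ] <- 1L
  half[8, 10:14, 10:11] <- 1L  # 10 of 25 footprint pixels
  expect_equal(axial_overlap(vox, binary_mask(half, sp)), 0.75)
  expect_error(axial_overlap(vox, binary_mask(array(1L, c(4, 8, 8)), sp)),
               class = "oligouptake_validation_error")
})

make_overlap_scene <- function(mask_planes, spot_planes = 3:12,
                               xs = 20:24, ys = 20:24, gap_px = 0) {
  # mask slab over given planes; spot column laterally displaced by gap_px
  sp <- voxel_spacing()
  mask <- array(0L, c(16, 48, 48))
  mask[mask_planes, 5:30, 5:24] <- 1L
  arr <- array(0, c(16, 48, 48))
  arr[spot_planes, ys, xs + gap_px] <- 100
  cfg <- analysis_config(spot_threshold = "fixed:50")
  spots <- detect_spots(arr, cfg, sp)
  list(spots = spots, mask = binary_mask(mask, sp), cfg = cfg)
}

test_that("classification thresholds split internalized / attached / indeterminate / background", {
  # overlap 7/10 = 0.70 -> internalized
  sc <- make_overlap_scene(mask_planes = 3:9)
  out <- classify_spots(sc$spots, sc$mask, sc$cfg)
  expect_equal(out$overlap_fraction, 0.7)
  expect_equal(out$class, "internalized")

  # overlap 0.25 with the spot inside the slab footprint (distance 0) -> attached
  sc <- make_overlap_scene(mask_planes = 3:4, spot_planes = 3:10)
  out <- classify_spots(sc$spots, sc$mask, sc$cfg)
  expect_equal(out$overlap_fraction, 0.25)
  expect_equal(out$class, "attached")

  # overlap 0.50 -> indeterminate, excluded from both tallies
  sc <- make_overlap_scene(mask_planes = 3:7, spot_planes = 3:12)
  out <- classify_spots(sc$spots, sc$mask, sc$cfg)
  expect_equal(out$overlap_fraction, 0.5)
  expect_equal(out$class, "indeterminate")

  # zero overlap far from any neuron -> background
  sc <- make_overlap_scene(mask_planes = 14:15, spot_planes = 3:10, gap_px = 20)
  out <- classify_spots(sc$spots, sc$mask, sc$cfg)
  expect_equal(out$class, "background")

  # classification is a partition: exactly one class per spot
  expect_true(all(out$class %in%
    c("internalized", "attached", "indeterminate", "background")))
})

test_that("attached requires proximity to the mask surface", {
  sp <- voxel_spacing()
  mask <- array(0L, c(16, 48, 48))
  mask[2:15, 5:30, 5:24] <- 1L
  arr <- array(0, c(16, 48, 48))
  arr[4:11, 20:24, 26:30] <- 100  # 2 px from the mask edge (~0.18 um)
  cfg <- analysis_config(spot_threshold = "fixed:50")
  near <- classify_spots(detect_spots(arr, cfg, sp), binary_mask(mask, sp), cfg)
  expect_equal(near$class, "attached")

  arr2 <- array(0, c(16, 48, 48))
  arr2[4:11, 20:24, 30:34] <- 100  # 6 px away (~0.5 um) -> background
  far <- classify_spots(detect_spots(arr2, cfg, sp), binary_mask(mask, sp), cfg)
  expect_equal(far$class, "background")
})

test_that("detection and classification respond monotonically to thresholds", {
  cfg <- noiseless_config(23L)
  f <- simulate_field(cfg)
  mask <- binarize_marker(f$stack)
  base <- sim_analysis_config("fixed:10")
  spots <- detect_spots(f$stack, base)
  n_internal <- function(ov) {
    cfg_i <- analysis_config(spot_threshold = "fixed:10",
                             overlap_internalized = ov)
    sum(classify_spots(spots, mask, cfg_i)$class == "internalized")
  }
  counts <- vapply(c(0.5, 0.65, 0.8, 0.95), n_internal, numeric(1))
  expect_true(all(diff(counts) <= 0))

  n_detected <- function(area, height) {
    nrow(detect_spots(f$stack, analysis_config(
      spot_threshold = "fixed:10", min_xy_area = area, min_z_height = height)))
  }
  expect_true(n_detected(0, 1e-9) >= n_detected(2e-4, 1.5))
  expect_true(n_detected(2e-4, 1.5) >= n_detected(0.5, 2.5))
})

test_that("spots are assigned to the neuron containing them", {
  sp <- voxel_spacing()
  labels <- array(0L, c(12, 40, 40))
  labels[3:10, 5:15, 5:15] <- 1L
  labels[3:10, 25:35, 25:35] <- 3L
  lm <- structure(list(labels = labels, n_neurons = 2L,
                       voxel_counts = c(968L, 968L), spacing = sp),
                  class = "neuron_label_map")
  spots <- tibble::tibble(
    spot_id = 1:2,
    z_um = c(6, 6) * 0.25, y_um = c(30, 20) * 0.09, x_um = c(30, 20) * 0.09,
    class = c("internalized", "background"),
    neuron_id = NA_integer_,
    voxels = list(as.matrix(expand.grid(z = 5:8, y = 29:31, x = 29:31)),
                  as.matrix(expand.grid(z = 5:8, y = 19:21, x = 19:21))))
  out <- assign_spots(spots, lm)
  expect_equal(out$neuron_id, c(3L, NA_integer_))
})

test_that("the MIP particle count is a lower bound on the 3-D count", {
  sp <- voxel_spacing()
  cfg <- analysis_config(spot_threshold = "fixed:50", min_z_height = 0.25)
  # two spots sharing an XY footprint but separated in Z
  arr <- array(0, c(16, 32, 32))
  arr[2:4, 10:14, 10:14] <- 100
  arr[10:12, 10:14, 10:14] <- 100
  expect_equal(nrow(detect_spots(arr, cfg, sp)), 2L)
  expect_equal(mip_count(arr, cfg, sp), 1L)

  # five disjoint footprints survive the projection
  arr5 <- array(0, c(16, 64, 64))
  for (k in 0:4) arr5[3:9, 5 + 10 * k + (0:3), 5 + 10 * k + (0:3)] <- 100
  expect_equal(mip_count(arr5, cfg, sp), 5L)
})
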