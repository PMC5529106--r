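make_marker_stack <- function(marker, spacing = voxel_spacing()) {
  d <- dim(marker)
  arr <- array(0, c(2, d))
  arr[1, , , ] <- marker
  image_stack(arr, spacing, channel_roles(neuron_marker = 0, oligomer = 1))
}

test_that("flat planes binarize to all-zero", {
  marker <- array(7, c(4, 16, 16))
  mask <- binarize_marker(make_marker_stack(marker))
  expect_true(all(mask$values == 0))
})

test_that("a fixed threshold reproduces a two-valued plane exactly", {
  marker <- array(10, c(2, 20, 20))
  marker[1, 5:10, 5:10] <- 200
  mask <- binarize_marker(make_marker_stack(marker), method = "fixed:100")
  want <- array(0L, dim(marker))
  want[1, 5:10, 5:10] <- 1L
  expect_identical(mask$values, want)
})

test_that("per-plane Otsu agrees with an exhaustive intra-class-variance search", {
  set.seed(7)
  for (i in 1:3) {
    plane <- matrix(round(rnorm(32 * 32, 20, 3)), 32, 32)
    fg <- matrix(FALSE, 32, 32)
    fg[sample(32, 10), sample(32, 10)] <- TRUE
    plane[fg] <- round(rnorm(sum(fg), 200, 5))
    marker <- array(0, c(2, 32, 32))
    marker[1, , ] <- plane
    marker[2, , ] <- plane
    mask <- binarize_marker(make_marker_stack(marker), floor_global = FALSE)
    t_star <- otsu_oracle(as.vector(plane))
    expect_identical(mask$values[1, , ], matrix(as.integer(plane > t_star), 32, 32))
  }
})

test_that("Otsu masks are invariant to affine intensity rescaling", {
  set.seed(8)
  plane <- matrix(c(round(rnorm(300, 20, 3)), round(rnorm(212, 150, 6))), 32, 16)
  marker <- array(0, c(2, 32, 16))
  marker[1, , ] <- plane
  marker[2, , ] <- plane
  m1 <- binarize_marker(make_marker_stack(marker))
  m2 <- binarize_marker(make_marker_stack(marker * 3 + 11))
  expect_identical(m1$values, m2$values)
})

test_that("mask multiplication keeps only in-mask oligomer signal and is idempotent", {
  d <- c(4, 16, 16)
  arr <- array(0, c(2, d))
  arr[1, , 1:8, ] <- 50
  arr[2, , , ] <- matrix(rpois(prod(d), 20), nrow = 1)
  stack <- image_stack(arr, voxel_spacing(),
                       channel_roles(neuron_marker = 0, oligomer = 1))
  zero <- binary_mask(array(0L, d), voxel_spacing())
  expect_true(all(get_channel(multiply_mask(zero, stack), "oligomer") == 0))

  one <- binary_mask(array(1L, d), voxel_spacing())
  expect_identical(multiply_mask(one, stack)$intensities, stack$intensities)

  half <- binary_mask(array(rep(c(1L, 0L), each = prod(d) / 2), d), voxel_spacing())
  once <- multiply_mask(half, stack)
  twice <- multiply_mask(half, once)
  expect_identical(once$intensities, twice$intensities)
  # marker channel untouched
  expect_identical(get_channel(once, "neuron_marker"),
                   get_channel(stack, "neuron_marker"))

  bad <- binary_mask(array(0L, c(2, 16, 16)), voxel_spacing())
  expect_error(multiply_mask(bad, stack), class = "oligouptake_validation_error")
})

test_that("masking removes off-neuron spots from the detection", {
  cfg <- noiseless_config(31L, n_neurons = 2L, mean_spots_surface = 0,
                          mean_spots_background = 3, p_internalizing = 1)
  f <- simulate_field(cfg)
  acfg <- sim_analysis_config("fixed:10")
  mask <- binarize_marker(f$stack)
  n_in <- sum(f$truth$class == "internalized")
  n_bg <- sum(f$truth$class == "background")
  raw_spots <- detect_spots(f$stack, acfg)
  masked <- multiply_mask(mask, f$stack)
  masked_spots <- detect_spots(masked, acfg)
  expect_equal(nrow(raw_spots), n_in + n_bg)
  expect_equal(nrow(masked_spots), n_in)
})

test_that("neuron labeling counts instances and honours min_volume", {
  sp <- voxel_spacing()
  vals <- array(0L, c(12, 60, 60))
  vals[3:10, 5:25, 5:25] <- 1L    # big block
  vals[3:10, 35:55, 35:55] <- 1L  # second block
  vals[6, 30, 30] <- 1L           # single-voxel debris
  mask <- binary_mask(vals, sp)
  lm <- label_neurons(mask, min_volume = 1)
  expect_equal(lm$n_neurons, 2L)
  expect_equal(label_neurons(binary_mask(array(0L, c(4, 8, 8)), sp))$n_neurons, 0L)
  # without filtering, per-label voxel counts add up to the mask total
  lm0 <- label_neurons(mask, min_volume = 0)
  expect_equal(sum(lm0$voxel_counts), sum(vals))
  expect_equal(lm0$n_neurons, 3L)
})

test_that("nuclear seeds split touching neurons", {
  sp <- voxel_spacing()
  vals <- array(0L, c(8, 40, 80))
  vals[2:7, 10:30, 10:70] <- 1L  # one elongated slab = one component
  nuc <- array(0L, dim(vals))
  nuc[4:5, 18:22, 20:24] <- 1L
  nuc[4:5, 18:22, 55:59] <- 1L
  lm <- label_neurons(binary_mask(vals, sp), nuclei = binary_mask(nuc, sp),
                      min_volume = 1)
  expect_equal(lm$n_neurons, 2L)
  # left half belongs to the left seed, right half to the right seed
  expect_equal(lm$labels[4, 20, 15], lm$labels[4, 20, 22])
  expect_true(lm$labels[4, 20, 15] != lm$labels[4, 20, 65])
})

test_that("simulated fields yield the planted number of neurons", {
  cfg <- noiseless_config(17L, n_neurons = 2L)
  f <- simulate_field(cfg)
  lm <- label_neurons(binarize_marker(f$stack))
  expect_equal(lm$n_neurons, 2L)
})
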