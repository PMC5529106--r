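test_that("identical config and seed give bit-identical fields", {
  cfg <- simulation_config(field_shape = c(20L, 128L, 128L), n_neurons = 1L,
                           seed = 5L)
  f1 <- simulate_field(cfg)
  f2 <- simulate_field(cfg)
  expect_identical(f1$stack$intensities, f2$stack$intensities)
  expect_identical(f1$truth, f2$truth)
  f3 <- simulate_field(simulation_config(field_shape = c(20L, 128L, 128L),
                                         n_neurons = 1L, seed = 6L))
  expect_false(identical(f1$stack$intensities, f3$stack$intensities))
})

test_that("a field with no uptake renders pure background in the oligomer channel", {
  cfg <- noiseless_config(2L, field_shape = c(20L, 128L, 128L), n_neurons = 1L,
                          p_internalizing = 0, mean_spots_surface = 0,
                          mean_spots_background = 0)
  f <- simulate_field(cfg)
  expect_equal(nrow(f$truth), 0L)
  expect_true(all(get_channel(f$stack, "oligomer") == cfg$background_level))
})

test_that("the detector recovers exactly the planted components on a noiseless render", {
  cfg <- noiseless_config(19L, n_neurons = 2L, p_internalizing = 1,
                          mean_spots_surface = 3, mean_spots_background = 2)
  f <- simulate_field(cfg)
  spots <- detect_spots(f$stack, sim_analysis_config("fixed:10"))
  expect_equal(nrow(spots), nrow(f$truth))
})

test_that("planted classes respect their geometric definitions", {
  cfg <- noiseless_config(29L, n_neurons = 2L, mean_spots_background = 2)
  f <- simulate_field(cfg)
  vol_mask <- binary_mask(array(as.integer(f$truth_labels > 0),
                                dim(f$truth_labels)), cfg$spacing)
  sp <- cfg$spacing
  to_vox <- function(r) {
    cbind(round(r$z_um / sp$dz + 0.5), round(r$y_um / sp$dy + 0.5),
          round(r$x_um / sp$dx + 0.5))
  }
  for (i in seq_len(nrow(f$truth))) {
    r <- f$truth[i, ]
    v <- to_vox(r)
    if (r$class == "internalized") {
      expect_equal(f$truth_labels[v], r$neuron_id)
    } else if (r$class == "attached") {
      # centred on the boundary shell: centroid outside, but surface nearby
      expect_equal(f$truth_labels[v], 0L)
      expect_lte(spot_mask_dist_for_test(r, vol_mask, sp), 0.6)
    } else {
      expect_gt(spot_mask_dist_for_test(r, vol_mask, sp), 0.5)
    }
  }
  # planted spot geometry passes the detection criteria by construction
  expect_true(all(f$truth$z_extent_um >= 1.5))
  expect_true(all(f$truth$xy_area_um2 >= 2e-4))
})

test_that("noiseless spot centres carry at least exp(-1/2) of the peak intensity", {
  cfg <- noiseless_config(37L, n_neurons = 2L, mean_spots_background = 1)
  f <- simulate_field(cfg)
  olig <- get_channel(f$stack, "oligomer")
  sp <- cfg$spacing
  for (i in seq_len(nrow(f$truth))) {
    r <- f$truth[i, ]
    v <- cbind(round(r$z_um / sp$dz + 0.5), round(r$y_um / sp$dy + 0.5),
               round(r$x_um / sp$dx + 0.5))
    expect_gte(olig[v], cfg$spot_intensity * exp(-0.5))
  }
})

test_that("two-arm experiments derive independent per-field seeds", {
  cfg <- simulation_config(field_shape = c(20L, 112L, 112L), n_neurons = 1L,
                           psf_sigma_xy = 0, psf_sigma_z = 0,
                           gaussian_noise_sd = 0, poisson_noise = FALSE,
                           mean_spots_background = 0, seed = 77L)
  none <- simulate_experiment(cfg, cfg, n_fields = 0)
  expect_length(none$a, 0)
  expect_length(none$b, 0)

  exp2 <- simulate_experiment(cfg, cfg, n_fields = 2)
  # same config in both arms must still give different fields
  expect_false(identical(exp2$a[[1]]$stack$intensities,
                         exp2$b[[1]]$stack$intensities))

  bad <- simulation_config(field_shape = c(20L, 96L, 96L), n_neurons = 1L)
  expect_error(simulate_experiment(cfg, bad, 1),
               class = "oligouptake_validation_error")
})

test_that("planted index ratio of a WT/KO experiment matches the configured rates", {
  base <- list(field_shape = c(20L, 112L, 112L), n_neurons = 1L,
               psf_sigma_xy = 0, psf_sigma_z = 0, gaussian_noise_sd = 0,
               poisson_noise = FALSE, mean_spots_background = 0,
               mean_spots_surface = 1)
  cfg_wt <- do.call(simulation_config, c(base, list(
    p_internalizing = 0.91, mean_spots_internalized = 5.3, seed = 100L)))
  cfg_ko <- do.call(simulation_config, c(base, list(
    p_internalizing = 0.73, mean_spots_internalized = 2.9, seed = 500L)))
  ex <- simulate_experiment(cfg_wt, cfg_ko, n_fields = 20)
  per_neuron <- function(arm) {
    # with one neuron per field, the field index equals its internalized count
    vapply(arm, function(f) sum(f$truth$class == "internalized"), numeric(1))
  }
  wt <- per_neuron(ex$a); ko <- per_neuron(ex$b)
  ratio <- mean(ko) / mean(wt)
  se <- ratio * sqrt((sd(wt) / mean(wt))^2 / length(wt) +
                     (sd(ko) / mean(ko))^2 / length(ko))
  planted <- (0.73 * 2.9) / (0.91 * 5.3)
  expect_lt(abs(ratio - planted), 3 * se + 1e-12)
})

test_that("a null two-arm experiment shows no spurious group difference", {
  cfg <- simulation_config(field_shape = c(20L, 112L, 112L), n_neurons = 1L,
                           psf_sigma_xy = 0, psf_sigma_z = 0,
                           gaussian_noise_sd = 0, poisson_noise = FALSE,
                           mean_spots_background = 0, mean_spots_surface = 0,
                           seed = 4242L)
  ex <- simulate_experiment(cfg, cfg, n_fields = 8)
  idx <- function(arm) vapply(arm, function(f) {
    summarize_truth(f$truth, 1L)$internalization_index
  }, numeric(1))
  cmp <- compare_groups(idx(ex$a), idx(ex$b))
  expect_gt(cmp$p_value, 0.05)
})

test_that("impossible geometry fails loudly, naming the constraint", {
  expect_error(
    simulation_config(field_shape = c(6L, 128L, 128L)),
    class = "oligouptake_validation_error")  # field too shallow for somata
  cramped <- noiseless_config(1L, field_shape = c(20L, 64L, 64L), n_neurons = 4L)
  expect_error(simulate_field(cramped),
               class = "oligouptake_simulation_error")
})
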