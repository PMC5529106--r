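#' Configuration of the synthetic confocal scene generator
#'
#' The generator renders fields that carry the statistical structure the
#' uptake analysis assumes: MAP2-like neuron bodies (axis-aligned ellipsoids,
#' optionally with thin tubular processes) in a neuron-marker channel;
#' per-neuron Bernoulli uptake with Poisson spot counts inside internalizing
#' neurons; surface-attached spots straddling the mask boundary with low
#' axial overlap; optional background spots; anisotropic Gaussian blur
#' emulating the PSF; and Poisson-then-Gaussian camera noise. Default rates
#' are the wild-type regime reported for oligomeric amyloid-beta uptake
#' (91% of neurons internalizing, 5.3 spots per internalizing neuron,
#' ~6.9 surface spots per neuron); a knock-out-like arm is obtained by
#' lowering `p_internalizing` and `mean_spots_internalized`.
#'
#' @param field_shape Integer `(z, y, x)` voxel counts. Default
#'   `c(20, 320, 320)`: a 28.8 x 28.8 x 5 um field at the default spacing.
#' @param spacing A [voxel_spacing()].
#' @param n_neurons Neurons per field.
#' @param p_internalizing Probability a neuron internalizes oligomers.
#' @param mean_spots_internalized Poisson mean of internalized spots in an
#'   internalizing neuron.
#' @param mean_spots_surface Poisson mean of surface-attached spots per
#'   neuron.
#' @param mean_spots_background Poisson mean of background (off-neuron)
#'   spots per field.
#' @param soma_radius_xy,soma_radius_z Ranges (um) the ellipsoid semi-axes
#'   are drawn from.
#' @param n_processes Tubular processes per neuron (0 disables).
#' @param process_radius Process radius in um.
#' @param spot_radius_xy Spot footprint radius (um); also the lateral
#'   Gaussian sigma, so the footprint edge sits at exp(-1/2) of the peak.
#' @param spot_extent_z Spot axial extent (um); the axial sigma is half of
#'   it. Default 1.75 (7 planes at dz = 0.25), comfortably above the 1.5 um
#'   detection criterion.
#' @param min_spot_separation Target minimum 3-D distance between planted
#'   spot centres (um). Enforced by maximin sampling over candidate
#'   positions; in crowded draws the best available candidate is accepted,
#'   so this is a target, not a hard guarantee.
#' @param neuron_intensity,spot_intensity,background_level Arbitrary-unit
#'   (photon-count-like) intensities.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas in um (0 disables).
#' @param gaussian_noise_sd Read-noise standard deviation (0 disables).
#' @param poisson_noise Apply Poisson (shot) noise.
#' @param seed Integer seed; identical configs give bit-identical fields.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(field_shape = c(20L, 320L, 320L),
                              spacing = voxel_spacing(),
                              n_neurons = 4L,
                              p_internalizing = 0.91,
                              mean_spots_internalized = 5.3,
                              mean_spots_surface = 6.9,
                              mean_spots_background = 2,
                              soma_radius_xy = c(3.0, 4.0),
                              soma_radius_z = c(1.7, 2.2),
                              n_processes = 0L,
                              process_radius = 0.4,
                              spot_radius_xy = 0.27,
                              spot_extent_z = 1.75,
                              min_spot_separation = 1.5,
                              neuron_intensity = 80,
                              spot_intensity = 150,
                              background_level = 5,
                              psf_sigma_xy = 0.15,
                              psf_sigma_z = 0.35,
                              gaussian_noise_sd = 3,
                              poisson_noise = TRUE,
                              seed = 1L) {
  cfg <- list(field_shape = as.integer(field_shape), spacing = spacing,
              n_neurons = as.integer(n_neurons),
              p_internalizing = p_internalizing,
              mean_spots_internalized = mean_spots_internalized,
              mean_spots_surface = mean_spots_surface,
              mean_spots_background = mean_spots_background,
              soma_radius_xy = soma_radius_xy, soma_radius_z = soma_radius_z,
              n_processes = as.integer(n_processes),
              process_radius = process_radius,
              spot_radius_xy = spot_radius_xy, spot_extent_z = spot_extent_z,
              min_spot_separation = min_spot_separation,
              neuron_intensity = neuron_intensity,
              spot_intensity = spot_intensity,
              background_level = background_level,
              psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
              gaussian_noise_sd = gaussian_noise_sd,
              poisson_noise = isTRUE(poisson_noise),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$field_shape) != 3L || any(cfg$field_shape < 2L)) {
    abort("field_shape must be (z, y, x) with every extent >= 2",
          class = "oligouptake_validation_error")
  }
  if (cfg$p_internalizing < 0 || cfg$p_internalizing > 1) {
    abort("p_internalizing must lie in [0, 1]",
          class = "oligouptake_validation_error")
  }
  for (m in c("mean_spots_internalized", "mean_spots_surface",
              "mean_spots_background")) {
    if (cfg[[m]] < 0) abort(sprintf("%s must be >= 0", m),
                            class = "oligouptake_validation_error")
  }
  depth <- cfg$field_shape[1] * cfg$spacing$dz
  if (cfg$spot_extent_z >= depth) {
    abort("spot_extent_z must be smaller than the field depth",
          class = "oligouptake_validation_error")
  }
  if (2 * max(cfg$soma_radius_z) + 0.2 > depth) {
    abort("field too shallow for the soma Z radius",
          class = "oligouptake_validation_error")
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> field %dx%dx%d px, %d neurons, p=%.2f, lambda_int=%.2f, lambda_surf=%.2f, seed=%d\n",
              x$field_shape[1], x$field_shape[2], x$field_shape[3],
              x$n_neurons, x$p_internalizing, x$mean_spots_internalized,
              x$mean_spots_surface, x$seed))
  invisible(x)
}

sim_error <- function(msg) abort(msg, class = "oligouptake_simulation_error")

# separable anisotropic Gaussian blur of a (z, y, x) array, sigma in voxels;
# edge-renormalized so flat regions stay flat near the borders
gaussian_blur_3d <- function(arr, sigma_vox) {
  blur_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    d <- dim(a)
    n <- d[axis]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- k[off + r + 1]
    }
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = n)
    out <- K %*% m
    dim(out) <- d[perm]
    aperm(out, order(perm))
  }
  arr <- blur_axis(arr, 1L, sigma_vox[1])
  arr <- blur_axis(arr, 2L, sigma_vox[2])
  blur_axis(arr, 3L, sigma_vox[3])
}

# voxels (1-based (z,y,x)) and Gaussian intensities of a spot's truncated
# footprint: disc of radius r_xy in XY crossed with ext_z in Z
spot_support <- function(center_um, r_xy, ext_z, spacing, dims) {
  zc <- (seq_len(dims[1]) - 0.5) * spacing$dz
  zi <- which(abs(zc - center_um[1]) <= ext_z / 2)
  yc <- (seq_len(dims[2]) - 0.5) * spacing$dy
  yi <- which(abs(yc - center_um[2]) <= r_xy)
  xc <- (seq_len(dims[3]) - 0.5) * spacing$dx
  xi <- which(abs(xc - center_um[3]) <= r_xy)
  if (!length(zi) || !length(yi) || !length(xi)) {
    return(list(vox = matrix(integer(), 0, 3), intensity = numeric()))
  }
  g <- expand.grid(z = zi, y = yi, x = xi)
  dy2 <- (yc[g$y] - center_um[2])^2
  dx2 <- (xc[g$x] - center_um[3])^2
  keep <- dy2 + dx2 <= r_xy^2
  g <- g[keep, , drop = FALSE]
  dz2 <- (zc[g$z] - center_um[1])^2
  inten <- exp(-((dy2 + dx2)[keep] / (2 * r_xy^2) + dz2 / (2 * (ext_z / 2)^2)))
  list(vox = as.matrix(g), intensity = inten)
}

# min 3-D distance (um) from a candidate centre to previously placed centres
min_center_dist <- function(center, placed) {
  if (nrow(placed) == 0L) return(Inf)
  sqrt(min(rowSums(sweep(placed, 2, center)^2)))
}

# TRUE when a candidate's cylindrical support would touch (and hence merge
# with) any already-placed spot's support under 26-connectivity: spots merge
# iff their XY discs come within a pixel of each other while their Z extents
# overlap, which plain 3-D centre distance does not capture
support_conflict <- function(center, placed, r_xy, ext_z, sp) {
  if (nrow(placed) == 0L) return(FALSE)
  dz <- abs(placed[, 1] - center[1])
  dxy <- sqrt((placed[, 2] - center[2])^2 + (placed[, 3] - center[3])^2)
  any(dz < ext_z + 2 * sp$dz & dxy < 2 * r_xy + 3 * sp$dx)
}

# maximin placement: draw candidates from gen(), discard any whose support
# would touch an existing spot, prefer the first at >= min_sep from every
# placed centre, otherwise fall back to the most isolated valid candidate
# (the separation target is a soft constraint; support disjointness is hard)
place_spot <- function(gen, placed, min_sep, conflict, n_candidates = 150L) {
  best <- NULL
  best_d <- -Inf
  for (i in seq_len(n_candidates)) {
    cand <- gen()
    if (is.null(cand)) next
    if (conflict(cand$center)) next
    d <- min_center_dist(cand$center, placed)
    if (d >= min_sep) return(cand)
    if (d > best_d) { best <- cand; best_d <- d }
  }
  best
}

#' Simulate one ground-truthed confocal field
#'
#' Renders neurons and planted spots into a 2-channel stack (channel 0 =
#' neuron marker, channel 1 = oligomer), applies PSF blur and noise per the
#' config, and returns the stack together with the plant-time truth. Planted
#' classes are validated at planting time with the package's own overlap
#' rule against the noiseless neuron volume: internalized spots have axial
#' overlap >= 0.9, attached spots < 0.25 while touching the surface, and
#' background spots keep >= 0.6 um clearance from any neuron.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `stack` (an [image_stack()]), `truth` (tibble:
#'   `spot_id`, `neuron_id`, `z_um`, `y_um`, `x_um`, `class`,
#'   `xy_area_um2`, `z_extent_um`), and `truth_labels` (integer `(z, y, x)`
#'   array of the rendered neuron volumes).
#' @export
simulate_field <- function(cfg = simulation_config()) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, simulate_field_impl(cfg))
}

simulate_field_impl <- function(cfg) {
  dims <- cfg$field_shape
  sp <- cfg$spacing
  L <- dims * c(sp$dz, sp$dy, sp$dx)  # physical (z, y, x) extents

  # --- neuron placement (bounded retries, whole-field restarts) -------------
  place_neurons <- function() {
    res <- list()
    for (i in seq_len(cfg$n_neurons)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, cfg$soma_radius_xy[1], cfg$soma_radius_xy[2])
        b <- runif(1, cfg$soma_radius_xy[1], cfg$soma_radius_xy[2])
        cz <- runif(1, cfg$soma_radius_z[1], cfg$soma_radius_z[2])
        if (2 * (max(a, b) + 0.3) > min(L[2], L[3])) next
        ctr <- c(runif(1, cz + 0.1, L[1] - cz - 0.1),
                 runif(1, b + 0.3, L[2] - b - 0.3),
                 runif(1, a + 0.3, L[3] - a - 0.3))
        clash <- FALSE
        for (r2 in res) {
          need <- max(a, b) + max(r2$semi[2], r2$semi[3]) + 0.3
          if (sqrt(sum((ctr[2:3] - r2$center[2:3])^2)) < need) { clash <- TRUE; break }
        }
        if (!clash) {
          res[[i]] <- list(center = ctr, semi = c(cz, b, a))
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    }
    res
  }
  neurons <- NULL
  for (restart in seq_len(50L)) {
    neurons <- place_neurons()
    if (!is.null(neurons)) break
  }
  if (is.null(neurons)) {
    sim_error(sprintf(
      "could not place %d non-overlapping somata (radii %.1f-%.1f um) in a %.1f x %.1f um field",
      cfg$n_neurons, cfg$soma_radius_xy[1], cfg$soma_radius_xy[2], L[2], L[3]))
  }

  # --- render neuron volumes ------------------------------------------------
  truth_labels <- array(0L, dims)
  zc <- (seq_len(dims[1]) - 0.5) * sp$dz
  yc <- (seq_len(dims[2]) - 0.5) * sp$dy
  xc <- (seq_len(dims[3]) - 0.5) * sp$dx
  for (i in seq_along(neurons)) {
    nb <- neurons[[i]]
    zi <- which(abs(zc - nb$center[1]) <= nb$semi[1])
    yi <- which(abs(yc - nb$center[2]) <= nb$semi[2])
    xi <- which(abs(xc - nb$center[3]) <= nb$semi[3])
    tz <- ((zc[zi] - nb$center[1]) / nb$semi[1])^2
    ty <- ((yc[yi] - nb$center[2]) / nb$semi[2])^2
    tx <- ((xc[xi] - nb$center[3]) / nb$semi[3])^2
    inside <- outer(outer(tz, ty, "+"), tx, "+") <= 1
    crop <- truth_labels[zi, yi, xi, drop = FALSE]
    crop[inside & crop == 0L] <- i
    truth_labels[zi, yi, xi] <- crop
    if (cfg$n_processes > 0L) {
      for (p in seq_len(cfg$n_processes)) {
        truth_labels <- render_process(truth_labels, nb, i, cfg, sp, L)
      }
    }
  }
  neuron_vol <- truth_labels > 0L

  # --- plant spots ----------------------------------------------------------
  r_xy <- cfg$spot_radius_xy
  ext_z <- cfg$spot_extent_z
  m_xy <- r_xy + 2 * sp$dx
  m_z <- ext_z / 2 + sp$dz
  placed <- matrix(numeric(), 0, 3)
  truth_rows <- list()
  oligomer <- array(0, dims)
  add_spot <- function(center, class, neuron_id) {
    supp <- spot_support(center, r_xy, ext_z, sp, dims)
    oligomer[supp$vox] <<- oligomer[supp$vox] + cfg$spot_intensity * supp$intensity
    placed <<- rbind(placed, center)
    truth_rows[[length(truth_rows) + 1L]] <<- tibble::tibble(
      neuron_id = neuron_id,
      z_um = center[1], y_um = center[2], x_um = center[3], class = class,
      xy_area_um2 = nrow(unique(supp$vox[, 2:3, drop = FALSE])) * sp$dx * sp$dy,
      z_extent_um = length(unique(supp$vox[, 1])) * sp$dz
    )
  }
  in_conflict <- function(center) {
    support_conflict(center, placed, r_xy, ext_z, sp)
  }
  support_ok <- function(center) {
    center[1] - ext_z / 2 > 0 && center[1] + ext_z / 2 < L[1] &&
      center[2] - r_xy > sp$dy && center[2] + r_xy < L[2] - sp$dy &&
      center[3] - r_xy > sp$dx && center[3] + r_xy < L[3] - sp$dx
  }

  for (i in seq_along(neurons)) {
    nb <- neurons[[i]]
    semi_in <- nb$semi - c(m_z, m_xy, m_xy)
    internalizes <- rbinom(1, 1, cfg$p_internalizing) == 1L
    if (internalizes && cfg$mean_spots_internalized > 0) {
      if (any(semi_in <= 0)) {
        sim_error(sprintf(
          "soma semi-axes %s um cannot contain a spot of radius %.2f / extent %.2f um",
          paste(signif(rev(nb$semi), 2), collapse = "x"), r_xy, ext_z))
      }
      k <- rpois(1, cfg$mean_spots_internalized)
      gen_int <- function() {
        repeat {
          u <- runif(3, -1, 1)
          if (sum(u^2) <= 1) break
        }
        center <- nb$center + u * semi_in
        supp <- spot_support(center, r_xy, ext_z, sp, dims)
        if (nrow(supp$vox) == 0L) return(NULL)
        if (overlap_for_voxels(supp$vox, neuron_vol) < 0.9) return(NULL)
        list(center = center)
      }
      for (s in seq_len(k)) {
        cand <- place_spot(gen_int, placed, cfg$min_spot_separation, in_conflict)
        if (is.null(cand)) {
          sim_error(sprintf("failed to place an internalized spot inside neuron %d", i))
        }
        add_spot(cand$center, "internalized", i)
      }
    }
    if (cfg$mean_spots_surface > 0) {
      k <- rpois(1, cfg$mean_spots_surface)
      gen_surf <- function() {
        zf <- runif(1, -0.4, 0.4)
        zc_s <- nb$center[1] + zf * nb$semi[1]
        shrink <- sqrt(1 - zf^2)
        a_z <- nb$semi[3] * shrink
        b_z <- nb$semi[2] * shrink
        th <- runif(1, 0, 2 * pi)
        dvec <- c(cos(th), sin(th))  # (x, y)
        t_star <- 1 / sqrt((dvec[1] / a_z)^2 + (dvec[2] / b_z)^2)
        for (gap in sp$dx * c(1, 2, 3)) {
          off <- t_star + 0.8 * r_xy + gap
          center <- c(zc_s, nb$center[2] + dvec[2] * off,
                      nb$center[3] + dvec[1] * off)
          if (!support_ok(center)) next
          supp <- spot_support(center, r_xy, ext_z, sp, dims)
          if (nrow(supp$vox) == 0L) next
          if (overlap_for_voxels(supp$vox, neuron_vol) >= 0.25) next
          d <- spot_mask_distance(supp$vox, neuron_vol, sp, 0.3)
          if (d > 0.15) next
          return(list(center = center))
        }
        NULL
      }
      for (s in seq_len(k)) {
        cand <- place_spot(gen_surf, placed, cfg$min_spot_separation, in_conflict)
        if (is.null(cand)) {
          sim_error(sprintf("failed to place a surface-attached spot on neuron %d", i))
        }
        add_spot(cand$center, "attached", i)
      }
    }
  }
  if (cfg$mean_spots_background > 0) {
    k <- rpois(1, cfg$mean_spots_background)
    gen_bg <- function() {
      center <- c(runif(1, ext_z / 2 + sp$dz, L[1] - ext_z / 2 - sp$dz),
                  runif(1, r_xy + 2 * sp$dy, L[2] - r_xy - 2 * sp$dy),
                  runif(1, r_xy + 2 * sp$dx, L[3] - r_xy - 2 * sp$dx))
      supp <- spot_support(center, r_xy, ext_z, sp, dims)
      if (nrow(supp$vox) == 0L) return(NULL)
      if (spot_mask_distance(supp$vox, neuron_vol, sp, 0.7) <= 0.6) return(NULL)
      list(center = center)
    }
    for (s in seq_len(k)) {
      cand <- place_spot(gen_bg, placed, cfg$min_spot_separation, in_conflict)
      if (is.null(cand)) {
        sim_error("failed to place a background spot clear of all neurons")
      }
      add_spot(cand$center, "background", NA_integer_)
    }
  }

  # --- compose channels, PSF, noise ----------------------------------------
  marker <- cfg$background_level + cfg$neuron_intensity * neuron_vol
  oligomer <- oligomer + cfg$background_level
  sig_vox <- c(cfg$psf_sigma_z / sp$dz, cfg$psf_sigma_xy / sp$dy,
               cfg$psf_sigma_xy / sp$dx)
  if (any(sig_vox > 0)) {
    marker <- gaussian_blur_3d(marker, sig_vox)
    oligomer <- gaussian_blur_3d(oligomer, sig_vox)
  }
  if (cfg$poisson_noise) {
    marker[] <- rpois(length(marker), lambda = marker)
    oligomer[] <- rpois(length(oligomer), lambda = oligomer)
  }
  if (cfg$gaussian_noise_sd > 0) {
    marker <- marker + rnorm(length(marker), sd = cfg$gaussian_noise_sd)
    oligomer <- oligomer + rnorm(length(oligomer), sd = cfg$gaussian_noise_sd)
  }
  marker <- round(pmax(marker, 0))
  oligomer <- round(pmax(oligomer, 0))

  arr <- array(0, c(2L, dims))
  arr[1, , , ] <- marker
  arr[2, , , ] <- oligomer
  stack <- image_stack(arr, spacing = sp,
                       channels = channel_roles(neuron_marker = 0, oligomer = 1),
                       provenance = sprintf("synthetic seed=%d", cfg$seed))

  truth <- if (length(truth_rows)) {
    dplyr::bind_rows(truth_rows)
  } else {
    tibble::tibble(neuron_id = integer(), z_um = double(), y_um = double(),
                   x_um = double(), class = character(),
                   xy_area_um2 = double(), z_extent_um = double())
  }
  truth <- dplyr::mutate(truth, spot_id = dplyr::row_number(), .before = 1)
  list(stack = stack, truth = truth, truth_labels = truth_labels)
}

# thin horizontal cylinder from the soma edge toward the field border
render_process <- function(truth_labels, nb, id, cfg, sp, L) {
  th <- runif(1, 0, 2 * pi)
  dvec <- c(cos(th), sin(th))  # (x, y)
  start <- nb$center[2:3] + rev(dvec) * 0.8 * c(nb$semi[2], nb$semi[3])
  zc_n <- nb$center[1]
  r <- cfg$process_radius
  dims <- dim(truth_labels)
  yc <- (seq_len(dims[2]) - 0.5) * sp$dy
  xc <- (seq_len(dims[3]) - 0.5) * sp$dx
  zcv <- (seq_len(dims[1]) - 0.5) * sp$dz
  zi <- which(abs(zcv - zc_n) <= r)
  if (!length(zi)) return(truth_labels)
  # distance of every XY pixel to the ray start + t * (y, x) direction
  gy <- matrix(yc, dims[2], dims[3])
  gx <- matrix(xc, dims[2], dims[3], byrow = TRUE)
  vy <- gy - start[1]; vx <- gx - start[2]
  t_par <- vy * dvec[2] + vx * dvec[1]
  d_perp <- abs(vx * dvec[2] - vy * dvec[1])
  hit <- t_par > 0 & d_perp <= r
  if (!any(hit)) return(truth_labels)
  idx <- which(hit)
  for (z in zi) {
    plane <- truth_labels[z, , ]
    plane[idx][plane[idx] == 0L] <- id
    truth_labels[z, , ] <- plane
  }
  truth_labels
}

#' Simulate a two-arm uptake experiment
#'
#' Generates `n_fields` independent fields per arm. Field seeds derive from
#' each arm's config seed (`seed + i - 1` for the first arm,
#' `seed + n_fields + i - 1` for the second), so the two arms stay
#' independent even when both configs carry the same seed.
#'
#' @param cfg_a,cfg_b [simulation_config()]s for the two arms; they must
#'   share field geometry.
#' @param n_fields Fields per arm.
#' @param seed Optional base seed overriding both config seeds.
#' @return A list with elements `a` and `b`, each a list of
#'   [simulate_field()] results.
#' @export
simulate_experiment <- function(cfg_a, cfg_b, n_fields, seed = NULL) {
  stopifnot(inherits(cfg_a, "simulation_config"),
            inherits(cfg_b, "simulation_config"))
  if (!identical(cfg_a$field_shape, cfg_b$field_shape) ||
      !identical(unclass(cfg_a$spacing), unclass(cfg_b$spacing))) {
    abort("both arms must share field geometry",
          class = "oligouptake_validation_error")
  }
  n_fields <- as.integer(n_fields)
  base_a <- if (is.null(seed)) cfg_a$seed else as.integer(seed)
  base_b <- if (is.null(seed)) cfg_b$seed else as.integer(seed)
  run_arm <- function(cfg, base, offset) {
    purrr::map(seq_len(n_fields), function(i) {
      cfg$seed <- base + offset + i - 1L
      simulate_field(cfg)
    })
  }
  list(a = run_arm(cfg_a, base_a, 0L),
       b = run_arm(cfg_b, base_b, n_fields))
}

#' Uptake statistics implied by a planted truth table
#'
#' Computes the same per-field summary as [summarize_field()] directly from
#' the generator's ground truth, bypassing imaging entirely. Used as the
#' oracle in simulator-backed tests.
#'
#' @param truth Truth tibble from [simulate_field()].
#' @param n_neurons Number of neurons rendered in the field.
#' @param field_id Identifier for the output row.
#' @inheritParams summarize_field
#' @return A one-row tibble with the same columns as [summarize_field()].
#' @export
summarize_truth <- function(truth, n_neurons, field_id = 1L,
                            mean_over = c("internalizing", "all")) {
  mean_over <- match.arg(mean_over)
  spots <- dplyr::mutate(truth, neuron_id = as.integer(.data$neuron_id))
  summarize_field(spots, n_neurons, field_id = field_id, mean_over = mean_over)
}
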