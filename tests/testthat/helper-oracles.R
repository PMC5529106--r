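# Independent brute-force oracles used across the suite.

# flood-fill connected-component labeling by explicit stack walk,
# independent of the package's labeler
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  offs <- as.matrix(offs)
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (labels[start] > 0L) next
    cur <- cur + 1L
    labels[start] <- cur
    frontier <- start
    while (length(frontier)) {
      v <- frontier[length(frontier)]
      frontier <- frontier[-length(frontier)]
      ai <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        p <- ai + offs[k, ]
        if (any(p < 1L) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1L) + d[2] * (p[3] - 1L))
        if (mask[w] != 0 && labels[w] == 0L) {
          labels[w] <- cur
          frontier <- c(frontier, w)
        }
      }
    }
  }
  labels
}

# two labelings describe the same partition (up to label renumbering)
same_partition <- function(a, b) {
  if (!identical(as.vector(a > 0), as.vector(b > 0))) return(FALSE)
  fg <- a > 0
  if (!any(fg)) return(TRUE)
  ct <- table(a[fg], b[fg])
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}

# exhaustive Otsu: minimize within-class variance over 256 candidate levels
otsu_oracle <- function(v) {
  lo <- min(v); hi <- max(v)
  cand <- seq(lo, hi, length.out = 257)[2:256]
  var0 <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  icv <- vapply(cand, function(t) var0(v[v <= t]) + var0(v[v > t]), numeric(1))
  cand[which.min(icv)]
}

# small noiseless simulation config used by several files
noiseless_config <- function(seed, field_shape = c(20L, 192L, 192L),
                             n_neurons = 2L, ...) {
  simulation_config(field_shape = field_shape, n_neurons = n_neurons,
                    psf_sigma_xy = 0, psf_sigma_z = 0,
                    gaussian_noise_sd = 0, poisson_noise = FALSE,
                    seed = seed, ...)
}

# distance (um) from a truth-table spot centre to the nearest mask voxel,
# computed directly from voxel centres, independent of the package's crops
spot_mask_dist_for_test <- function(r, mask, sp) {
  pos <- which(mask$values > 0, arr.ind = TRUE)
  if (nrow(pos) == 0L) return(Inf)
  sqrt(min(((pos[, 1] - 0.5) * sp$dz - r$z_um)^2 +
           ((pos[, 2] - 0.5) * sp$dy - r$y_um)^2 +
           ((pos[, 3] - 0.5) * sp$dx - r$x_um)^2))
}

# analysis settings matched to the generator's radiometry (see vignette)
sim_analysis_config <- function(threshold = "fixed:45", ...) {
  analysis_config(spot_threshold = threshold, ...)
}
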