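#' @rdname binarize_marker
#' @param values 0/1 integer array `(z, y, x)`.
#' @param spacing A [voxel_spacing()].
#' @param source Role name of the channel the mask was derived from.
#' @export
binary_mask <- function(values, spacing, source = "neuron_marker") {
  if (is.matrix(values)) dim(values) <- c(1L, dim(values))
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("mask values must be a 3-D (z, y, x) array",
          class = "oligouptake_validation_error")
  }
  if (!all(values %in% c(0, 1))) {
    abort("mask values must be 0/1", class = "oligouptake_validation_error")
  }
  structure(list(values = array(as.integer(values), dim(values)),
                 spacing = spacing, source = source),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d planes, %d x %d px, %d positive voxels (%.1f%%)\n",
              d[1], d[2], d[3], sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

# parse "otsu" | "fixed:<v>" | "quantile:<q>" into list(kind, value)
parse_threshold <- function(method) {
  if (is.list(method) && !is.null(method$kind)) return(method)
  if (!is.character(method) || length(method) != 1L) {
    abort("threshold method must be a string", class = "oligouptake_validation_error")
  }
  if (method == "otsu") return(list(kind = "otsu", value = NA_real_))
  if (grepl("^fixed:", method)) {
    v <- suppressWarnings(as.numeric(sub("^fixed:", "", method)))
    if (is.na(v)) abort(sprintf("cannot parse threshold '%s'", method),
                        class = "oligouptake_validation_error")
    return(list(kind = "fixed", value = v))
  }
  if (grepl("^quantile:", method)) {
    q <- suppressWarnings(as.numeric(sub("^quantile:", "", method)))
    if (is.na(q) || q < 0 || q > 1) {
      abort(sprintf("cannot parse threshold '%s' (need quantile in [0,1])", method),
            class = "oligouptake_validation_error")
    }
    return(list(kind = "quantile", value = q))
  }
  abort(sprintf("unknown threshold method '%s' (use otsu, fixed:<v>, quantile:<q>)",
                method),
        class = "oligouptake_validation_error")
}

# threshold for a vector of intensities; mask rule is values > threshold.
# Flat input yields +Inf so the mask comes out empty.
compute_threshold <- function(values, thr) {
  thr <- parse_threshold(thr)
  switch(thr$kind,
    fixed = thr$value,
    quantile = {
      if (diff(range(values)) == 0) Inf else unname(quantile(values, thr$value))
    },
    otsu = {
      lo <- min(values); hi <- max(values)
      if (hi - lo == 0) return(Inf)
      norm <- matrix((values - lo) / (hi - lo), ncol = 1L)
      t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256L)
      lo + as.numeric(t01) * (hi - lo)
    }
  )
}

#' Binarize the neuron-marker channel plane by plane
#'
#' Thresholds the MAP2-like channel on every XY plane to form the neuron
#' mask used for colocalization. For `otsu` and `quantile` the threshold is
#' computed independently per plane; `fixed:<v>` applies one global value.
#' Flat (degenerate) planes binarize to all-zero so that empty planes above
#' and below the cells never join neurons across Z. With `floor_global = TRUE`
#' (default) per-plane thresholds are additionally floored by the threshold
#' of the whole channel, which keeps planes that contain only noise empty —
#' Otsu always splits a histogram, even a unimodal one.
#'
#' @param stack An [image_stack()] with a `neuron_marker` channel.
#' @param method `"otsu"` (default), `"fixed:<value>"`, or `"quantile:<q>"`.
#' @param floor_global Floor per-plane thresholds at the global one.
#' @return A `binary_mask`.
#' @export
binarize_marker <- function(stack, method = "otsu", floor_global = TRUE) {
  stopifnot(is_image_stack(stack))
  chan <- get_channel(stack, "neuron_marker")
  thr <- parse_threshold(method)
  nz <- dim(chan)[1]
  out <- array(0L, dim(chan))
  if (thr$kind == "fixed") {
    out[] <- as.integer(chan > thr$value)
  } else {
    floor_t <- if (floor_global) compute_threshold(as.vector(chan), thr) else -Inf
    for (z in seq_len(nz)) {
      plane <- chan[z, , ]
      if (diff(range(plane)) == 0) next
      t_z <- max(compute_threshold(as.vector(plane), thr), floor_t)
      out[z, , ] <- as.integer(plane > t_z)
    }
  }
  binary_mask(out, stack$spacing, source = "neuron_marker")
}

#' Multiply the oligomer channel by the neuron mask, plane by plane
#'
#' Voxelwise product of the binary neuron mask with the oligomer channel:
#' oligomer fluorescence outside MAP2-positive areas is deleted, so only
#' signal colocalizing with the neuron volume survives. All other channels
#' are returned unchanged. The operation is idempotent.
#'
#' @param mask A `binary_mask` with the same `(z, y, x)` shape as the stack.
#' @param stack An [image_stack()] with an `oligomer` channel.
#' @return An [image_stack()] whose oligomer channel is masked.
#' @export
multiply_mask <- function(mask, stack) {
  stopifnot(is_binary_mask(mask), is_image_stack(stack))
  if (!all(dim(mask$values) == dim(stack$intensities)[-1])) {
    abort("mask and stack shapes differ", class = "oligouptake_validation_error")
  }
  olig <- get_channel(stack, "oligomer")
  out <- set_channel(stack, "oligomer", olig * mask$values)
  out$provenance <- paste0(stack$provenance, " [oligomer masked]")
  out
}

#' Label individual neurons in a binary neuron mask
#'
#' Instances neurons as 26-connected components of the mask, optionally
#' split by nuclear seeds (connected components of a nucleus-channel mask;
#' every neuron voxel is assigned to the nearest seed centroid). Components
#' smaller than `min_volume` are dropped as debris.
#'
#' @param mask A `binary_mask` of the neuron-marker channel.
#' @param nuclei Optional `binary_mask` of a nucleus channel used as seeds.
#' @param min_volume Minimum neuron volume in um^3 (default 50).
#' @return A `neuron_label_map`: list with `labels` (integer `(z, y, x)`
#'   array, 0 = background), `n_neurons`, `voxel_counts`, `spacing`.
#' @export
label_neurons <- function(mask, nuclei = NULL, min_volume = 50) {
  stopifnot(is_binary_mask(mask))
  labels <- label_components(mask$values, connectivity = 26)
  if (!is.null(nuclei)) {
    stopifnot(is_binary_mask(nuclei))
    seed_labels <- label_components(nuclei$values, connectivity = 26)
    n_seeds <- max(seed_labels)
    if (n_seeds > 0) {
      seed_centroids <- t(vapply(seq_len(n_seeds), function(s) {
        idx <- which(seed_labels == s, arr.ind = TRUE)
        colMeans(idx)
      }, numeric(3)))
      pos <- which(mask$values > 0, arr.ind = TRUE)
      sp <- mask$spacing
      d2 <- sapply(seq_len(n_seeds), function(s) {
        ((pos[, 1] - seed_centroids[s, 1]) * sp$dz)^2 +
        ((pos[, 2] - seed_centroids[s, 2]) * sp$dy)^2 +
        ((pos[, 3] - seed_centroids[s, 3]) * sp$dx)^2
      })
      d2 <- matrix(d2, nrow = nrow(pos))
      labels[labels > 0] <- 0L
      labels[pos] <- max.col(-d2, ties.method = "first")
    }
  }
  counts <- tabulate(labels[labels > 0])
  vol <- voxel_volume(mask$spacing)
  keep <- which(counts * vol >= min_volume)
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  labels[labels > 0] <- remap[labels[labels > 0]]
  structure(
    list(labels = labels, n_neurons = length(keep),
         voxel_counts = counts[keep], spacing = mask$spacing),
    class = "neuron_label_map"
  )
}

#' @export
print.neuron_label_map <- function(x, ...) {
  cat(sprintf("<neuron_label_map> %d neuron(s); volumes (um^3): %s\n",
              x$n_neurons,
              paste(signif(x$voxel_counts * voxel_volume(x$spacing), 3),
                    collapse = ", ")))
  invisible(x)
}
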