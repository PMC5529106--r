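#' Channel role table
#'
#' Maps semantic channel roles to 0-based channel indices. Every analysis
#' stack needs exactly one `neuron_marker` channel (MAP2-like somatodendritic
#' stain defining the neuron volume) and exactly one `oligomer` channel
#' (labeled amyloid-beta or Tau). A `nucleus` channel (DAPI-like) is optional
#' and only used to seed neuron instancing.
#'
#' @param neuron_marker 0-based index of the neuron-marker channel.
#' @param oligomer 0-based index of the labeled-oligomer channel.
#' @param nucleus Optional 0-based index of a nuclear-stain channel.
#' @param other Optional integer vector of any remaining channel indices.
#' @return A tibble with columns `role` and `index`.
#' @examples
#' channel_roles(neuron_marker = 0, oligomer = 1)
#' @export
channel_roles <- function(neuron_marker, oligomer, nucleus = NULL, other = NULL) {
  idx <- c(neuron_marker, oligomer, nucleus, other)
  if (!all(idx == floor(idx)) || any(idx < 0)) {
    abort("channel indices must be non-negative integers (0-based)",
          class = "oligouptake_validation_error")
  }
  roles <- tibble::tibble(
    role = c("neuron_marker", "oligomer",
             if (!is.null(nucleus)) "nucleus",
             rep("other", length(other))),
    index = as.integer(idx)
  )
  if (anyDuplicated(roles$index)) {
    abort("channel indices must be unique", class = "oligouptake_validation_error")
  }
  roles
}

# parse "neuron_marker=0,oligomer=1[,nucleus=2]" (CLI/config form)
parse_roles <- function(text) {
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    abort(sprintf("cannot parse channel-role mapping '%s'", text),
          class = "oligouptake_validation_error")
  }
  vals <- setNames(
    suppressWarnings(as.integer(vapply(kv, `[[`, "", 2L))),
    vapply(kv, `[[`, "", 1L)
  )
  if (anyNA(vals)) {
    abort(sprintf("non-integer channel index in role mapping '%s'", text),
          class = "oligouptake_validation_error")
  }
  known <- c("neuron_marker", "oligomer", "nucleus")
  if (!all(names(vals) %in% known)) {
    abort(sprintf("unknown role in mapping '%s' (allowed: %s)",
                  text, paste(known, collapse = ", ")),
          class = "oligouptake_validation_error")
  }
  missing <- setdiff(c("neuron_marker", "oligomer"), names(vals))
  if (length(missing)) {
    abort(sprintf("role mapping '%s' lacks required role(s): %s",
                  text, paste(missing, collapse = ", ")),
          class = "oligouptake_validation_error")
  }
  channel_roles(neuron_marker = vals[["neuron_marker"]],
                oligomer = vals[["oligomer"]],
                nucleus = if ("nucleus" %in% names(vals)) vals[["nucleus"]])
}

validate_roles <- function(roles, n_channels) {
  if (!is.data.frame(roles) || !all(c("role", "index") %in% names(roles))) {
    abort("roles must be a data frame with columns 'role' and 'index'",
          class = "oligouptake_validation_error")
  }
  for (needed in c("neuron_marker", "oligomer")) {
    if (sum(roles$role == needed) != 1L) {
      abort(sprintf("roles must contain exactly one '%s' channel", needed),
            class = "oligouptake_validation_error")
    }
  }
  if (anyDuplicated(roles$index)) {
    abort("channel indices must be unique", class = "oligouptake_validation_error")
  }
  if (any(roles$index < 0L | roles$index >= n_channels)) {
    abort(sprintf("role mapping references channel index outside 0..%d",
                  n_channels - 1L),
          class = "oligouptake_validation_error")
  }
  invisible(roles)
}

#' Multichannel 3D image stack
#'
#' Container for a confocal Z-stack: a 4-D intensity array ordered
#' `(channel, z, y, x)` together with the voxel spacing and a channel-role
#' table. All physical quantities in the package are in micrometres; indices
#' are 1-based inside R, channel roles are 0-based (matching on-disk order).
#'
#' @param intensities Numeric 4-D array ordered `(channel, z, y, x)`. A 3-D
#'   array is promoted to a single-channel stack.
#' @param spacing A [voxel_spacing()].
#' @param channels A role table from [channel_roles()].
#' @param provenance Free-text label describing where the stack came from.
#' @return An `image_stack` object.
#' @seealso [read_stack()], [write_stack()], [get_channel()]
#' @export
image_stack <- function(intensities, spacing = voxel_spacing(),
                        channels = NULL, provenance = "") {
  if (is.array(intensities) && length(dim(intensities)) == 3L) {
    dim(intensities) <- c(1L, dim(intensities))
  }
  if (!is.array(intensities) || length(dim(intensities)) != 4L) {
    abort("intensities must be a 4-D array ordered (channel, z, y, x)",
          class = "oligouptake_validation_error")
  }
  if (!all(is.finite(intensities))) {
    abort("stack intensities must be finite", class = "oligouptake_validation_error")
  }
  if (any(intensities < 0)) {
    abort("stack intensities must be non-negative", class = "oligouptake_validation_error")
  }
  if (dim(intensities)[2] < 2L) {
    abort("a Z-stack needs at least 2 planes", class = "oligouptake_validation_error")
  }
  if (!is_voxel_spacing(spacing)) {
    abort("spacing must be a voxel_spacing object", class = "oligouptake_validation_error")
  }
  if (!is.null(channels)) validate_roles(channels, dim(intensities)[1])
  structure(
    list(intensities = intensities, spacing = spacing,
         channels = channels, provenance = provenance),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %d channel(s), %d planes, %d x %d px, spacing %s\n",
              d[1], d[2], d[3], d[4], format(x$spacing)))
  if (!is.null(x$channels)) {
    cat("  roles:", paste(sprintf("%s=%d", x$channels$role, x$channels$index),
                          collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$intensities)

is_image_stack <- function(x) inherits(x, "image_stack")

#' Extract one channel of a stack as a 3-D array
#'
#' @param stack An [image_stack()].
#' @param role A role name (`"neuron_marker"`, `"oligomer"`, `"nucleus"`) or a
#'   0-based channel index.
#' @return A 3-D numeric array ordered `(z, y, x)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(is_image_stack(stack))
  if (is.character(role)) {
    if (is.null(stack$channels) || !role %in% stack$channels$role) {
      abort(sprintf("stack has no channel with role '%s'", role),
            class = "oligouptake_validation_error")
    }
    idx <- stack$channels$index[match(role, stack$channels$role)]
  } else {
    idx <- as.integer(role)
  }
  nchan <- dim(stack$intensities)[1]
  if (idx < 0L || idx >= nchan) {
    abort(sprintf("channel index %d outside 0..%d", idx, nchan - 1L),
          class = "oligouptake_validation_error")
  }
  arr <- stack$intensities[idx + 1L, , , , drop = FALSE]
  dim(arr) <- dim(stack$intensities)[-1]
  arr
}

# replace one channel, returning a new stack
set_channel <- function(stack, role, values) {
  idx <- if (is.character(role)) {
    stack$channels$index[match(role, stack$channels$role)]
  } else as.integer(role)
  stopifnot(all(dim(values) == dim(stack$intensities)[-1]))
  stack$intensities[idx + 1L, , , ] <- values
  stack
}
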