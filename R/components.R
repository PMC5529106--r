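#' Label connected components of a binary volume
#'
#' 3-D connected-component labeling under face (6) or face/edge/corner (26)
#' connectivity. A 2-D matrix is treated as a single-plane volume, where the
#' two connectivities reduce to the usual 4- and 8-neighbourhoods.
#'
#' @param mask Logical or 0/1 numeric array ordered `(z, y, x)`, or a matrix.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered 1..k in scan order of their first voxel.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (is.matrix(mask)) dim(mask) <- c(1L, dim(mask))
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    abort("mask must be a 3-D (z, y, x) array or a matrix",
          class = "oligouptake_validation_error")
  }
  if (!connectivity %in% c(6, 26)) {
    abort("connectivity must be 6 or 26", class = "oligouptake_validation_error")
  }
  storage <- as.integer(mask != 0)
  cpp_label_components(storage, dim(mask), as.integer(connectivity))
}
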