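#' Voxel spacing of a confocal stack
#'
#' Physical size of one voxel, in micrometres. Confocal stacks are usually
#' anisotropic: the XY pixel size is set by the objective and scan zoom
#' (0.090 um here, matching a 60x/1.4 NA objective with additional 2.5x zoom
#' on a 512 x 512 scan), while the Z step is chosen at acquisition and is
#' typically coarser.
#'
#' @param dx,dy Pixel size along X and Y in micrometres. Default 0.090.
#' @param dz Plane spacing along Z in micrometres. Default 0.250.
#' @return A `voxel_spacing` object (named list with `dx`, `dy`, `dz`).
#' @examples
#' voxel_spacing()
#' voxel_spacing(dz = 0.3)
#' @export
voxel_spacing <- function(dx = 0.090, dy = 0.090, dz = 0.250) {
  for (v in c(dx = dx, dy = dy, dz = dz)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort("voxel spacing components must be single positive finite numbers",
            class = "oligouptake_validation_error")
    }
  }
  structure(list(dx = dx, dy = dy, dz = dz), class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dx=%.4g dy=%.4g dz=%.4g um\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' @export
format.voxel_spacing <- function(x, ...) {
  sprintf("(%g, %g, %g) um", x$dx, x$dy, x$dz)
}

# voxel volume in um^3
voxel_volume <- function(spacing) spacing$dx * spacing$dy * spacing$dz

is_voxel_spacing <- function(x) inherits(x, "voxel_spacing")
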