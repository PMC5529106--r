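#' Read a multichannel TIFF / OME-TIFF Z-stack
#'
#' Reads a multi-page TIFF and normalizes it to an [image_stack()] with axis
#' order `(channel, z, y, x)`. Dimensional metadata is resolved in this
#' order: an OME-XML ImageDescription embedded in the first page (as written
#' by Bio-Formats or tifffile), a companion `<path>.ome.xml` sidecar (as
#' written by [write_stack()]), then the explicit `shape`/`spacing`
#' arguments. A plain multi-page TIFF without any of these is interpreted as
#' Z planes of a single channel, and spacing falls back to
#' (0.090, 0.090, 0.250) um with a warning.
#'
#' @param path Path to a TIFF file.
#' @param roles Channel-role table from [channel_roles()], or a string like
#'   `"neuron_marker=0,oligomer=1"`. When `NULL`, roles embedded in OME
#'   channel names are used if present.
#' @param spacing Optional [voxel_spacing()] overriding file metadata.
#' @param shape Optional integer pair `c(n_channels, n_z)` for plain TIFFs
#'   without channel metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, roles = NULL, spacing = NULL, shape = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", path),
          class = "oligouptake_io_error")
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) {
      abort(sprintf("cannot read '%s' as TIFF: %s", path, conditionMessage(e)),
            class = "oligouptake_io_error")
    }
  )
  if (length(pages) == 0L) {
    abort(sprintf("'%s' contains no image planes", path),
          class = "oligouptake_io_error")
  }
  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE)) {
    meta <- parse_ome_xml(desc)
  }
  sidecar <- paste0(path, ".ome.xml")
  if (is.null(meta) && file.exists(sidecar)) {
    meta <- parse_ome_xml(paste(readLines(sidecar, warn = FALSE), collapse = "\n"))
  }

  n_pages <- length(pages)
  if (!is.null(meta)) {
    nc <- meta$size_c
    nz <- meta$size_z
    dim_order <- meta$dimension_order
  } else if (!is.null(shape)) {
    nc <- as.integer(shape[1]); nz <- as.integer(shape[2])
    dim_order <- "XYZCT"
  } else {
    nc <- 1L; nz <- n_pages
    dim_order <- "XYZCT"
  }
  if (nc * nz != n_pages) {
    abort(sprintf("metadata says %d channels x %d planes but file has %d pages",
                  nc, nz, n_pages),
          class = "oligouptake_validation_error")
  }

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nc, nz, ny, nx))
  scale <- if (!is.null(meta) && !is.null(meta$value_scale)) meta$value_scale else 1
  for (p in seq_len(n_pages)) {
    # page order: XYZCT = Z fastest within channel; XYCZT = C fastest
    if (startsWith(dim_order, "XYC")) {
      ci <- (p - 1L) %% nc + 1L
      zi <- (p - 1L) %/% nc + 1L
    } else {
      zi <- (p - 1L) %% nz + 1L
      ci <- (p - 1L) %/% nz + 1L
    }
    arr[ci, zi, , ] <- pages[[p]] * scale
  }

  if (is.null(spacing)) {
    if (!is.null(meta) && !is.null(meta$spacing)) {
      spacing <- meta$spacing
    } else {
      warn(sprintf("no voxel-size metadata for '%s'; assuming %s",
                   path, format(voxel_spacing())))
      spacing <- voxel_spacing()
    }
  }

  if (is.character(roles)) roles <- parse_roles(roles)
  if (is.null(roles) && !is.null(meta) && !is.null(meta$roles)) roles <- meta$roles
  if (!is.null(roles)) validate_roles(roles, nc)

  image_stack(arr, spacing = spacing, channels = roles,
              provenance = sprintf("read from %s", basename(path)))
}

#' Write an image stack as multi-page TIFF with OME-XML metadata
#'
#' Planes are written Z-fastest within each channel (OME dimension order
#' XYZCT). Integer-valued stacks with intensities in 0..65535 are stored as
#' 16-bit and round-trip losslessly; other stacks are stored as 32-bit float
#' scaled into `[0, 1]`, with the scale recorded in the metadata. The OME-XML
#' (channel count, plane count, physical voxel sizes, channel role names)
#' goes to a companion `<path>.ome.xml` file.
#'
#' @param stack An [image_stack()].
#' @param path Output path (conventionally `.ome.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  if (!all(is.finite(stack$intensities))) {
    abort("cannot write non-finite intensities", class = "oligouptake_validation_error")
  }
  d <- dim(stack$intensities)
  nc <- d[1]; nz <- d[2]
  vals <- stack$intensities
  integerish <- all(vals == floor(vals)) && max(vals) <= 65535
  if (integerish) {
    bits <- 16L
    scale <- 65535
  } else {
    bits <- 32L
    scale <- max(1, max(vals))
  }
  pages <- vector("list", nc * nz)
  p <- 1L
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      plane <- vals[ci, zi, , ]
      dim(plane) <- d[3:4]
      pages[[p]] <- plane / scale
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "deflate")
  writeLines(build_ome_xml(stack, pixel_type = if (integerish) "uint16" else "float",
                           value_scale = if (integerish) 1 else scale),
             paste0(path, ".ome.xml"))
  invisible(path)
}

# ---- OME-XML helpers --------------------------------------------------------

build_ome_xml <- function(stack, pixel_type, value_scale = 1) {
  d <- dim(stack$intensities)
  ch_names <- rep("", d[1])
  if (!is.null(stack$channels)) {
    ch_names[stack$channels$index + 1L] <- stack$channels$role
  }
  channels <- paste(sprintf(
    '      <Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
    seq_len(d[1]) - 1L, ch_names), collapse = "\n")
  sp <- stack$spacing
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">\n',
    sprintf('  <Image ID="Image:0" Name="%s">\n', xml_escape(stack$provenance)),
    sprintf(paste0('    <Pixels ID="Pixels:0" DimensionOrder="XYZCT" Type="%s"',
                   ' SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1"',
                   ' PhysicalSizeX="%g" PhysicalSizeXUnit="µm"',
                   ' PhysicalSizeY="%g" PhysicalSizeYUnit="µm"',
                   ' PhysicalSizeZ="%g" PhysicalSizeZUnit="µm"',
                   ' ValueScale="%g">\n'),
            pixel_type, d[4], d[3], d[2], d[1],
            sp$dx, sp$dy, sp$dz, value_scale),
    channels, "\n",
    '    </Pixels>\n',
    '  </Image>\n',
    '</OME>\n'
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# namespace-agnostic OME-XML parse; returns NULL if no Pixels element
parse_ome_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  at <- function(name) xml2::xml_attr(px, name)
  num <- function(name) suppressWarnings(as.numeric(at(name)))
  size_c <- as.integer(num("SizeC")); size_z <- as.integer(num("SizeZ"))
  if (is.na(size_c) || is.na(size_z)) return(NULL)
  spacing <- NULL
  if (!is.na(num("PhysicalSizeX")) && !is.na(num("PhysicalSizeY"))) {
    dz <- num("PhysicalSizeZ")
    spacing <- voxel_spacing(num("PhysicalSizeX"), num("PhysicalSizeY"),
                             if (is.na(dz)) 0.250 else dz)
  }
  chn <- xml2::xml_find_all(px, ".//*[local-name()='Channel']")
  roles <- NULL
  if (length(chn) > 0) {
    nm <- xml2::xml_attr(chn, "Name")
    if ("neuron_marker" %in% nm && "oligomer" %in% nm) {
      roles <- channel_roles(
        neuron_marker = match("neuron_marker", nm) - 1L,
        oligomer = match("oligomer", nm) - 1L,
        nucleus = if ("nucleus" %in% nm) match("nucleus", nm) - 1L
      )
    }
  }
  vs <- num("ValueScale")
  list(size_c = size_c, size_z = size_z,
       dimension_order = if (is.na(at("DimensionOrder"))) "XYZCT" else at("DimensionOrder"),
       spacing = spacing, roles = roles,
       value_scale = if (is.na(vs)) NULL else vs)
}
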