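#' Two-channel 8-bit confocal volume
#'
#' Container for a two-channel image stack: green carries the cytoplasmic
#' astrocyte reporter (EGFP), red the dye-labeled axonal mitochondria.
#' Voxels are isotropic; the acquisition default is 0.4 um in x, y and z
#' (the z-step is matched to the pixel size).
#'
#' @param green,red integer arrays (2D or 3D), same dimensions, values 0..255.
#' @param voxel_size_um isotropic voxel edge length in micrometers.
#' @return an object of class `voxel_stack` with elements `green`, `red`,
#'   `voxel_size_um`.
#' @examples
#' vs <- voxel_stack(array(255L, c(8, 8, 8)), array(0L, c(8, 8, 8)))
#' dim(vs$green)
#' @export
voxel_stack <- function(green, red, voxel_size_um = 0.4) {
  green <- as_vol(green); red <- as_vol(red)
  if (!identical(dim(green), dim(red)))
    stop_gq("green and red channels must have identical dimensions")
  for (ch in list(green, red))
    if (any(ch < 0 | ch > 255)) stop_gq("channel intensities must lie in 0..255")
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    stop_gq("voxel_size_um must be a positive length")
  structure(list(green = green, red = red,
                 voxel_size_um = as.numeric(voxel_size_um)),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf("voxel_stack: %d x %d x %d voxels, %.3g um/voxel (isotropic)\n",
              d[1], d[2], d[3], x$voxel_size_um))
  invisible(x)
}

#' Write / read a two-channel stack as paired multi-page TIFF files
#'
#' Channels are stored as paired files `<stem>_green.tif` and
#' `<stem>_red.tif` (one page per z-slice); the voxel size travels in a JSON
#' sidecar `<stem>_meta.json`.
#'
#' @param stack a [voxel_stack()].
#' @param stem path stem (no extension).
#' @return `write_stack()`: the stem, invisibly. `read_stack()`: a
#'   [voxel_stack()].
#' @export
write_stack <- function(stack, stem) {
  stopifnot(inherits(stack, "voxel_stack"))
  write_tiff_stack(stack$green, paste0(stem, "_green.tif"))
  write_tiff_stack(stack$red, paste0(stem, "_red.tif"))
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size_um),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_stack
#' @export
read_stack <- function(stem) {
  meta_path <- paste0(stem, "_meta.json")
  vox <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path)$voxel_size_um else 0.4
  voxel_stack(read_tiff_stack(paste0(stem, "_green.tif")),
              read_tiff_stack(paste0(stem, "_red.tif")),
              voxel_size_um = vox)
}
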