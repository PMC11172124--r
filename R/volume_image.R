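#' 3D intensity volume with physical voxel spacing
#'
#' The basic container for a single-channel Z-stack. Voxels are stored as a
#' 3D array in `(Z, Y, X)` order (page order of the source TIFF = Z), with
#' the physical voxel spacing `(dz, dy, dx)` in micrometres carried
#' alongside. Intensities are kept in their native (usually integer) values;
#' no rescaling or normalisation is applied on construction.
#'
#' @param voxels 3D numeric array of non-negative, finite intensities,
#'   axis order `(Z, Y, X)`, at least 2 planes per axis.
#' @param spacing_um numeric triple `(dz, dy, dx)` in micrometres, all
#'   positive. Confocal stacks are typically anisotropic (e.g. the default
#'   Airyscan geometry `c(0.21, 0.05, 0.05)`).
#' @param condition free-text condition label attached to every downstream
#'   record produced from this image (e.g. `"minusDTT"`).
#' @param source_id image identifier used in output tables.
#'
#' @return An object of class `volume_image`: a list with fields `voxels`,
#'   `spacing_um`, `condition`, `source_id`.
#' @seealso [load_stack()], [gaussian_smooth()], [segment_nuclei()]
#' @export
volume_image <- function(voxels, spacing_um, condition = "unspecified",
                         source_id = "image") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    ns_stop("`voxels` must be a 3D array in (Z, Y, X) order", "validation_error")
  if (any(dim(voxels) < 2L))
    ns_stop("volume must have at least 2 planes along each axis",
            "validation_error")
  if (!is.numeric(spacing_um) || length(spacing_um) != 3L ||
      any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    ns_stop("`spacing_um` must be a positive numeric triple (dz, dy, dx)",
            "validation_error")
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0))
    ns_stop("intensities must be finite and non-negative", "validation_error")
  structure(
    list(voxels = voxels, spacing_um = as.numeric(spacing_um),
         condition = as.character(condition)[1],
         source_id = as.character(source_id)[1]),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %s [%s]\n  %d x %d x %d voxels (Z, Y, X), spacing %.3g x %.3g x %.3g um\n  intensity range [%g, %g]\n",
    x$source_id, x$condition, d[1], d[2], d[3],
    x$spacing_um[1], x$spacing_um[2], x$spacing_um[3],
    min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Read a multi-page greyscale TIFF as a volume
#'
#' Pages are mapped to Z in file order; intensities are read as stored
#' (`as.is`), without rescaling. Voxel spacing is *not* read from TIFF tags
#' -- it must be supplied, because resolution tags are unreliable across
#' writers while acquisition spacing is known from the microscope settings.
#'
#' @param path path to a readable multi-page greyscale TIFF.
#' @param spacing_um voxel spacing `(dz, dy, dx)` in micrometres.
#' @param condition,source_id metadata labels; `source_id` defaults to the
#'   file name without extension.
#' @return A [volume_image()].
#' @export
load_stack <- function(path, spacing_um, condition = "unspecified",
                       source_id = NULL) {
  if (!file.exists(path))
    ns_stop(sprintf("cannot read '%s'", path), "format_error")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3L)
      ns_stop(sprintf(
        "multi-channel TIFF: page has %d channels, expected a greyscale image",
        dim(p)[3]), "format_error")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    ns_stop("pages differ in Y/X dimensions", "format_error")
  nz <- length(pages)
  vox <- array(0, dim = c(nz, dims[1, 1], dims[2, 1]))
  for (i in seq_len(nz)) vox[i, , ] <- pages[[i]]
  if (is.null(source_id))
    source_id <- sub("\\.[^.]*$", "", basename(path))
  volume_image(vox, spacing_um, condition, source_id)
}

#' Write a volume (or integer label mask) as a multi-page 16-bit TIFF
#'
#' Intended for phantom export and mask/shell QC export. Values must be
#' integers in `[0, 65535]`; they round-trip bit-for-bit through
#' [load_stack()].
#'
#' @param x a [volume_image()], a `label_mask`, or a 3D integer-valued array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  arr <- if (inherits(x, "volume_image")) x$voxels
         else if (inherits(x, "label_mask")) x$labels
         else x
  if (!is.array(arr) || length(dim(arr)) != 3L)
    ns_stop("`x` must contain a 3D array", "validation_error")
  if (any(arr < 0) || any(arr > 65535) || any(arr != round(arr)))
    ns_stop("TIFF export requires integer values in [0, 65535]",
            "validation_error")
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) arr[i, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "LZW")
  invisible(path)
}
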