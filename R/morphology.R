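#' Binary morphology with ball structuring elements
#'
#' 3D binary dilation, erosion and closing with a Euclidean ball of the
#' given radius in voxel units. Implemented through the exact Euclidean
#' distance transform: a voxel survives erosion iff its distance to the
#' nearest background voxel exceeds the radius, and joins a dilation iff
#' its distance to the nearest foreground voxel is at most the radius.
#' This is identical to structuring-element morphology with the digital
#' ball `{o : |o| <= r}`. Space outside the volume counts as background.
#'
#' @param mask logical 3D array.
#' @param radius ball radius in voxels (>= 1).
#' @return Logical 3D array of the same shape.
#' @name morphology
NULL

#' @rdname morphology
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) return(mask)
  d <- dist_to_set(mask)
  mask | (d <= radius)
}

#' @rdname morphology
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- edt_padded(mask, c(1, 1, 1))
  mask & (d > radius)
}

#' @rdname morphology
#' @export
close_mask <- function(mask, radius) {
  # dilate/erode on a radius-padded grid so the intermediate dilation can
  # extend past the volume edge; this keeps closing extensive (M subset of
  # closing(M)) for objects touching the border
  r <- as.integer(ceiling(radius))
  d <- dim(mask)
  pad <- array(FALSE, d + 2L * r)
  core <- lapply(seq_len(3), function(a) (r + 1L):(r + d[a]))
  pad[core[[1]], core[[2]], core[[3]]] <- mask
  out <- erode_mask(dilate_mask(pad, radius), radius)
  out[core[[1]], core[[2]], core[[3]]]
}

# Distance from every voxel to the nearest TRUE voxel (voxel units), with
# no virtual foreground outside the volume. Used for dilation.
dist_to_set <- function(set) {
  d <- dim(set)
  pad <- array(TRUE, d + 2L)  # pad the complement with "not in set"
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !set
  full <- .edt3d(pad, dim(pad), c(1, 1, 1))
  full[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# Exact EDT of a foreground mask with out-of-volume space counted as
# background: every foreground voxel gets the distance (weighted by `step`
# per axis) to the nearest background voxel centre, where one virtual
# background layer abuts each face. Background voxels get 0.
edt_padded <- function(mask, step) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  full <- .edt3d(pad, dim(pad), step)
  full[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}
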