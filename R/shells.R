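#' Euclidean distance transform of a label mask
#'
#' Computes, for every foreground voxel, the exact shortest distance to the
#' nearest background voxel centre (so boundary-layer foreground voxels are
#' one step from background, and background voxels are 0). Space outside
#' the volume counts as background. Two metric modes are provided because
#' confocal stacks are strongly anisotropic (here the Z-step is typically
#' 4.2x the XY pixel):
#'
#' * `"physical"` (default): axis steps are weighted by `spacing_um`, so
#'   distances are in micrometres and anisotropy is respected;
#' * `"isotropic"`: unit steps on the voxel grid, distances in voxel units.
#'
#' The transform is computed on the union foreground; since each nucleus is
#' bounded by background, per-nucleus distances equal global distances for
#' non-touching nuclei.
#'
#' @param labels a `label_mask` (from [segment_nuclei()] et al.) or a
#'   logical 3D array (then `spacing_um` must be supplied).
#' @param metric_mode `"physical"` or `"isotropic"`.
#' @param spacing_um only used when `labels` is a bare array.
#' @return A `distance_map`: list with numeric 3D `dist`, `spacing_um`,
#'   `metric_mode`.
#' @export
distance_transform <- function(labels, metric_mode = c("physical", "isotropic"),
                               spacing_um = NULL) {
  metric_mode <- match.arg(metric_mode)
  if (inherits(labels, "label_mask")) {
    fg <- labels$labels > 0L
    spacing_um <- labels$spacing_um
  } else {
    stopifnot(is.logical(labels), length(dim(labels)) == 3L,
              !is.null(spacing_um))
    fg <- labels
  }
  step <- if (metric_mode == "physical") spacing_um else c(1, 1, 1)
  d <- edt_padded(fg, step)
  structure(list(dist = d, spacing_um = spacing_um, metric_mode = metric_mode),
            class = "distance_map")
}

#' Partition nuclei into K equally-spaced concentric 3D shells
#'
#' For each nucleus the maximum boundary distance `d_max` is found and every
#' foreground voxel's normalised depth `nd = d / d_max` (in `(0, 1]`) is
#' binned into `K` equal-width, half-open (lower-exclusive, upper-inclusive)
#' depth bins: layer `l = K + 1 - ceiling(K * nd)`. Layer 1 therefore
#' contains the distance-maximal voxel(s) at the nuclear centre and layer K
#' abuts the boundary. Normalisation is per nucleus, so nuclei of different
#' sizes all yield K layers.
#'
#' @param dmap a `distance_map` from [distance_transform()].
#' @param labels the matching `label_mask`.
#' @param K number of shells (default 24).
#' @return A `shell_assignment`: list with integer 3D `layer` (0 =
#'   background), `K`, and `per_nucleus_dmax` (named by nucleus id, in the
#'   distance map's units).
#' @export
assign_shells <- function(dmap, labels, K = 24) {
  stopifnot(inherits(dmap, "distance_map"), inherits(labels, "label_mask"))
  if (!identical(dim(dmap$dist), dim(labels$labels)))
    ns_stop("distance map and labels differ in shape", "validation_error")
  if (K < 1) ns_stop("K must be >= 1", "validation_error")
  L <- labels$labels
  idx <- which(L > 0L)
  if (length(idx) == 0L)
    ns_stop("no foreground voxels to assign", "degenerate_error")
  ids <- L[idx]
  d <- dmap$dist[idx]
  nlab <- max(ids)
  dmax <- vapply(split(d, ids), max, numeric(1))
  if (any(dmax <= 0))
    ns_stop("nucleus with zero maximum distance: degenerate object",
            "degenerate_error")
  dmax_full <- setNames(numeric(nlab), as.character(seq_len(nlab)))
  dmax_full[names(dmax)] <- dmax
  nd <- d / dmax_full[as.character(ids)]
  layer <- as.integer(K + 1 - ceiling(K * nd))
  layer[layer < 1L] <- 1L
  layer[layer > K] <- K  # guards against nd underflow at the boundary
  out <- array(0L, dim(L))
  out[idx] <- layer
  structure(list(layer = out, K = as.integer(K),
                 per_nucleus_dmax = dmax_full),
            class = "shell_assignment")
}

#' Per-shell mean intensity profile of each nucleus
#'
#' Averages *raw* (unsmoothed) intensities over each `(nucleus, layer)`
#' cell. Smoothing redistributes signal across shells, which would bias the
#' peripheral gradient, so it is never applied before this step. Layers
#' with no voxels (possible for large `K` on thin nuclei) are reported with
#' `voxel_count = 0` and `NA` mean -- missing, never imputed.
#'
#' @param raw the raw [volume_image()].
#' @param shells a `shell_assignment` from [assign_shells()].
#' @param labels the matching `label_mask`.
#' @return A `radial_profiles` data frame with one row per
#'   `(source_id, nucleus_id, layer)`: columns `source_id`, `nucleus_id`,
#'   `condition`, `layer`, `mean_intensity`, `voxel_count`, and attribute
#'   `K`.
#' @export
layer_profile <- function(raw, shells, labels) {
  stopifnot(inherits(raw, "volume_image"), inherits(shells, "shell_assignment"),
            inherits(labels, "label_mask"))
  if (!identical(dim(raw$voxels), dim(shells$layer)) ||
      !identical(dim(raw$voxels), dim(labels$labels)))
    ns_stop("raw volume, shells and labels differ in shape", "validation_error")
  K <- shells$K
  L <- labels$labels
  idx <- which(L > 0L)
  ids <- L[idx]
  lay <- shells$layer[idx]
  val <- as.numeric(raw$voxels[idx])
  nlab <- max(ids)
  cell <- (ids - 1L) * K + lay  # 1..nlab*K
  sums <- rowsum(val, cell)
  counts <- tabulate(cell, nbins = nlab * K)
  means <- rep(NA_real_, nlab * K)
  means[as.integer(rownames(sums))] <-
    sums[, 1] / counts[as.integer(rownames(sums))]
  out <- data.frame(
    source_id = raw$source_id,
    nucleus_id = rep(seq_len(nlab), each = K),
    condition = raw$condition,
    layer = rep(seq_len(K), nlab),
    mean_intensity = means,
    voxel_count = counts,
    stringsAsFactors = FALSE
  )
  structure(out, K = K, class = c("radial_profiles", "data.frame"))
}

#' Combine radial profile tables
#'
#' Row-binds `radial_profiles` tables from several images, checking that
#' they share the same number of shells.
#'
#' @param ... `radial_profiles` objects (or a single list of them).
#' @return A combined `radial_profiles` data frame.
#' @export
bind_profiles <- function(...) {
  ps <- list(...)
  if (length(ps) == 1L && !inherits(ps[[1]], "radial_profiles"))
    ps <- ps[[1]]
  Ks <- vapply(ps, function(p) attr(p, "K"), integer(1))
  if (length(unique(Ks)) > 1L)
    ns_stop("profiles mix different shell counts K", "validation_error")
  out <- do.call(rbind, lapply(ps, as.data.frame))
  structure(out, K = Ks[1], class = c("radial_profiles", "data.frame"))
}

#' Write radial profiles to CSV
#'
#' One row per `(source_id, nucleus_id, layer)` in deterministic order
#' (source, nucleus, layer); columns `source_id`, `nucleus_id`, `condition`,
#' `layer_index`, `mean_intensity`, `voxel_count`.
#'
#' @param profiles a `radial_profiles` data frame (possibly combined via
#'   [bind_profiles()]), or an empty list for a header-only file.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  cols <- c("source_id", "nucleus_id", "condition", "layer_index",
            "mean_intensity", "voxel_count")
  if (is.list(profiles) && !is.data.frame(profiles)) {
    if (length(profiles) == 0L) {
      empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                      cols))
      write.csv(empty, path, row.names = FALSE)
      return(invisible(path))
    }
    profiles <- bind_profiles(profiles)
  }
  stopifnot(inherits(profiles, "radial_profiles"))
  df <- as.data.frame(profiles)
  names(df)[names(df) == "layer"] <- "layer_index"
  df <- df[order(df$source_id, df$nucleus_id, df$layer_index), cols]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
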