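#' Configuration for a synthetic nuclear phantom
#'
#' Describes a 3D test volume with known ground truth: one or more
#' ellipsoidal nuclei (optionally with smooth surface folds), a radial
#' intensity profile expressed in normalised boundary depth
#' `nd = d / d_max` (1 at the nuclear centre, -> 0 at the envelope),
#' punctate speckles blurred by an anisotropic PSF, Poisson + Gaussian
#' noise, and optional border-touching distractor blobs. Identical
#' `seed` + config always renders the identical volume.
#'
#' Radial profile classes (all take `nd`):
#' * `flat(v)`: constant `v`;
#' * `linear(v_centre, v_edge)`: `v_centre` at `nd = 1`, `v_edge` as
#'   `nd -> 0`;
#' * `step(v_in, v_out, depth_break)`: `v_in` for `nd > depth_break`,
#'   `v_out` otherwise;
#' * `band(v_base, v_peak, centre_depth, width)`: Gaussian bump of height
#'   `v_peak - v_base` centred at depth `centre_depth` -- the
#'   nuclear-envelope-enriched pattern (peak near `nd ~ 0.1`).
#'
#' @param dim grid shape `(Z, Y, X)` in voxels.
#' @param spacing_um voxel spacing, default the Airyscan acquisition
#'   geometry `c(0.21, 0.05, 0.05)` (dz, dy, dx).
#' @param nuclei list of nuclei, each
#'   `list(centre_um =, semi_axes_um =, angles =, fold_amplitude =,
#'   fold_order =)`; `centre_um` defaults to the grid centre, `angles` are
#'   intrinsic rotations (radians) about the Z, Y, X axes,
#'   `fold_amplitude` in `[0, 1]` modulates the surface radius with a
#'   low-order angular harmonic of order `fold_order`.
#' @param profile radial profile spec, e.g.
#'   `list(type = "band", v_base = 140, v_peak = 320, centre_depth = 0.1,
#'   width = 0.1)`.
#' @param speckle `list(density_per_um3 =, amplitude =, psf_sigma_um =)`;
#'   point emitters scattered uniformly in the nucleus and convolved with
#'   an anisotropic Gaussian PSF (defaults approximate the ~140 nm XY /
#'   ~400 nm Z resolution of the targeted acquisition).
#' @param noise `list(poisson_scale =, gaussian_sd =)`: intensities are
#'   scaled by `poisson_scale`, Poisson-sampled and rescaled, then Gaussian
#'   read noise is added; zero both for exact noise-free tests.
#' @param background_level intensity outside nuclei.
#' @param distractors list of border-touching blobs
#'   `list(centre_um =, radius_um =, value =)` excluded from the ground
#'   truth (the segmentation stage is expected to remove them).
#' @param seed integer seed; all randomness in the phantom flows from it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(32, 128, 128),
                           spacing_um = c(0.21, 0.05, 0.05),
                           nuclei = list(list(semi_axes_um = c(1.5, 2.5, 2.5))),
                           profile = list(type = "band", v_base = 140,
                                          v_peak = 320, centre_depth = 0.1,
                                          width = 0.1),
                           speckle = list(density_per_um3 = 0.3,
                                          amplitude = 150,
                                          psf_sigma_um = c(0.17, 0.06, 0.06)),
                           noise = list(poisson_scale = 0.5, gaussian_sd = 8),
                           background_level = 40,
                           distractors = list(),
                           seed = 1) {
  nuclei <- lapply(nuclei, function(nuc) {
    nuc$centre_um <- nuc$centre_um %||% ((dim - 1) / 2 * spacing_um)
    nuc$angles <- nuc$angles %||% c(0, 0, 0)
    nuc$fold_amplitude <- nuc$fold_amplitude %||% 0
    nuc$fold_order <- nuc$fold_order %||% 3
    if (any(nuc$semi_axes_um <= 0))
      ns_stop("semi-axes must be positive", "validation_error")
    if (nuc$fold_amplitude < 0 || nuc$fold_amplitude > 1)
      ns_stop("fold_amplitude must be in [0, 1]", "validation_error")
    nuc
  })
  if (speckle$density_per_um3 < 0 || speckle$amplitude < 0)
    ns_stop("speckle density and amplitude must be >= 0", "validation_error")
  structure(list(dim = as.integer(dim), spacing_um = as.numeric(spacing_um),
                 nuclei = nuclei, profile = profile, speckle = speckle,
                 noise = noise, background_level = background_level,
                 distractors = distractors, seed = as.integer(seed)),
            class = "phantom_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate a radial profile spec at normalised depth nd (1 = centre).
eval_radial_profile <- function(profile, nd) {
  switch(profile$type,
         flat = rep(profile$v, length(nd)),
         linear = profile$v_edge + (profile$v_centre - profile$v_edge) * nd,
         step = ifelse(nd > profile$depth_break, profile$v_in, profile$v_out),
         band = profile$v_base + (profile$v_peak - profile$v_base) *
           exp(-0.5 * ((nd - profile$centre_depth) / profile$width)^2),
         ns_stop(sprintf("unknown profile type '%s'", profile$type),
                 "validation_error"))
}

# Rotation matrix from intrinsic angles about Z, Y, X.
rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Render one ellipsoid (optionally fold-perturbed) into a logical array.
# Returns the linear indices of its voxels. Coordinates are physical (um).
render_nucleus <- function(nuc, dim, spacing_um, phase) {
  a <- nuc$semi_axes_um
  rmax <- max(a) * (1 + nuc$fold_amplitude) + 2 * max(spacing_um)
  lo <- pmax(1L, floor((nuc$centre_um - rmax) / spacing_um) + 1L)
  hi <- pmin(dim, ceiling((nuc$centre_um + rmax) / spacing_um) + 1L)
  iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
  pz <- (iz - 1) * spacing_um[1] - nuc$centre_um[1]
  py <- (iy - 1) * spacing_um[2] - nuc$centre_um[2]
  px <- (ix - 1) * spacing_um[3] - nuc$centre_um[3]
  nz <- length(iz); ny <- length(iy); nx <- length(ix)
  P <- cbind(rep(pz, times = ny * nx),
             rep(rep(py, each = nz), times = nx),
             rep(px, each = nz * ny))
  Q <- P %*% rotation_matrix(nuc$angles)  # = t(R) applied to rows
  u <- sweep(Q, 2, a, "/")
  rho <- sqrt(rowSums(u^2))
  thr <- 1
  if (nuc$fold_amplitude > 0) {
    r <- pmax(rho, 1e-12)
    pol <- acos(pmin(1, pmax(-1, u[, 1] / r)))
    az <- atan2(u[, 2], u[, 3])
    fold <- sin(nuc$fold_order * az + phase[1]) * sin(pol)^2
    thr <- 1 + nuc$fold_amplitude * fold
  }
  inside <- rho <= thr
  sub_idx <- which(inside)
  z <- iz[((sub_idx - 1) %% nz) + 1]
  y <- iy[(((sub_idx - 1) %/% nz) %% ny) + 1]
  x <- ix[((sub_idx - 1) %/% (nz * ny)) + 1]
  (x - 1) * dim[1] * dim[2] + (y - 1) * dim[1] + z
}

#' Generate a synthetic nuclear phantom with ground truth
#'
#' Renders the configured nuclei, evaluates the radial intensity profile on
#' the *true* normalised boundary depth (computed by the exact physical
#' distance transform of the true mask), adds the blurred speckle field and
#' distractors, then applies Poisson scaling and Gaussian read noise.
#' The returned truth is populated before noise.
#'
#' @param config a [phantom_config()].
#' @return A list with `$image` (a [volume_image()] with integer voxels)
#'   and `$truth` (class `phantom_truth`): fields `mask` (logical array),
#'   `labels` (`label_mask` of true nuclei), `nd` (normalised depth array,
#'   0 outside), `dmap` (the true `distance_map`), `noiseless` (intensity
#'   array before noise), `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  dim <- config$dim
  sp <- config$spacing_um
  labels <- array(0L, dim)
  for (i in seq_along(config$nuclei)) {
    phase <- runif(2, 0, 2 * pi)
    idx <- render_nucleus(config$nuclei[[i]], dim, sp, phase)
    if (length(idx) == 0L)
      ns_stop("nucleus renders no voxels (too small for the grid?)",
              "config_error")
    if (any(labels[idx] != 0L))
      ns_stop("nuclei overlap: the pipeline assumes separable nuclei",
              "config_error")
    labels[idx] <- i
  }
  if (!any(labels > 0L))
    ns_stop("no nucleus voxels rendered", "config_error")
  mask <- labels > 0L
  lmask <- structure(list(labels = labels, spacing_um = sp),
                     class = "label_mask")

  dmap <- distance_transform(lmask, "physical")
  idx_fg <- which(mask)
  ids <- labels[idx_fg]
  dmax <- vapply(split(dmap$dist[idx_fg], ids), max, numeric(1))
  nd <- array(0, dim)
  nd[idx_fg] <- dmap$dist[idx_fg] / dmax[as.character(ids)]

  noiseless <- array(config$background_level, dim)
  noiseless[idx_fg] <- eval_radial_profile(config$profile, nd[idx_fg])

  spk <- config$speckle
  if (spk$density_per_um3 > 0 && spk$amplitude > 0) {
    vol_um3 <- length(idx_fg) * prod(sp)
    n_spk <- rpois(1, spk$density_per_um3 * vol_um3)
    if (n_spk > 0) {
      at <- sample(idx_fg, n_spk, replace = TRUE)
      field <- array(0, dim)
      hits <- tabulate(at, nbins = prod(dim))
      field[hits > 0] <- hits[hits > 0]
      sig_vox <- spk$psf_sigma_um / sp
      kern_peak <- prod(vapply(sig_vox, function(s) {
        if (s <= 0) return(1)
        r <- ceiling(4 * s)
        w <- exp(-0.5 * ((-r):r)^2 / s^2)
        max(w) / sum(w)
      }, numeric(1)))
      field <- .sepgauss(as.double(field), dim, sig_vox) *
        (spk$amplitude / kern_peak)
      noiseless <- noiseless + field
    }
  }

  for (dis in config$distractors) {
    lo <- pmax(1L, floor((dis$centre_um - dis$radius_um) / sp) + 1L)
    hi <- pmin(dim, ceiling((dis$centre_um + dis$radius_um) / sp) + 1L)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- ((iz - 1) * sp[1] - dis$centre_um[1])^2
    dy2 <- ((iy - 1) * sp[2] - dis$centre_um[2])^2
    dx2 <- ((ix - 1) * sp[3] - dis$centre_um[3])^2
    D <- outer(outer(dz2, dy2, "+"), dx2, "+")
    block <- noiseless[iz, iy, ix, drop = FALSE]
    block[D <= dis$radius_um^2] <- dis$value %||% 200
    noiseless[iz, iy, ix] <- block
  }

  vox <- noiseless
  if (config$noise$poisson_scale > 0) {
    s <- config$noise$poisson_scale
    vox <- rpois(length(vox), pmax(0, vox) * s) / s
  }
  if (config$noise$gaussian_sd > 0)
    vox <- vox + rnorm(length(vox), 0, config$noise$gaussian_sd)
  vox <- array(pmin(65535, pmax(0, round(vox))), dim)

  truth <- structure(list(mask = mask, labels = lmask, nd = nd, dmap = dmap,
                          per_nucleus_dmax = dmax, noiseless = noiseless,
                          config = config),
                     class = "phantom_truth")
  image <- volume_image(vox, sp, condition = "phantom",
                        source_id = sprintf("phantom_seed%d", config$seed))
  list(image = image, truth = truth)
}

#' Ground-truth shell assignment and RO statistics
#'
#' `truth_shells()` bins the true normalised depth with the same rule as
#' [assign_shells()] (`layer = K + 1 - ceiling(K * nd)`), giving the exact
#' layer label of every true-mask voxel for any `K`. `truth_ro_fold()`
#' averages the *noiseless* intensities over true layers and returns the
#' RO-to/RO-from ratio of voxel-weighted RO means -- the quantity the
#' pipeline estimates from noisy data.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param K number of shells.
#' @param ro_size,ro_from,ro_to RO geometry as in [aggregate_ro()] and
#'   [fold_change()].
#' @return `truth_shells()`: integer array of layer labels (0 outside);
#'   `truth_layer_means()`: numeric vector of K per-layer means of the
#'   noiseless intensity (single-nucleus phantoms);
#'   `truth_ro_fold()`: a single numeric ratio.
#' @export
truth_shells <- function(truth, K = 24) {
  stopifnot(inherits(truth, "phantom_truth"))
  idx <- which(truth$mask)
  layer <- as.integer(K + 1 - ceiling(K * truth$nd[idx]))
  layer[layer < 1L] <- 1L
  layer[layer > K] <- K
  out <- array(0L, dim(truth$mask))
  out[idx] <- layer
  out
}

#' @rdname truth_shells
#' @export
truth_layer_means <- function(truth, K = 24) {
  lay <- truth_shells(truth, K)
  idx <- which(lay > 0L)
  means <- rep(NA_real_, K)
  m <- tapply(truth$noiseless[idx], lay[idx], mean)
  means[as.integer(names(m))] <- m
  means
}

#' @rdname truth_shells
#' @export
truth_ro_fold <- function(truth, K = 24, ro_size = 4, ro_from = 1, ro_to = 6) {
  lay <- truth_shells(truth, K)
  idx <- which(lay > 0L)
  ro <- (lay[idx] - 1L) %/% ro_size + 1L
  m <- tapply(truth$noiseless[idx], ro, mean)
  unname(m[as.character(ro_to)] / m[as.character(ro_from)])
}

#' Phantom presets for the two targeted nuclear morphologies
#'
#' `mcf10a_like()` renders a flat, disc-shaped nucleus (Z semi-axis well
#' below the lateral semi-axes, no surface folds), emulating non-tumorigenic
#' epithelial nuclei. `mda231_like()` renders a taller nucleus with an
#' irregular, fold-perturbed surface and a denser, brighter speckle field,
#' emulating the invasive-line morphology. Both carry the
#' nuclear-envelope-enriched band profile (peak near depth 0.1, roughly
#' 2-fold periphery-to-centre contrast after shell averaging), a
#' border-touching distractor blob, and per-phantom semi-axis jitter of
#' +/- 5% so replicate phantoms vary like replicate nuclei.
#'
#' @param seed integer seed (drives geometry jitter, speckle and noise).
#' @param peripheral_scale multiplies the band height `v_peak - v_base`;
#'   e.g. `0.7` emulates a treatment that strips 30% of the peripheral
#'   pool while leaving the interior untouched.
#' @return As [generate_phantom()]: list with `$image` and `$truth`.
#' @export
mcf10a_like <- function(seed = 1, peripheral_scale = 1) {
  jit <- jitter_factors(seed, 3)
  cfg <- phantom_config(
    dim = c(32, 240, 240),
    nuclei = list(list(semi_axes_um = c(2.0, 5.0, 5.0) * jit)),
    profile = list(type = "band", v_base = 140,
                   v_peak = 140 + 180 * peripheral_scale,
                   centre_depth = 0.1, width = 0.1),
    distractors = list(list(centre_um = c(3.3, 0, 2.0), radius_um = 1.2,
                            value = 220)),
    seed = seed)
  generate_phantom(cfg)
}

#' @rdname mcf10a_like
#' @export
mda231_like <- function(seed = 1, peripheral_scale = 1) {
  jit <- jitter_factors(seed + 1000L, 3)
  cfg <- phantom_config(
    dim = c(40, 216, 216),
    nuclei = list(list(semi_axes_um = c(3.0, 4.5, 4.0) * jit,
                       fold_amplitude = 0.12, fold_order = 3)),
    profile = list(type = "band", v_base = 140,
                   v_peak = 140 + 180 * peripheral_scale,
                   centre_depth = 0.1, width = 0.1),
    speckle = list(density_per_um3 = 0.5, amplitude = 250,
                   psf_sigma_um = c(0.17, 0.06, 0.06)),
    distractors = list(list(centre_um = c(4.2, 2.0, 0), radius_um = 1.2,
                            value = 220)),
    seed = seed)
  generate_phantom(cfg)
}

# +/- 5% multiplicative jitter, deterministic in the seed, drawn from a
# stream separate from the phantom's own (which generate_phantom reseeds).
jitter_factors <- function(seed, n) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed + 500000L)
  runif(n, 0.95, 1.05)
}
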