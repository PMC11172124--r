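# Independent brute-force oracles and small fixture builders. These share no
# code with the package's computational paths.

# O(n^2) exhaustive nearest-background search. Background includes a virtual
# layer of voxels just outside every face (matching the package's stated
# boundary convention). `step` = per-axis physical step (dz, dy, dx).
edt_oracle <- function(mask, step = c(1, 1, 1)) {
  d <- dim(mask)
  out <- array(0, d)
  coords <- as.matrix(expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3]))
  phys <- sweep(coords - 1, 2, step, "*")
  fg <- which(mask)
  bg <- which(!mask)
  bgt <- if (length(bg)) t(phys[bg, , drop = FALSE]) else NULL
  for (i in fg) {
    p <- phys[i, ]
    db <- if (!is.null(bgt)) sqrt(min(colSums((bgt - p)^2))) else Inf
    border <- min(coords[i, ] * step, (d - coords[i, ] + 1) * step)
    out[i] <- min(db, border)
  }
  out
}

# Exhaustive Otsu: same histogram construction, but between-class variance
# evaluated per candidate cut by direct summation over bins (no cumulative
# recurrences). Returns the upper edge of the last background bin.
otsu_oracle <- function(v, n_bins = 256) {
  v <- as.numeric(v)
  rng <- range(v)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(n_bins, floor((v - rng[1]) / width) + 1L)
  counts <- tabulate(bin, nbins = n_bins)
  centres <- rng[1] + (seq_len(n_bins) - 0.5) * width
  best <- -Inf
  kbest <- NA_integer_
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k])
    n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * centres[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * centres[(k + 1):n_bins]) / n1
    bcv <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      kbest <- k
    }
  }
  rng[1] + kbest * width
}

# Brute-force binary morphology with the digital ball {o : |o| <= r}.
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

dilate_oracle <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- ball_offsets(radius)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(offs))) {
    sh <- sweep(idx, 2, as.numeric(offs[i, ]), "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    out[sh[ok, , drop = FALSE]] <- TRUE
  }
  out
}

erode_oracle <- function(mask, radius) {
  # complement duality, with out-of-volume space treated as background
  d <- dim(mask)
  pad <- array(TRUE, d + 2 * ceiling(radius))
  r <- ceiling(radius)
  pad[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- !mask
  dil <- dilate_oracle(pad, radius)
  !dil[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])]
}

# Solid sphere mask of given voxel radius centred in a cubic grid.
sphere_mask <- function(n, radius) {
  c0 <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= radius^2, c(n, n, n))
}

# Wrap a matrix of per-nucleus layer means (rows = nuclei) as a
# radial_profiles table with unit voxel counts.
profiles_from_matrix <- function(m, condition = "g", source_id = "sim") {
  K <- ncol(m)
  df <- data.frame(
    source_id = source_id,
    nucleus_id = rep(seq_len(nrow(m)), each = K),
    condition = condition,
    layer = rep(seq_len(K), nrow(m)),
    mean_intensity = as.vector(t(m)),
    voxel_count = 1L,
    stringsAsFactors = FALSE
  )
  structure(df, K = K, class = c("radial_profiles", "data.frame"))
}

# Small, quick phantom used by module tests (noise-free unless stated).
small_phantom <- function(seed = 1, profile = list(type = "flat", v = 150),
                          noise = list(poisson_scale = 0, gaussian_sd = 0),
                          speckle = list(density_per_um3 = 0, amplitude = 0,
                                         psf_sigma_um = c(0.17, 0.06, 0.06)),
                          dim = c(24, 96, 96),
                          nuclei = list(list(semi_axes_um = c(1.4, 1.8, 1.8))),
                          ...) {
  generate_phantom(phantom_config(dim = dim, nuclei = nuclei,
                                  profile = profile, speckle = speckle,
                                  noise = noise, seed = seed, ...))
}

# Full pipeline on one image, returning the profiles of nucleus 1.
profile_nucleus1 <- function(img, params = segmentation_params(), K = 24,
                             metric_mode = "physical") {
  labels <- segment_nuclei(img, params)
  dmap <- distance_transform(labels, metric_mode)
  shells <- assign_shells(dmap, labels, K)
  prof <- layer_profile(img, shells, labels)
  prof[prof$nucleus_id == 1, ]
}
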