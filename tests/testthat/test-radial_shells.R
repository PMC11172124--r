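as_label_mask <- function(mask, spacing = c(1, 1, 1)) {
  structure(list(labels = array(as.integer(mask), dim(mask)),
                 spacing_um = spacing), class = "label_mask")
}

test_that("distance transform handles canonical toy geometries", {
  # single foreground voxel: nearest background is adjacent
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  d <- distance_transform(as_label_mask(m), "isotropic")
  expect_equal(d$dist[3, 3, 3], 1)
  expect_true(all(d$dist[!m] == 0))
  # 1x1x7 rod: centre voxel is 1 away laterally, not 4 along the rod
  rod <- array(FALSE, c(7, 5, 5))
  rod[, 3, 3] <- TRUE
  dr <- distance_transform(as_label_mask(rod), "isotropic")
  expect_equal(dr$dist[4, 3, 3], 1)
  # 9x9x9 solid cube: centre voxel is 5 steps from virtual outside background
  cube <- array(TRUE, c(9, 9, 9))
  dc <- distance_transform(as_label_mask(cube), "isotropic")
  expect_equal(dc$dist[5, 5, 5], 5)
})

test_that("distance transform matches exhaustive search in both metrics", {
  set.seed(41)
  for (i in 1:6) {
    d <- sample(5:12, 3, replace = TRUE)
    m <- array(runif(prod(d)) < 0.55, d)
    lm_iso <- as_label_mask(m, c(1, 1, 1))
    expect_equal(distance_transform(lm_iso, "isotropic")$dist,
                 edt_oracle(m, c(1, 1, 1)))
    sp <- c(0.21, 0.05, 0.05)
    lm_phys <- as_label_mask(m, sp)
    expect_equal(distance_transform(lm_phys, "physical")$dist,
                 edt_oracle(m, sp))
  }
})

test_that("shell assignment bins normalised depth with layer 1 central", {
  sph <- sphere_mask(25, 12)
  lm <- as_label_mask(sph)
  dmap <- distance_transform(lm, "isotropic")
  sh <- assign_shells(dmap, lm, 4)
  # distance-maximal voxel(s) sit in layer 1
  expect_true(all(sh$layer[dmap$dist == max(dmap$dist)] == 1))
  expect_equal(unname(sh$per_nucleus_dmax["1"]), max(dmap$dist))
  # occupancy equals brute-force equal-width binning of exhaustive distances
  dex <- edt_oracle(sph)
  nd <- dex[sph] / max(dex)
  lay_oracle <- 4 + 1 - ceiling(4 * nd)
  expect_equal(tabulate(sh$layer[sh$layer > 0], 4), tabulate(lay_oracle, 4))
  # K = 1: every foreground voxel in layer 1
  sh1 <- assign_shells(dmap, lm, 1)
  expect_true(all(sh1$layer[sph] == 1))
  expect_true(all(sh1$layer[!sph] == 0))
})

test_that("layers are disjoint, exhaustive, and nested by distance", {
  ph <- small_phantom(seed = 5, dim = c(20, 72, 72),
                      nuclei = list(list(semi_axes_um = c(1.2, 1.5, 1.5))),
                      noise = list(poisson_scale = 0.4, gaussian_sd = 5))
  lm <- ph$truth$labels
  dmap <- distance_transform(lm, "physical")
  K <- 24
  sh <- assign_shells(dmap, lm, K)
  fg <- lm$labels > 0
  # cover exactly the foreground, one layer per voxel
  expect_true(all(sh$layer[fg] >= 1 & sh$layer[fg] <= K))
  expect_true(all(sh$layer[!fg] == 0))
  prof <- layer_profile(ph$image, sh, lm)
  expect_equal(sum(prof$voxel_count), sum(fg))
  # bin edges respected: layer l+1 distances never exceed layer l's minimum
  # beyond the shared bin edge
  dmax <- sh$per_nucleus_dmax["1"]
  edges <- dmax * (K - seq_len(K)) / K  # lower edge of layer l
  for (l in seq_len(K)) {
    dl <- dmap$dist[sh$layer == l]
    if (length(dl)) {
      expect_gt(min(dl), edges[l])
      expect_lte(max(dl), dmax * (K - l + 1) / K + 1e-12)
    }
  }
})

test_that("layer profiles average raw intensities per shell", {
  sph <- sphere_mask(21, 9)
  lm <- as_label_mask(sph)
  dmap <- distance_transform(lm, "isotropic")
  sh <- assign_shells(dmap, lm, 3)
  # constant nucleus -> flat profile at that constant
  img_c <- volume_image(array(77, c(21, 21, 21)), c(1, 1, 1),
                        condition = "flat", source_id = "c1")
  pc <- layer_profile(img_c, sh, lm)
  expect_equal(pc$mean_intensity, rep(77, 3))
  expect_equal(pc$condition, rep("flat", 3))
  # intensity = distance -> strictly decreasing in layer index
  img_d <- volume_image(dmap$dist, c(1, 1, 1))
  pd <- layer_profile(img_d, sh, lm)
  expect_true(all(diff(pd$mean_intensity) < 0))
  # two-value step aligned with K = 2 bins -> exact (10, 50) profile
  dex <- edt_oracle(sph)
  ndx <- dex / max(dex)
  step_img <- array(50, c(21, 21, 21))
  step_img[ndx > 0.5] <- 10
  sh2 <- assign_shells(dmap, lm, 2)
  p2 <- layer_profile(volume_image(step_img, c(1, 1, 1)), sh2, lm)
  expect_equal(p2$mean_intensity, c(10, 50))
  # shape mismatch rejected
  expect_error(layer_profile(volume_image(array(1, c(4, 4, 4)), c(1, 1, 1)),
                             sh, lm), class = "validation_error")
})

test_that("profiles are affine-equivariant in intensity", {
  ph <- small_phantom(seed = 6, dim = c(18, 60, 60),
                      nuclei = list(list(semi_axes_um = c(1.0, 1.2, 1.2))),
                      profile = list(type = "linear", v_centre = 100,
                                     v_edge = 200))
  lm <- ph$truth$labels
  dmap <- distance_transform(lm, "physical")
  sh <- assign_shells(dmap, lm, 8)
  base <- layer_profile(ph$image, sh, lm)
  scaled <- ph$image
  scaled$voxels <- 3 * scaled$voxels + 11
  psc <- layer_profile(scaled, sh, lm)
  expect_equal(psc$mean_intensity, 3 * base$mean_intensity + 11)
  expect_equal(psc$voxel_count, base$voxel_count)
})

test_that("a rotated spherical stack yields the identical profile", {
  cfg <- phantom_config(dim = c(41, 41, 41), spacing_um = c(0.1, 0.1, 0.1),
                        nuclei = list(list(semi_axes_um = c(1.4, 1.4, 1.4))),
                        profile = list(type = "band", v_base = 140,
                                       v_peak = 320, centre_depth = 0.1,
                                       width = 0.1),
                        seed = 9)
  ph <- generate_phantom(cfg)
  p <- segmentation_params(sigma_um = c(0.1, 0.1, 0.1), min_volume_um3 = 5)
  rotations <- list(
    function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1],  # 90 deg about Z
    function(a) aperm(a, c(3, 2, 1))[, , dim(a)[1]:1],  # 90 deg about Y
    function(a) aperm(a, c(2, 1, 3))[, dim(a)[1]:1, ]   # 90 deg about X
  )
  ref <- profile_nucleus1(ph$image, p, K = 12, metric_mode = "isotropic")
  for (rot in rotations) {
    img_r <- volume_image(rot(ph$image$voxels), c(0.1, 0.1, 0.1))
    pr <- profile_nucleus1(img_r, p, K = 12, metric_mode = "isotropic")
    # voxel sets per layer are identical; summation order may differ
    expect_identical(pr$voxel_count, ref$voxel_count)
    expect_equal(pr$mean_intensity, ref$mean_intensity, tolerance = 1e-12)
  }
})
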