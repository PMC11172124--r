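test_that("gaussian smoothing preserves DC, mass and symmetry", {
  v <- array(runif(6 * 7 * 8, 10, 20), c(6, 7, 8))
  img <- volume_image(v, c(1, 1, 1))
  # sigma 0 -> identity
  expect_equal(gaussian_smooth(img, c(0, 0, 0))$voxels, v)
  # constant volume unchanged for any sigma
  cimg <- volume_image(array(42, c(8, 8, 8)), c(0.21, 0.05, 0.05))
  sm <- gaussian_smooth(cimg, c(0.4, 0.2, 0.1))
  expect_equal(max(abs(sm$voxels - 42)), 0, tolerance = 1e-12)
  # unit impulse: mass conserved, symmetric about the impulse
  imp <- array(0, c(25, 25, 25))
  imp[13, 13, 13] <- 1
  smi <- gaussian_smooth(volume_image(imp, c(1, 1, 1)), c(2, 2, 2))$voxels
  expect_equal(sum(smi), 1, tolerance = 1e-6)
  expect_equal(smi, smi[25:1, , ])
  expect_equal(smi, aperm(smi, c(3, 2, 1)))
  # anisotropic spacing: physical sigma converts to voxel sigma per axis
  an <- gaussian_smooth(volume_image(imp, c(0.2, 0.1, 0.1)), c(0.2, 0.2, 0.2))
  expect_equal(an$voxels, aperm(an$voxels, c(1, 3, 2)))  # y/x symmetric
  expect_false(isTRUE(all.equal(an$voxels, aperm(an$voxels, c(2, 1, 3)))))
  expect_error(gaussian_smooth(img, c(-1, 0, 0)), class = "validation_error")
})

test_that("Otsu threshold separates bimodal data and rejects constants", {
  v <- array(c(rep(10, 500), rep(200, 500)), c(10, 10, 10))
  thr <- otsu_threshold(v)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  set.seed(11)
  modes <- array(c(rnorm(2000, 30, 10), rnorm(2000, 160, 10)), c(10, 20, 20))
  modes[modes < 0] <- 0
  thr2 <- otsu_threshold(modes)
  # the between-class variance is nearly flat across the inter-mode valley,
  # so assert mode separation plus agreement with the exhaustive scan
  expect_gt(thr2, 30)
  expect_lt(thr2, 160)
  expect_equal(thr2, otsu_oracle(modes))
  expect_error(otsu_threshold(array(5, c(4, 4, 4))),
               class = "degenerate_error")
})

test_that("Otsu equals exhaustive between-class-variance search", {
  set.seed(21)
  for (i in 1:8) {
    nvals <- sample(3:64, 1)
    vals <- sort(runif(nvals, 0, 300))
    v <- array(sample(vals, 9 * 9 * 9, replace = TRUE,
                      prob = runif(nvals)), c(9, 9, 9))
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }
})

test_that("binarize_and_refine applies threshold then listed morphology", {
  v <- array(runif(8^3, 50, 100), c(8, 8, 8))
  img <- volume_image(v, c(1, 1, 1))
  p0 <- segmentation_params(morph_ops = list())
  # threshold below the global minimum -> all foreground
  expect_true(all(binarize_and_refine(img, 49, p0)$binary))
  # empty morph list -> pure strict thresholding
  thr <- 75
  expect_equal(binarize_and_refine(img, thr, p0)$binary, v > thr)
  gte <- segmentation_params(morph_ops = list(), threshold_mode = "gte")
  v[1, 1, 1] <- thr
  img2 <- volume_image(v, c(1, 1, 1))
  expect_false(binarize_and_refine(img2, thr, p0)$binary[1, 1, 1])
  expect_true(binarize_and_refine(img2, thr, gte)$binary[1, 1, 1])
  # closing radius 1 fills an interior hole of a solid cube
  cube <- array(0, c(11, 11, 11))
  cube[2:10, 2:10, 2:10] <- 100
  cube[6, 6, 6] <- 0
  pcl <- segmentation_params(morph_ops = list(list(op = "closing",
                                                   radius = 1)))
  ref <- binarize_and_refine(volume_image(cube, c(1, 1, 1)), 50, pcl)
  expect_true(ref$binary[6, 6, 6])
})

test_that("ball morphology matches the brute-force structuring element", {
  set.seed(31)
  for (r in c(1, 2)) {
    m <- array(runif(10 * 11 * 9) < 0.25, c(10, 11, 9))
    expect_identical(dilate_mask(m, r), dilate_oracle(m, r))
    expect_identical(erode_mask(m, r), erode_oracle(m, r))
  }
})

test_that("opening never adds voxels beyond closing (containment)", {
  set.seed(32)
  for (i in 1:5) {
    m <- array(runif(12^3) < 0.35, c(12, 12, 12))
    opening <- dilate_mask(erode_mask(m, 1), 1)
    closing <- close_mask(m, 1)
    expect_true(all(!opening | closing))
  }
})

test_that("labelling respects connectivity, volume filter and size order", {
  m <- array(FALSE, c(12, 14, 12))
  m[2:6, 2:6, 2:6] <- TRUE       # 125 voxels
  m[8:10, 9:11, 8:10] <- TRUE    # 27 voxels
  sm <- structure(list(binary = m, spacing_um = c(1, 1, 1)),
                  class = "segmentation_mask")
  lab <- label_and_filter(sm, segmentation_params(min_volume_um3 = 0))
  expect_equal(max(lab$labels), 2)
  # renumbered in decreasing volume order
  expect_equal(sum(lab$labels == 1), 125)
  expect_equal(sum(lab$labels == 2), 27)
  # speck below the volume filter is removed
  m2 <- m
  m2[12, 1, 1] <- TRUE
  sm2 <- structure(list(binary = m2, spacing_um = c(1, 1, 1)),
                   class = "segmentation_mask")
  lab2 <- label_and_filter(sm2, segmentation_params(min_volume_um3 = 5))
  expect_equal(max(lab2$labels), 2)
  expect_equal(lab2$labels[12, 1, 1], 0L)
  # diagonal-touching cubes: 2 components face-only, 1 with full connectivity
  dg <- array(FALSE, c(8, 8, 8))
  dg[2:3, 2:3, 2:3] <- TRUE
  dg[4:5, 4:5, 4:5] <- TRUE
  smd <- structure(list(binary = dg, spacing_um = c(1, 1, 1)),
                   class = "segmentation_mask")
  expect_equal(max(label_and_filter(
    smd, segmentation_params(min_volume_um3 = 0, connectivity = 6))$labels), 2)
  expect_equal(max(label_and_filter(
    smd, segmentation_params(min_volume_um3 = 0, connectivity = 26))$labels), 1)
})

test_that("border clearing removes lateral objects, keeps Z-extreme ones", {
  L <- array(0L, c(10, 12, 12))
  L[4:6, 1:3, 4:6] <- 1L    # touches y = 1 face -> removed
  L[1, 5:7, 5:7] <- 2L      # touches only z = 1 plane -> retained
  L[5:7, 6:9, 8:10] <- 3L   # interior -> retained
  lm <- structure(list(labels = L, spacing_um = c(1, 1, 1)),
                  class = "label_mask")
  out <- clear_lateral_border(lm)
  expect_equal(max(out$labels), 2)
  expect_true(all(out$labels[4:6, 1:3, 4:6] == 0))
  # survivors renumbered by decreasing volume: interior (36) > z-slab (9)
  expect_true(all(out$labels[5:7, 6:9, 8:10] == 1))
  expect_true(all(out$labels[1, 5:7, 5:7] == 2))
  # x-face contact is also lateral
  L2 <- array(0L, c(6, 6, 6))
  L2[3, 3, 1] <- 1L
  lm2 <- structure(list(labels = L2, spacing_um = c(1, 1, 1)),
                   class = "label_mask")
  expect_equal(max(clear_lateral_border(lm2)$labels), 0)
  # idempotence
  again <- clear_lateral_border(out)
  expect_identical(again$labels, out$labels)
})

test_that("segmentation recovers a noise-free ellipsoid (Jaccard >= 0.95)", {
  # net-neutral morphology: a flat noise-free object has no bright-rim edge
  # bias, so the default's compensating erosion is not wanted here
  p <- segmentation_params(morph_ops = list(list(op = "closing", radius = 2)),
                           min_volume_um3 = 10)
  ph <- small_phantom(seed = 3, dim = c(24, 120, 120),
                      nuclei = list(list(semi_axes_um = c(1.6, 2.2, 2.2))))
  lab <- segment_nuclei(ph$image, p)
  est <- lab$labels == 1L
  tru <- ph$truth$mask
  expect_gte(sum(est & tru) / sum(est | tru), 0.95)
  # the default (deliberately conservative) morphology stays inside truth
  pd <- segmentation_params(min_volume_um3 = 10)
  est_def <- segment_nuclei(ph$image, pd)$labels == 1L
  expect_lte(sum(est_def & !tru), 0.005 * sum(tru))
})
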