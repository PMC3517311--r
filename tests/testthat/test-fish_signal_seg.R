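sp0 <- rep(0.1236, 3)

test_that("preprocessing rescales every nonconstant crop to exactly [0, 255]", {
  set.seed(21)
  crop <- image_stack(array(runif(20^3, 5, 80), rep(20L, 3)), sp0)
  pre <- preprocess_channel(crop)
  expect_equal(min(pre$voxels), 0)
  expect_equal(max(pre$voxels), 255)
  expect_error(preprocess_channel(image_stack(array(7, rep(20L, 3)), sp0)),
               "no signal variance")
})

test_that("the 2D median filter removes single-voxel impulses", {
  d <- rep(15L, 3)
  v <- array(rep(seq(10, 12, length.out = d[1]), times = prod(d[1:2])), d)
  v[8, 8, 8] <- 200
  pre <- preprocess_channel(image_stack(v, sp0))
  # the impulse voxel is no longer an outlier after filtering
  expect_lt(pre$voxels[8, 8, 8], 250)
  expect_false(which.max(pre$voxels) == (8 - 1) + 15 * (8 - 1) + 225 * (8 - 1) + 1 &&
                 max(pre$voxels) - sort(pre$voxels, decreasing = TRUE)[2] > 100)
})

test_that("top-hat peak mask is empty on flat images and smooth gradients", {
  flat <- image_stack(array(42, rep(12L, 3)), sp0)
  expect_false(any(peak_mask(flat, c(3L, 3L, 1L))))

  # a pure large-scale gradient leaves no interior peaks (the clipped
  # windows of the opening can respond within one element radius of the
  # image border, so the assertion excludes that band)
  d <- c(30L, 30L, 10L)
  ramp <- array(rep((1:d[2]) * 2, each = d[1]), d)  # smooth x gradient
  m <- peak_mask(image_stack(ramp, sp0), c(3L, 3L, 1L))
  expect_false(any(m[4:27, 4:27, ]))
})

test_that("top-hat peak mask captures a blob narrower than the element", {
  d <- rep(25L, 3)
  img <- array(5, d)
  img <- nucorg3d:::add_spot(img, sp0, (d - 1) / 2 * sp0, 0.25, 150)
  m <- peak_mask(image_stack(img, sp0), c(3L, 3L, 1L))
  ctr <- (d + 1) %/% 2
  expect_true(m[ctr[1], ctr[2], ctr[3]])
  # mask stays local to the blob
  ai <- arrayInd(which(m), d)
  expect_true(all(abs(ai[, 1] - ctr[1]) <= 8 & abs(ai[, 2] - ctr[2]) <= 8))
})

test_that("bright-region mask covers a bright blob and is empty on flat input", {
  flat <- image_stack(array(9, rep(20L, 3)), sp0)
  expect_false(any(bright_region_mask(flat)))

  d <- rep(61L, 3)
  img <- array(5, d)
  img <- nucorg3d:::add_spot(img, sp0, (d - 1) / 2 * sp0, 0.8, 150)
  m <- bright_region_mask(image_stack(img, sp0), sigma_um = 1.24)
  ctr <- (d + 1) %/% 2
  expect_true(m[ctr[1], ctr[2], ctr[3]])
  # the far corner stays background
  expect_false(m[2, 2, 2])
})

test_that("objects below the 0.123 um^3 volume opening are removed", {
  d <- rep(24L, 3)
  m <- array(FALSE, d)
  m[2:3, 2:3, 2:3] <- TRUE                         # 8 voxels ~ 0.015 um^3
  m[10:17, 10:17, 10:17] <- TRUE                   # 512 voxels ~ 0.97 um^3
  lab <- nucorg3d:::label_above_min(m, sp0, 0.123)
  expect_equal(max(lab), 1L)
  expect_false(any(lab[2:3, 2:3, 2:3] > 0))
})

test_that("erosion-split separates a dumbbell into its two lobes", {
  sp <- sp0
  d <- c(50L, 30L, 30L)
  r_lobe <- 0.66  # each lobe ~ 1.2 um^3
  m <- ball_mask(d, sp, r_lobe, center = c(1.8, 1.8, 1.8)) |
    ball_mask(d, sp, r_lobe, center = c(4.0, 1.8, 1.8))
  iy <- round(1.8 / sp[1]) + 1
  m[(round(1.8 / sp[1]) + 1):(round(4.0 / sp[1]) + 1), iy, iy] <- TRUE  # thin neck
  lab <- array(as.integer(m), d)
  expect_gt(sum(m) * prod(sp), 1.90)
  out <- nucorg3d:::apply_spot_selection(lab, sp, signal_seg_config())
  expect_equal(max(out), 2L)
  # both pieces keep roughly a lobe's volume
  cnt <- nucorg3d:::label_counts(out) * prod(sp)
  expect_true(all(cnt > 0.8 & cnt < 1.7))
})

test_that("a lone ball above the split volume survives the split attempt intact", {
  sp <- sp0
  d <- rep(30L, 3)
  m <- ball_mask(d, sp, 0.85)   # ~ 2.6 um^3 > 1.90
  lab <- array(as.integer(m), d)
  out <- nucorg3d:::apply_spot_selection(lab, sp, signal_seg_config())
  expect_equal(max(out), 1L)
  expect_equal(sum(out > 0), sum(m))
})

test_that("flat objects are removed only when smaller than 1 um^3", {
  sp <- sp0
  d <- c(40L, 40L, 20L)
  plate_small <- array(0L, d); plate_small[2:15, 2:15, 3:4] <- 1L  # ~0.74 um^3, flatness 7
  out <- nucorg3d:::apply_spot_selection(plate_small, sp, signal_seg_config())
  expect_equal(max(out), 0L)

  plate_big <- array(0L, d); plate_big[2:31, 2:31, 3:5] <- 1L     # ~5 um^3, same shape
  out2 <- nucorg3d:::apply_spot_selection(plate_big, sp,
                                          signal_seg_config(split_volume = 50))
  expect_equal(max(out2), 1L)
})

test_that("above 40 objects, spots below 1% of the total spot volume are dropped", {
  sp <- sp0
  d <- c(140L, 140L, 12L)
  lab <- array(0L, d)
  k <- 0L
  for (i in 0:6) for (j in 0:6) {   # 49 objects on a grid
    k <- k + 1L
    y <- 4 + i * 19; x <- 4 + j * 19
    if (k <= 44) lab[y:(y + 6), x:(x + 6), 4:9] <- k       # 294 vox each
    else lab[y, x, 4:5] <- k                               # 2 vox each (< 1%)
  }
  cfg <- signal_seg_config(split_volume = 1e6, flatness_max = 1e6)
  out <- nucorg3d:::apply_spot_selection(lab, sp, cfg)
  expect_equal(max(out), 44L)
  # but with at most 40 objects the small ones are kept
  lab45 <- lab; lab45[lab45 > 40L] <- 0L
  lab45[lab45 > 36L] <- 0L  # 36 large objects only: under the guard
  out2 <- nucorg3d:::apply_spot_selection(lab45, sp, cfg)
  expect_equal(max(out2), 36L)
})

test_that("pericentromere segmentation is invariant to a constant intensity offset", {
  set.seed(31)
  sp <- rep(0.2, 3)
  d <- rep(40L, 3)
  img <- array(rnorm(prod(d), 20, 1), d)
  for (ctr in list(c(3, 3, 3), c(5.5, 5.5, 5.5))) {
    q <- nucorg3d:::add_spot(array(0, d), sp, ctr, 0.8, 120)
    img <- img + q
  }
  roi <- roi_from_mask(array(TRUE, d), sp)
  a <- segment_pericentromeres(image_stack(img, sp), roi)
  b <- segment_pericentromeres(image_stack(img + 57, sp), roi)
  expect_identical(a$labels, b$labels)
  expect_equal(max(a$labels), 2L)
})

test_that("signals outside the nucleus ROI are rejected", {
  set.seed(32)
  sp <- rep(0.2, 3)
  d <- rep(40L, 3)
  img <- array(rnorm(prod(d), 20, 1), d)
  img <- nucorg3d:::add_spot(img, sp, c(2, 2, 2), 0.8, 120)    # outside ROI
  img <- nucorg3d:::add_spot(img, sp, c(5.5, 5.5, 5.5), 0.8, 120)  # inside
  roi_mask <- ball_mask(d, sp, 2.2, center = c(5.5, 5.5, 5.5))
  roi <- roi_from_mask(roi_mask, sp)
  lm <- segment_pericentromeres(image_stack(img, sp), roi)
  expect_equal(max(lm$labels), 1L)
  expect_true(all(roi_mask[lm$labels > 0]))
})
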