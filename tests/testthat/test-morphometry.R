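sp0 <- rep(0.1236, 3)

test_that("equivalent sphere surface matches the closed form", {
  expect_equal(equivalent_sphere_surface(4 / 3 * pi), 4 * pi)
  expect_equal(equivalent_sphere_surface(0.123), 1.1961, tolerance = 1e-3)
  expect_error(equivalent_sphere_surface(0), "positive")
  expect_error(equivalent_sphere_surface(-1), "positive")
})

test_that("volumes are exact and sphericity is calibrated on canonical solids", {
  # digital ball, radius 10 voxels
  d <- rep(31L, 3)
  ball <- ball_mask(d, sp0, 10 * sp0[1])
  s <- shape_stats(label_map(array(as.integer(ball), d), sp0))
  expect_equal(s$volume_um3, sum(ball) * prod(sp0))
  expect_gte(s$sphericity, 0.95)
  expect_lt(s$flatness, 1.05)

  # 40 x 2 x 2 voxel rod: elongation from closed-form box moments
  rod <- array(0L, c(46L, 8L, 8L)); rod[4:43, 4:5, 4:5] <- 1L
  sr <- shape_stats(label_map(rod, sp0))
  expect_gte(sr$elongation, 10)
  expect_lt(abs(sr$flatness - 1), 0.05)

  # single voxel: degenerate axes handled
  sv <- array(0L, rep(5L, 3)); sv[3, 3, 3] <- 1L
  ss <- shape_stats(label_map(sv, sp0))
  expect_equal(ss$flatness, 1, tolerance = 1e-6)
  expect_equal(ss$elongation, 1, tolerance = 1e-6)
  expect_gt(ss$sphericity, 0)
  expect_lte(ss$sphericity, 1.1)
})

test_that("sphericity is scale-invariant within digitization tolerance", {
  d1 <- rep(41L, 3)
  s1 <- shape_stats(label_map(array(as.integer(ball_mask(d1, sp0, 14 * sp0[1])), d1), sp0))
  sp2 <- 2 * sp0
  d2 <- rep(21L, 3)
  s2 <- shape_stats(label_map(array(as.integer(ball_mask(d2, sp2, 14 * sp0[1])), d2), sp2))
  expect_lt(abs(s1$sphericity - s2$sphericity) / s1$sphericity, 0.02)
})

test_that("pericentromere classification follows the volume and roundness rules", {
  shapes <- tibble::tibble(
    label = 1:4,
    volume_um3 = c(0.30, 1.0, 1.0, 0.46),
    sphericity = c(0.95, 0.85, 0.30, 0.9))
  cl <- classify_pericentromere(shapes)
  expect_equal(as.character(cl$class),
               c("not_analyzed", "compact", "elongated", "not_analyzed"))
  # boundary: sphericity exactly 0.8 is elongated (strictly greater is compact)
  cl2 <- classify_pericentromere(tibble::tibble(volume_um3 = 1, sphericity = 0.8))
  expect_equal(as.character(cl2$class), "elongated")
})

test_that("separated objects score Null; a hugging shell scores Strong", {
  sp <- rep(0.2, 3)
  d <- c(60L, 40L, 40L)
  ctr <- c(4, 4, 4)
  npb <- array(0L, d); npb[ball_mask(d, sp, 2.0, center = ctr)] <- 1L

  # far-away compact signal -> Null
  sig <- array(0L, d); sig[ball_mask(d, sp, 0.5, center = c(10, 4, 4))] <- 1L
  res <- score_interactions(label_map(sig, sp), label_map(npb, sp))
  expect_equal(as.character(res$category), "Null")
  expect_true(is.na(res$npb))

  # hemispherical shell hugging the NPB -> contact area above equal-volume
  # sphere surface -> Strong
  shell_full <- ball_mask(d, sp, 2.45, center = ctr) &
    !ball_mask(d, sp, 2.05, center = ctr)
  ygrid <- (seq_len(d[1]) - 1) * sp[1]
  hemi <- array(rep(ygrid >= ctr[1], times = d[2] * d[3]), d)
  sig2 <- array(0L, d); sig2[shell_full & hemi] <- 1L
  res2 <- score_interactions(label_map(sig2, sp), label_map(npb, sp))
  expect_equal(as.character(res2$category), "Strong")
  expect_gt(res2$ratio, 1)
  expect_gt(res2$interaction_volume_um3, 0)
})

test_that("a barely tangent spot scores Close", {
  sp <- rep(0.2, 3)
  d <- c(60L, 40L, 40L)
  ctr <- c(4, 4, 4)
  npb <- array(0L, d); npb[ball_mask(d, sp, 2.0, center = ctr)] <- 1L
  # spot centre placed so only a voxel column touches the dilated halo
  sig <- array(0L, d); sig[ball_mask(d, sp, 0.6, center = c(7.0, 4, 4))] <- 1L
  res <- score_interactions(label_map(sig, sp), label_map(npb, sp),
                            dilation_um = 0.4)
  expect_equal(nrow(res), 1L)
  expect_true(as.character(res$category) %in% c("Close", "Low"))
  expect_lte(res$ratio, 0.5)
})

test_that("interaction categories are monotone in the ratio", {
  set.seed(51)
  sp <- rep(0.2, 3)
  d <- c(70L, 40L, 40L)
  npb <- array(0L, d); npb[ball_mask(d, sp, 2.2, center = c(5, 4, 4))] <- 1L
  sig <- array(0L, d)
  # signals at graded distances from the NPB produce graded ratios
  centers <- list(c(8.2, 4, 4), c(7.6, 4, 4), c(7.2, 5.5, 4), c(5, 4, 7.4))
  for (i in seq_along(centers))
    sig[ball_mask(d, sp, 0.55, center = centers[[i]]) & npb == 0L] <- i
  res <- score_interactions(label_map(sig, sp), label_map(npb, sp))
  res <- res[!is.na(res$npb), ]
  lv <- c("Close", "Low", "Medium", "Strong")
  ord <- order(res$ratio)
  ranks <- match(as.character(res$category[ord]), lv)
  expect_true(all(diff(ranks) >= 0))
})

test_that("mismatched grids are a fatal error", {
  a <- label_map(array(0L, c(5L, 5L, 5L)), rep(0.2, 3))
  b <- label_map(array(0L, c(6L, 5L, 5L)), rep(0.2, 3))
  expect_error(score_interactions(a, b), "share one voxel grid")
})
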