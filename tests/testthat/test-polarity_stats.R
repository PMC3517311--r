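test_that("moment normalization equalizes the principal moments", {
  sp <- rep(0.25, 3)
  d <- rep(40L, 3)
  # sphere: the map is (nearly) rigid
  sph <- ball_mask(d, sp, 3.5)
  n1 <- moment_normalize(sph, spacing = sp)
  expect_lt(max(n1$scales) / min(n1$scales) - 1, 0.01)

  # 2:1 prolate ellipsoid: normalized second moments equal within 2%
  ctr <- (d - 1) / 2 * sp
  ell <- nucorg3d:::rasterize_ellipsoid(d, sp, ctr, c(4.2, 2.1, 2.1))
  n2 <- moment_normalize(ell, spacing = sp)
  mom <- eigen(crossprod(sweep(n2$coords, 2, colMeans(n2$coords))) /
                 nrow(n2$coords), symmetric = TRUE)$values
  expect_lt(max(mom) / min(mom) - 1, 0.02)
  # the map preserves volume, so r_eq matches the voxel-count volume
  expect_equal(n2$r_eq, (3 * sum(ell) * prod(sp) / (4 * pi))^(1 / 3))

  # a point at the mask centroid maps to the origin
  cen_pt <- matrix(colMeans(nucorg3d:::mask_coords(ell, sp)), 1)
  n3 <- moment_normalize(ell, points = cen_pt, spacing = sp)
  expect_lt(sqrt(sum(n3$points^2)), 1e-6)
})

test_that("degenerate planar masks are rejected", {
  d <- c(20L, 20L, 5L)
  m <- array(FALSE, d); m[3:18, 3:18, 3] <- TRUE
  expect_error(moment_normalize(m, spacing = rep(0.25, 3)), "degenerate")
})

test_that("polarity index is 0 at the centre and ~1 at the boundary of a sphere", {
  sp <- rep(0.25, 3)
  d <- rep(41L, 3)
  m <- ball_mask(d, sp, 4.0)
  ctr <- (d - 1) / 2 * sp
  n <- moment_normalize(m, points = matrix(ctr, 1), spacing = sp)
  expect_lt(polarity_index(n), 1e-6)

  n2 <- moment_normalize(m, points = matrix(ctr + c(3.9, 0, 0), 1), spacing = sp)
  expect_equal(polarity_index(n2), 1, tolerance = 0.05)
})

test_that("the mean of many uniform points is close to the centre", {
  sp <- rep(0.3, 3)
  d <- rep(31L, 3)
  m <- ball_mask(d, sp, 4.0)
  vox <- nucorg3d:::mask_coords(m, sp)
  set.seed(61)
  small <- vapply(1:20, function(i) {
    pts <- vox[sample.int(nrow(vox), 1000, replace = TRUE), ]
    polarity_index(moment_normalize(m, points = pts, spacing = sp))
  }, numeric(1))
  expect_gte(mean(small < 0.05), 0.95)
})

test_that("permutation p-values follow the proportion definition", {
  sp <- rep(0.3, 3)
  d <- rep(31L, 3)
  m <- ball_mask(d, sp, 4.0)
  ctr <- (d - 1) / 2 * sp

  # all points clustered at the boundary: d exceeds every null distance
  pole <- matrix(rep(ctr + c(3.7, 0, 0), each = 6), 6)
  r1 <- polarity_test(m, pole, sp, n_patterns = 300, seed = 5)
  expect_equal(r1$p_value, 0)

  # a single point at the centroid: d = 0, no null distance is below it
  r2 <- polarity_test(m, matrix(ctr, 1), sp, n_patterns = 300, seed = 5)
  expect_equal(r2$p_value, 1)

  # fixed seed -> identical result; warning for coarse resolution
  r3 <- polarity_test(m, pole, sp, n_patterns = 300, seed = 5)
  expect_identical(r1$null_d, r3$null_d)
  expect_warning(polarity_test(m, pole, sp, n_patterns = 50, seed = 1),
                 "coarse")
})

test_that("the polarity index is invariant to rigid motions of the scene", {
  sp <- rep(0.25, 3)
  d <- rep(37L, 3)
  ell <- nucorg3d:::rasterize_ellipsoid(d, sp, (d - 1) / 2 * sp, c(3.8, 2.6, 2.2))
  coords <- nucorg3d:::mask_coords(ell, sp)
  set.seed(62)
  pts <- coords[sample.int(nrow(coords), 15), ]
  vol <- nrow(coords) * prod(sp)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  d0 <- polarity_index(moment_normalize(coords, points = pts), r_eq = r_eq)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- matrix(c(cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1]), 0, 0, 0, 1), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2])), 3)
    R <- Rz %*% Rx
    shift <- runif(3, -5, 5)
    di <- polarity_index(
      moment_normalize(sweep(coords %*% R, 2, shift, `+`),
                       points = sweep(pts %*% R, 2, shift, `+`)),
      r_eq = r_eq)
    expect_equal(di, d0, tolerance = 1e-6)
  }
})

test_that("population uniformity test behaves at both extremes", {
  grid <- (1:100 - 0.5) / 100
  res <- population_uniformity_test(grid)
  expect_false(res$rejected)

  res0 <- population_uniformity_test(rep(0, 30))
  expect_true(res0$rejected)

  expect_error(population_uniformity_test(c(0.1, 0.5, 0.9)), "at least 5")
})

test_that("tidy and glance summarise a polarity result", {
  sp <- rep(0.3, 3)
  m <- ball_mask(rep(25L, 3), sp, 3.0)
  pts <- matrix(rep((25 - 1) / 2 * sp, each = 4), 4)
  r <- polarity_test(m, pts, sp, n_patterns = 200, seed = 9, nucleus_id = 7L)
  td <- tidy(r)
  expect_named(td, c("nucleus_id", "n_centromeres", "d", "p_value", "n_patterns"))
  expect_equal(td$nucleus_id, 7L)
  gl <- glance(r)
  expect_true(all(c("d", "p_value", "null_median", "null_q99") %in% names(gl)))
})
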