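sp0 <- rep(0.1236, 3)

# A synthetic DNA crop: bright nucleus ball with dark spherical voids.
make_dna_fixture <- function(d, sp, nucleus_r, voids, noise_sd = 2, seed = 1) {
  set.seed(seed)
  ctr <- (d - 1) / 2 * sp
  nuc <- ball_mask(d, sp, nucleus_r, center = ctr)
  img <- array(10, d)
  img[nuc] <- 120
  for (v in voids) {
    hole <- ball_mask(d, sp, v$r, center = v$center)
    img[hole] <- 12
  }
  img <- nucorg3d:::gaussian_blur(img, 0.2 / sp)
  img <- img + array(rnorm(prod(d), 0, noise_sd), d)
  list(crop = image_stack(img, sp), mask = nuc,
       roi = roi_from_mask(nuc, sp))
}

test_that("dark spherical voids are recovered with majority overlap", {
  sp <- rep(0.2, 3)
  d <- rep(56L, 3)
  ctr <- (d - 1) / 2 * sp
  voids <- list(list(center = ctr + c(-2.2, 0, 0), r = 1.3),
                list(center = ctr + c(2.0, 1.2, 0), r = 1.1),
                list(center = ctr + c(0, -1.5, 2.0), r = 1.0))
  fx <- make_dna_fixture(d, sp, 4.8, voids, seed = 41)
  lm <- segment_npbs(fx$crop, fx$roi)
  expect_equal(max(lm$labels), 3L)
  for (v in voids) {
    truth <- ball_mask(d, sp, v$r, center = v$center)
    got <- lm$labels > 0 & truth
    expect_gt(sum(got) / sum(truth), 0.5)
  }
})

test_that("dark objects below 0.23 um^3 are removed", {
  sp <- rep(0.2, 3)
  d <- rep(40L, 3)
  ctr <- (d - 1) / 2 * sp
  # tiny void: even after PSF inflation its detected dark extent stays
  # below the 0.23 um^3 minimum
  fx <- make_dna_fixture(d, sp, 3.4, list(list(center = ctr, r = 0.2)),
                         noise_sd = 1, seed = 42)
  lm <- segment_npbs(fx$crop, fx$roi)
  expect_equal(max(lm$labels), 0L)
})

test_that("a dark band hugging the nuclear rim is removed by contour subtraction", {
  sp <- rep(0.2, 3)
  d <- rep(50L, 3)
  ctr <- (d - 1) / 2 * sp
  nuc <- ball_mask(d, sp, 4.4, center = ctr)
  img <- array(10, d)
  img[nuc] <- 120
  # dark shell just inside the nuclear boundary
  rim <- nuc & !ball_mask(d, sp, 3.9, center = ctr)
  img[rim] <- 15
  img <- nucorg3d:::gaussian_blur(img, 0.2 / sp)
  img <- img + array(rnorm(prod(d), 0, 1), d)
  lm <- segment_npbs(image_stack(img, sp), roi_from_mask(nuc, sp))
  expect_equal(max(lm$labels), 0L)
})

test_that("refinement removes small low-sphericity objects and splits fused pairs", {
  sp <- rep(0.2, 3)
  d <- c(60L, 60L, 40L)
  lab <- array(0L, d)
  # crescent-like flat sliver: low sphericity, volume ~10 um^3
  lab[5:44, 5:20, 5:6] <- 1L
  lm <- refine_npbs(label_map(lab, sp))
  expect_equal(max(lm$labels), 0L)

  # two barely overlapping balls, total > 94.5 um^3, split back into two
  r <- 2.35  # each ~54 um^3
  pair <- ball_mask(d, sp, r, center = c(5.2, 6, 4)) |
    ball_mask(d, sp, r, center = c(9.75, 6, 4))
  lab2 <- array(as.integer(pair), d)
  expect_gt(sum(pair) * prod(sp), 94.5)
  lm2 <- refine_npbs(label_map(lab2, sp))
  expect_equal(max(lm2$labels), 2L)

  # a lone ball above the split volume stays one object
  lone <- ball_mask(d, sp, 2.85, center = c(6, 6, 4))  # ~97 um^3
  lm3 <- refine_npbs(label_map(array(as.integer(lone), d), sp))
  expect_equal(max(lm3$labels), 1L)
})

test_that("refinement never increases labelled volume except via split dilation", {
  sp <- rep(0.2, 3)
  d <- c(40L, 40L, 40L)
  set.seed(43)
  lab <- array(0L, d)
  lab[ball_mask(d, sp, 1.6, center = c(3, 3, 3))] <- 1L
  lab[ball_mask(d, sp, 1.2, center = c(6, 5, 4))] <- 2L
  lm <- refine_npbs(label_map(lab, sp))
  expect_lte(sum(lm$labels > 0), sum(lab > 0))
})

test_that("edit lists add rasterized ellipsoids and remove labels, in order", {
  sp <- rep(0.2, 3)
  d <- rep(30L, 3)
  lab <- array(0L, d)
  lab[ball_mask(d, sp, 1.0, center = c(1.6, 1.6, 1.6))] <- 1L
  lm <- label_map(lab, sp)

  out <- apply_edits(lm, edit_list(
    edit_remove(1),
    edit_add(centroid = c(3.5, 3.5, 3.5), semiaxes = c(1, 1, 1))
  ))
  expect_equal(max(out$labels), 1L)
  vol <- sum(out$labels > 0) * prod(sp)
  expect_lt(abs(vol - 4 / 3 * pi) / (4 / 3 * pi), 0.1)
  log <- attr(out, "edit_log")
  expect_equal(log$op, c("remove", "add"))

  expect_error(apply_edits(lm, edit_list(edit_remove(3))), "not present")
  expect_error(apply_edits(lm, edit_list(
    edit_add(centroid = c(1.6, 1.6, 1.6), semiaxes = c(0.5, 0.5, 0.5)))),
    "collides")
  expect_identical(apply_edits(lm, edit_list())$labels, lm$labels)
})

test_that("edit lists survive a JSON round trip", {
  e <- edit_list(edit_remove(2),
                 edit_add(centroid = c(1, 2, 3), semiaxes = c(0.5, 0.6, 0.7)))
  path <- tempfile(fileext = ".json")
  write_edit_list(e, path)
  got <- read_edit_list(path)
  expect_equal(length(got), 2L)
  expect_equal(got[[1]]$op, "remove")
  expect_equal(got[[2]]$centroid, c(1, 2, 3))
  expect_equal(got[[2]]$semiaxes, c(0.5, 0.6, 0.7))
})
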