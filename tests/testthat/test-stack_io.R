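test_that("multichannel TIFF round trip preserves intensities, spacing and roles", {
  d <- c(24L, 20L, 8L)
  sp <- c(0.1236, 0.1236, 0.371)
  set.seed(42)
  a <- array(sample(0:255, prod(d), replace = TRUE), d)
  b <- array(sample(0:255, prod(d), replace = TRUE), d)
  path <- tempfile(fileext = ".tif")
  write_stack(list(image_stack(a, sp, "dna"), image_stack(b, sp, "centromere")),
              path)
  got <- read_stack(path, channel_map(dna = 1, centromere = 2))
  expect_named(got, c("dna", "centromere"))
  expect_equal(got$dna$voxels, a, ignore_attr = TRUE)
  expect_equal(got$centromere$voxels, b, ignore_attr = TRUE)
  expect_equal(got$dna$spacing, sp, tolerance = 1e-6)
  expect_equal(got$dna$channel, "dna")

  # spacing override takes precedence over metadata
  ov <- read_stack(path, channel_map(dna = 1, centromere = 2),
                   spacing_override = c(0.2, 0.2, 0.2))
  expect_equal(ov$dna$spacing, c(0.2, 0.2, 0.2))

  # channel count mismatch is fatal
  expect_error(read_stack(path, channel_map(dna = 1, centromere = 2, rdna = 3)),
               "not a multiple|addresses channel")
})

test_that("label map TIFF round trip is bit-exact, including all-zero maps", {
  d <- c(15L, 17L, 6L)
  sp <- rep(0.1236, 3)
  set.seed(7)
  lab <- array(sample(0:5, prod(d), replace = TRUE), d)
  path <- tempfile(fileext = ".tif")
  write_label_map(label_map(lab, sp), path)
  got <- read_label_map(path)
  expect_identical(got$labels, array(as.integer(lab), d))
  expect_equal(got$spacing, sp, tolerance = 1e-6)

  path2 <- tempfile(fileext = ".tif")
  write_label_map(label_map(array(0L, d), sp), path2)
  expect_identical(max(read_label_map(path2)$labels), 0L)
})

test_that("isotropic resampling triples the z-plane count at the nominal geometry", {
  d <- c(10L, 12L, 16L)
  sp <- c(0.1236, 0.1236, 0.371)
  s <- image_stack(array(runif(prod(d)), d), sp)
  r <- resample_isotropic(s)
  expect_equal(dim(r$voxels)[3], round(16 * 0.371 / 0.1236))  # = 48
  expect_equal(r$spacing, rep(0.1236, 3))
  expect_equal(dim(r$voxels)[1:2], d[1:2])
})

test_that("resampling is a no-op on isotropic input and preserves constants", {
  d <- c(8L, 8L, 8L)
  iso <- image_stack(array(runif(prod(d)), d), rep(0.2, 3))
  expect_identical(resample_isotropic(iso), iso)

  const <- image_stack(array(5, c(6L, 6L, 10L)), c(0.1, 0.1, 0.3))
  r <- resample_isotropic(const)
  expect_true(all(abs(r$voxels - 5) < 1e-12))
})

test_that("resampling preserves total intensity of smooth images within 1%", {
  d <- c(30L, 30L, 14L)
  sp <- c(0.1236, 0.1236, 0.371)
  ctr <- (d - 1) / 2 * sp
  img <- array(0, d)
  for (k in seq_len(d[3])) {
    z2 <- ((k - 1) * sp[3] - ctr[3])^2
    img[, , k] <- outer(
      ((seq_len(d[1]) - 1) * sp[1] - ctr[1])^2,
      ((seq_len(d[2]) - 1) * sp[2] - ctr[2])^2, `+`)
    img[, , k] <- 100 * exp(-(img[, , k] + z2) / (2 * 0.8^2))
  }
  s <- image_stack(img, sp)
  r <- resample_isotropic(s)
  tot_in <- sum(s$voxels) * prod(s$spacing)
  tot_out <- sum(r$voxels) * prod(r$spacing)
  expect_lt(abs(tot_out - tot_in) / tot_in, 0.01)
})

test_that("nearest-neighbour resampling never blends label values", {
  d <- c(6L, 6L, 9L)
  lab <- array(sample(c(0, 3, 7), prod(d), replace = TRUE), d)
  s <- image_stack(lab, c(0.1, 0.1, 0.3))
  r <- resample_isotropic(s, method = "nearest")
  expect_true(all(r$voxels %in% c(0, 3, 7)))
})

test_that("write_outputs emits label TIFFs, CSV tables and a manifest", {
  d <- c(8L, 8L, 4L)
  sp <- rep(0.2, 3)
  lm <- label_map(array(rep(c(0L, 2L), length.out = prod(d)), d), sp)
  out <- file.path(tempdir(), "wo_test")
  man <- write_outputs(list(nuclei = lm),
                       list(objects = data.frame(label = 1:2, v = c(1, 2))),
                       out, config = list(a = 1))
  expect_true(file.exists(file.path(out, "nuclei.tif")))
  expect_true(file.exists(file.path(out, "objects.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_setequal(man$files, c("nuclei.tif", "objects.csv"))
  got <- read_label_map(file.path(out, "nuclei.tif"))
  expect_identical(got$labels, lm$labels)

  blocker <- tempfile()
  writeLines("x", blocker)
  expect_error(write_outputs(list(), list(), file.path(blocker, "sub")),
               "not writable")
})
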