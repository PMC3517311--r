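test_that("truth inventory counts match the requested object numbers", {
  spec <- small_phantom_spec(seed = 3, n_npbs = 5, n_chromosomes = 6)
  ph <- generate_phantom(spec)
  inv <- ph$truth$inventory
  expect_equal(sum(inv$channel == "npb"), 5)
  expect_equal(sum(inv$channel == "centromere"), 6)
  expect_equal(sum(inv$channel == "telomere"), 12)  # 2 per telocentric chromosome
  expect_equal(sum(inv$channel == "pericentromere"), 6)
  # inventory rows agree with the label maps, class by class
  for (ch in c("npb", "centromere", "telomere", "pericentromere"))
    expect_equal(max(ph$truth$labels[[ch]]$labels), sum(inv$channel == ch))
})

test_that("a haploid mouse karyotype yields 20 centromeric and 40 telomeric marks", {
  spec <- phantom_spec(nucleus_semiaxes = c(6.2, 6.0, 5.8),
                       n_npbs = 2, npb_radius_range = c(1.0, 1.5),
                       n_chromosomes = 20,
                       motif_weights = c(chromocenter = 0.8, filament = 0.2),
                       spot_min_sep = 1.4, spacing = 0.25, seed = 5)
  ph <- generate_phantom(spec, render = FALSE)
  inv <- ph$truth$inventory
  expect_equal(sum(inv$channel == "centromere"), 20)
  expect_equal(sum(inv$channel == "telomere"), 40)
})

test_that("identical specs give bit-identical phantoms and leave the RNG alone", {
  spec <- small_phantom_spec(seed = 9, n_chromosomes = 3, n_npbs = 2)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$stacks$dna$voxels, b$stacks$dna$voxels)
  expect_identical(a$stacks$centromere$voxels, b$stacks$centromere$voxels)
  expect_identical(a$truth$inventory, b$truth$inventory)
  expect_equal(runif(1), before)  # caller RNG state restored
})

test_that("unknown stage and impossible placements raise informative errors", {
  expect_error(phantom_presets("16cell"), "valid stages")
  cramped <- phantom_spec(nucleus_semiaxes = c(2.2, 2.2, 2.2),
                          n_npbs = 3, npb_radius_range = c(1.9, 2.0),
                          n_chromosomes = 0, spacing = 0.3, seed = 1)
  expect_error(generate_phantom(cramped, render = FALSE), "NPB #")
})

test_that("stage presets draw NPB counts inside the published ranges", {
  n_late2 <- replicate(20, phantom_presets("2cell_late")$n_npbs)
  expect_true(all(n_late2 >= 8 & n_late2 <= 12))
  n_4c <- replicate(20, phantom_presets("4cell")$n_npbs)
  expect_true(all(n_4c >= 1 & n_4c <= 5))
  expect_equal(phantom_presets("haploid_pn")$n_chromosomes, 20)
})

test_that("rendering is conservative: signal objects are brighter than background", {
  spec <- small_phantom_spec(seed = 4, n_chromosomes = 4, n_npbs = 2,
                             poisson_gain = 0, gaussian_sd = 0)
  ph <- generate_phantom(spec)
  inv <- ph$truth$inventory
  for (ch in c("centromere", "telomere", "pericentromere")) {
    lm <- ph$truth$labels[[ch]]$labels
    img <- ph$stacks[[ch]]$voxels
    for (l in seq_len(max(lm))) {
      mean_in <- mean(img[lm == l])
      expect_gt(mean_in, spec$background)
    }
  }
  # NPBs are voids: darker inside than the surrounding nucleoplasm
  npb <- ph$truth$labels$npb$labels
  nuc <- ph$truth$labels$dna$labels > 0 & npb == 0
  expect_lt(mean(ph$stacks$dna$voxels[npb > 0]), mean(ph$stacks$dna$voxels[nuc]))
})

test_that("all truth geometry lies inside the nucleus ellipsoid", {
  spec <- small_phantom_spec(seed = 8, n_chromosomes = 5, n_npbs = 3,
                             motif_weights = c(chromocenter = 0.4, filament = 0.3,
                                               peripheral = 0.3))
  ph <- generate_phantom(spec, render = FALSE)
  nuc <- ph$truth$labels$dna$labels > 0
  for (ch in c("npb", "centromere", "telomere", "pericentromere")) {
    obj <- ph$truth$labels[[ch]]$labels > 0
    expect_true(all(nuc[obj]), label = paste(ch, "inside nucleus"))
  }
})

test_that("strong polarity shifts the centromere pattern off-centre", {
  # with rho = 1 the polarity index exceeds the 99th percentile of the
  # uniform null in nearly all phantoms
  # point-process mode: the property concerns placement statistics, and
  # with repulsive packing the polarity index is attenuated
  hits <- 0L
  for (s in 1:10) {
    spec <- small_phantom_spec(seed = 100 + s, n_chromosomes = 12, n_npbs = 0,
                               rho = 1, spot_min_sep = 0)
    ph <- generate_phantom(spec, render = FALSE)
    inv <- ph$truth$inventory
    pts <- as.matrix(inv[inv$channel == "centromere", c("cy", "cx", "cz")])
    mask <- ph$truth$labels$dna$labels == 1L
    res <- polarity_test(mask, pts, rep(spec$spacing, 3),
                         n_patterns = 200, seed = s)
    if (res$d > stats::quantile(res$null_d, 0.99)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
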