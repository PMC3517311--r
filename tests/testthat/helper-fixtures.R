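# Fixtures are built in code at test time; physical units are um.

# A nucleus_roi wrapping an arbitrary mask (bbox = full grid), for testing
# segmentation operations without running nucleus extraction.
roi_from_mask <- function(mask, spacing) {
  structure(list(
    label = 1L, mask = mask,
    bbox = list(lo = c(1L, 1L, 1L), hi = dim(mask)),
    spacing = as.double(spacing),
    volume_um3 = sum(mask) * prod(spacing),
    channels = list()
  ), class = "nucleus_roi")
}

# Logical ball mask centred in an array of the given dims.
ball_mask <- function(dims, spacing, radius, center = NULL) {
  center <- center %||% ((dims - 1) / 2 * spacing)
  y <- ((seq_len(dims[1]) - 1) * spacing[1] - center[1])^2
  x <- ((seq_len(dims[2]) - 1) * spacing[2] - center[2])^2
  z <- ((seq_len(dims[3]) - 1) * spacing[3] - center[3])^2
  o <- outer(y, x, `+`)
  out <- array(FALSE, dims)
  for (k in seq_len(dims[3])) out[, , k] <- o + z[k] <= radius^2
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, quick phantom spec used by several integration tests: modest
# nucleus, coarse grid, chromocenter-dominated heterochromatin.
small_phantom_spec <- function(seed = 1, ...) {
  args <- list(
    nucleus_semiaxes = c(4.6, 4.4, 4.2),
    n_npbs = 3, npb_radius_range = c(0.9, 1.4),
    n_chromosomes = 6,
    motif_weights = c(chromocenter = 1),
    spot_min_sep = 1.6,
    spacing = 0.2, margin = 1.0,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(phantom_spec, args)
}

# Memoised haploid-pronucleus phantom run shared by the acceptance tests
# (generation plus nucleus extraction take minutes at full scale).
haploid_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- phantom_presets("haploid_pn", seed = 1)
    spec$poisson_gain <- 0
    spec$gaussian_sd <- 0
    ph <- generate_phantom(spec)
    bg <- suppressWarnings(estimate_background(ph$stacks$dna))
    mask <- suppressWarnings(nucleus_mask(ph$stacks$dna, bg))
    rois <- suppressWarnings(extract_nuclei(mask, ph$stacks$dna$spacing))
    roi <- crop_channels(rois[[1]], ph$stacks)
    cache <<- list(phantom = ph, roi = roi, spec = spec)
    cache
  }
})
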