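# Internal geometry and array helpers. All arrays are column-major with
# dim = (ny, nx, nz); physical coordinates are voxel centres at
# (index - 1) * spacing, in micrometres.

`%||%` <- function(a, b) if (is.null(a)) b else a

dim3 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  as.integer(d)
}

#' @noRd
voxel_volume <- function(spacing) prod(spacing)

# Offsets (dy,dx,dz) of a digital ball of the given voxel radii.
ball_offsets <- function(radius_vox) {
  r <- pmax(radius_vox, 0)
  ri <- floor(r)
  g <- expand.grid(dy = -ri[1]:ri[1], dx = -ri[2]:ri[2], dz = -ri[3]:ri[3])
  sel <- (g$dy / max(r[1], 1e-9))^2 + (g$dx / max(r[2], 1e-9))^2 +
    (g$dz / max(r[3], 1e-9))^2 <= 1 + 1e-9
  as.matrix(g[sel, , drop = FALSE])
}

# Run a ball-element operation on the mask's bounding box (padded so that
# border effects cannot reach the mask) and write the result back; outside
# the box everything stays background.
ball_op_cropped <- function(mask, radius_vox, op) {
  d <- dim3(mask)
  if (!any(mask)) return(array(FALSE, d))
  bb <- mask_bbox(mask, margin = as.integer(2L * max(ceiling(radius_vox)) + 1L))
  sub <- crop_array(mask, bb)
  res <- op(sub)
  out <- array(FALSE, d)
  uncrop_assign(out, res, bb)
}

open_ball <- function(mask, radius_vox) {
  off <- ball_offsets(radius_vox)
  ball_op_cropped(mask, radius_vox, function(sub) {
    ds <- dim3(sub)
    er <- offset_morph(as.logical(sub), ds, off, dilate = FALSE)
    array(offset_morph(er, ds, off, dilate = TRUE), ds)
  })
}

close_ball <- function(mask, radius_vox) {
  off <- ball_offsets(radius_vox)
  ball_op_cropped(mask, radius_vox, function(sub) {
    ds <- dim3(sub)
    di <- offset_morph(as.logical(sub), ds, off, dilate = TRUE)
    array(offset_morph(di, ds, off, dilate = FALSE), ds)
  })
}

dilate_ball <- function(mask, radius_vox) {
  off <- ball_offsets(radius_vox)
  ball_op_cropped(mask, radius_vox, function(sub) {
    ds <- dim3(sub)
    array(offset_morph(as.logical(sub), ds, off, dilate = TRUE), ds)
  })
}

erode_ball <- function(mask, radius_vox) {
  off <- ball_offsets(radius_vox)
  ball_op_cropped(mask, radius_vox, function(sub) {
    ds <- dim3(sub)
    array(offset_morph(as.logical(sub), ds, off, dilate = FALSE), ds)
  })
}

# Grayscale opening by a centred box with half-widths radius_vox (ry, rx, rz).
box_opening <- function(img, radius_vox) {
  d <- dim3(img)
  er <- box_morph(as.double(img), d, as.integer(radius_vox), dilate = FALSE)
  op <- box_morph(er, d, as.integer(radius_vox), dilate = TRUE)
  array(op, d)
}

gaussian_blur <- function(img, sigma_vox) {
  d <- dim3(img)
  array(gauss_blur3(as.double(img), d, as.double(rep(sigma_vox, length.out = 3))), d)
}

# Fill fully enclosed background cavities of a binary mask (6-connected
# background components that do not touch the array border). NPBs appear as
# dark voids inside the nucleus foreground, so the nucleus mask must be
# filled before it can serve as a region of interest.
fill_holes <- function(mask) {
  d <- dim3(mask)
  comp <- array(cc_label3d(!mask, d, 6L), d)
  border <- unique(c(comp[c(1, d[1]), , ], comp[, c(1, d[2]), ], comp[, , c(1, d[3])]))
  border <- border[border > 0L]
  holes <- comp > 0L & !(comp %in% border)
  mask | holes
}

# 26-connected labeling returning an integer array.
label_components <- function(mask, connectivity = 26L) {
  d <- dim3(mask)
  array(cc_label3d(as.logical(mask), d, connectivity), d)
}

# Voxel-centre coordinate matrix (um) of TRUE voxels; columns y, x, z.
mask_coords <- function(mask, spacing) {
  idx <- which(mask)
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("y", "x", "z"))))
  d <- dim3(mask)
  ai <- arrayInd(idx, d)
  sweep(ai - 1, 2, spacing, `*`)
}

# Bounding box of TRUE voxels as half-open index ranges with a margin,
# clipped to the array. Returns list(lo = c(y,x,z), hi = c(y,x,z)) 1-based
# inclusive.
mask_bbox <- function(mask, margin = 0L) {
  idx <- which(mask)
  stopifnot(length(idx) > 0L)
  d <- dim3(mask)
  ai <- arrayInd(idx, d)
  lo <- pmax(apply(ai, 2, min) - margin, 1L)
  hi <- pmin(apply(ai, 2, max) + margin, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_array <- function(x, bbox) {
  x[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3], drop = FALSE]
}

# Insert a subarray back at a bounding box position (in place semantics by
# returning the modified full array).
uncrop_assign <- function(full, sub, bbox) {
  full[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2], bbox$lo[3]:bbox$hi[3]] <- sub
  full
}

# Squared normalized ellipsoid coordinate for every voxel of a grid region.
# center/semiaxes in um, in (y, x, z) order. Returns an array over the region.
ellipsoid_field <- function(dims, spacing, center, semiaxes) {
  y <- ((seq_len(dims[1]) - 1) * spacing[1] - center[1]) / semiaxes[1]
  x <- ((seq_len(dims[2]) - 1) * spacing[2] - center[2]) / semiaxes[2]
  z <- ((seq_len(dims[3]) - 1) * spacing[3] - center[3]) / semiaxes[3]
  o <- outer(y^2, x^2, `+`)
  out <- array(0, dims)
  for (k in seq_len(dims[3])) out[, , k] <- o + z[k]^2
  out
}

# Rasterize an ellipsoid into a logical array (TRUE inside).
rasterize_ellipsoid <- function(dims, spacing, center, semiaxes) {
  lo <- pmax(floor((center - semiaxes) / spacing) + 1 - 1, 1)
  hi <- pmin(ceiling((center + semiaxes) / spacing) + 1 + 1, dims)
  out <- array(FALSE, dims)
  if (any(lo > hi)) return(out)
  sub_dims <- hi - lo + 1
  offset <- (lo - 1) * spacing
  f <- ellipsoid_field(sub_dims, spacing, center - offset, semiaxes)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- f <= 1
  out
}

# Voxel-scale multiplicative texture field (unit sd, zero mean, smoothed
# over ~1 voxel); emulates the internal granularity of hybridization
# signals so that rendered objects are not analytically smooth.
speckle_field <- function(dims, smooth = 1.6) {
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- gaussian_blur(f, rep(smooth, 3))
  f / max(stats::sd(f), 1e-9)
}

# Add a flat-topped spot profile to img around center (um): full intensity
# inside 0.8 r, cosine shoulder to zero at 1.3 r (a probe-filled chromatin
# domain, to be smoothed by the PSF stage). speckle_sd > 0 modulates the
# profile with multiplicative texture.
add_spot <- function(img, spacing, center, r, peak, speckle_sd = 0) {
  dims <- dim3(img)
  rmax <- 1.3 * r
  lo <- pmax(floor((center - rmax) / spacing) + 1, 1)
  hi <- pmin(ceiling((center + rmax) / spacing) + 1, dims)
  if (any(lo > hi)) return(img)
  sub_dims <- hi - lo + 1
  offset <- (lo - 1) * spacing
  q <- sqrt(ellipsoid_field(sub_dims, spacing, center - offset, rep(r, 3)))
  t <- pmin(pmax((q - 0.8) / 0.5, 0), 1)
  prof <- peak * (0.5 + 0.5 * cos(pi * t))
  if (speckle_sd > 0) {
    s <- speckle_field(sub_dims)
    s <- s - mean(s[q <= 1])   # texture must not change the spot's brightness
    prof <- prof * pmax(1 + speckle_sd * s, 0.2)
  }
  prof[q > 1.3] <- 0
  img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + prof
  img
}

# Per-label voxel counts of a label array (labels 1..max).
label_counts <- function(labels) {
  m <- max(labels)
  if (m == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = m)
}

# Relabel so that labels are consecutive and sorted by decreasing volume.
relabel_by_volume <- function(labels) {
  cnt <- label_counts(labels)
  keep <- which(cnt > 0)
  if (length(keep) == 0L) return(labels)
  ord <- keep[order(cnt[keep], decreasing = TRUE)]
  map <- integer(max(labels))
  map[ord] <- seq_along(ord)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}
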