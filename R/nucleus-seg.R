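# Iterative kappa-sigma clipping of a value vector: exclude values above
# mean + 3 sigma, recompute, <= 10 iterations or convergence. Starts from
# median and 1.4826 * MAD so a large bright foreground cannot trap the
# first iteration.
kappa_sigma_stats <- function(v) {
  med <- stats::median(v)
  scale <- 1.4826 * stats::median(abs(v - med))
  keep <- if (scale > 0) v <= med + 3 * scale else v <= med
  if (!any(keep)) keep <- rep(TRUE, length(v))
  m <- mean(v[keep]); s <- stats::sd(v[keep])
  if (is.na(s)) s <- 0
  for (i in seq_len(10L)) {
    keep_new <- v <= m + 3 * s
    if (!any(keep_new)) break
    m_new <- mean(v[keep_new]); s_new <- stats::sd(v[keep_new])
    if (is.na(s_new)) s_new <- 0
    converged <- abs(m_new - m) <= 1e-6 * max(abs(m), 1) &&
      abs(s_new - s) <= 1e-6 * max(s, 1)
    m <- m_new; s <- s_new
    if (converged) break
  }
  list(mean = m, sigma = s)
}

#' Background statistics by iterative kappa-sigma clipping
#'
#' Estimates the background mean and standard deviation of a stack the way
#' astronomy sky estimators do: voxels brighter than `mean + 3 sigma` are
#' excluded and the moments recomputed, for at most 10 iterations or until
#' convergence. The starting centre/scale are the median and 1.4826 * MAD so
#' that a bright foreground occupying a large volume fraction cannot trap
#' the first iteration. The signal-to-noise ratio is estimated as
#' `(mean of voxels above an Otsu split - background mean) / sigma`, and the
#' threshold weighting factor `f` is that SNR clamped to `[1, 2]`.
#'
#' @param stack An [image_stack()] with at least 100 voxels.
#' @return A list of class `background_stats`: `mean`, `sigma`, `snr`, `f`.
#' @export
estimate_background <- function(stack) {
  v <- as.double(stack$voxels)
  if (length(v) < 100L) stop("background estimation needs at least 100 voxels")
  ks <- kappa_sigma_stats(v)
  m <- ks$mean; s <- ks$sigma
  if (is.na(s) || s == 0) {
    warning("background sigma is zero after clipping; f forced to 1")
    return(structure(list(mean = m, sigma = 0, snr = NA_real_, f = 1),
                     class = "background_stats"))
  }
  # foreground level via an Otsu split of the full intensity range
  rng <- range(v)
  snr <- NA_real_
  if (diff(rng) > 0) {
    vs <- (v - rng[1]) / diff(rng)
    thr <- EBImage::otsu(matrix(vs, nrow = 1), range = c(0, 1)) * diff(rng) + rng[1]
    fg <- v > thr
    if (any(fg)) snr <- (mean(v[fg]) - m) / s
  }
  f <- min(max(if (is.na(snr)) 1 else snr, 1), 2)
  structure(list(mean = m, sigma = s, snr = snr, f = f),
            class = "background_stats")
}

#' @export
print.background_stats <- function(x, ...) {
  cat(sprintf("<background_stats> mean %.3f, sigma %.3f, SNR %.2f, f %.2f\n",
              x$mean, x$sigma, x$snr, x$f))
  invisible(x)
}

#' Foreground mask from background statistics
#'
#' Thresholds the DNA channel at the inclusive lower threshold
#' `mean + f * sigma`.
#'
#' @param stack An [image_stack()].
#' @param bg A `background_stats` from [estimate_background()] of the same
#'   stack.
#' @return A logical 3D array.
#' @export
nucleus_mask <- function(stack, bg) {
  stopifnot(inherits(bg, "background_stats"))
  thr <- bg$mean + bg$f * bg$sigma
  m <- stack$voxels >= thr
  if (all(m) || !any(m))
    warning("nucleus mask is all-", if (all(m)) "foreground" else "background",
            "; background/SNR estimation has likely failed")
  m
}

#' Nucleus region of interest
#'
#' One labelled nucleus: its binary mask (cropped), the bounding box in the
#' full grid (1-based inclusive index ranges with a 2-voxel margin), and
#' optionally per-channel cropped stacks attached by [crop_channels()].
#'
#' @name nucleus_roi
NULL

#' Extract nucleus ROIs from a foreground mask
#'
#' A 3D volume attribute opening removes connected components (26-
#' connectivity) below `min_volume`; a morphological opening then closing
#' with a ball element smooths each surviving object and severs thin
#' bridges, and fully enclosed cavities (the dark NPB/nucleolus voids) are
#' filled so the ROI covers the whole nucleus. Labels are assigned in
#' decreasing-volume order; bounding boxes carry a 2-voxel margin clipped
#' to the image bounds.
#'
#' @param mask Logical 3D array from [nucleus_mask()].
#' @param spacing Voxel spacing (um).
#' @param min_volume Minimum object volume (um^3); default 50 (well below
#'   the ~200 um^3 of the smallest blastocyst nuclei).
#' @param smooth_radius Ball radius (um) of the opening/closing; default 0.5.
#' @return A list of `nucleus_roi` objects (empty, with a warning, if no
#'   object survives).
#' @export
extract_nuclei <- function(mask, spacing, min_volume = 50, smooth_radius = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  vv <- voxel_volume(spacing)
  r_vox <- pmax(round(smooth_radius / spacing), 1)
  opened <- open_ball(mask, r_vox)
  labels <- label_components(opened)
  cnt <- label_counts(labels)
  keep <- which(cnt * vv >= min_volume)
  if (length(keep) == 0L) {
    warning("no object above min_volume = ", min_volume, " um^3")
    return(list())
  }
  keep <- keep[order(cnt[keep], decreasing = TRUE)]
  d <- dim3(mask)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    obj <- labels == keep[i]
    # closing and cavity filling on a padded crop, written back into the
    # full grid; NPBs/nucleoli are dark voids that must belong to the ROI
    bb <- mask_bbox(obj, margin = as.integer(2 + max(r_vox)))
    sub <- fill_holes(close_ball(crop_array(obj, bb), r_vox))
    obj[] <- FALSE
    obj <- uncrop_assign(obj, sub, bb)
    bbox <- mask_bbox(obj, margin = 2L)   # clipped to image bounds
    m <- crop_array(obj, bbox)
    out[[i]] <- structure(list(
      label = i,
      mask = m,
      bbox = bbox,
      spacing = as.double(spacing),
      volume_um3 = sum(m) * vv,
      channels = list()
    ), class = "nucleus_roi")
  }
  out
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("<nucleus_roi> label %d, %.0f um^3, bbox [%s]-[%s]%s\n",
              x$label, x$volume_um3,
              paste(x$bbox$lo, collapse = ","), paste(x$bbox$hi, collapse = ","),
              if (length(x$channels)) paste0(", channels: ",
                                             paste(names(x$channels), collapse = ", "))
              else ""))
  invisible(x)
}

#' Attach per-channel crops to a nucleus ROI
#'
#' Crops every stack to the ROI bounding box so that downstream signal and
#' NPB segmentation work on small sub-volumes.
#'
#' @param roi A `nucleus_roi` from [extract_nuclei()].
#' @param stacks Named list of [image_stack()] objects on the same grid the
#'   mask was computed on.
#' @return The ROI with `$channels` filled with cropped [image_stack()]s.
#' @export
crop_channels <- function(roi, stacks) {
  stopifnot(inherits(roi, "nucleus_roi"))
  roi$channels <- lapply(stacks, function(s) {
    image_stack(crop_array(s$voxels, roi$bbox), s$spacing, channel = s$channel,
                bit_depth = s$bit_depth)
  })
  roi
}

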