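#' Configuration of NPB/nucleolus segmentation
#'
#' @param gradient_sigma Sigma (um) of the Gaussian-derivative gradient
#'   added to the DNA crop to amplify the contour of the dark round areas.
#' @param min_volume Minimum object volume (um^3).
#' @param split_volume Volume (um^3) above which an object is assumed to be
#'   two fused nucleoli and gets an erosion-split attempt.
#' @param min_sphericity Objects below `split_volume` with sphericity under
#'   this are removed.
#' @param split_element Structuring element radius `(x, y, z)` of the
#'   split erosion/dilation (ITK convention; radius 3 is a 7 x 7 x 7 box).
#' @param otsu_mode `"slice2d"` (per z-slice Otsu, the default) or
#'   `"volume3d"` (one 3D Otsu, for late-stage non-spherical nucleoli).
#' @param contour_thickness Thickness (voxels) of the inner nuclear-contour
#'   shell subtracted from the dark class.
#' @param smooth_radius Ball radius (um) of the opening that smooths rough
#'   objects and severs thin residues.
#' @return A list of class `npb_config`.
#' @export
npb_config <- function(gradient_sigma = 0.62, min_volume = 0.23,
                       split_volume = 94.5, min_sphericity = 0.5,
                       split_element = c(3L, 3L, 3L),
                       otsu_mode = c("slice2d", "volume3d"),
                       contour_thickness = 2L, smooth_radius = 0.25) {
  otsu_mode <- match.arg(otsu_mode)
  stopifnot(gradient_sigma > 0, min_volume > 0, split_volume > 0,
            min_sphericity > 0, min_sphericity <= 1)
  structure(list(gradient_sigma = gradient_sigma, min_volume = min_volume,
                 split_volume = split_volume, min_sphericity = min_sphericity,
                 split_element = as.integer(split_element),
                 otsu_mode = otsu_mode,
                 contour_thickness = as.integer(contour_thickness),
                 smooth_radius = smooth_radius),
            class = "npb_config")
}

# Gaussian gradient magnitude with sigma in um.
gradient_magnitude <- function(v, spacing, sigma_um) {
  sm <- gaussian_blur(v, sigma_um / spacing)
  d <- dim3(sm)
  gy <- array(0, d); gx <- array(0, d); gz <- array(0, d)
  gy[2:(d[1] - 1), , ] <- (sm[3:d[1], , ] - sm[1:(d[1] - 2), , ]) / (2 * spacing[1])
  gx[, 2:(d[2] - 1), ] <- (sm[, 3:d[2], ] - sm[, 1:(d[2] - 2), ]) / (2 * spacing[2])
  gz[, , 2:(d[3] - 1)] <- (sm[, , 3:d[3]] - sm[, , 1:(d[3] - 2)]) / (2 * spacing[3])
  sqrt(gy^2 + gx^2 + gz^2)
}

otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  vs <- (v - rng[1]) / diff(rng)
  EBImage::otsu(matrix(vs, nrow = 1), range = c(0, 1)) * diff(rng) + rng[1]
}

#' Segment NPBs/nucleoli as dark round regions of the DNA channel
#'
#' The working image is the DNA crop plus its Gaussian gradient magnitude
#' (sigma 0.62 um), which amplifies the contour of the dark round areas. An
#' Otsu threshold (per z-slice, or one 3D threshold per `otsu_mode`) keeps
#' the dark class inside the nucleus; the inner nuclear-contour shell
#' (derived from the nucleus mask) is subtracted so that dark voxels merely
#' hugging the nuclear rim are trimmed; a morphological opening smooths and
#' separates objects; objects below `min_volume` (0.23 um^3) are removed
#' and 26-connected components labelled.
#'
#' @param dna_crop DNA-channel [image_stack()] crop of `roi`.
#' @param roi A `nucleus_roi`.
#' @param cfg An [npb_config()].
#' @return A [label_map()] (empty, with a warning, when the nucleus
#'   interior is empty).
#' @export
segment_npbs <- function(dna_crop, roi, cfg = npb_config()) {
  stopifnot(inherits(roi, "nucleus_roi"))
  sp <- dna_crop$spacing
  interior <- erode_ball(roi$mask, rep(cfg$contour_thickness, 3))
  if (!any(interior)) {
    warning("empty nucleus interior; no NPB segmentation possible")
    return(label_map(array(0L, dim3(roi$mask)), sp))
  }
  work <- dna_crop$voxels + gradient_magnitude(dna_crop$voxels, sp, cfg$gradient_sigma)
  d <- dim3(work)
  dark <- array(FALSE, d)
  # Otsu statistics run over the whole cropped image: the dark extranuclear
  # background anchors the dark class at the NPB intensity level, so the
  # split lands between nucleoplasm and {background, NPBs} even when NPBs
  # occupy a small volume fraction.
  if (cfg$otsu_mode == "slice2d") {
    for (k in seq_len(d[3])) {
      sl <- roi$mask[, , k]
      if (!any(sl)) next
      thr <- otsu_threshold(work[, , k])
      dark[, , k] <- work[, , k] < thr & sl
    }
  } else {
    thr <- otsu_threshold(work)
    dark <- work < thr & roi$mask
  }
  # subtract the nuclear contour shell, then open to smooth/separate
  dark <- dark & interior
  r_vox <- pmax(round(cfg$smooth_radius / sp), 1)
  dark <- open_ball(dark, r_vox)
  label_map(label_above_min(dark, sp, cfg$min_volume), sp)
}

#' Refine NPB labels by roundness and fused-pair splitting
#'
#' Objects below `split_volume` (94.5 um^3) with sphericity under
#' `min_sphericity` (0.5) are removed; objects at or above `split_volume`
#' (usually two very close nucleoli) are eroded by the split element,
#' relabelled and grown back over their support to recover separate
#' objects when possible.
#'
#' @param labels A [label_map()] from [segment_npbs()].
#' @param shapes Optional [shape_stats()] tibble for `labels` (computed if
#'   missing).
#' @param cfg An [npb_config()].
#' @return A [label_map()].
#' @export
refine_npbs <- function(labels, shapes = NULL, cfg = npb_config()) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels$labels) == 0L) return(labels)
  if (is.null(shapes)) shapes <- shape_stats(labels)
  lab <- labels$labels
  drop <- shapes$label[shapes$volume_um3 < cfg$split_volume &
                         shapes$sphericity < cfg$min_sphericity]
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  big <- shapes$label[shapes$volume_um3 >= cfg$split_volume]
  if (length(big) > 0) {
    nxt <- max(lab)
    for (l in big) {
      sp_res <- erosion_split(lab, l, element_radius(cfg$split_element))
      if (sp_res$n <= 1L) next
      sub <- crop_array(lab, sp_res$bb)
      sub[sub == l] <- 0L
      for (p in seq_len(sp_res$n)) {
        nxt <- nxt + 1L
        sub[sp_res$masks[[p]]] <- nxt
      }
      lab <- uncrop_assign(lab, sub, sp_res$bb)
    }
  }
  label_map(relabel_by_volume(lab), labels$spacing)
}

#' Scripted corrections of an NPB label map
#'
#' Reifies the published manual correction step as data: an edit list of
#' ordered `remove(label)` and `add(centroid, semi-axes)` operations.
#' Additions rasterize an ellipsoid at the stated centroid and semi-axes
#' (um), clipped to the nucleus mask, as a new label. Every edit is
#' recorded in an attached log.
#'
#' @param labels A [label_map()].
#' @param edits An [edit_list()].
#' @param roi Optional `nucleus_roi`; when given, added ellipsoids are
#'   clipped to its mask.
#' @return A [label_map()] with attribute `"edit_log"` (a tibble).
#' @export
apply_edits <- function(labels, edits, roi = NULL) {
  stopifnot(inherits(labels, "label_map"), inherits(edits, "edit_list"))
  lab <- labels$labels
  sp <- labels$spacing
  log <- list()
  for (e in edits) {
    if (e$op == "remove") {
      if (!any(lab == e$label))
        stop("cannot remove label ", e$label, ": not present in the label map")
      lab[lab == e$label] <- 0L
      log[[length(log) + 1L]] <- tibble::tibble(op = "remove", label = e$label,
                                                volume_um3 = NA_real_)
    } else {
      m <- rasterize_ellipsoid(dim3(lab), sp, e$centroid, e$semiaxes)
      if (!is.null(roi)) m <- m & roi$mask
      hit <- unique(lab[m & lab > 0L])
      if (length(hit) > 0)
        stop("added ellipsoid collides with existing label(s) ",
             paste(sort(hit), collapse = ", "))
      new_lab <- max(lab) + 1L
      lab[m] <- new_lab
      log[[length(log) + 1L]] <- tibble::tibble(op = "add", label = new_lab,
                                                volume_um3 = sum(m) * voxel_volume(sp))
    }
  }
  out <- label_map(lab, sp)
  attr(out, "edit_log") <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(op = character(), label = integer(), volume_um3 = double())
  out
}

#' Ordered NPB edit list
#'
#' @param ... Edits created by [edit_remove()] / [edit_add()].
#' @return An object of class `edit_list`.
#' @export
edit_list <- function(...) {
  edits <- list(...)
  ok <- vapply(edits, function(e) is.list(e) && e$op %in% c("remove", "add"),
               logical(1))
  if (length(edits) && !all(ok)) stop("edits must be edit_remove()/edit_add() objects")
  structure(edits, class = "edit_list")
}

#' @param label Label id to remove.
#' @rdname edit_list
#' @export
edit_remove <- function(label) list(op = "remove", label = as.integer(label))

#' @param centroid Ellipsoid centroid (um, `(y, x, z)` within the crop).
#' @param semiaxes Ellipsoid semi-axes (um), all positive.
#' @rdname edit_list
#' @export
edit_add <- function(centroid, semiaxes) {
  semiaxes <- rep(as.double(semiaxes), length.out = 3)
  if (any(semiaxes <= 0)) stop("semi-axes must be positive")
  list(op = "add", centroid = as.double(centroid), semiaxes = semiaxes)
}

#' Serialize / deserialize an edit list as JSON
#'
#' @param edits An [edit_list()].
#' @param path JSON file path.
#' @rdname edit_list_io
#' @export
write_edit_list <- function(edits, path) {
  stopifnot(inherits(edits, "edit_list"))
  jsonlite::write_json(unclass(edits), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname edit_list_io
#' @export
read_edit_list <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(edit_list, lapply(raw, function(e) {
    if (e$op == "remove") edit_remove(e$label)
    else edit_add(unlist(e$centroid), unlist(e$semiaxes))
  }))
}
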