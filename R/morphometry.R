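#' Surface area of the sphere with an equivalent volume
#'
#' `S = pi^(1/3) * (6 V)^(2/3)`, the theoretical surface used both for the
#' sphericity (roundness) score and for interaction ratios.
#'
#' @param volume Volume in um^3 (vectorized); must be positive.
#' @return Surface in um^2.
#' @export
equivalent_sphere_surface <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3)
}

# Surface area (um^2) of one binary object: total variation of the
# Gaussian-smoothed indicator function. For a plane the estimator is exact
# for any sigma; for curved surfaces the bias is O((sigma/R)^2). Voxel-face
# counting would bias sphericity low by ~1.5x, which the published
# roundness thresholds (sphere ~ 1) are not compatible with. Objects too
# small to carry the smoothing kernel fall back to exposed-face counting.
tv_surface <- function(mask, spacing, sigma_vox = 0.5) {
  bbt <- mask_bbox(mask, margin = 0L)
  if (sum(mask) < 32 || min(bbt$hi - bbt$lo + 1L) < 4L)
    return(face_surface(mask, spacing))
  bb <- mask_bbox(mask, margin = as.integer(ceiling(3.5 * sigma_vox) + 2L))
  u <- crop_array(mask, bb) * 1.0
  d <- dim3(u)
  if (any(d < 3L)) {
    pad <- pmax(3L - d, 0L)
    u2 <- array(0, d + 2L * pad)
    u2[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- u
    u <- u2; d <- dim3(u)
  }
  u <- gaussian_blur(u, rep(sigma_vox, 3))
  gy <- (u[c(2:d[1], d[1]), , ] - u[c(1, 1:(d[1] - 1)), , ]) / (2 * spacing[1])
  gx <- (u[, c(2:d[2], d[2]), ] - u[, c(1, 1:(d[2] - 1)), ]) / (2 * spacing[2])
  gz <- (u[, , c(2:d[3], d[3])] - u[, , c(1, 1:(d[3] - 1))]) / (2 * spacing[3])
  sum(sqrt(gy^2 + gx^2 + gz^2)) * voxel_volume(spacing)
}

# Exposed 6-neighbour face count times face area; used for objects only a
# few voxels across, where the smoothed estimator cannot resolve a surface.
face_surface <- function(mask, spacing) {
  bb <- mask_bbox(mask, margin = 0L)
  mc <- crop_array(mask, bb)
  d0 <- dim3(mc)
  m <- array(0L, d0 + 2L)
  m[1L + seq_len(d0[1]), 1L + seq_len(d0[2]), 1L + seq_len(d0[3])] <- mc * 1L
  d <- dim3(m)
  faces <-
    sum(abs(m[2:d[1], , ] - m[1:(d[1] - 1), , ])) +
    sum(abs(m[, 2:d[2], ] - m[, 1:(d[2] - 1), ])) +
    sum(abs(m[, , 2:d[3]] - m[, , 1:(d[3] - 1)]))
  faces * spacing[1] * spacing[2]
}

#' Per-object shape statistics of a label map
#'
#' For every labelled object: volume (voxel count x voxel volume), surface
#' (area of the smoothed isosurface via the total-variation estimator),
#' sphericity (surface of the equal-volume sphere divided by the object
#' surface, ~1 for digital balls, lower for elongated/flat objects),
#' centroid (um), principal axis lengths `a >= b >= c` (equivalent-
#' ellipsoid axes from the voxel second-moment matrix), flatness `b / c`
#' and elongation `a / b`. Single-voxel (and otherwise degenerate) objects
#' report flatness = elongation = 1 via the per-voxel moment term.
#'
#' @param labels A [label_map()].
#' @param surface_sigma Smoothing sigma (voxels) of the surface estimator.
#' @return A tibble with one row per label.
#' @export
shape_stats <- function(labels, surface_sigma = 0.5) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  sp <- labels$spacing
  vv <- voxel_volume(sp)
  n <- max(lab)
  if (n == 0L)
    return(tibble::tibble(label = integer(), volume_um3 = double(),
                          surface_um2 = double(), sphericity = double(),
                          flatness = double(), elongation = double(),
                          cy = double(), cx = double(), cz = double(),
                          axis_a = double(), axis_b = double(), axis_c = double()))
  idx <- which(lab > 0L)
  ai <- arrayInd(idx, dim3(lab))
  labv <- lab[idx]
  rows <- lapply(seq_len(n), function(l) {
    sel <- labv == l
    if (!any(sel)) return(NULL)
    pts <- sweep(ai[sel, , drop = FALSE] - 1, 2, sp, `*`)
    nv <- nrow(pts)
    vol <- nv * vv
    cen <- colMeans(pts)
    # population covariance + per-voxel second moment (handles degeneracy)
    cc <- sweep(pts, 2, cen)
    cov <- crossprod(cc) / nv + diag(sp^2 / 12)
    ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 1e-12)
    axes <- 2 * sqrt(5 * ev)
    # surface on the object's own mask
    m <- array(FALSE, dim3(lab))
    m[idx[sel]] <- TRUE
    surf <- tv_surface(m, sp, surface_sigma)
    tibble::tibble(label = l, volume_um3 = vol, surface_um2 = surf,
                   sphericity = equivalent_sphere_surface(vol) / surf,
                   flatness = axes[2] / axes[3], elongation = axes[1] / axes[2],
                   cy = cen[1], cx = cen[2], cz = cen[3],
                   axis_a = axes[1], axis_b = axes[2], axis_c = axes[3])
  })
  dplyr::bind_rows(rows)
}

#' Classify pericentromeres as compact / elongated / not analyzed
#'
#' Objects smaller than `volume_min` (0.47 um^3) are not analyzed;
#' otherwise sphericity above `roundness_min` (0.8) is compact, at or below
#' it elongated.
#'
#' @param shapes A [shape_stats()] tibble (or any data frame with
#'   `volume_um3` and `sphericity` columns).
#' @param roundness_min Compactness threshold on sphericity.
#' @param volume_min Minimum analyzable volume (um^3).
#' @return `shapes` with an added factor column `class`.
#' @export
classify_pericentromere <- function(shapes, roundness_min = 0.8, volume_min = 0.47) {
  stopifnot(all(c("volume_um3", "sphericity") %in% names(shapes)))
  dplyr::mutate(
    shapes,
    class = factor(
      dplyr::case_when(
        .data$volume_um3 < volume_min ~ "not_analyzed",
        .data$sphericity > roundness_min ~ "compact",
        TRUE ~ "elongated"),
      levels = c("compact", "elongated", "not_analyzed"))
  )
}

#' Score signal-to-NPB interactions
#'
#' The NPB mask is dilated by a ball of radius `dilation_um` (default
#' 0.37 um ~ 3 voxels on the nominal grid, i.e. objects separated by less
#' than ~0.5 um count as interacting); halo voxels keep the identity of the
#' nearest NPB. For every signal object intersecting a halo, the
#' interaction volume is the overlap with the halo, the interaction surface
#' is the area of the signal's boundary faces adjacent to the halo, and the
#' ratio `r` compares that surface with the theoretical interaction surface
#' of a sphere of the signal's volume. Categories: `Null` (no overlap),
#' `Close` (0 < r <= 0.1), `Low` (0.1 < r <= 0.5), `Medium` (0.5 < r <= 1),
#' `Strong` (r > 1, e.g. shells hugging an NPB). Signals interacting with
#' no NPB are reported once with `npb = NA` and category `Null`.
#'
#' @param signals A [label_map()] of FISH signals.
#' @param npbs A [label_map()] of NPBs/nucleoli on the same grid.
#' @param dilation_um Halo radius (um).
#' @param breaks Upper category boundaries on `r` for Close/Low/Medium.
#' @return A tibble with one row per (signal, NPB) interacting pair plus
#'   one `Null` row per non-interacting signal.
#' @export
score_interactions <- function(signals, npbs, dilation_um = 0.37,
                               breaks = c(0.1, 0.5, 1)) {
  stopifnot(inherits(signals, "label_map"), inherits(npbs, "label_map"))
  if (!identical(dim(signals$labels), dim(npbs$labels)) ||
      max(abs(signals$spacing - npbs$spacing)) > 1e-9)
    stop("signal and NPB label maps must share one voxel grid")
  sp <- signals$spacing
  vv <- voxel_volume(sp)
  d <- dim3(signals$labels)
  lvls <- c("Null", "Close", "Low", "Medium", "Strong")
  empty <- tibble::tibble(signal = integer(), npb = integer(),
                          interaction_volume_um3 = double(),
                          interaction_surface_um2 = double(),
                          ratio = double(),
                          category = factor(character(), levels = lvls))
  ns <- max(signals$labels)
  if (ns == 0L) return(empty)

  svol <- label_counts(signals$labels) * vv
  if (max(npbs$labels) == 0L) {
    halo <- array(0L, d)
  } else {
    r_vox <- pmax(round(dilation_um / sp), 1)
    dil <- dilate_ball(npbs$labels > 0L, r_vox)
    halo <- array(grow_labels(npbs$labels, as.logical(dil), d, 6L), d)
  }

  both <- signals$labels > 0L & halo > 0L
  pairs <- if (any(both))
    dplyr::count(tibble::tibble(signal = signals$labels[both], npb = halo[both]),
                 .data$signal, .data$npb, name = "nvox")
  else tibble::tibble(signal = integer(), npb = integer(), nvox = integer())

  rows <- list()
  for (j in sort(unique(pairs$npb))) {
    contact <- face_contact_counts(signals$labels, halo == j, d, ns)
    pj <- pairs[pairs$npb == j, ]
    pj$interaction_surface_um2 <- contact[pj$signal] * sp[1] * sp[2]
    rows[[length(rows) + 1L]] <- pj
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(signal = integer(), npb = integer(), nvox = integer(),
                   interaction_surface_um2 = double())
  out <- dplyr::mutate(out,
    interaction_volume_um3 = .data$nvox * vv,
    ratio = .data$interaction_surface_um2 /
      equivalent_sphere_surface(svol[.data$signal]),
    category = factor(
      dplyr::case_when(
        .data$ratio > breaks[3] ~ "Strong",
        .data$ratio > breaks[2] ~ "Medium",
        .data$ratio > breaks[1] ~ "Low",
        TRUE ~ "Close"),
      levels = lvls))
  out$nvox <- NULL
  lonely <- setdiff(seq_len(ns), out$signal)
  if (length(lonely) > 0)
    out <- dplyr::bind_rows(out, tibble::tibble(
      signal = lonely, npb = NA_integer_,
      interaction_volume_um3 = 0, interaction_surface_um2 = 0, ratio = 0,
      category = factor("Null", levels = lvls)))
  dplyr::arrange(out, .data$signal, .data$npb)
}
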