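#' Moment normalization of a nucleus and its centromere positions
#'
#' Maps the nucleus to a shape with equal principal second moments: the
#' affine map translates to the mask centroid, rotates to the principal
#' axes, and rescales each axis by `sqrt(g / lambda_i)` where `g` is the
#' geometric mean of the moment eigenvalues (so the volume is preserved and
#' the equivalent-sphere radius is meaningful). The same map is applied to
#' the centromere points.
#'
#' @param mask Either a logical 3D array (with `spacing`) or an `n x 3`
#'   matrix of voxel-centre coordinates (um).
#' @param points Optional `n x 3` matrix of point coordinates (um) to
#'   transform with the mask.
#' @param spacing Voxel spacing (um) when `mask` is an array.
#' @return A list of class `moment_normalized`: `coords` (normalized mask
#'   voxel centres), `points`, `r_eq` (radius of the equal-volume sphere),
#'   `volume_um3`, and the affine pieces `center`, `rotation`, `scales`.
#' @export
moment_normalize <- function(mask, points = NULL, spacing = NULL) {
  if (is.array(mask) && length(dim(mask)) == 3L) {
    stopifnot(!is.null(spacing))
    vv <- voxel_volume(spacing)
    coords <- mask_coords(mask > 0, spacing)
  } else {
    coords <- as.matrix(mask)
    vv <- if (is.null(spacing)) NA_real_ else voxel_volume(spacing)
  }
  if (nrow(coords) == 0L) stop("mask is empty")
  cen <- colMeans(coords)
  cc <- sweep(coords, 2, cen)
  cov <- crossprod(cc) / nrow(cc)
  eg <- eigen(cov, symmetric = TRUE)
  if (min(eg$values) <= 1e-6 * max(eg$values))
    stop("degenerate (planar or linear) mask; moments cannot be equalized")
  g <- prod(eg$values)^(1 / 3)
  scales <- sqrt(g / eg$values)
  xf <- function(p) {
    p <- sweep(as.matrix(p), 2, cen)
    sweep(p %*% eg$vectors, 2, scales, `*`)
  }
  vol <- if (is.na(vv)) NA_real_ else nrow(coords) * vv  # volume-preserving map
  structure(list(
    coords = xf(coords),
    points = if (is.null(points)) NULL else xf(points),
    r_eq = if (is.na(vol)) NA_real_ else (3 * vol / (4 * pi))^(1 / 3),
    volume_um3 = vol,
    center = cen, rotation = eg$vectors, scales = scales
  ), class = "moment_normalized")
}

#' Normalized polarity index
#'
#' Distance between the centre of mass of the centromere points and the
#' centre of mass of the (moment-normalized) nucleus, divided by the
#' radius of the sphere with the nucleus volume.
#'
#' @param norm A `moment_normalized` object carrying `points`, or a matrix
#'   of normalized mask coordinates (then `points` must be given).
#' @param points Optional normalized points when `norm` is a matrix.
#' @param r_eq Equivalent-sphere radius override (um).
#' @return The dimensionless polarity distance `d >= 0`.
#' @export
polarity_index <- function(norm, points = NULL, r_eq = NULL) {
  if (inherits(norm, "moment_normalized")) {
    coords <- norm$coords
    points <- points %||% norm$points
    r_eq <- r_eq %||% norm$r_eq
  } else coords <- as.matrix(norm)
  if (is.null(points) || nrow(as.matrix(points)) == 0L)
    stop("at least one centromere point is required")
  if (is.null(r_eq) || is.na(r_eq))
    stop("an equivalent-sphere radius is required")
  delta <- colMeans(as.matrix(points)) - colMeans(coords)
  sqrt(sum(delta^2)) / r_eq
}

#' Permutation test of nuclear polarity
#'
#' Compares the observed polarity index of `n` centromeres with the index
#' of `n_patterns` random patterns of `n` points drawn uniformly over the
#' nucleus mask voxel centres, all under the same moment normalization.
#' The p-value is the plain proportion of random patterns with a distance
#' equal to or above the observed one (so `p = 0` is attainable).
#'
#' @param mask Logical 3D nucleus mask.
#' @param points `n x 3` matrix of centromere centroids (um, same grid).
#' @param spacing Voxel spacing (um).
#' @param n_patterns Number of random patterns (default 500).
#' @param seed Optional integer seed for reproducibility.
#' @param nucleus_id Identifier carried through to the result.
#' @return A list of class `polarity_result`: `nucleus_id`,
#'   `n_centromeres`, `d`, `null_d` (length `n_patterns`), `p_value`,
#'   `seed`.
#' @export
polarity_test <- function(mask, points, spacing, n_patterns = 500L,
                          seed = NULL, nucleus_id = NA_integer_) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1L, ncol(points) == 3L)
  if (n_patterns < 100L)
    warning("fewer than 100 random patterns gives a coarse p-value resolution")
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  norm <- moment_normalize(mask, points = points, spacing = spacing)
  d_obs <- polarity_index(norm)
  n <- nrow(points)
  cen0 <- colMeans(norm$coords)
  # random patterns are drawn over the mask's voxel centres; the mask's own
  # normalization has already been applied to norm$coords
  voxT <- norm$coords
  idx <- matrix(sample.int(nrow(voxT), n * n_patterns, replace = TRUE), n)
  dy <- colMeans(matrix(voxT[, 1][idx], n)) - cen0[1]
  dx <- colMeans(matrix(voxT[, 2][idx], n)) - cen0[2]
  dz <- colMeans(matrix(voxT[, 3][idx], n)) - cen0[3]
  null_d <- sqrt(dy^2 + dx^2 + dz^2) / norm$r_eq
  structure(list(
    nucleus_id = nucleus_id, n_centromeres = n, d = d_obs, null_d = null_d,
    p_value = mean(null_d >= d_obs), seed = seed
  ), class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("<polarity_result> nucleus %s: n = %d centromeres, d = %.3f, p = %.3f (%d patterns)\n",
              as.character(x$nucleus_id), x$n_centromeres, x$d,
              x$p_value, length(x$null_d)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.polarity_result <- function(x, ...) {
  tibble::tibble(nucleus_id = x$nucleus_id, n_centromeres = x$n_centromeres,
                 d = x$d, p_value = x$p_value, n_patterns = length(x$null_d))
}

#' @export
glance.polarity_result <- function(x, ...) {
  tibble::tibble(d = x$d, p_value = x$p_value,
                 null_median = stats::median(x$null_d),
                 null_q99 = stats::quantile(x$null_d, 0.99, names = FALSE))
}

#' Population-level uniformity test of polarity p-values
#'
#' Under random centromere placement the per-nucleus p-values are uniform
#' on `[0, 1]`; this is tested with a two-sided Kolmogorov-Smirnov test at
#' `alpha` (default 1%).
#'
#' @param p_values Numeric vector of per-nucleus p-values (at least 5).
#' @param alpha Rejection level.
#' @return A tibble with `ks_statistic`, `ks_p_value`, `rejected`, `n`.
#' @export
population_uniformity_test <- function(p_values, alpha = 0.01) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) < 5L) stop("at least 5 p-values are required")
  ks <- suppressWarnings(stats::ks.test(p_values, "punif", 0, 1))
  tibble::tibble(ks_statistic = unname(ks$statistic),
                 ks_p_value = ks$p.value,
                 rejected = ks$p.value < alpha,
                 n = length(p_values))
}
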