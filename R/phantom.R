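#' Specification of a synthetic embryo-nucleus phantom
#'
#' Describes the geometry, intensity and noise model of a ground-truthed
#' synthetic multichannel stack emulating a preimplantation-embryo nucleus:
#' an ellipsoidal nucleus with textured DNA counterstain, dark spherical
#' NPBs (nucleolar precursor bodies), per-chromosome pericentromeric
#' heterochromatin motifs, punctate centromeric and telomeric marks (one
#' centromere and two telomeres per telocentric chromosome), optional
#' Rabl-like polarity, Gaussian PSF blur and Poisson-Gaussian noise.
#'
#' @param nucleus_semiaxes Ellipsoid semi-axes (um), `(ay, ax, az)`.
#' @param nucleus_mean Mean DNA intensity inside the nucleus (8-bit scale).
#' @param texture_sd Standard deviation of the smooth DNA texture.
#' @param background Background intensity outside the nucleus.
#' @param n_npbs Number of NPBs.
#' @param npb_radius_range NPB radius range (um); radii drawn uniformly.
#' @param n_chromosomes Number of telocentric chromosomes (mouse haploid =
#'   20, diploid = 40). Each contributes one centromeric and two telomeric
#'   marks and one pericentromeric motif.
#' @param motif_weights Named non-negative weights over the motif classes
#'   `shell`, `patch`, `chromocenter`, `filament`, `peripheral`.
#' @param spot_radius Centromere/telomere mark radius (um).
#' @param spot_peak Peak intensity of the rendered marks.
#' @param peri_peak Peak intensity of pericentromeric heterochromatin.
#' @param speckle_sd Relative sd of the multiplicative voxel-scale texture
#'   modulating rendered FISH signals (hybridization granularity; 0
#'   renders analytically smooth objects).
#' @param spot_min_sep Minimum separation between marks of one channel
#'   (um). Setting it to 0 switches to point-process mode: every
#'   mutual-exclusion constraint between marks and between heterochromatin
#'   masses is disabled, so mark placement at `rho = 0` is exactly
#'   spatially uniform (intended for calibration studies, not for
#'   detection benchmarks).
#' @param rho Polarity parameter in `[0, 1]`: 0 = isotropic placement; 1 =
#'   all marks concentrated around one pole (mapped to a von Mises-Fisher
#'   concentration).
#' @param psf_sigma Gaussian PSF sigma (um), applied after rendering.
#' @param poisson_gain Photon gain of the Poisson noise stage (0 disables).
#' @param gaussian_sd Additive read-noise standard deviation (0 disables).
#' @param spacing Isotropic voxel spacing of the rendered grid (um).
#' @param margin Clear margin between nucleus and stack border (um).
#' @param n_nuclei Number of nuclei placed in one stack.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param stage Optional stage label carried through to outputs.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nucleus_semiaxes = c(9.5, 9.4, 8.6),
                         nucleus_mean = 120, texture_sd = 12, background = 10,
                         n_npbs = 10, npb_radius_range = c(1.6, 3.0),
                         n_chromosomes = 40,
                         motif_weights = c(shell = 0.3, patch = 0.3,
                                           chromocenter = 0.25, filament = 0.1,
                                           peripheral = 0.05),
                         spot_radius = 0.35, spot_peak = 180, peri_peak = 150,
                         speckle_sd = 0.25,
                         spot_min_sep = 2.0, rho = 0, psf_sigma = 0.25,
                         poisson_gain = 1, gaussian_sd = 2,
                         spacing = 0.1236, margin = 1.5, n_nuclei = 1,
                         seed = 1, stage = NA_character_) {
  motifs <- c("shell", "patch", "chromocenter", "filament", "peripheral")
  w <- motif_weights[motifs]
  if (any(is.na(w))) {
    w <- stats::setNames(rep(0, 5), motifs)
    w[names(motif_weights)] <- motif_weights
  }
  if (any(w < 0) || sum(w) <= 0) stop("motif_weights must be non-negative with positive sum")
  stopifnot(length(nucleus_semiaxes) == 3, all(nucleus_semiaxes > 0),
            n_npbs >= 0, n_chromosomes >= 0, spot_radius > 0,
            rho >= 0, rho <= 1, spacing > 0)
  structure(list(
    nucleus_semiaxes = as.double(nucleus_semiaxes),
    nucleus_mean = nucleus_mean, texture_sd = texture_sd,
    background = background,
    n_npbs = as.integer(n_npbs), npb_radius_range = as.double(npb_radius_range),
    n_chromosomes = as.integer(n_chromosomes), motif_weights = w / sum(w),
    spot_radius = spot_radius, spot_peak = spot_peak, peri_peak = peri_peak,
    speckle_sd = speckle_sd,
    spot_min_sep = spot_min_sep, rho = rho, psf_sigma = psf_sigma,
    poisson_gain = poisson_gain, gaussian_sd = gaussian_sd,
    spacing = spacing, margin = margin, n_nuclei = as.integer(n_nuclei),
    seed = as.integer(seed), stage = stage
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  v <- 4 / 3 * pi * prod(x$nucleus_semiaxes)
  cat(sprintf(paste0("<phantom_spec> stage %s: %d nucleus(ei) of %.0f um^3, %d NPBs, ",
                     "%d chromosomes, rho = %.2f, seed %d\n"),
              x$stage, x$n_nuclei, v, x$n_npbs, x$n_chromosomes, x$rho, x$seed))
  invisible(x)
}

#' Stage presets for the phantom generator
#'
#' Returns a [phantom_spec()] whose nuclear volume, NPB count and
#' heterochromatin motif mix emulate the published per-stage summaries:
#' mean nuclear volume ~3500 um^3 at the 2-cell stage falling ~10-fold to
#' ~390 um^3 at the blastocyst stage; mean NPB/nucleolus counts of ~12
#' (early 2-cell), ~10 (late 2-cell), ~3 (late 4-cell), ~4-5 (8-cell);
#' NPB-attached shells and patches dominating at the 2-cell stage, free
#' chromocenters from the 4-cell stage on. Counts are drawn uniformly
#' within the stage's interquartile-like range, so repeated calls vary.
#'
#' @param stage One of `"2cell_early"`, `"2cell_late"`, `"4cell"`,
#'   `"8cell"`, `"blastocyst"`, `"haploid_pn"`.
#' @param seed Seed stored in the returned spec.
#' @return A [phantom_spec()].
#' @export
phantom_presets <- function(stage, seed = 1) {
  presets <- list(
    "2cell_early" = list(semi = c(10.5, 9.5, 8.6), npb = c(10L, 15L),
                         npb_r = c(1.3, 2.4), nchr = 40L,
                         w = c(shell = 0.45, patch = 0.35, chromocenter = 0.05,
                               filament = 0.1, peripheral = 0.05)),
    "2cell_late"  = list(semi = c(10.0, 9.5, 8.8), npb = c(8L, 12L),
                         npb_r = c(1.5, 2.6), nchr = 40L,
                         w = c(shell = 0.15, patch = 0.45, chromocenter = 0.3,
                               filament = 0.05, peripheral = 0.05)),
    "4cell"       = list(semi = c(7.8, 7.5, 7.2), npb = c(1L, 5L),
                         npb_r = c(1.8, 2.9), nchr = 40L,
                         w = c(shell = 0, patch = 0.07, chromocenter = 0.9,
                               filament = 0.03, peripheral = 0)),
    "8cell"       = list(semi = c(6.3, 6.0, 5.7), npb = c(3L, 6L),
                         npb_r = c(1.3, 2.2), nchr = 40L,
                         w = c(shell = 0, patch = 0.05, chromocenter = 0.9,
                               filament = 0, peripheral = 0.05)),
    "blastocyst"  = list(semi = c(4.8, 4.5, 4.2), npb = c(1L, 3L),
                         npb_r = c(1.2, 2.0), nchr = 40L,
                         w = c(shell = 0, patch = 0, chromocenter = 0.95,
                               filament = 0, peripheral = 0.05)),
    "haploid_pn"  = list(semi = c(8.2, 8.0, 7.8), npb = c(3L, 5L),
                         npb_r = c(1.6, 2.6), nchr = 20L,
                         w = c(shell = 0.55, patch = 0.2, chromocenter = 0.05,
                               filament = 0.15, peripheral = 0.05))
  )
  if (!stage %in% names(presets))
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[stage]]
  phantom_spec(
    nucleus_semiaxes = p$semi,
    n_npbs = sample(p$npb[1]:p$npb[2], 1),
    npb_radius_range = p$npb_r,
    n_chromosomes = p$nchr,
    motif_weights = p$w,
    seed = seed, stage = stage
  )
}

# --- von Mises-Fisher sampling -----------------------------------------------

rho_to_kappa <- function(rho) {
  # capped so that rho = 1 concentrates marks in one hemisphere (~1/sqrt(10)
  # rad angular spread) rather than on a single ray, which could not host a
  # full karyotype of separated marks
  if (rho <= 0) 0 else min(10 * rho / (1 - rho + 1e-9), 10)
}

# n unit vectors from vMF(mu, kappa); kappa = 0 is uniform on the sphere.
rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (kappa <= 0) {
    z <- stats::rnorm(n); y <- stats::rnorm(n); x <- stats::rnorm(n)
    m <- cbind(y, x, z)
    return(m / sqrt(rowSums(m^2)))
  }
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal frame around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  s <- sqrt(pmax(1 - w^2, 0))
  t(vapply(seq_len(n), function(i)
    s[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2) + w[i] * mu, numeric(3)))
}

# --- placement helpers -------------------------------------------------------

# Distance from ellipsoid centre to boundary along unit direction u.
ellipsoid_radius <- function(u, semi) 1 / sqrt(sum((u / semi)^2))

# Rejection sampling with graduated relaxation: every 250 failed attempts
# the separation constraints are relaxed by 0.8x (accept receives the
# current factor), mimicking the crowding of real polarized nuclei while
# keeping full separation whenever geometrically feasible.
place_reject <- function(propose, accept, what, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    relax <- 0.8^((i - 1L) %/% 250L)
    cand <- propose()
    ok <- tryCatch(accept(cand, relax), error = function(e) accept(cand))
    if (isTRUE(ok)) return(cand)
  }
  stop("could not place ", what, " within ", max_tries, " rejection-sampling attempts")
}

# --- motif rasterization -----------------------------------------------------

local_grid <- function(dims, spacing, center, radius) {
  lo <- pmax(floor((center - radius) / spacing) + 1, 1)
  hi <- pmin(ceiling((center + radius) / spacing) + 1, dims)
  if (any(lo > hi)) return(NULL)
  sd3 <- hi - lo + 1
  cy <- ((lo[1]:hi[1]) - 1) * spacing[1] - center[1]
  cx <- ((lo[2]:hi[2]) - 1) * spacing[2] - center[2]
  cz <- ((lo[3]:hi[3]) - 1) * spacing[3] - center[3]
  list(lo = lo, hi = hi, dims = sd3,
       Y = array(cy, sd3),
       X = array(rep(cx, each = sd3[1]), sd3),
       Z = array(rep(cz, each = sd3[1] * sd3[2]), sd3))
}

# Rasterize one pericentromeric motif; returns list(bbox lo/hi, mask,
# intensity) where intensity is a multiplicative profile in [0,1].
rasterize_motif <- function(motif, dims, spacing) {
  g <- switch(motif$type,
    shell = ,
    patch = local_grid(dims, spacing, motif$npb_center, motif$r_out + 0.2),
    chromocenter = ,
    peripheral = local_grid(dims, spacing, motif$center, max(motif$semi) + 0.2),
    filament = local_grid(dims, spacing, (motif$p0 + motif$p1) / 2,
                          sqrt(sum((motif$p1 - motif$p0)^2)) / 2 + motif$radius + 0.2)
  )
  if (is.null(g)) return(NULL)
  if (motif$type %in% c("shell", "patch")) {
    d2 <- g$Y^2 + g$X^2 + g$Z^2
    d <- sqrt(d2)
    cosang <- (g$Y * motif$dir[1] + g$X * motif$dir[2] + g$Z * motif$dir[3]) /
      pmax(d, 1e-9)
    mask <- d > motif$r_in & d <= motif$r_out & cosang >= motif$cap_cos
    inten <- array(1, dim(mask))
  } else if (motif$type %in% c("chromocenter", "peripheral")) {
    q <- (g$Y / motif$semi[1])^2 + (g$X / motif$semi[2])^2 + (g$Z / motif$semi[3])^2
    mask <- q <= 1
    inten <- array(1, dim(mask))
  } else { # filament with beaded intensity
    v <- motif$p1 - motif$p0
    L <- sqrt(sum(v^2)); u <- v / L
    off <- motif$p0 - (motif$p0 + motif$p1) / 2   # grid is centred mid-segment
    PY <- g$Y - off[1]; PX <- g$X - off[2]; PZ <- g$Z - off[3]
    t <- PY * u[1] + PX * u[2] + PZ * u[3]
    tc <- pmin(pmax(t, 0), L)
    d2 <- (PY - tc * u[1])^2 + (PX - tc * u[2])^2 + (PZ - tc * u[3])^2
    mask <- d2 <= motif$radius^2 & t >= 0 & t <= L
    inten <- array(0.65 + 0.35 * cos(2 * pi * tc / motif$bead_period), dim(mask))
  }
  list(lo = g$lo, hi = g$hi, mask = mask, inten = inten)
}

# --- generator ---------------------------------------------------------------

#' Generate a ground-truthed synthetic embryo-nucleus stack
#'
#' Renders the channels described by a [phantom_spec()] (DNA counterstain
#' with dark NPB voids, pericentromeric heterochromatin, centromeric and
#' telomeric marks), applies PSF blur and Poisson-Gaussian noise, and emits
#' noiseless ground-truth label maps plus an object inventory. Identical
#' specs (including seed) give bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param render When `FALSE`, only the ground-truth geometry is generated
#'   (`stacks` is `NULL`); an order of magnitude faster, for placement and
#'   calibration studies. The RNG stream differs between render modes, so
#'   truth geometries are reproducible per mode, not across modes.
#' @return A list with elements `stacks` (named list of [image_stack()]:
#'   `dna`, `pericentromere`, `centromere`, `telomere`) and `truth`, a
#'   `phantom_truth` object: `labels` (named list of [label_map()] on the
#'   pre-blur geometry), `inventory` (tibble: nucleus, channel, label,
#'   class, volume_um3, centroid), and the generating `spec`.
#' @export
generate_phantom <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  sp <- rep(spec$spacing, 3)
  semi <- spec$nucleus_semiaxes
  # stack extent: nuclei side by side along x when n_nuclei > 1
  ext_y <- 2 * (semi[1] + spec$margin)
  ext_x <- 2 * (semi[2] + spec$margin) * spec$n_nuclei
  ext_z <- 2 * (semi[3] + spec$margin)
  dims <- as.integer(ceiling(c(ext_y, ext_x, ext_z) / sp)) + 1L

  ch_names <- c("dna", "pericentromere", "centromere", "telomere")
  img <- NULL
  if (render) {
    img <- lapply(ch_names, function(ch) array(spec$background, dims))
    names(img) <- ch_names
    img$pericentromere[] <- spec$background * 0.6
    img$centromere[] <- spec$background * 0.6
    img$telomere[] <- spec$background * 0.6
  }
  truth <- lapply(ch_names, function(ch) array(0L, dims))
  names(truth) <- ch_names
  truth$npb <- array(0L, dims)

  inv <- list()
  next_label <- stats::setNames(rep(0L, 5), c(ch_names, "npb"))
  add_truth <- function(channel, mask_info, class, nucleus) {
    next_label[channel] <<- next_label[channel] + 1L
    lab <- next_label[channel]
    sel <- mask_info$mask & crop_array(truth[[channel]],
                                       list(lo = mask_info$lo, hi = mask_info$hi)) == 0L
    sub <- crop_array(truth[[channel]], list(lo = mask_info$lo, hi = mask_info$hi))
    sub[sel] <- lab
    truth[[channel]] <<- uncrop_assign(truth[[channel]], sub,
                                       list(lo = mask_info$lo, hi = mask_info$hi))
    nvox <- sum(sel)
    idx <- which(sel)
    cen <- if (nvox > 0) {
      ai <- arrayInd(idx, dim(sel))
      colMeans(sweep(ai - 1 + matrix(mask_info$lo - 1, nvox, 3, byrow = TRUE),
                     2, sp, `*`))
    } else c(NA_real_, NA_real_, NA_real_)
    inv[[length(inv) + 1L]] <<- tibble::tibble(
      nucleus = nucleus, channel = channel, label = lab, class = class,
      volume_um3 = nvox * prod(sp), cy = cen[1], cx = cen[2], cz = cen[3])
    lab
  }

  for (nuc in seq_len(spec$n_nuclei)) {
    center <- c(semi[1] + spec$margin,
                (2 * nuc - 1) * (semi[2] + spec$margin),
                semi[3] + spec$margin)

    # nucleus body
    nuc_mask_info <- {
      lo <- pmax(floor((center - semi - 0.1) / sp) + 1, 1)
      hi <- pmin(ceiling((center + semi + 0.1) / sp) + 1, dims)
      sd3 <- hi - lo + 1
      f <- ellipsoid_field(sd3, sp, center - (lo - 1) * sp, semi)
      list(lo = lo, hi = hi, mask = f <= 1)
    }
    add_truth("dna", nuc_mask_info, "nucleus", nuc)

    # smooth DNA texture inside the nucleus
    if (render) {
      tex <- array(stats::rnorm(prod(nuc_mask_info$hi - nuc_mask_info$lo + 1)),
                   nuc_mask_info$hi - nuc_mask_info$lo + 1)
      tex <- gaussian_blur(tex, 0.5 / sp)
      tex <- tex / max(stats::sd(tex), 1e-9) * spec$texture_sd
      sub <- crop_array(img$dna, nuc_mask_info)
      sub[nuc_mask_info$mask] <- spec$nucleus_mean + tex[nuc_mask_info$mask]
      img$dna <- uncrop_assign(img$dna, sub, nuc_mask_info)
    }

    # --- NPBs: dark spherical voids, non-overlapping, fully inside ----------
    npbs <- list()
    if (spec$n_npbs > 0) {
      # draw all radii, place largest first (greatly improves packing)
      radii <- sort(stats::runif(spec$n_npbs, spec$npb_radius_range[1],
                                 spec$npb_radius_range[2]), decreasing = TRUE)
      for (k in seq_len(spec$n_npbs)) {
        r <- radii[k]
        pos <- place_reject(
          propose = function() {
            u <- rvmf(1, c(0, 0, 1), 0)[1, ]
            fmax <- 1 - (r + 0.3) / ellipsoid_radius(u, semi)
            if (fmax <= 0) return(NULL)
            f <- stats::runif(1)^(1 / 3) * fmax
            center + f * ellipsoid_radius(u, semi) * u
          },
          accept = function(p, relax = 1) {
            if (is.null(p)) return(FALSE)
            for (o in npbs) if (sqrt(sum((p - o$center)^2)) < r + o$r + 0.3 * relax) return(FALSE)
            TRUE
          },
          what = sprintf("NPB #%d of nucleus %d", k, nuc))
        npbs[[k]] <- list(center = pos, r = r)
        gi <- local_grid(dims, sp, pos, r)
        m <- list(lo = gi$lo, hi = gi$hi, mask = gi$Y^2 + gi$X^2 + gi$Z^2 <= r^2)
        add_truth("npb", m, "npb", nuc)
        if (render) {
          # dark void in the DNA channel
          sub <- crop_array(img$dna, m)
          sub[m$mask] <- spec$background
          img$dna <- uncrop_assign(img$dna, sub, m)
        }
      }
    }

    # --- chromosomes: pericentromeric motif + 1 centromere + 2 telomeres ----
    kappa <- rho_to_kappa(spec$rho)
    mu <- c(0, 0, 1)                    # polarity pole (z axis)
    cen_pts <- matrix(numeric(0), ncol = 3)
    tel_pts <- matrix(numeric(0), ncol = 3)
    motif_centers <- list()
    # spot_min_sep = 0 is point-process mode: all mutual-exclusion
    # constraints are disabled so that rho = 0 mark placement is exactly
    # uniform (for calibration studies)
    exclusions_on <- spec$spot_min_sep > 0
    min_sep_cen <- if (exclusions_on) spec$spot_min_sep + 1.0 else 0
    # boundary clearance of mark centres: whole rendered spots for
    # detection phantoms; half a voxel in point-process mode, where the
    # marks stand for point locations and the null samples the full mask
    cen_clear <- if (exclusions_on) spec$spot_radius + 0.15 else 0.5 * spec$spacing

    inside_ok <- function(p, clearance) {
      q <- (p - center) / semi
      sqrt(sum(q^2)) < 1 - clearance / min(semi)
    }
    far_from_npbs <- function(p, clearance) {
      for (o in npbs) if (sqrt(sum((p - o$center)^2)) < o$r + clearance) return(FALSE)
      TRUE
    }
    sep_ok <- function(p, pts, sep) {
      nrow(pts) == 0 || min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2))) >= sep
    }

    if (spec$n_chromosomes > 0) {
      motif_types <- sample(names(spec$motif_weights), spec$n_chromosomes,
                            replace = TRUE, prob = spec$motif_weights)
      if (length(npbs) == 0)
        motif_types[motif_types %in% c("shell", "patch")] <- "chromocenter"

      for (k in seq_len(spec$n_chromosomes)) {
        ty <- motif_types[k]
        placed <- place_reject(
          propose = function() {
            u <- rvmf(1, mu, kappa)[1, ]
            if (ty %in% c("shell", "patch")) {
              # attach to the NPB whose direction best matches u
              dirs <- t(vapply(npbs, function(o) {
                d <- o$center - center; d / max(sqrt(sum(d^2)), 1e-9)
              }, numeric(3)))
              j <- which.max(dirs %*% u)
              o <- npbs[[j]]
              t_sh <- stats::runif(1, 0.5, 0.8)
              cap <- if (ty == "shell") stats::runif(1, pi / 3, pi) else
                stats::runif(1, pi / 7, pi / 4)
              cen_pos <- o$center + (o$r + t_sh + spec$spot_radius + 0.1) * u
              list(type = ty, npb_center = o$center, r_in = o$r + 0.05,
                   r_out = o$r + 0.05 + t_sh, dir = u, cap_cos = cos(cap),
                   cen = cen_pos, rough_c = o$center, rough_r = o$r + t_sh)
            } else if (ty == "chromocenter") {
              base_r <- stats::runif(1, 0.55, 1.1)
              semib <- base_r * stats::runif(3, 0.85, 1.15)
              # the centromeric mark is the primary object, placed
              # volume-uniformly along its direction (so that rho = 0 is
              # spatially random); the heterochromatin mass hangs off it
              R_u <- ellipsoid_radius(u, semi)
              fmax <- 1 - (cen_clear + 0.05) / R_u
              fr <- (stats::runif(1, 0, fmax^3))^(1 / 3)
              cen_pos <- center + fr * R_u * u
              p <- cen_pos + rvmf(1, -u, 1)[1, ] * (max(semib) + spec$spot_radius + 0.1)
              list(type = ty, center = p, semi = semib, cen = cen_pos,
                   rough_c = p, rough_r = max(semib))
            } else if (ty == "peripheral") {
              base_r <- stats::runif(1, 0.4, 0.75)
              semib <- base_r * stats::runif(3, 0.85, 1.15)
              fr <- stats::runif(1, 0.78, 0.92)
              p <- center + fr * ellipsoid_radius(u, semi) * u
              cen_pos <- p - u * (max(semib) + spec$spot_radius + 0.1)
              list(type = ty, center = p, semi = semib, cen = cen_pos,
                   rough_c = p, rough_r = max(semib))
            } else { # filament
              L <- stats::runif(1, 2, 4)
              fr <- stats::runif(1, 0.45, 0.85)
              p0 <- center + fr * ellipsoid_radius(u, semi) * u
              ax <- rvmf(1, -u, 3)[1, ]
              p1 <- p0 + L * ax
              cen_pos <- p0 - (spec$spot_radius + 0.35) * ax
              list(type = ty, p0 = p0, p1 = p1, radius = stats::runif(1, 0.25, 0.35),
                   bead_period = 0.55, cen = cen_pos,
                   rough_c = (p0 + p1) / 2, rough_r = L / 2)
            }
          },
          accept = function(m, relax = 1) {
            if (!inside_ok(m$cen, cen_clear)) return(FALSE)
            if (!far_from_npbs(m$cen, spec$spot_radius * max(relax, 0.6))) return(FALSE)
            if (!sep_ok(m$cen, cen_pts, min_sep_cen * relax)) return(FALSE)
            # keep room for this chromosome's proximal telomere
            if (exclusions_on &&
                !sep_ok(m$cen, tel_pts, (spec$spot_min_sep + 0.5) * relax)) return(FALSE)
            if (exclusions_on && m$type %in% c("chromocenter", "peripheral", "filament")) {
              # peripheral foci hug the envelope (they are clipped to the
              # nucleus at rasterization), so only half their radius is
              # required as clearance
              clr <- if (m$type == "peripheral") 0.5 else 1
              if (m$type != "filament" && !inside_ok(m$rough_c, m$rough_r * clr)) return(FALSE)
              if (m$type == "filament" &&
                  !(inside_ok(m$p0, m$radius) && inside_ok(m$p1, m$radius))) return(FALSE)
              if (!far_from_npbs(m$rough_c,
                                 (if (m$type == "filament") 0 else m$rough_r) * relax)) return(FALSE)
              # distinct heterochromatin masses keep a resolvable gap; under
              # crowding the clearance relaxes and chromocenters may merge,
              # as pericentromeres of several chromosomes do in real nuclei
              if (exclusions_on)
                for (o in motif_centers)
                  if (sqrt(sum((m$rough_c - o$c)^2)) < (m$rough_r + o$r + 0.8) * relax) return(FALSE)
            }
            TRUE
          },
          what = sprintf("%s motif (chromosome %d) of nucleus %d", ty, k, nuc))

        motif_centers[[length(motif_centers) + 1L]] <-
          list(c = placed$rough_c, r = placed$rough_r)
        mi <- rasterize_motif(placed, dims, sp)
        if (!is.null(mi)) {
          # clip motif to the nucleus ellipsoid
          gi2 <- ellipsoid_field(mi$hi - mi$lo + 1, sp,
                                 center - (mi$lo - 1) * sp, semi)
          mi$mask <- mi$mask & gi2 <= 1
          add_truth("pericentromere", mi, placed$type, nuc)
          if (render) {
            sub <- crop_array(img$pericentromere, mi)
            inten <- mi$inten
            if (spec$speckle_sd > 0)
              inten <- inten * pmax(1 + spec$speckle_sd * speckle_field(dim(inten)), 0.2)
            sub[mi$mask] <- sub[mi$mask] + spec$peri_peak * inten[mi$mask]
            img$pericentromere <- uncrop_assign(img$pericentromere, sub, mi)
            # pericentromeric heterochromatin is DNA-dense: echo into DNA channel
            sub <- crop_array(img$dna, mi)
            sub[mi$mask] <- sub[mi$mask] + 0.25 * spec$peri_peak * mi$inten[mi$mask]
            img$dna <- uncrop_assign(img$dna, sub, mi)
          }
        }

        # centromere mark
        cen_pts <- rbind(cen_pts, placed$cen)
        gi <- local_grid(dims, sp, placed$cen, spec$spot_radius)
        in_nuc <- ellipsoid_field(gi$dims, sp, center - (gi$lo - 1) * sp, semi) <= 1
        add_truth("centromere",
                  list(lo = gi$lo, hi = gi$hi,
                       mask = (gi$Y^2 + gi$X^2 + gi$Z^2 <= spec$spot_radius^2) & in_nuc),
                  "centromere", nuc)
        if (render)
          img$centromere <- add_spot(img$centromere, sp, placed$cen,
                                     spec$spot_radius, spec$spot_peak,
                                     speckle_sd = spec$speckle_sd)

        # proximal telomere: adjacent to the centromeric chromosome end
        prox <- place_reject(
          propose = function() placed$cen + rvmf(1, mu, 0)[1, ] * 0.45,
          accept = function(p, relax = 1) inside_ok(p, cen_clear) &&
            sep_ok(p, tel_pts, spec$spot_min_sep * relax),
          what = sprintf("proximal telomere (chromosome %d) of nucleus %d", k, nuc))
        # distal telomere: opposite pole under polarity (Rabl-like)
        dist_tel <- place_reject(
          propose = function() {
            u <- rvmf(1, -mu, kappa)[1, ]
            f <- stats::runif(1, 0.35, 0.9)
            center + f * ellipsoid_radius(u, semi) * u
          },
          accept = function(p, relax = 1) inside_ok(p, cen_clear) &&
            far_from_npbs(p, spec$spot_radius) &&
            sep_ok(p, rbind(tel_pts, prox), spec$spot_min_sep * relax),
          what = sprintf("distal telomere (chromosome %d) of nucleus %d", k, nuc))
        for (p in list(prox, dist_tel)) {
          tel_pts <- rbind(tel_pts, p)
          gi <- local_grid(dims, sp, p, spec$spot_radius)
          in_nuc <- ellipsoid_field(gi$dims, sp, center - (gi$lo - 1) * sp, semi) <= 1
          add_truth("telomere",
                    list(lo = gi$lo, hi = gi$hi,
                         mask = (gi$Y^2 + gi$X^2 + gi$Z^2 <= spec$spot_radius^2) & in_nuc),
                    "telomere", nuc)
          if (render)
            img$telomere <- add_spot(img$telomere, sp, p,
                                     spec$spot_radius, spec$spot_peak,
                                     speckle_sd = spec$speckle_sd)
        }
      }
    }
  }

  # --- PSF blur and noise ----------------------------------------------------
  for (ch in if (render) ch_names else character(0)) {
    if (spec$psf_sigma > 0)
      img[[ch]] <- gaussian_blur(img[[ch]], spec$psf_sigma / sp)
    if (spec$poisson_gain > 0) {
      lam <- pmax(img[[ch]] * spec$poisson_gain, 0)
      img[[ch]] <- array(stats::rpois(length(lam), lam) / spec$poisson_gain, dims)
    }
    if (spec$gaussian_sd > 0)
      img[[ch]] <- img[[ch]] + array(stats::rnorm(prod(dims), 0, spec$gaussian_sd), dims)
    img[[ch]] <- pmin(pmax(img[[ch]], 0), 255)
  }

  inventory <- if (length(inv) > 0) dplyr::bind_rows(inv) else
    tibble::tibble(nucleus = integer(), channel = character(), label = integer(),
                   class = character(), volume_um3 = double(),
                   cy = double(), cx = double(), cz = double())

  stacks <- NULL
  if (render) {
    stacks <- lapply(ch_names, function(ch)
      image_stack(img[[ch]], sp, channel = ch))
    names(stacks) <- ch_names
  }
  labels <- lapply(truth, function(t) label_map(t, sp))
  list(
    stacks = stacks,
    truth = structure(list(labels = labels, inventory = inventory, spec = spec),
                      class = "phantom_truth")
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth>\n")
  print(dplyr::count(x$inventory, .data$channel, .data$class))
  invisible(x)
}
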