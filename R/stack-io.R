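#' Single-channel 3D image stack
#'
#' Container for one channel of a confocal z-stack: a 3D numeric array of
#' voxel intensities with physical voxel spacing and a channel role. Arrays
#' are stored column-major with `dim = (ny, nx, nz)` (slice-last), voxel
#' centres at `(index - 1) * spacing` micrometres.
#'
#' @param voxels 3D numeric array, `dim = (ny, nx, nz)`.
#' @param spacing Numeric length-3, voxel spacing in micrometres in the same
#'   dimension order as `voxels`, i.e. `(sy, sx, sz)`.
#' @param channel Channel role, one of `"dna"`, `"pericentromere"`,
#'   `"centromere"`, `"telomere"`, `"rdna"`, `"other"`.
#' @param bit_depth Nominal acquisition bit depth (8 for the supported
#'   confocal data; intensities themselves are stored as doubles).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, channel = "other", bit_depth = 8L) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (um)")
  channel <- match.arg(channel, c("dna", "pericentromere", "centromere",
                                  "telomere", "rdna", "other"))
  structure(
    list(voxels = voxels, spacing = spacing, channel = channel,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s channel, %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              x$channel, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Labelled 3D objects on a voxel grid
#'
#' Integer array of the same shape as an [image_stack()], with 0 =
#' background and positive integers labelling objects.
#'
#' @param labels 3D integer array.
#' @param spacing Voxel spacing (um), `(sy, sx, sz)`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (um)")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be non-negative")
  structure(list(labels = labels, spacing = spacing), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d object(s), %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              max(x$labels), d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Map stack channel indices to channel roles
#'
#' @param ... Named integer arguments, e.g. `dna = 1, pericentromere = 2`.
#'   Exactly one channel must be mapped to `dna`.
#' @return A named integer vector of class `channel_map`.
#' @export
channel_map <- function(...) {
  m <- c(...)
  if (is.null(names(m)) || any(names(m) == ""))
    stop("all channel_map entries must be named by role")
  roles <- c("dna", "pericentromere", "centromere", "telomere", "rdna", "other")
  bad <- setdiff(names(m), roles)
  if (length(bad) > 0)
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (sum(names(m) == "dna") != 1L)
    stop("exactly one channel must be mapped to the dna role")
  if (anyDuplicated(m)) stop("channel indices must be distinct")
  structure(as.integer(m), names = names(m), class = "channel_map")
}

# Extract spacing (um) from a TIFF description string if possible.
# Understands the OME PhysicalSize attributes and the ImageJ "spacing=" key
# (z step) plus x/y resolution tags.
parse_tiff_spacing <- function(info) {
  desc <- info$description %||% ""
  num <- function(pat) {
    m <- regmatches(desc, regexpr(pat, desc, perl = TRUE))
    if (length(m) == 0) return(NA_real_)
    as.numeric(sub(pat, "\\1", m, perl = TRUE))
  }
  sx <- num('PhysicalSizeX="([0-9.eE+-]+)"')
  sy <- num('PhysicalSizeY="([0-9.eE+-]+)"')
  sz <- num('PhysicalSizeZ="([0-9.eE+-]+)"')
  if (is.na(sz)) sz <- num("spacing=([0-9.eE+-]+)")
  if ((is.na(sx) || is.na(sy)) && !is.null(info$x.resolution) &&
      isTRUE(info$x.resolution > 0)) {
    # TIFF resolution = pixels per unit; ImageJ writes micrometre units
    unit_ok <- is.null(info$resolution.unit) || info$resolution.unit %in% c("none", 1L)
    if (unit_ok) {
      sx <- 1 / info$x.resolution
      sy <- if (!is.null(info$y.resolution) && isTRUE(info$y.resolution > 0))
        1 / info$y.resolution else sx
    }
  }
  c(sy, sx, sz)
}

#' Read a multichannel TIFF / OME-TIFF z-stack
#'
#' Pages are read as z-slices. Multichannel data may be stored either as
#' multi-sample pages (RGB-style) or as channel-interleaved pages
#' (c fastest, as written by [write_stack()] for multichannel input).
#' Original intensities are passed through unmodified.
#'
#' @param path TIFF file path.
#' @param channels A [channel_map()] assigning a role to each channel index.
#' @param spacing_override Optional `(sy, sx, sz)` um, used when the file
#'   carries no spacing metadata (and taking precedence when it does).
#' @return A named list of [image_stack()] objects, one per mapped channel.
#' @export
read_stack <- function(path, channels, spacing_override = NULL) {
  if (!inherits(channels, "channel_map")) stop("`channels` must be a channel_map")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  spacing <- if (!is.null(spacing_override)) as.double(spacing_override)
             else parse_tiff_spacing(info)
  if (any(is.na(spacing))) spacing <- read_spacing_sidecar(path)
  if (length(spacing) != 3L || any(is.na(spacing)) || any(spacing <= 0))
    stop("no voxel spacing in TIFF metadata or sidecar and no `spacing_override` given")

  nc <- length(channels)
  first <- pages[[1]]
  if (length(dim(first)) == 3L) {
    # samples-per-pixel layout: each page is (y, x, s)
    ns <- dim(first)[3]
    if (max(unclass(channels)) > ns)
      stop(sprintf("channel map addresses channel %d but file has %d sample(s)",
                   max(unclass(channels)), ns))
    nz <- length(pages)
    out <- lapply(seq_along(channels), function(i) {
      ch <- unclass(channels)[i]
      vox <- vapply(pages, function(p) p[, , ch], first[, , 1])
      image_stack(vox, spacing, channel = names(channels)[i],
                  bit_depth = info$bits.per.sample %||% 8L)
    })
  } else {
    if (length(pages) %% nc != 0L)
      stop(sprintf("page count (%d) is not a multiple of the channel count (%d)",
                   length(pages), nc))
    nz <- length(pages) %/% nc
    out <- lapply(seq_along(channels), function(i) {
      ch <- unclass(channels)[i]
      sel <- pages[seq(ch, length(pages), by = nc)]
      vox <- vapply(sel, identity, first)
      image_stack(vox, spacing, channel = names(channels)[i],
                  bit_depth = info$bits.per.sample %||% 8L)
    })
  }
  names(out) <- names(channels)
  out
}

# Spacing sidecar: the linked libtiff writer exposes no description or
# resolution tags, so physical spacing is stored in a small JSON file next
# to the TIFF; read_stack()/read_label_map() fall back to it when the TIFF
# itself carries no spacing metadata.
sidecar_path <- function(path) paste0(path, ".meta.json")

write_spacing_sidecar <- function(path, spacing, channels = NULL) {
  meta <- list(spacing_um = as.double(spacing), axis_order = "yxz")
  if (!is.null(channels)) meta$channels <- channels
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_spacing_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) return(rep(NA_real_, 3))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  as.double(meta$spacing_um)
}

#' Write an image stack (or a multichannel set) as multi-page TIFF
#'
#' Intensities are stored as 16-bit samples (losslessly for integer-valued
#' data in `[0, 65535]`). Voxel spacing is recorded in a JSON sidecar
#' (`<path>.meta.json`) so that [read_stack()] can recover it.
#'
#' @param stacks A single [image_stack()] or list of them (same grid);
#'   multichannel sets are written channel-interleaved (c fastest).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stacks, path) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  spacing <- stacks[[1]]$spacing
  d <- dim(stacks[[1]]$voxels)
  for (s in stacks) stopifnot(identical(dim(s$voxels), d))
  pages <- list()
  for (k in seq_len(d[3]))
    for (s in stacks)
      pages[[length(pages) + 1L]] <- s$voxels[, , k] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  write_spacing_sidecar(path, spacing,
                        channels = vapply(stacks, `[[`, character(1), "channel"))
  invisible(path)
}

#' Write / read a label map as 16-bit TIFF (lossless round trip)
#'
#' @param lm A [label_map()].
#' @param path File path.
#' @rdname label_map_io
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  if (max(lm$labels) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  d <- dim(lm$labels)
  pages <- lapply(seq_len(d[3]), function(k) lm$labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  write_spacing_sidecar(path, lm$spacing)
  invisible(path)
}

#' @param spacing Spacing override for reading (um), if the file lacks metadata.
#' @rdname label_map_io
#' @export
read_label_map <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sp <- if (!is.null(spacing)) as.double(spacing) else parse_tiff_spacing(attributes(pages[[1]]))
  if (any(is.na(sp))) sp <- read_spacing_sidecar(path)
  if (length(sp) != 3L || any(is.na(sp)) || any(sp <= 0))
    stop("no voxel spacing in TIFF metadata or sidecar and no `spacing` given")
  vox <- vapply(pages, identity, pages[[1]])
  label_map(array(as.integer(round(vox * 65535)), dim(vox)), sp)
}

#' Resample a stack to the isotropic analysis grid
#'
#' Confocal stacks are acquired with a coarser z-step than the xy pixel
#' size; the whole pipeline runs on an isotropic grid at the xy spacing.
#' z-planes are interpolated (linearly for intensities) to that spacing; xy
#' sampling is unchanged. For the nominal acquisition geometry
#' (0.1236 um xy, 0.371 um z) this triples the number of z-planes.
#' Already-isotropic input is returned unchanged.
#'
#' @param stack An [image_stack()].
#' @param method `"linear"` (intensities) or `"nearest"` (labels).
#' @return An [image_stack()] with equal spacing on all axes.
#' @export
resample_isotropic <- function(stack, method = c("linear", "nearest")) {
  method <- match.arg(method)
  sp <- stack$spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * sp[1])
    stop("xy spacing must already be equal; got ", sp[1], " x ", sp[2])
  if (abs(sp[3] - sp[1]) <= 1e-9 * sp[1]) return(stack)
  d <- dim(stack$voxels)
  target <- sp[1]
  nz_out <- max(1L, as.integer(round(d[3] * sp[3] / target)))
  # output plane k (0-based) sits at k * target um along z
  zpos <- (seq_len(nz_out) - 1) * target / sp[3]      # in input plane units
  zpos <- pmin(pmax(zpos, 0), d[3] - 1)
  lo <- pmin(floor(zpos), d[3] - 1)
  w <- zpos - lo
  hi <- pmin(lo + 1, d[3] - 1)
  out <- array(0, c(d[1], d[2], nz_out))
  if (method == "linear") {
    for (k in seq_len(nz_out)) {
      out[, , k] <- (1 - w[k]) * stack$voxels[, , lo[k] + 1] +
        w[k] * stack$voxels[, , hi[k] + 1]
    }
  } else {
    for (k in seq_len(nz_out)) {
      src <- if (w[k] < 0.5) lo[k] else hi[k]
      out[, , k] <- stack$voxels[, , src + 1]
    }
  }
  image_stack(out, c(target, target, target), channel = stack$channel,
              bit_depth = stack$bit_depth)
}

#' Write pipeline outputs with a JSON manifest
#'
#' Label maps are written as 16-bit TIFF aligned voxel-for-voxel with the
#' analysis grid; tables as CSV; a manifest JSON lists every file together
#' with a hash of the configuration and the package version.
#'
#' @param labelmaps Named list of [label_map()] objects (may be empty).
#' @param tables Named list of data frames (may be empty).
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration list recorded (hashed) in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(labelmaps = list(), tables = list(), out_dir,
                          config = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  files <- character(0)
  for (nm in names(labelmaps)) {
    f <- file.path(out_dir, paste0(nm, ".tif"))
    write_label_map(labelmaps[[nm]], f)
    files <- c(files, f)
  }
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    files = basename(files),
    config_hash = sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                        seq_along(utf8ToInt(as.character(cfg_json)))) %% 0xFFFFFFF),
    package = "nucorg3d",
    version = as.character(utils::packageVersion("nucorg3d"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
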