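#' Pipeline configuration
#'
#' Nested configuration of every stage, serializable to/from YAML. All
#' thresholds are in physical units (um, um^2, um^3).
#'
#' @param nucleus,signals,npb,shape,interaction,polarity Named lists
#'   overriding individual defaults of each block.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(nucleus = list(), signals = list(), npb = list(),
                            shape = list(), interaction = list(),
                            polarity = list()) {
  def <- list(
    nucleus = list(min_volume_um3 = 50, smooth_radius_um = 0.5,
                   f_bounds = c(1, 2)),
    signals = list(median_radius_px = 1, peak_threshold_k = 3.3,
                   bright_sigma = 1.24, min_signal_volume = 0.123,
                   split_volume = 1.90, flatness_max = 3, volume_gate = 1,
                   max_spots = 40, small_fraction = 0.01,
                   apply_bright_gate = FALSE, telomere_max_spots = 80),
    npb = list(gradient_sigma = 0.62, min_volume = 0.23, split_volume = 94.5,
               min_sphericity = 0.5, otsu_mode = "slice2d",
               contour_thickness = 2, smooth_radius = 0.25),
    shape = list(surface_sigma = 0.5, roundness_min = 0.8, volume_min = 0.47),
    interaction = list(dilation_um = 0.37, breaks = c(0.1, 0.5, 1)),
    polarity = list(n_patterns = 500, alpha = 0.01, seed = 1)
  )
  override <- list(nucleus = nucleus, signals = signals, npb = npb,
                   shape = shape, interaction = interaction,
                   polarity = polarity)
  for (blk in names(def)) {
    bad <- setdiff(names(override[[blk]]), names(def[[blk]]))
    if (length(bad) > 0)
      stop("unknown config key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
    def[[blk]][names(override[[blk]])] <- override[[blk]]
  }
  structure(def, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("nucleus", "signals", "npb", "shape", "interaction", "polarity")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config block(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' @param config A `pipeline_config`.
#' @rdname pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

signal_cfg_from <- function(config, channel = "centromere") {
  s <- config$signals
  signal_seg_config(
    median_radius_px = s$median_radius_px, peak_threshold_k = s$peak_threshold_k,
    bright_sigma = s$bright_sigma, min_signal_volume = s$min_signal_volume,
    split_volume = s$split_volume, flatness_max = s$flatness_max,
    volume_gate = s$volume_gate,
    max_spots = if (channel == "telomere") s$telomere_max_spots else s$max_spots,
    small_fraction = s$small_fraction, apply_bright_gate = s$apply_bright_gate)
}

npb_cfg_from <- function(config) {
  n <- config$npb
  npb_config(gradient_sigma = n$gradient_sigma, min_volume = n$min_volume,
             split_volume = n$split_volume, min_sphericity = n$min_sphericity,
             otsu_mode = n$otsu_mode, contour_thickness = n$contour_thickness,
             smooth_radius = n$smooth_radius)
}

#' Analyse one nucleus ROI
#'
#' Runs NPB segmentation and refinement, FISH signal segmentation for every
#' available channel, shape statistics, pericentromere classification,
#' interaction scoring and the polarity test on one cropped nucleus.
#'
#' @param roi A `nucleus_roi` with channels attached ([crop_channels()]).
#' @param config A [pipeline_config()].
#' @param stage Stage label recorded in the outputs.
#' @return A list: `labels` (per-channel [label_map()]s), `shapes`
#'   (tibble), `interactions` (tibble), `polarity`
#'   (`polarity_result` or `NULL`), `summary` (one-row tibble), `qc`.
#' @export
analyze_nucleus <- function(roi, config = pipeline_config(),
                            stage = NA_character_) {
  stopifnot(inherits(roi, "nucleus_roi"))
  if (length(roi$channels) == 0L) stop("roi has no channels; run crop_channels() first")
  sp <- roi$spacing
  vv <- voxel_volume(sp)
  qc <- "ok"
  labels <- list()
  shapes <- list()

  dna <- roi$channels$dna
  if (!is.null(dna)) {
    npbs <- segment_npbs(dna, roi, npb_cfg_from(config))
    npb_shapes <- shape_stats(npbs, config$shape$surface_sigma)
    npbs <- refine_npbs(npbs, npb_shapes, npb_cfg_from(config))
    labels$npb <- npbs
    if (max(npbs$labels) > 0) {
      s <- shape_stats(npbs, config$shape$surface_sigma)
      shapes$npb <- dplyr::mutate(s, channel = "npb")
    } else qc <- "no_npb"
  }

  if (!is.null(roi$channels$pericentromere)) {
    peri <- segment_pericentromeres(roi$channels$pericentromere, roi,
                                    signal_cfg_from(config, "pericentromere"))
    labels$pericentromere <- peri
    if (max(peri$labels) > 0) {
      s <- shape_stats(peri, config$shape$surface_sigma)
      s <- classify_pericentromere(s, config$shape$roundness_min,
                                   config$shape$volume_min)
      shapes$pericentromere <- dplyr::mutate(s, channel = "pericentromere")
    }
  }
  for (ch in c("centromere", "telomere")) {
    if (is.null(roi$channels[[ch]])) next
    lm <- segment_spots(roi$channels[[ch]], roi, signal_cfg_from(config, ch))
    labels[[ch]] <- lm
    if (max(lm$labels) > 0)
      shapes[[ch]] <- dplyr::mutate(
        shape_stats(lm, config$shape$surface_sigma), channel = ch)
  }

  interactions <- NULL
  if (!is.null(labels$pericentromere) && !is.null(labels$npb) &&
      max(labels$pericentromere$labels) > 0 && max(labels$npb$labels) > 0)
    interactions <- score_interactions(labels$pericentromere, labels$npb,
                                       config$interaction$dilation_um,
                                       config$interaction$breaks)

  polarity <- NULL
  if (!is.null(shapes$centromere) && nrow(shapes$centromere) > 0) {
    pts <- as.matrix(shapes$centromere[, c("cy", "cx", "cz")])
    polarity <- polarity_test(roi$mask, pts, sp,
                              n_patterns = config$polarity$n_patterns,
                              seed = config$polarity$seed + roi$label,
                              nucleus_id = roi$label)
  }

  shape_tbl <- if (length(shapes)) dplyr::bind_rows(shapes) else
    tibble::tibble()
  npb_vols <- if (!is.null(shapes$npb)) shapes$npb$volume_um3 else numeric(0)
  peri_cls <- if (!is.null(shapes$pericentromere)) shapes$pericentromere$class else
    factor(character(), levels = c("compact", "elongated", "not_analyzed"))
  analyzed <- peri_cls[peri_cls != "not_analyzed"]
  cat_counts <- if (!is.null(interactions))
    table(interactions$category) else
    table(factor(character(), levels = c("Null", "Close", "Low", "Medium", "Strong")))
  summary <- tibble::tibble(
    nucleus = roi$label, stage = stage,
    nuclear_volume_um3 = roi$volume_um3,
    npb_count = length(npb_vols),
    npb_volume_median = if (length(npb_vols)) stats::median(npb_vols) else NA_real_,
    npb_volume_q1 = if (length(npb_vols)) stats::quantile(npb_vols, 0.25, names = FALSE) else NA_real_,
    npb_volume_q3 = if (length(npb_vols)) stats::quantile(npb_vols, 0.75, names = FALSE) else NA_real_,
    npb_relative_volume_pct = 100 * sum(npb_vols) / roi$volume_um3,
    peri_count = length(peri_cls),
    peri_compact = sum(peri_cls == "compact"),
    peri_elongated = sum(peri_cls == "elongated"),
    peri_not_analyzed = sum(peri_cls == "not_analyzed"),
    compact_fraction = if (length(analyzed)) mean(analyzed == "compact") else NA_real_,
    interactions_null = unname(cat_counts["Null"]),
    interactions_close = unname(cat_counts["Close"]),
    interactions_low = unname(cat_counts["Low"]),
    interactions_medium = unname(cat_counts["Medium"]),
    interactions_strong = unname(cat_counts["Strong"]),
    polarity_d = if (!is.null(polarity)) polarity$d else NA_real_,
    polarity_p = if (!is.null(polarity)) polarity$p_value else NA_real_,
    qc = qc
  )
  list(labels = labels, shapes = shape_tbl, interactions = interactions,
       polarity = polarity, summary = summary, qc = qc)
}

#' Run the full pipeline on a stack set or a phantom spec
#'
#' Orchestrates reading/generation, isotropic resampling, nucleus
#' extraction, per-nucleus NPB/signal segmentation, morphometry,
#' interaction scoring and polarity testing, and (optionally) writes label
#' maps, CSV tables and a JSON manifest.
#'
#' @param input Either a named list of [image_stack()] objects (names are
#'   channel roles; `dna` required) or a [phantom_spec()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param stage Stage label attached to all outputs (for a phantom input,
#'   defaults to the spec's stage).
#' @return A list of class `nucorg_run`: `summaries` (one row per
#'   nucleus), `shapes`, `interactions`, `polarity` (tibble), `rois`,
#'   `nucleus_labels` ([label_map()] of nuclei on the full grid),
#'   `per_nucleus` (raw per-nucleus results), `background`, `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         stage = NULL) {
  if (inherits(input, "phantom_spec")) {
    stage <- stage %||% input$stage
    input <- generate_phantom(input)$stacks
  }
  stage <- stage %||% NA_character_
  if (!is.list(input) || is.null(input$dna))
    stop("input must contain a 'dna' channel stack")
  stacks <- lapply(input, resample_isotropic)
  dna <- stacks$dna
  sp <- dna$spacing

  bg <- estimate_background(dna)
  mask <- nucleus_mask(dna, bg)
  rois <- extract_nuclei(mask, sp, config$nucleus$min_volume_um3,
                         config$nucleus$smooth_radius_um)
  nuc_labels <- array(0L, dim3(dna$voxels))
  for (r in rois) {
    sub <- crop_array(nuc_labels, r$bbox)
    sub[r$mask] <- r$label
    nuc_labels <- uncrop_assign(nuc_labels, sub, r$bbox)
  }

  per_nucleus <- lapply(rois, function(r) {
    r <- crop_channels(r, stacks)
    analyze_nucleus(r, config, stage = stage)
  })

  summaries <- if (length(per_nucleus))
    dplyr::bind_rows(lapply(per_nucleus, `[[`, "summary")) else tibble::tibble()
  shapes <- dplyr::bind_rows(lapply(seq_along(per_nucleus), function(i) {
    s <- per_nucleus[[i]]$shapes
    if (nrow(s) > 0) dplyr::mutate(s, nucleus = i) else s
  }))
  interactions <- dplyr::bind_rows(lapply(seq_along(per_nucleus), function(i) {
    s <- per_nucleus[[i]]$interactions
    if (!is.null(s)) dplyr::mutate(s, nucleus = i) else NULL
  }))
  polarity <- dplyr::bind_rows(lapply(per_nucleus, function(x)
    if (!is.null(x$polarity)) tidy(x$polarity) else NULL))

  out <- structure(list(
    summaries = summaries, shapes = shapes, interactions = interactions,
    polarity = polarity, rois = rois,
    nucleus_labels = label_map(nuc_labels, sp),
    per_nucleus = per_nucleus, background = bg, config = config
  ), class = "nucorg_run")

  if (!is.null(out_dir)) {
    lms <- list(nuclei = out$nucleus_labels)
    tbls <- list(nucleus_summaries = summaries)
    if (nrow(shapes) > 0) tbls$objects <- shapes
    if (nrow(interactions) > 0) tbls$interactions <- interactions
    if (nrow(polarity) > 0) tbls$polarity <- polarity
    write_outputs(lms, tbls, out_dir, config = unclass(config))
  }
  out
}

#' @export
print.nucorg_run <- function(x, ...) {
  cat(sprintf("<nucorg_run> %d nucleus(ei)\n", nrow(x$summaries)))
  if (nrow(x$summaries) > 0)
    print(x$summaries[, c("nucleus", "nuclear_volume_um3", "npb_count",
                          "peri_count", "compact_fraction", "polarity_p", "qc")])
  invisible(x)
}

#' @export
glance.nucorg_run <- function(x, ...) {
  tibble::tibble(
    n_nuclei = nrow(x$summaries),
    mean_nuclear_volume_um3 = mean(x$summaries$nuclear_volume_um3),
    mean_npb_count = mean(x$summaries$npb_count),
    mean_compact_fraction = mean(x$summaries$compact_fraction, na.rm = TRUE))
}

#' Pairwise Wilcoxon rank-sum comparison of adjacent stages
#'
#' Two-sided rank-sum tests between adjacent stage pairs (in factor-level
#' or first-appearance order). p-values are reported unadjusted by
#' default, matching common practice of reporting raw Wilcoxon p-values
#' per comparison; a Holm correction is available.
#'
#' @param data A data frame with a stage column and a value column.
#' @param value Name of the numeric column to compare.
#' @param stage Name of the grouping column (default `"stage"`).
#' @param adjust p-value adjustment method (`"none"` default, or any
#'   [stats::p.adjust()] method such as `"holm"`).
#' @return A tibble with one row per adjacent pair: `stage1`, `stage2`,
#'   `n1`, `n2`, `statistic`, `p_value`.
#' @export
compare_stages <- function(data, value, stage = "stage", adjust = "none") {
  stopifnot(value %in% names(data), stage %in% names(data))
  g <- data[[stage]]
  lv <- if (is.factor(g)) levels(g) else unique(as.character(g))
  lv <- lv[lv %in% as.character(g)]
  if (length(lv) < 2L) stop("at least 2 stage groups are required")
  vals <- lapply(lv, function(s) {
    v <- data[[value]][as.character(g) == s]
    v[!is.na(v)]
  })
  ns <- lengths(vals)
  if (any(ns < 3L))
    stop("every stage group needs at least 3 values; too small: ",
         paste(lv[ns < 3L], collapse = ", "))
  rows <- lapply(seq_len(length(lv) - 1L), function(i) {
    x <- vals[[i]]; y <- vals[[i + 1L]]
    if (length(unique(c(x, y))) == 1L) {
      warning("all values tied between ", lv[i], " and ", lv[i + 1L],
              "; p-value computed with tie correction")
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
    }
    tibble::tibble(stage1 = lv[i], stage2 = lv[i + 1L],
                   n1 = length(x), n2 = length(y),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out
}
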