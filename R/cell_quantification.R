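#' Illumination correction and denoising of a fluorescence section
#'
#' Morphological white top-hat with a disc structuring element removes
#' background varying on scales larger than `tophat_radius` (uneven
#' illumination), then a 2-D median filter suppresses shot noise. Input and
#' output are 8-bit-range numeric matrices (0-255).
#'
#' @param img Numeric matrix, intensities in 0-255.
#' @param tophat_radius Disc radius of the structuring element (px);
#'   should exceed the cell radius or cells are attenuated (warned).
#' @param median_size Median-filter window half-width (px); 1 gives the
#'   classic 3 x 3 filter.
#' @param cell_radius Nominal cell radius used only for the warning check.
#' @return The processed matrix, clipped to `[0, 255]`.
#' @export
preprocess_image <- function(img, tophat_radius = 25, median_size = 1,
                             cell_radius = 6) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  if (min(img) < 0 || max(img) > 255) {
    stop("`img` must be in the 8-bit range [0, 255]", call. = FALSE)
  }
  if (tophat_radius <= cell_radius) {
    warning("tophat_radius <= cell_radius: cells will be attenuated")
  }
  x <- EBImage::Image(img / 255)
  brush_size <- 2L * as.integer(tophat_radius) + 1L
  x <- EBImage::whiteTopHat(x, EBImage::makeBrush(brush_size, shape = "disc"))
  x <- EBImage::medianFilter(x, as.integer(median_size))
  out <- EBImage::imageData(x) * 255
  pmin(pmax(out, 0), 255)
}

#' Segment and count labeled nuclei
#'
#' Binarizes the (preprocessed) image at pixels strictly greater than
#' `threshold`, removes connected components smaller than `min_area`, and
#' splits touching nuclei by watershed on the distance transform (with an
#' h-maxima tolerance to avoid over-segmentation). The count is the number
#' of final labels.
#'
#' @param img Numeric matrix (0-255), typically from [preprocess_image()].
#' @param threshold Intensity threshold; pixels `> threshold` are foreground
#'   (default 50).
#' @param min_area Minimum component area in px (default 20).
#' @param watershed_h Height tolerance of the watershed on the distance
#'   transform (px, default 1): neighbouring distance-map maxima closer in
#'   height than this are merged, which suppresses over-segmentation while
#'   still splitting nuclei overlapping by ~30% of a radius.
#' @return A list: `labels` (integer matrix), `count`, `centroids`
#'   (data.frame `x`, `y` in matrix row/col coordinates).
#' @export
segment_nuclei <- function(img, threshold = 50, min_area = 20,
                           watershed_h = 1) {
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  }
  mask <- img > threshold
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(img), ncol(img)), count = 0L,
                centroids = data.frame(x = numeric(0), y = numeric(0))))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_h, ext = 1)
  lab <- EBImage::imageData(lab)
  # drop fragments below the area floor, then relabel compactly
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  lab[!(lab %in% keep)] <- 0L
  relab <- match(lab, c(0L, keep)) - 1L
  lab <- matrix(as.integer(relab), nrow(img), ncol(img))
  count <- length(keep)
  cent <- if (count) {
    rows <- row(lab); cols <- col(lab)
    data.frame(
      x = vapply(seq_len(count), function(k) mean(rows[lab == k]),
                 numeric(1L)),
      y = vapply(seq_len(count), function(k) mean(cols[lab == k]),
                 numeric(1L)))
  } else {
    data.frame(x = numeric(0), y = numeric(0))
  }
  list(labels = lab, count = count, centroids = cent)
}

#' Cell density over sections
#'
#' Counts and masked volumes are summed across all sections of a region
#' before dividing, so density is a per-animal pooled estimate:
#' `density = sum(counts) / sum(area_px * pixel_size^2 * thickness)`.
#'
#' @param counts Integer vector, cells per section.
#' @param mask_areas_px Masked region area per section (px).
#' @param pixel_size_um Pixel size (um/px).
#' @param thickness_um Section thickness (um), 40 or 60 in practice.
#' @return A list: `count`, `volume_mm3`, `density` (cells/mm^3).
#' @export
compute_density <- function(counts, mask_areas_px, pixel_size_um,
                            thickness_um) {
  stopifnot(length(counts) == length(mask_areas_px), length(counts) >= 1L)
  vol_mm3 <- sum(mask_areas_px) * pixel_size_um^2 * thickness_um / 1e9
  if (vol_mm3 <= 0) stop("region volume is zero", call. = FALSE)
  list(count = sum(counts), volume_mm3 = vol_mm3,
       density = sum(counts) / vol_mm3)
}

#' Fold induction of labeled-cell density
#'
#' Per animal, relative density = A1 density / S1 density (the
#' somatosensory region is the within-animal control); fold induction
#' divides by the mean relative density of the baseline (`"No Stim"`)
#' condition, whose group mean is therefore exactly 1. Animals with zero S1
#' density are excluded with a warning.
#'
#' @param animals A data.frame with columns `animal`, `condition`,
#'   `density_a1`, `density_s1`.
#' @param baseline Baseline condition label (default `"No Stim"`).
#' @return A list: `per_animal` (with `relative` and `fold` columns),
#'   `per_condition` (mean, SEM, n).
#' @export
fold_induction <- function(animals, baseline = "No Stim") {
  need <- c("animal", "condition", "density_a1", "density_s1")
  if (!all(need %in% names(animals))) {
    stop("`animals` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- animals$density_s1 <= 0
  if (any(bad)) {
    warning(sprintf("%d animal(s) excluded: zero S1 density", sum(bad)))
    animals <- animals[!bad, , drop = FALSE]
  }
  if (!any(animals$condition == baseline)) {
    stop(sprintf("baseline condition '%s' not present", baseline),
         call. = FALSE)
  }
  animals$relative <- animals$density_a1 / animals$density_s1
  base_mean <- mean(animals$relative[animals$condition == baseline])
  animals$fold <- animals$relative / base_mean
  agg <- do.call(rbind, lapply(split(animals, animals$condition), function(d) {
    data.frame(condition = d$condition[1L], n = nrow(d),
               mean_fold = mean(d$fold),
               sem_fold = if (nrow(d) > 1L) {
                 stats::sd(d$fold) / sqrt(nrow(d))
               } else {
                 NA_real_
               })
  }))
  rownames(agg) <- NULL
  list(per_animal = animals, per_condition = agg)
}

#' Match segmented centroids to ground truth
#'
#' Greedy nearest-neighbour matching within `max_dist`; used to score
#' counting recall and precision against the synthetic generator's true
#' centroids.
#'
#' @param detected,truth Data.frames with `x`, `y` columns.
#' @param max_dist Matching radius (px), typically one cell radius.
#' @return A list: `n_matched`, `recall`, `precision`.
#' @export
match_centroids <- function(detected, truth, max_dist) {
  if (!nrow(truth)) {
    return(list(n_matched = 0L, recall = NA_real_,
                precision = if (nrow(detected)) 0 else NA_real_))
  }
  if (!nrow(detected)) {
    return(list(n_matched = 0L, recall = 0, precision = NA_real_))
  }
  d <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  d <- sqrt(d)
  matched <- 0L
  while (TRUE) {
    m <- which.min(d)
    if (!length(m) || d[m] > max_dist) break
    ij <- arrayInd(m, dim(d))
    matched <- matched + 1L
    d[ij[1L], ] <- Inf
    d[, ij[2L]] <- Inf
  }
  list(n_matched = matched,
       recall = matched / nrow(truth),
       precision = matched / nrow(detected))
}
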