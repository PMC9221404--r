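# Training-free star-convex segmentation stage.
#
# A deterministic classical pipeline standing in for a learned
# object-probability predictor: local contrast enhancement of the DAPI and
# PE channels, a foreground map, a per-component normalized interior
# distance transform whose local maxima sit at object centers, watershed
# partitioning of the resulting probability map, ray-cast star polygons per
# candidate, greedy NMS, and score-resolved rasterization to a label map.
# The stage is pluggable: any externally produced label map can be fed to
# the downstream feature/gate/audit modules instead.

#' Segmentation parameters
#'
#' @param prob_thresh Minimum object probability for a candidate (default
#'   0.3).
#' @param nms_thresh IoU threshold for the greedy polygon NMS (default 0.3).
#' @param n_rays Number of rays per star polygon (default 32).
#' @param window_px Local contrast enhancement window, odd, in pixels.
#'   65 px (about 42 um) is larger than a cell but smaller than a clump.
#' @param weight_dapi,weight_pe Foreground channel weights; the probability
#'   combines the enhanced channels with a pixel-wise weighted max, so
#'   single-channel events (e.g. PE-only vesicles) remain detectable.
#' @param fg_thresh Threshold on the smoothed enhanced image defining
#'   foreground.
#' @param min_contrast Enhancement windows whose raw dynamic range (as a
#'   fraction of the intensity range) falls below this are mapped to 0;
#'   suppresses amplification of pure background noise.
#' @param smooth_sigma Gaussian smoothing sigma (px) before thresholding.
#' @param ws_tolerance Watershed tolerance: minimum probability drop that
#'   separates two candidate peaks.
#' @param ray_dilate_px Each candidate's basin support is dilated by this
#'   many pixels before ray-casting, so the polygon reaches the dim outer
#'   rim of the cell that falls just below the foreground threshold.
#' @param dt_scale_px Distance-transform normalization scale in pixels
#'   (about a small-cell radius): interior distances are mapped to
#'   `min(1, dt / dt_scale_px)`, so object centers reach high probability
#'   even when many cells fuse into one foreground component.
#' @return A `SegParams` object.
#' @export
seg_params <- function(prob_thresh = 0.3, nms_thresh = 0.3, n_rays = 32,
                       window_px = 65, weight_dapi = 1, weight_pe = 1,
                       fg_thresh = 0.25, min_contrast = 0.012,
                       smooth_sigma = 1.0, ws_tolerance = 0.05,
                       ray_dilate_px = 1, dt_scale_px = 5) {
  stopifnot(is_fraction(prob_thresh), is_fraction(nms_thresh),
            is_count(n_rays, min = 4),
            is_count(window_px, min = 3), window_px %% 2 == 1,
            weight_dapi >= 0, weight_pe >= 0,
            is_fraction(fg_thresh), min_contrast >= 0,
            smooth_sigma > 0, ws_tolerance > 0, dt_scale_px > 0,
            is_count(ray_dilate_px))
  structure(list(prob_thresh = prob_thresh, nms_thresh = nms_thresh,
                 n_rays = as.integer(n_rays),
                 window_px = as.integer(window_px),
                 weight_dapi = weight_dapi, weight_pe = weight_pe,
                 fg_thresh = fg_thresh, min_contrast = min_contrast,
                 smooth_sigma = smooth_sigma, ws_tolerance = ws_tolerance,
                 ray_dilate_px = as.integer(ray_dilate_px),
                 dt_scale_px = dt_scale_px),
            class = "SegParams")
}

#' Local min-max contrast enhancement
#'
#' Maps each pixel to `(v - local_min) / (local_max - local_min)` over a
#' centered sliding window (truncated at the border). Windows whose range is
#' at most `min_range` (in the input's units) map to 0; with the default
#' `min_range = 0` this reduces to plain min-max normalization where only
#' strictly flat windows map to 0.
#'
#' @param image Numeric matrix.
#' @param window_px Odd window size in pixels.
#' @param min_range Minimum window dynamic range required for enhancement.
#' @return Matrix in `[0, 1]`.
#' @export
local_contrast_enhance <- function(image, window_px = 65, min_range = 0) {
  stopifnot(is.matrix(image), window_px %% 2 == 1, window_px >= 3)
  lmin <- roll_extreme2d(image, window_px, "min")
  lmax <- roll_extreme2d(image, window_px, "max")
  rng <- lmax - lmin
  out <- ifelse(rng > max(min_range, 0) & rng > 0,
                (image - lmin) / rng, 0)
  matrix(clip(out, 0, 1), nrow(image), ncol(image))
}

#' Object probability map
#'
#' Pixel-wise weighted max of the locally contrast-enhanced DAPI and PE
#' channels, Gaussian-smoothed, multiplied by the normalized interior
#' distance transform of the foreground (`min(1, dt / dt_scale_px)`), so
#' that local maxima sit at object centers and the map stays in `[0, 1]`.
#'
#' @param stack A `ChannelStack`.
#' @param params A [seg_params()].
#' @return List with `prob` (matrix in `[0, 1]`), `fg` (logical foreground),
#'   and `smooth` (the smoothed enhanced image).
#' @export
object_probability <- function(stack, params = seg_params()) {
  stopifnot(inherits(stack, "ChannelStack"))
  top <- 2^stack$bit_depth - 1
  eD <- local_contrast_enhance(stack$dapi / top, params$window_px,
                               min_range = params$min_contrast)
  eP <- local_contrast_enhance(stack$pe / top, params$window_px,
                               min_range = params$min_contrast)
  comb <- pmax(params$weight_dapi * eD, params$weight_pe * eP)
  sm <- as.matrix(EBImage::gblur(comb, sigma = params$smooth_sigma))
  sm <- clip(sm, 0, 1)
  fg <- sm > params$fg_thresh
  if (!any(fg)) {
    return(list(prob = matrix(0, nrow(sm), ncol(sm)), fg = fg, smooth = sm))
  }
  dt <- as.matrix(EBImage::distmap(EBImage::Image(fg * 1)))
  dtn <- pmin(1, dt / params$dt_scale_px)
  list(prob = sm * dtn, fg = fg, smooth = sm)
}

#' Segment a channel stack into star-convex events
#'
#' Computes the object-probability map, partitions its support with a
#' watershed (one basin per probability peak), keeps basins whose peak
#' probability exceeds `prob_thresh`, encodes each as a star polygon by
#' ray-casting the foreground restricted to its basin from the peak, applies
#' greedy NMS at `nms_thresh`, and rasterizes the kept polygons into a label
#' map, resolving overlaps in favor of the higher score. Fully deterministic.
#'
#' @param stack A `ChannelStack`.
#' @param params A [seg_params()].
#' @return List with `labels` (integer `LabelMap` matrix, 0 = background,
#'   labels contiguous 1..n) and `polygons` (list of [star_polygon()], one
#'   per label, in label order).
#' @export
segment <- function(stack, params = seg_params()) {
  op <- object_probability(stack, params)
  H <- nrow(op$prob); W <- ncol(op$prob)
  empty <- list(labels = matrix(0L, H, W), polygons = list())
  if (!any(op$fg)) return(empty)
  ws <- as.matrix(EBImage::watershed(EBImage::Image(op$prob),
                                     tolerance = params$ws_tolerance,
                                     ext = 1))
  nz <- which(ws > 0 & op$fg)
  if (length(nz) == 0) return(empty)
  regions <- split(nz, ws[nz])
  cands <- list()
  dil <- params$ray_dilate_px
  brush <- if (dil > 0) EBImage::makeBrush(2L * dil + 1L, "disc") else NULL
  for (px in regions) {
    pk <- px[which.max(op$prob[px])]
    peak <- op$prob[pk]
    if (peak <= params$prob_thresh) next
    rr <- ((px - 1L) %% H) + 1L
    cc <- ((px - 1L) %/% H) + 1L
    r_lo <- max(1L, min(rr) - dil); r_hi <- min(H, max(rr) + dil)
    c_lo <- max(1L, min(cc) - dil); c_hi <- min(W, max(cc) + dil)
    sub <- matrix(FALSE, r_hi - r_lo + 1L, c_hi - c_lo + 1L)
    sub[cbind(rr - r_lo + 1L, cc - c_lo + 1L)] <- TRUE
    if (dil > 0) sub <- as.matrix(EBImage::dilate(sub * 1, brush)) > 0
    ctr_sub <- c(((pk - 1L) %% H) + 1L - r_lo + 1L,
                 ((pk - 1L) %/% H) + 1L - c_lo + 1L)
    p_sub <- rays_from_mask(sub, ctr_sub, K = params$n_rays,
                            score = min(1, peak))
    cands[[length(cands) + 1L]] <- star_polygon(
      p_sub$center + c(r_lo - 1L, c_lo - 1L), p_sub$distances, p_sub$score)
  }
  if (length(cands) == 0) return(empty)
  kept <- nms(cands, nms_params(params$nms_thresh), dims = c(H, W))
  if (length(kept) == 0) return(empty)
  # rasterize in descending score order; first (highest) score wins a pixel
  labels <- matrix(0L, H, W)
  for (i in seq_along(kept)) {
    px <- polygon_pixels(kept[[i]], c(H, W))
    px <- px[labels[px] == 0L]
    labels[px] <- i
  }
  present <- sort(unique(labels[labels > 0L]))
  relabel <- integer(length(kept))
  relabel[present] <- seq_along(present)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  list(labels = labels, polygons = kept[present])
}
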