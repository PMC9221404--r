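# Star-convex polygon primitives: ray encoding of masks, rasterization,
# rasterized IoU, and greedy non-maximum suppression.

#' Star-convex polygon
#'
#' A shape encoded as a center plus `K` radial boundary distances at fixed
#' angles `2*pi*k/K` (k = 0..K-1); every boundary point is visible from the
#' center. Angle k points along direction `(sin, cos)` in (row, col) image
#' coordinates.
#'
#' @param center Numeric `(row, col)`, fractional pixels allowed.
#' @param distances `K >= 4` positive ray lengths in pixels.
#' @param score Detection score in `[0, 1]`.
#' @return A `StarPolygon` object.
#' @export
star_polygon <- function(center, distances, score = 1) {
  stopifnot(length(center) == 2, is.finite(center),
            length(distances) >= 4, all(distances > 0),
            is_fraction(score))
  structure(list(center = as.numeric(center),
                 distances = as.numeric(distances),
                 score = as.numeric(score)),
            class = "StarPolygon")
}

#' @export
print.StarPolygon <- function(x, ...) {
  cat(sprintf("StarPolygon: center (%.1f, %.1f), K = %d, score %.3f\n",
              x$center[1], x$center[2], length(x$distances), x$score))
  invisible(x)
}

poly_vertices <- function(p) {
  K <- length(p$distances)
  th <- 2 * pi * (seq_len(K) - 1) / K
  cbind(row = p$center[1] + p$distances * sin(th),
        col = p$center[2] + p$distances * cos(th))
}

#' Encode a pixel mask as a star-convex polygon
#'
#' Casts `K` rays from the center at angles `2*pi*k/K` and records, for each,
#' the distance to the last in-mask sample (marching step `step_px`).
#'
#' @param mask Logical or 0/1 matrix.
#' @param center `(row, col)` of the ray origin; must lie inside the mask.
#' @param K Number of rays (>= 4).
#' @param score Score to attach to the polygon.
#' @param step_px Ray marching step; 0.25 px keeps the radial error below the
#'   rasterization error.
#' @return A [star_polygon()].
#' @export
rays_from_mask <- function(mask, center, K = 32, score = 1,
                           step_px = 0.25) {
  stopifnot(is.matrix(mask), K >= 4)
  H <- nrow(mask); W <- ncol(mask)
  r0 <- round(center[1]); c0 <- round(center[2])
  if (r0 < 1 || r0 > H || c0 < 1 || c0 > W || !(mask[r0, c0] > 0)) {
    stop("center is outside the mask", call. = FALSE)
  }
  th <- 2 * pi * (seq_len(K) - 1) / K
  max_t <- sqrt(H^2 + W^2)
  t_seq <- seq(step_px, max_t, by = step_px)
  dists <- numeric(K)
  for (k in seq_len(K)) {
    rr <- round(center[1] + t_seq * sin(th[k]))
    cc <- round(center[2] + t_seq * cos(th[k]))
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    inside <- ok & (mask[cbind(pmax(pmin(rr, H), 1),
                               pmax(pmin(cc, W), 1))] > 0)
    # distance to the last in-mask sample along the ray
    out_run <- which(!inside)
    last_in <- if (length(out_run) == 0) length(t_seq) else
      (out_run[1] - 1L)
    dists[k] <- max(t_seq[1] / 2, if (last_in >= 1) t_seq[last_in] else 0)
  }
  star_polygon(center, dists, score)
}

#' Rasterize a star-convex polygon to a pixel mask
#'
#' Fills the K-gon whose vertices are the ray endpoints (even-odd rule on
#' pixel centers), clipped to the frame.
#'
#' @param p A [star_polygon()].
#' @param dims Frame dimensions `(height, width)`.
#' @return Logical matrix of size `dims`.
#' @export
polygon_to_mask <- function(p, dims) {
  stopifnot(inherits(p, "StarPolygon"), length(dims) == 2)
  out <- matrix(FALSE, dims[1], dims[2])
  idx <- polygon_pixels(p, dims)
  out[idx] <- TRUE
  out
}

# linear pixel indices covered by the polygon, clipped to dims
polygon_pixels <- function(p, dims) {
  H <- dims[1]; W <- dims[2]
  v <- poly_vertices(p)
  r_lo <- max(1L, floor(min(v[, "row"]))); r_hi <- min(H, ceiling(max(v[, "row"])))
  c_lo <- max(1L, floor(min(v[, "col"]))); c_hi <- min(W, ceiling(max(v[, "col"])))
  if (r_lo > r_hi || c_lo > c_hi) return(integer(0))
  rr <- r_lo:r_hi; cc <- c_lo:c_hi
  py <- rep(rr, times = length(cc))
  px <- rep(cc, each = length(rr))
  inside <- rep(FALSE, length(py))
  K <- nrow(v)
  j <- K
  for (i in seq_len(K)) {
    yi <- v[i, "row"]; xi <- v[i, "col"]
    yj <- v[j, "row"]; xj <- v[j, "col"]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sel <- which(inside)
  (px[sel] - 1L) * H + py[sel]
}

poly_bbox <- function(p) {
  v <- poly_vertices(p)
  c(r0 = min(v[, "row"]), r1 = max(v[, "row"]),
    c0 = min(v[, "col"]), c1 = max(v[, "col"]))
}

#' Rasterized intersection-over-union of two star polygons
#'
#' IoU is computed on the pixel grid (the representation consumed downstream),
#' not by analytic clipping. Symmetric, in `[0, 1]`; defined as 0 when both
#' rasterizations are empty.
#'
#' @param a,b [star_polygon()] objects.
#' @param dims Frame dimensions `(height, width)`.
#' @return IoU fraction.
#' @export
polygon_iou <- function(a, b, dims) {
  ba <- poly_bbox(a); bb <- poly_bbox(b)
  if (ba["r0"] > bb["r1"] || bb["r0"] > ba["r1"] ||
      ba["c0"] > bb["c1"] || bb["c0"] > ba["c1"]) {
    return(0)
  }
  pa <- polygon_pixels(a, dims)
  pb <- polygon_pixels(b, dims)
  u <- length(union(pa, pb))
  if (u == 0) return(0)
  length(intersect(pa, pb)) / u
}

#' Non-maximum suppression parameters
#'
#' @param nms_thresh Maximum allowed IoU between kept candidates (default
#'   0.3, the post-processing threshold used throughout the pipeline).
#' @return An `NmsParams` object.
#' @export
nms_params <- function(nms_thresh = 0.3) {
  stopifnot(is_fraction(nms_thresh))
  structure(list(nms_thresh = nms_thresh), class = "NmsParams")
}

#' Greedy non-maximum suppression of star polygons
#'
#' Visits candidates by descending score (ties broken by input index) and
#' keeps a candidate iff its rasterized IoU with every already-kept candidate
#' is at most `nms_thresh`. Output order is the kept (descending-score)
#' order.
#'
#' @param candidates List of [star_polygon()] objects.
#' @param params An [nms_params()].
#' @param dims Frame dimensions for rasterization.
#' @return The kept sublist, with attribute `kept` giving the input indices.
#' @export
nms <- function(candidates, params = nms_params(), dims) {
  stopifnot(inherits(params, "NmsParams"))
  n <- length(candidates)
  if (n == 0) return(structure(list(), kept = integer(0)))
  scores <- vapply(candidates, function(p) p$score, numeric(1))
  ord <- order(-scores, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    p <- candidates[[i]]
    bb <- poly_bbox(p)
    suppressed <- FALSE
    for (j in kept) {
      if (polygon_iou(p, candidates[[j]], dims) > params$nms_thresh) {
        suppressed <- TRUE
        break
      }
    }
    if (!suppressed) kept <- c(kept, i)
  }
  structure(candidates[kept], kept = kept)
}
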