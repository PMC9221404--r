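# Shared fixtures and independent oracles used across the test files.

small_spec <- function(n_frames = 1, h = 160, w = 200) {
  cartridge_spec(n_frames = n_frames, frame_height_px = h,
                 frame_width_px = w)
}

quiet_cfg <- function(...) {
  # noise-free, flat-illumination config for exact-arithmetic checks
  sim_config(..., vignetting_strength = 0, noise_gaussian_sd = 0,
             noise_poisson_scale = 0, background = 0)
}

disk_mask <- function(dims, center, radius) {
  m <- matrix(FALSE, dims[1], dims[2])
  dy <- row(m) - center[1]; dx <- col(m) - center[2]
  m[dy^2 + dx^2 <= radius^2] <- TRUE
  m
}

# independently rasterized star-convex blob: boundary radius from a smooth
# random radial function, pixel in iff its polar radius is within the
# boundary (no package code involved)
random_blob_mask <- function(dims, center, radius, n_harm = 3, amp = 0.1) {
  a <- stats::rnorm(n_harm, sd = amp); b <- stats::rnorm(n_harm, sd = amp)
  m <- matrix(FALSE, dims[1], dims[2])
  dy <- row(m) - center[1]; dx <- col(m) - center[2]
  th <- atan2(dy, dx)
  bound <- radius * exp(Reduce(`+`, lapply(seq_len(n_harm), function(h)
    a[h] * cos((h + 1) * th) + b[h] * sin((h + 1) * th))))
  m[sqrt(dy^2 + dx^2) <= bound] <- TRUE
  m
}

# a square of side 2*s as a K = 8 star polygon (axis rays s, diagonal s*sqrt2)
square_polygon <- function(center, s, score = 1) {
  star_polygon(center, s * rep(c(1, sqrt(2)), 4), score)
}

random_star_polygon <- function(dims, score = NULL) {
  ctr <- c(stats::runif(1, 15, dims[1] - 15), stats::runif(1, 15, dims[2] - 15))
  K <- sample(c(8, 16, 32), 1)
  base <- stats::runif(1, 4, 12)
  d <- base * exp(stats::rnorm(K, sd = 0.15))
  star_polygon(ctr, d, if (is.null(score)) stats::runif(1) else score)
}

# pixel-set IoU computed directly from rasterized masks (oracle path)
mask_iou <- function(a, b) {
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) 0 else i / u
}

# exhaustive greedy NMS oracle: quadratic pairwise IoU table first, then a
# plain greedy sweep by descending score with index tie-break
nms_oracle <- function(cands, thresh, dims) {
  n <- length(cands)
  masks <- lapply(cands, polygon_to_mask, dims = dims)
  iou <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    iou[i, j] <- mask_iou(masks[[i]], masks[[j]])
  }
  scores <- vapply(cands, function(p) p$score, numeric(1))
  ord <- order(-scores, seq_len(n))
  kept <- integer(0)
  for (i in ord) {
    if (all(iou[i, kept] <= thresh)) kept <- c(kept, i)
  }
  kept
}

# brute-force match-quality oracle following the published classification
# rules literally, from an explicit truth x label overlap table
match_oracle <- function(truth_masks, labels, tau_min = 0.2, tau_cov = 0.8) {
  n <- length(truth_masks)
  lab_ids <- setdiff(sort(unique(as.vector(labels))), 0)
  ov <- matrix(0, n, length(lab_ids), dimnames = list(NULL, lab_ids))
  for (i in seq_len(n)) for (j in seq_along(lab_ids)) {
    ov[i, j] <- sum(labels[truth_masks[[i]]] == lab_ids[j]) /
      length(truth_masks[[i]])
  }
  qual <- character(n)
  for (i in seq_len(n)) {
    hit <- which(ov[i, ] >= tau_min)
    if (length(hit) == 0) { qual[i] <- "missed"; next }
    best <- hit[which.max(ov[i, hit])]
    if (sum(ov[, best] >= tau_min) > 1) { qual[i] <- "merged"; next }
    if (length(hit) >= 2) { qual[i] <- "split"; next }
    qual[i] <- if (sum(ov[i, hit]) < tau_cov) "partial" else "correct"
  }
  qual
}

# naive sliding-window extreme (truncated at borders), oracle for the
# enhancement window statistics
naive_roll <- function(m, w, f) {
  r <- (w - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- f(m[max(1, i - r):min(nrow(m), i + r),
                     max(1, j - r):min(ncol(m), j + r)])
  }
  out
}
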