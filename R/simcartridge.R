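# Synthetic cartridge simulator.
#
# Emulates CellSearch-style four-channel immunofluorescence cartridges with
# known ground truth: nucleated leukocytes (DAPI+/APC+), tumor cells
# (DAPI+/PE+), small PE-only tumor-derived EVs, bare nuclei, touching-cell
# clumps, PE-to-APC spectral crosstalk, edge vignetting, and sample-age
# dependent leukocyte carryover.

CLASSES <- c("tumor", "leukocyte", "tdev", "bare_nucleus")

#' Cartridge geometry specification
#'
#' Describes the scanned cartridge: number of frames, frame size in pixels,
#' pixel pitch and intensity quantization. The defaults mirror the CellSearch
#' convention of 140 four-channel frames; the pitch of 0.64 um/px is the one
#' implied by a 20 um cell covering about 2500 px (32 x 32 um^2).
#'
#' @param n_frames Number of frames per cartridge (>= 1).
#' @param frame_height_px,frame_width_px Frame dimensions in pixels (>= 64).
#' @param pixel_pitch_um Physical size of one pixel in micrometers (> 0).
#' @param bit_depth Intensity quantization; pixel values span
#'   `0 .. 2^bit_depth - 1`.
#' @return A `CartridgeSpec` object.
#' @export
cartridge_spec <- function(n_frames = 140,
                           frame_height_px = 977,
                           frame_width_px = 1211,
                           pixel_pitch_um = 0.64,
                           bit_depth = 12) {
  stopifnot(is_count(n_frames, min = 1),
            is_count(frame_height_px, min = 64),
            is_count(frame_width_px, min = 64),
            is.numeric(pixel_pitch_um), pixel_pitch_um > 0,
            is_count(bit_depth, min = 1))
  structure(list(n_frames = as.integer(n_frames),
                 frame_height_px = as.integer(frame_height_px),
                 frame_width_px = as.integer(frame_width_px),
                 pixel_pitch_um = pixel_pitch_um,
                 bit_depth = as.integer(bit_depth)),
            class = "CartridgeSpec")
}

#' Pixel pitch implied by a cell-area convention
#'
#' Derives the micrometers-per-pixel pitch from the statement that a square
#' region of `area_px` pixels corresponds to `side_um` x `side_um`
#' micrometers (e.g. 2500 px for 32 x 32 um^2 gives 0.64 um/px).
#'
#' @param area_px Pixel area of the square region.
#' @param side_um Physical side length in micrometers.
#' @return Pitch in um/px.
#' @export
pitch_from_area <- function(area_px, side_um) {
  stopifnot(area_px > 0, side_um > 0)
  side_um / sqrt(area_px)
}

#' Pixel area equivalent of a physical square
#'
#' Converts a physical square of side `side_um` micrometers to its pixel-area
#' equivalent at a given pitch, rounding the side to whole pixels first (so
#' 70 um at 0.64 um/px gives 109^2 = 11881 px).
#'
#' @param side_um Side length in micrometers.
#' @param pitch_um Pixel pitch in um/px.
#' @return Pixel area (integer).
#' @export
square_area_px <- function(side_um, pitch_um) {
  stopifnot(side_um > 0, pitch_um > 0)
  as.integer(round(side_um / pitch_um)^2)
}

default_intensity_model <- function() {
  # log-normal (meanlog, sdlog) per class and channel, 12-bit scale;
  # anchored so the candidate-CTC gate thresholds are meaningful:
  # tumor PE and leukocyte APC locations ~300 counts over a ~20 background
  list(
    tumor        = list(dapi = c(log(300), 0.25), pe = c(log(300), 0.30),
                        apc = NULL),
    leukocyte    = list(dapi = c(log(300), 0.25), pe = NULL,
                        apc = c(log(300), 0.30)),
    tdev         = list(dapi = NULL, pe = c(log(150), 0.40), apc = NULL),
    bare_nucleus = list(dapi = c(log(250), 0.30), pe = NULL, apc = NULL)
  )
}

default_radius_model <- function() {
  # mean and sd of object radius in micrometers per class
  list(tumor        = c(7.5, 1.0),
       leukocyte    = c(4.5, 0.6),
       tdev         = c(1.6, 0.3),
       bare_nucleus = c(3.8, 0.6))
}

#' Simulation configuration
#'
#' Object counts and imaging-physics parameters for [generate_cartridge()].
#' Intensities are drawn per object from log-normal distributions per class
#' and channel; shapes are star-convex blobs from smoothed random radial
#' profiles, except for a configurable fraction of tumor cells rendered as
#' dumbbells (two fused lobes), which are deliberately not star-convex.
#'
#' @param n_tumor,n_leukocyte,n_tdev,n_bare_nucleus Object counts (whole
#'   cartridge).
#' @param clump_fraction Probability that an object is placed touching an
#'   already-placed object in its frame.
#' @param nonstarconvex_fraction Probability that a tumor cell is rendered as
#'   a two-lobed dumbbell.
#' @param intensity Nested list `class -> channel -> c(meanlog, sdlog)`
#'   (NULL channel = no signal); see `ctcsegaudit:::default_intensity_model`.
#' @param radius_um List `class -> c(mean, sd)` radius in micrometers.
#' @param pe_to_apc_crosstalk Multiplicative bleed of PE signal into the APC
#'   channel (>= 0).
#' @param vignetting_strength Fractional signal loss at the frame corner
#'   (0 = flat illumination).
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (counts).
#' @param noise_poisson_scale Signal-proportional (shot-noise-like) variance
#'   scale: total variance is `noise_gaussian_sd^2 + noise_poisson_scale * I`.
#' @param background Background level in counts.
#' @param nucleus_fraction Fraction of the tumor-cell radius occupied by the
#'   DAPI+ nucleus (other DAPI+ classes are DAPI over the whole mask).
#' @param seed Integer root seed; all frame and object streams are derived
#'   from it with [derive_seed()].
#' @return A `SimConfig` object.
#' @export
sim_config <- function(n_tumor = 0, n_leukocyte = 0, n_tdev = 0,
                       n_bare_nucleus = 0,
                       clump_fraction = 0.1,
                       nonstarconvex_fraction = 0.02,
                       intensity = default_intensity_model(),
                       radius_um = default_radius_model(),
                       pe_to_apc_crosstalk = 0.05,
                       vignetting_strength = 0.3,
                       noise_gaussian_sd = 5,
                       noise_poisson_scale = 0.25,
                       background = 20,
                       nucleus_fraction = 0.6,
                       seed = 1L) {
  stopifnot(is_count(n_tumor), is_count(n_leukocyte), is_count(n_tdev),
            is_count(n_bare_nucleus),
            is_fraction(clump_fraction), is_fraction(nonstarconvex_fraction),
            is.numeric(pe_to_apc_crosstalk), pe_to_apc_crosstalk >= 0,
            is_fraction(vignetting_strength),
            noise_gaussian_sd >= 0, noise_poisson_scale >= 0,
            background >= 0, is_fraction(nucleus_fraction),
            is_count(seed))
  stopifnot(all(CLASSES %in% names(intensity)),
            all(CLASSES %in% names(radius_um)))
  structure(list(counts = c(tumor = as.integer(n_tumor),
                            leukocyte = as.integer(n_leukocyte),
                            tdev = as.integer(n_tdev),
                            bare_nucleus = as.integer(n_bare_nucleus)),
                 clump_fraction = clump_fraction,
                 nonstarconvex_fraction = nonstarconvex_fraction,
                 intensity = intensity,
                 radius_um = radius_um,
                 pe_to_apc_crosstalk = pe_to_apc_crosstalk,
                 vignetting_strength = vignetting_strength,
                 noise_gaussian_sd = noise_gaussian_sd,
                 noise_poisson_scale = noise_poisson_scale,
                 background = background,
                 nucleus_fraction = nucleus_fraction,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# radial boundary r(theta) of a star-convex blob: base radius modulated by a
# low-order Fourier perturbation (harmonics 2..4)
radial_profile_r <- function(theta, radius, prof) {
  theta <- as.vector(theta)
  h <- seq_len(ncol(prof)) + 1
  mod <- drop(prof[1, ] %*% cos(outer(h, theta)) +
              prof[2, ] %*% sin(outer(h, theta)))
  radius * exp(mod)
}

max_radius <- function(radius, prof) radius * exp(sum(abs(prof)))

# pixel mask (linear indices, column-major) of one truth object;
# detail = TRUE also returns the relative radial position u in [0, 1]
# of every mask pixel (0 at the center), used for the dome-shaped
# intensity profile
object_mask_px <- function(obj, spec, scale = 1, detail = FALSE) {
  H <- spec$frame_height_px; W <- spec$frame_width_px
  r_max <- max_radius(obj$radius, obj$prof[[1]]) * scale
  has_lobe <- !is.na(obj$lobe_radius)
  if (has_lobe) {
    r_max <- max(r_max, sqrt(obj$lobe_dr^2 + obj$lobe_dc^2) +
                          max_radius(obj$lobe_radius, obj$prof[[1]]) * scale)
  }
  rr <- clip(floor(obj$row - r_max):ceiling(obj$row + r_max), 1, H)
  cc <- clip(floor(obj$col - r_max):ceiling(obj$col + r_max), 1, W)
  rr <- unique(rr); cc <- unique(cc)
  dy <- outer(rr - obj$row, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - obj$col)
  th <- atan2(dy, dx)
  rad <- sqrt(dy^2 + dx^2)
  r_bound <- radial_profile_r(th, obj$radius * scale, obj$prof[[1]])
  u <- as.vector(rad) / r_bound
  if (has_lobe) {
    dy2 <- dy - obj$lobe_dr; dx2 <- dx - obj$lobe_dc
    th2 <- atan2(dy2, dx2)
    rad2 <- sqrt(dy2^2 + dx2^2)
    r_bound2 <- radial_profile_r(th2, obj$lobe_radius * scale, obj$prof[[1]])
    u <- pmin(u, as.vector(rad2) / r_bound2)
  }
  idx <- which(u <= 1)
  lin <- (cc[((idx - 1) %/% length(rr)) + 1] - 1) * H +
    rr[((idx - 1) %% length(rr)) + 1]
  if (detail) list(idx = lin, u = u[idx]) else lin
}

#' Ground-truth pixel masks of a set of objects
#'
#' @param truth Truth data frame as stored in a `SampleArchive`.
#' @param spec The archive's [cartridge_spec()].
#' @return A list, one integer vector of column-major linear pixel indices
#'   (within the object's frame) per truth row, named by object id.
#' @export
truth_masks <- function(truth, spec) {
  out <- lapply(seq_len(nrow(truth)), function(i)
    object_mask_px(truth[i, ], spec))
  names(out) <- truth$id
  out
}

#' Truth summary table
#'
#' @param archive A `SampleArchive`.
#' @param area Compute per-object mask areas (set `FALSE` to skip the mask
#'   rasterization for very large cartridges).
#' @return A data frame with columns id, class, frame, row, col and (if
#'   requested) area_px.
#' @export
truth_table <- function(archive, area = TRUE) {
  tr <- archive$truth
  out <- data.frame(id = tr$id, class = tr$class, frame = tr$frame,
                    row = tr$row, col = tr$col)
  if (area && nrow(tr) > 0) {
    out$area_px <- vapply(truth_masks(tr, archive$spec), length, integer(1))
  } else if (area) {
    out$area_px <- integer(0)
  }
  out
}

# draw the truth objects of one frame; deterministic given (seed, frame)
place_frame_objects <- function(classes, spec, cfg, frame, id0) {
  n <- length(classes)
  H <- spec$frame_height_px; W <- spec$frame_width_px
  px <- cfg$radius_um
  set.seed(derive_seed(cfg$seed, 2L, frame))
  rad_mu <- vapply(px[classes], `[`, numeric(1), 1) / spec$pixel_pitch_um
  rad_sd <- vapply(px[classes], `[`, numeric(1), 2) / spec$pixel_pitch_um
  radius <- clip(stats::rnorm(n, rad_mu, rad_sd), 0.4 * rad_mu, 2 * rad_mu)
  radius <- pmax(radius, 1.2)
  # Fourier perturbation coefficients, harmonics 2..4
  coef <- matrix(stats::rnorm(n * 6, sd = 0.06), n, 6)
  prof <- lapply(seq_len(n), function(i) matrix(coef[i, ], 2, 3))
  # intensities
  draw_int <- function(ch) {
    v <- numeric(n)
    for (cl in unique(classes)) {
      par <- cfg$intensity[[cl]][[ch]]
      sel <- classes == cl
      if (!is.null(par)) v[sel] <- stats::rlnorm(sum(sel), par[1], par[2])
    }
    v
  }
  base_dapi <- draw_int("dapi"); base_pe <- draw_int("pe")
  base_apc <- draw_int("apc")
  # dumbbell (non-star-convex) tumor cells
  lobe_dr <- rep(NA_real_, n); lobe_dc <- rep(NA_real_, n)
  lobe_radius <- rep(NA_real_, n)
  is_dumb <- classes == "tumor" &
    stats::runif(n) < cfg$nonstarconvex_fraction
  if (any(is_dumb)) {
    ang <- stats::runif(sum(is_dumb), 0, 2 * pi)
    radius[is_dumb] <- 0.8 * radius[is_dumb]
    d <- 1.1 * radius[is_dumb]
    lobe_dr[is_dumb] <- d * sin(ang)
    lobe_dc[is_dumb] <- d * cos(ang)
    lobe_radius[is_dumb] <- 0.9 * radius[is_dumb]
  }
  # placement: jittered grid (quasi-uniform when sparse, close-packed
  # without heavy interpenetration when dense), with a clump_fraction of
  # objects re-placed touching a previously placed object
  row <- numeric(n); col <- numeric(n)
  if (n > 0) {
    s <- sqrt(H * W / n)
    nr <- ceiling(H / s); nc <- ceiling(W / s)
    cells <- sample.int(nr * nc, n) - 1L
    jit_r <- stats::runif(n, -0.35, 0.35) * H / nr
    jit_c <- stats::runif(n, -0.35, 0.35) * W / nc
    row <- ((cells %% nr) + 0.5) * H / nr + jit_r
    col <- ((cells %/% nr) + 0.5) * W / nc + jit_c
    m <- pmin(ceiling(radius) + 2, floor(min(H, W) / 4))
    u_clump <- stats::runif(n)
    clumped <- which(u_clump < cfg$clump_fraction & seq_len(n) > 1)
    for (i in clumped) {
      j <- sample.int(i - 1L, 1L)
      d <- stats::runif(1, 0.9, 1.2) * (radius[i] + radius[j])
      a <- stats::runif(1, 0, 2 * pi)
      row[i] <- row[j] + d * sin(a)
      col[i] <- col[j] + d * cos(a)
    }
    row <- clip(row, m, H - m + 1)
    col <- clip(col, m, W - m + 1)
  }
  nuc <- ifelse(classes == "tumor", cfg$nucleus_fraction, 1)
  nuc[classes == "tdev"] <- NA_real_
  out <- data.frame(id = id0 + seq_len(n) - 1L, class = classes,
                    frame = rep(as.integer(frame), n),
                    row = row, col = col, radius = radius,
                    lobe_dr = lobe_dr, lobe_dc = lobe_dc,
                    lobe_radius = lobe_radius,
                    base_dapi = base_dapi, base_pe = base_pe,
                    base_apc = base_apc, nucleus_fraction = nuc,
                    stringsAsFactors = FALSE)
  out$prof <- prof
  out
}

#' Generate a ground-truthed synthetic cartridge
#'
#' Places the configured objects across frames, draws their shapes and
#' intensities from per-frame random streams derived from the root seed, and
#' (optionally) renders the four-channel frames. Identical `(spec, cfg)`
#' always yields a bit-identical archive.
#'
#' @param spec A [cartridge_spec()].
#' @param cfg A [sim_config()].
#' @param render Render pixel frames (`TRUE`) or return truth only (for very
#'   large cartridges where only object-level ground truth is needed).
#' @param days_to_prep,sample_kind Archive metadata: days between sample
#'   collection and preparation (leukocyte carryover grows with it, see
#'   [carryover_multiplier()]), and `"blood"` or `"dla"`. The leukocyte count
#'   actually placed is `n_leukocyte * carryover_multiplier(...)`.
#' @return A `SampleArchive`: list with `spec`, `frames` (list of
#'   `ChannelStack` or `NULL` when not rendered), `truth` (data frame), and
#'   `metadata`.
#' @export
generate_cartridge <- function(spec, cfg, render = TRUE,
                               days_to_prep = 1, sample_kind = "blood") {
  stopifnot(inherits(spec, "CartridgeSpec"), inherits(cfg, "SimConfig"),
            sample_kind %in% c("blood", "dla"))
  counts <- cfg$counts
  counts["leukocyte"] <- as.integer(round(
    counts["leukocyte"] * carryover_multiplier(days_to_prep, sample_kind)))
  n_total <- sum(counts)
  H <- spec$frame_height_px; W <- spec$frame_width_px
  classes <- rep(names(counts), counts)
  set.seed(derive_seed(cfg$seed, 1L))
  frame_of <- if (n_total > 0) {
    sample.int(spec$n_frames, n_total, replace = TRUE)
  } else integer(0)
  # interleave classes so every frame gets a class mixture
  classes <- sample(classes)
  # capacity check: expected coverage must stay below 90% per frame
  exp_area <- vapply(cfg$radius_um[classes], function(r)
    pi * (r[1] / spec$pixel_pitch_um)^2, numeric(1))
  if (n_total > 0) {
    per_frame <- tapply(exp_area, frame_of, sum)
    if (any(per_frame > 0.9 * H * W)) {
      stop("placement failure: requested density exceeds 90% of frame area",
           call. = FALSE)
    }
  }
  truth_list <- list()
  id0 <- 1L
  for (f in sort(unique(frame_of))) {
    cls_f <- classes[frame_of == f]
    tf <- place_frame_objects(cls_f, spec, cfg, f, id0)
    id0 <- id0 + nrow(tf)
    truth_list[[length(truth_list) + 1L]] <- tf
  }
  truth <- if (length(truth_list)) do.call(rbind, truth_list) else
    place_frame_objects(character(0), spec, cfg, 1L, 1L)
  frames <- vector("list", spec$n_frames)
  if (render) {
    for (f in seq_len(spec$n_frames)) {
      frames[[f]] <- render_frame(truth[truth$frame == f, , drop = FALSE],
                                  spec, cfg, frame_index = f)
    }
  }
  structure(list(spec = spec, frames = frames, truth = truth,
                 metadata = list(days_to_prep = days_to_prep,
                                 sample_kind = sample_kind,
                                 rendered = render)),
            class = "SampleArchive")
}

#' Leukocyte carryover multiplier by sample age
#'
#' Calibrated scaling of the leukocyte count with the number of days between
#' sample collection and preparation: whole-blood carryover roughly quadruples
#' from day 1 to day 4+, while apheresis (DLA) samples show a much milder
#' dependence.
#'
#' @param days_to_prep Days between collection and preparation (>= 1; values
#'   above 4 use the 4+ multiplier).
#' @param sample_kind `"blood"` or `"dla"`.
#' @return A multiplicative factor (1 at day 1).
#' @export
carryover_multiplier <- function(days_to_prep, sample_kind = "blood") {
  stopifnot(days_to_prep >= 1, sample_kind %in% c("blood", "dla"))
  d <- min(as.integer(days_to_prep), 4L)
  tab <- if (sample_kind == "blood") c(1, 2.2, 2.8, 4.2) else
    c(1, 1.26, 1.28, 1.44)
  tab[d]
}

#' Render one four-channel frame
#'
#' Draws the objects' flat in-mask signals into DAPI/PE/APC planes, adds the
#' PE-to-APC crosstalk, applies radial vignetting to the signal, then adds
#' background and mixed Gaussian/shot noise, clipping and quantizing to the
#' spec's bit depth. The per-frame noise stream is derived from the config
#' seed and the frame index, so rendering is reproducible frame by frame.
#'
#' @param objects Truth rows assigned to this frame.
#' @param spec A [cartridge_spec()].
#' @param cfg A [sim_config()].
#' @param frame_index Frame number (seeds the noise stream).
#' @return A `ChannelStack`: list of matrices `dapi`, `pe`, `apc`, `spare`
#'   plus `bit_depth`.
#' @export
render_frame <- function(objects, spec, cfg, frame_index = 1L) {
  H <- spec$frame_height_px; W <- spec$frame_width_px
  dapi <- matrix(0, H, W); pe <- matrix(0, H, W); apc <- matrix(0, H, W)
  for (i in seq_len(nrow(objects))) {
    obj <- objects[i, ]
    md <- object_mask_px(obj, spec, detail = TRUE)
    mask <- md$idx
    # dome profile: cells are brighter at the center (projected thickness),
    # mean factor over the mask is ~1 so class intensity anchors are kept
    dome <- 0.4 + 1.2 * (1 - md$u^2)
    if (obj$base_pe > 0) pe[mask] <- pe[mask] + obj$base_pe * dome
    if (obj$base_apc > 0) apc[mask] <- apc[mask] + obj$base_apc * dome
    if (obj$base_dapi > 0) {
      if (!is.na(obj$nucleus_fraction) && obj$nucleus_fraction < 1) {
        nd <- object_mask_px(obj, spec, scale = obj$nucleus_fraction,
                             detail = TRUE)
        dapi[nd$idx] <- dapi[nd$idx] +
          obj$base_dapi * (0.4 + 1.2 * (1 - nd$u^2))
      } else {
        dapi[mask] <- dapi[mask] + obj$base_dapi * dome
      }
    }
  }
  apc <- apc + cfg$pe_to_apc_crosstalk * pe
  if (cfg$vignetting_strength > 0) {
    v <- vignette_field(H, W, cfg$vignetting_strength)
    dapi <- dapi * v; pe <- pe * v; apc <- apc * v
  }
  spare <- matrix(0, H, W)
  set.seed(derive_seed(cfg$seed, 3L, frame_index))
  finish <- function(sig) {
    img <- sig + cfg$background
    sd_tot <- sqrt(cfg$noise_gaussian_sd^2 + cfg$noise_poisson_scale * img)
    if (cfg$noise_gaussian_sd > 0 || cfg$noise_poisson_scale > 0) {
      img <- img + stats::rnorm(length(img), sd = sd_tot)
    }
    matrix(round(clip(img, 0, 2^spec$bit_depth - 1)), nrow(sig), ncol(sig))
  }
  structure(list(dapi = finish(dapi), pe = finish(pe), apc = finish(apc),
                 spare = finish(spare), bit_depth = spec$bit_depth),
            class = "ChannelStack")
}

# multiplicative illumination field: 1 at frame center,
# 1 - strength at the corners
vignette_field <- function(H, W, strength) {
  ry <- ((seq_len(H) - (H + 1) / 2) / ((H - 1) / 2))^2
  rx <- ((seq_len(W) - (W + 1) / 2) / ((W - 1) / 2))^2
  d2 <- (outer(ry, rep(1, W)) + outer(rep(1, H), rx)) / 2
  1 - strength * d2
}

#' Spike-in dilution series of cartridges
#'
#' One archive per requested leukocyte count, each with the same tumor-cell
#' count, emulating spike-in experiments in which a fixed number of cultured
#' tumor cells is mixed with increasing numbers of white blood cells. Seeds
#' are derived per series member from the base config seed.
#'
#' @param wbc_counts Vector of leukocyte counts (one archive each).
#' @param tumor_count Tumor cells per archive.
#' @param spec,cfg Cartridge spec and base config (counts are overridden).
#' @param render Render frames (see [generate_cartridge()]).
#' @return A list of `SampleArchive` objects.
#' @export
spike_in_series <- function(wbc_counts, tumor_count, spec, cfg,
                            render = TRUE) {
  stopifnot(all(wbc_counts >= 0), is_count(tumor_count))
  lapply(seq_along(wbc_counts), function(j) {
    cfg_j <- cfg
    cfg_j$counts <- c(tumor = as.integer(tumor_count),
                      leukocyte = as.integer(wbc_counts[j]),
                      tdev = cfg$counts[["tdev"]],
                      bare_nucleus = cfg$counts[["bare_nucleus"]])
    cfg_j$seed <- derive_seed(cfg$seed, 100L, j)
    generate_cartridge(spec, cfg_j, render = render)
  })
}

#' Emulated reference (rectangle) segmentation
#'
#' Reference CTC-scanner behavior: every DAPI+/PE+ object gets an axis-aligned
#' rectangle equal to its bounding box expanded by `margin_px` on each side,
#' clipped to the frame. With `merge_overlapping = TRUE`, overlapping
#' rectangles within a frame are iteratively replaced by their union bounding
#' box, emulating the joined segmentations seen in dense samples.
#'
#' @param truth Truth data frame (or a `SampleArchive`).
#' @param spec Cartridge spec (ignored when `truth` is an archive).
#' @param margin_px Margin added on each side of the bounding box.
#' @param merge_overlapping Merge overlapping rectangles into joint ones.
#' @return Data frame with columns frame, r0, r1, c0, c1 (1-based inclusive
#'   pixel bounds) and area_px.
#' @export
emulate_reference_segmentation <- function(truth, spec = NULL,
                                           margin_px = 10,
                                           merge_overlapping = FALSE) {
  if (inherits(truth, "SampleArchive")) {
    spec <- truth$spec
    truth <- truth$truth
  }
  stopifnot(inherits(spec, "CartridgeSpec"), is_count(margin_px))
  H <- spec$frame_height_px; W <- spec$frame_width_px
  sel <- truth$base_dapi > 0 & truth$base_pe > 0
  tr <- truth[sel, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(data.frame(frame = integer(0), r0 = integer(0), r1 = integer(0),
                      c0 = integer(0), c1 = integer(0), area_px = integer(0)))
  }
  rects <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
    mask <- object_mask_px(tr[i, ], spec)
    rr <- ((mask - 1) %% H) + 1
    cc <- ((mask - 1) %/% H) + 1
    c(frame = tr$frame[i],
      r0 = max(1L, min(rr) - margin_px), r1 = min(H, max(rr) + margin_px),
      c0 = max(1L, min(cc) - margin_px), c1 = min(W, max(cc) + margin_px))
  }))
  rects <- as.data.frame(rects)
  if (merge_overlapping) {
    merged <- lapply(split(rects, rects$frame), merge_rects)
    rects <- do.call(rbind, merged)
    rownames(rects) <- NULL
  }
  rects$area_px <- (rects$r1 - rects$r0 + 1) * (rects$c1 - rects$c0 + 1)
  rects
}

rects_overlap <- function(a, b) {
  a["r0"] <= b["r1"] && b["r0"] <= a["r1"] &&
    a["c0"] <= b["c1"] && b["c0"] <= a["c1"]
}

# iteratively union overlapping rectangles (within one frame) to fixpoint
merge_rects <- function(rects) {
  m <- as.matrix(rects[, c("r0", "r1", "c0", "c1")])
  frame <- rects$frame[1]
  repeat {
    n <- nrow(m)
    if (n <= 1) break
    merged_any <- FALSE
    keep <- rep(TRUE, n)
    for (i in seq_len(n - 1)) {
      if (!keep[i]) next
      for (j in seq((i + 1), n)) {
        if (!keep[j]) next
        if (rects_overlap(m[i, ], m[j, ])) {
          m[i, ] <- c(min(m[i, "r0"], m[j, "r0"]),
                      max(m[i, "r1"], m[j, "r1"]),
                      min(m[i, "c0"], m[j, "c0"]),
                      max(m[i, "c1"], m[j, "c1"]))
          keep[j] <- FALSE
          merged_any <- TRUE
        }
      }
    }
    m <- m[keep, , drop = FALSE]
    if (!merged_any) break
  }
  data.frame(frame = frame, r0 = m[, "r0"], r1 = m[, "r1"],
             c0 = m[, "c0"], c1 = m[, "c1"])
}
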