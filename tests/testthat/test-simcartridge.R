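test_that("empty configuration yields background-only frames", {
  spec <- small_spec(n_frames = 2, h = 96, w = 96)
  a <- generate_cartridge(spec, sim_config(seed = 3))
  expect_equal(nrow(a$truth), 0)
  expect_length(a$frames, 2)
  st <- a$frames[[1]]
  # background + noise only: nothing near the top of the dynamic range
  expect_lt(max(st$pe), 100)
  expect_lt(max(st$dapi), 100)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- small_spec(n_frames = 2, h = 128, w = 128)
  cfg <- sim_config(n_tumor = 5, n_leukocyte = 12, n_tdev = 4, seed = 77)
  a <- generate_cartridge(spec, cfg)
  b <- generate_cartridge(spec, cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$frames, b$frames)
})

test_that("truth conserves requested counts and stays inside frames", {
  spec <- small_spec(n_frames = 3, h = 128, w = 160)
  cfg <- sim_config(n_tumor = 9, n_leukocyte = 30, n_tdev = 7,
                    n_bare_nucleus = 5, seed = 5)
  a <- generate_cartridge(spec, cfg, render = FALSE)
  expect_equal(nrow(a$truth), 51)
  expect_equal(unname(table(a$truth$class)[c("tumor", "leukocyte", "tdev",
                                             "bare_nucleus")]),
               c(9, 30, 7, 5), ignore_attr = TRUE)
  expect_true(all(a$truth$frame %in% 1:3))
  expect_equal(anyDuplicated(a$truth$id), 0)
  masks <- truth_masks(a$truth, spec)
  expect_true(all(vapply(masks, length, integer(1)) > 0))
  expect_true(all(unlist(masks) >= 1 & unlist(masks) <= 128 * 160))
})

test_that("impossible densities raise a placement error", {
  spec <- small_spec(n_frames = 1, h = 64, w = 64)
  expect_error(
    generate_cartridge(spec, sim_config(n_tumor = 100, seed = 1),
                       render = FALSE),
    "placement failure")
})

test_that("rendered objects exceed local background in their channels", {
  spec <- small_spec(n_frames = 1, h = 160, w = 200)
  cfg <- sim_config(n_tumor = 3, n_leukocyte = 6, seed = 21)
  a <- generate_cartridge(spec, cfg)
  st <- a$frames[[1]]
  tr <- a$truth[a$truth$frame == 1, ]
  masks <- truth_masks(tr, spec)
  bg <- st$dapi[-unlist(masks)]
  for (i in seq_len(nrow(tr))) {
    expect_gt(mean(st$dapi[masks[[i]]]), mean(bg) + 50)
  }
})

test_that("PE-to-APC crosstalk is a linear bleed of the PE signal", {
  spec <- small_spec(n_frames = 1, h = 100, w = 100)
  # zero crosstalk: APC in a PE-only mask equals APC background
  cfg0 <- quiet_cfg(n_tdev = 1, pe_to_apc_crosstalk = 0, seed = 2)
  a0 <- generate_cartridge(spec, cfg0, render = FALSE)
  st0 <- render_frame(a0$truth, spec, cfg0, 1)
  mask <- truth_masks(a0$truth, spec)[[1]]
  expect_equal(mean(st0$apc[mask]), mean(st0$apc[-mask]))
  # crosstalk 0.1, PE mean 2000 over black background: APC in-mask ~ 200
  cfg1 <- quiet_cfg(n_tdev = 1, pe_to_apc_crosstalk = 0.1, seed = 2)
  a1 <- generate_cartridge(spec, cfg1, render = FALSE)
  tr <- a1$truth
  tr$base_pe <- 2000
  st1 <- render_frame(tr, spec, cfg1, 1)
  expect_equal(mean(st1$apc[mask]) / mean(st1$pe[mask]), 0.1,
               tolerance = 0.01)
})

test_that("zero vignetting keeps corner and center intensities equal", {
  spec <- small_spec(n_frames = 1, h = 200, w = 200)
  cfg <- quiet_cfg(n_tumor = 2, nonstarconvex_fraction = 0, seed = 6)
  a <- generate_cartridge(spec, cfg, render = FALSE)
  tr <- a$truth
  tr$radius <- c(10, 10)
  tr$prof <- list(matrix(0, 2, 3), matrix(0, 2, 3))
  tr$base_pe <- c(400, 400)
  tr[1, c("row", "col")] <- c(100, 100)  # center
  tr[2, c("row", "col")] <- c(15, 15)    # corner
  st <- render_frame(tr, spec, cfg, 1)
  masks <- truth_masks(tr, spec)
  expect_equal(mean(st$pe[masks[[1]]]), mean(st$pe[masks[[2]]]),
               tolerance = 1e-8)
  # with vignetting the corner object is dimmer
  cfg_v <- cfg; cfg_v$vignetting_strength <- 0.3
  st_v <- render_frame(tr, spec, cfg_v, 1)
  expect_lt(mean(st_v$pe[masks[[2]]]), 0.9 * mean(st_v$pe[masks[[1]]]))
})

test_that("class staining signatures hold in expectation", {
  spec <- small_spec(n_frames = 4, h = 256, w = 320)
  cfg <- sim_config(n_tumor = 60, n_leukocyte = 60, n_tdev = 40,
                    n_bare_nucleus = 40, seed = 31)
  a <- generate_cartridge(spec, cfg)
  tt <- a$truth
  masks <- truth_masks(tt, spec)
  ch_mean <- function(i, ch) {
    st <- a$frames[[tt$frame[i]]]
    mean(st[[ch]][masks[[i]]])
  }
  pe <- vapply(seq_len(nrow(tt)), ch_mean, numeric(1), ch = "pe")
  apc <- vapply(seq_len(nrow(tt)), ch_mean, numeric(1), ch = "apc")
  dapi <- vapply(seq_len(nrow(tt)), ch_mean, numeric(1), ch = "dapi")
  expect_gt(mean(pe[tt$class == "tumor"]), mean(pe[tt$class == "leukocyte"]))
  expect_gt(mean(apc[tt$class == "leukocyte"]),
            mean(apc[tt$class == "tumor"]))
  # tdEVs carry no nuclear stain: in-mask DAPI stays at background level
  bg_dapi <- mean(a$frames[[1]]$dapi[-unlist(masks[tt$frame == 1])])
  expect_lt(mean(dapi[tt$class == "tdev"]), bg_dapi + 3 * cfg$noise_gaussian_sd)
})

test_that("spike-in series reproduces requested totals deterministically", {
  spec <- small_spec(n_frames = 4, h = 128, w = 160)
  cfg <- sim_config(seed = 9)
  ser <- spike_in_series(c(0, 50, 100, 200), tumor_count = 30, spec, cfg,
                         render = FALSE)
  expect_equal(vapply(ser, function(a) nrow(a$truth), integer(1)),
               c(30, 80, 130, 230))
  ser2 <- spike_in_series(c(50), 30, spec, cfg, render = FALSE)
  ser3 <- spike_in_series(c(50), 30, spec, cfg, render = FALSE)
  expect_identical(ser2[[1]]$truth, ser3[[1]]$truth)
})

test_that("foreground coverage grows monotonically along the dilution series", {
  spec <- small_spec(n_frames = 4, h = 128, w = 160)
  ser <- spike_in_series(c(0, 50, 100, 200), tumor_count = 30, spec,
                         sim_config(seed = 9), render = FALSE)
  fg <- vapply(ser, function(a) {
    masks <- truth_masks(a$truth, spec)
    offs <- (a$truth$frame - 1) * 128 * 160
    length(unique(unlist(Map(`+`, masks, offs)))) / (4 * 128 * 160)
  }, numeric(1))
  expect_true(all(diff(fg) > 0))
})

test_that("full-cartridge spike-in arithmetic matches the dilution design", {
  # ~6000 tumor cells + 400k leukocytes over 140 frames: ~2900 objects/frame
  spec <- cartridge_spec()
  cfg <- sim_config(n_tumor = 6000, n_leukocyte = 400000, seed = 17)
  a <- generate_cartridge(spec, cfg, render = FALSE)
  expect_equal(nrow(a$truth), 406000)
  expect_equal(nrow(a$truth) / spec$n_frames, 2900)
})

test_that("leukocyte carryover scales with days to preparation", {
  expect_equal(carryover_multiplier(1, "blood"), 1)
  expect_equal(carryover_multiplier(4, "blood"), 4.2)
  expect_equal(carryover_multiplier(9, "blood"), 4.2)
  expect_lt(carryover_multiplier(4, "dla"), carryover_multiplier(4, "blood"))
  spec <- small_spec(n_frames = 2, h = 128, w = 160)
  a1 <- generate_cartridge(spec, sim_config(n_leukocyte = 50, seed = 2),
                           render = FALSE, days_to_prep = 1)
  a4 <- generate_cartridge(spec, sim_config(n_leukocyte = 50, seed = 2),
                           render = FALSE, days_to_prep = 4)
  expect_equal(nrow(a1$truth), 50)
  expect_equal(nrow(a4$truth), 210)
})

test_that("reference rectangles expand bounding boxes by the margin", {
  spec <- small_spec(n_frames = 1, h = 160, w = 200)
  cfg <- quiet_cfg(n_tumor = 1, nonstarconvex_fraction = 0, seed = 4)
  a <- generate_cartridge(spec, cfg, render = FALSE)
  tr <- a$truth
  # circular cell of radius 15 at an interior position: 31 x 31 bounding
  # box, +10 px margin on each side -> 51 x 51 = 2601 px
  tr$radius <- 15
  tr$prof <- list(matrix(0, 2, 3))
  tr[1, c("row", "col")] <- c(80, 100)
  r <- emulate_reference_segmentation(tr, spec, margin_px = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$area_px, 51 * 51)
  # an object at the frame edge gets clipped
  tr[1, c("row", "col")] <- c(8, 100)
  r_edge <- emulate_reference_segmentation(tr, spec, margin_px = 10)
  expect_equal(r_edge$r0, 1)
  expect_lt(r_edge$area_px, 51 * 51)
  # only DAPI+/PE+ objects are segmented by the reference
  cfg_l <- quiet_cfg(n_leukocyte = 5, seed = 4)
  al <- generate_cartridge(spec, cfg_l, render = FALSE)
  expect_equal(nrow(emulate_reference_segmentation(al$truth, spec)), 0)
})

test_that("overlapping reference rectangles merge into the union box", {
  spec <- small_spec(n_frames = 1, h = 160, w = 200)
  cfg <- quiet_cfg(n_tumor = 2, nonstarconvex_fraction = 0, seed = 4)
  a <- generate_cartridge(spec, cfg, render = FALSE)
  tr <- a$truth
  tr$radius <- c(10, 10)
  tr$prof <- list(matrix(0, 2, 3), matrix(0, 2, 3))
  tr[1, c("row", "col")] <- c(80, 90)
  tr[2, c("row", "col")] <- c(80, 112)  # margined boxes overlap
  r <- emulate_reference_segmentation(tr, spec, margin_px = 10,
                                      merge_overlapping = TRUE)
  expect_equal(nrow(r), 1)
  sep <- emulate_reference_segmentation(tr, spec, margin_px = 10)
  # union bounding box of the two separate rectangles
  expect_equal(r$r0, min(sep$r0)); expect_equal(r$r1, max(sep$r1))
  expect_equal(r$c0, min(sep$c0)); expect_equal(r$c1, max(sep$c1))
})

test_that("pixel pitch conventions convert consistently", {
  expect_equal(pitch_from_area(2500, 32), 0.64)
  expect_equal(square_area_px(32, 0.64), 2500)
  expect_equal(square_area_px(70, 0.64), 11881)
})
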