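# Pipeline orchestration: simulate -> segment -> extract/gate ->
# select candidates -> compare/audit, with a reproducibility manifest.

#' Pipeline run configuration
#'
#' Bundles all stage parameters. Everything is echoed into the run manifest
#' so a run can be reproduced bit-identically from its output directory.
#'
#' @param spec A [cartridge_spec()].
#' @param sim A [sim_config()].
#' @param seg A [seg_params()].
#' @param gate A [gate_thresholds()].
#' @param stain_thresh PE stain threshold for [extract_features()].
#' @param margin_px,merge_overlapping Reference-rectangle emulation
#'   parameters (see [emulate_reference_segmentation()]).
#' @param tau_min,tau_cov Match-quality overlap thresholds (see
#'   [match_events()]).
#' @param heatmap_rows,heatmap_cols Edge-heatmap grid.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param seed Root seed; overrides `sim$seed` when given.
#' @return A `RunConfig` object.
#' @export
run_config <- function(spec = cartridge_spec(n_frames = 5,
                                             frame_height_px = 160,
                                             frame_width_px = 200),
                       sim = sim_config(n_tumor = 12, n_leukocyte = 60,
                                        n_tdev = 10, n_bare_nucleus = 6),
                       seg = seg_params(),
                       gate = gate_thresholds(),
                       stain_thresh = 45,
                       margin_px = 10, merge_overlapping = FALSE,
                       tau_min = 0.2, tau_cov = 0.8,
                       heatmap_rows = 25, heatmap_cols = 31,
                       out_dir = NULL, seed = NULL) {
  cfg <- structure(list(spec = spec, sim = sim, seg = seg, gate = gate,
                        stain_thresh = stain_thresh, margin_px = margin_px,
                        merge_overlapping = merge_overlapping,
                        tau_min = tau_min, tau_cov = tau_cov,
                        heatmap_rows = heatmap_rows,
                        heatmap_cols = heatmap_cols,
                        out_dir = out_dir, seed = seed),
                   class = "RunConfig")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  ok <- inherits(cfg$spec, "CartridgeSpec") &&
    inherits(cfg$sim, "SimConfig") && inherits(cfg$seg, "SegParams") &&
    inherits(cfg$gate, "GateThresholds") &&
    is_fraction(cfg$tau_min) && is_fraction(cfg$tau_cov) &&
    is_count(cfg$margin_px) && cfg$stain_thresh >= 0 &&
    is_count(cfg$heatmap_rows, 2) && is_count(cfg$heatmap_cols, 2) &&
    (is.null(cfg$seed) || is_count(cfg$seed))
  if (!ok) {
    stop(errorCondition("invalid run configuration",
                        class = c("ctc_validation_error", "error",
                                  "condition")))
  }
  invisible(cfg)
}

#' Run the full pipeline on one synthetic cartridge
#'
#' Executes simulate, segment, feature extraction, candidate gating,
#' novel-candidate selection against the emulated reference rectangles, and
#' the comparison/audit statistics. When `cfg$out_dir` is set, all artifacts
#' (frames, label maps, polygons, event and candidate CSVs, comparison and
#' audit JSON, heatmap PNG) plus a manifest sufficient to re-run the
#' pipeline bit-identically are written there.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List with `archive`, `segmentation` (per frame), `events`,
#'   `candidates`, `matches`, `report`, `audit`, `heatmap`, `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  validate_run_config(cfg)
  t0 <- Sys.time()
  if (!is.null(cfg$seed)) cfg$sim$seed <- as.integer(cfg$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "ctc_validation_error")) stop(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  say("[simulate] %d frames, %d objects",
      cfg$spec$n_frames, sum(cfg$sim$counts))
  archive <- stage("simulate", generate_cartridge(cfg$spec, cfg$sim))
  tmasks <- truth_masks(archive$truth, cfg$spec)

  say("[segment] prob_thresh %.2f nms_thresh %.2f",
      cfg$seg$prob_thresh, cfg$seg$nms_thresh)
  seg <- stage("segment", lapply(archive$frames, segment, params = cfg$seg))

  say("[gate] extracting features")
  events <- stage("extract", do.call(rbind, lapply(
    seq_along(seg), function(f)
      extract_features(seg[[f]]$labels, archive$frames[[f]],
                       stain_thresh = cfg$stain_thresh, frame = f))))
  events <- stage("gate", candidate_gate(events, cfg$gate))
  rects <- stage("reference", emulate_reference_segmentation(
    archive$truth, cfg$spec, margin_px = cfg$margin_px,
    merge_overlapping = cfg$merge_overlapping))
  candidates <- stage("select", select_candidates(events, rects, cfg$gate))

  say("[compare] matching %d truth objects", nrow(archive$truth))
  matches <- stage("compare", do.call(rbind, lapply(
    seq_along(seg), function(f) {
      in_f <- archive$truth$frame == f
      if (!any(in_f)) return(NULL)
      match_events(tmasks[in_f], seg[[f]]$labels,
                   tau_min = cfg$tau_min, tau_cov = cfg$tau_cov)
    })))
  report <- if (!is.null(matches) && nrow(matches) > 0)
    recovery_report(matches) else NULL
  audit <- stage("audit", size_audit(
    list(rects$area_px),
    cartridge_area_px = cfg$spec$n_frames *
      cfg$spec$frame_height_px * cfg$spec$frame_width_px))
  heat <- stage("heatmap", edge_heatmap(
    candidates,
    frame_dims = c(cfg$spec$frame_height_px, cfg$spec$frame_width_px),
    n_rows = cfg$heatmap_rows, n_cols = cfg$heatmap_cols))

  manifest <- list(
    tool = "ctcsegaudit",
    version = as.character(utils::packageVersion("ctcsegaudit")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = cfg$sim$seed,
    config = serialize_config(cfg))
  out <- list(archive = archive, segmentation = seg, events = events,
              candidates = candidates, matches = matches, report = report,
              audit = audit, heatmap = heat, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(out, cfg)
  }
  out
}

serialize_config <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x)  # keep names in YAML maps
    else x
  }
  strip(cfg[setdiff(names(cfg), "out_dir")])
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(cfg$out_dir, ...)
  for (f in seq_along(out$archive$frames)) {
    write_channel_stack(out$archive$frames[[f]],
                        pth(sprintf("frame_%03d.tif", f)))
    write_label_map(out$segmentation[[f]]$labels,
                    pth(sprintf("labels_%03d.tif", f)))
    write_polygons_geojson(out$segmentation[[f]]$polygons,
                           pth(sprintf("polygons_%03d.geojson", f)),
                           frame = f)
  }
  utils::write.csv(truth_table(out$archive), pth("truth.csv"),
                   row.names = FALSE)
  write_events_csv(out$events, pth("events.csv"))
  write_events_csv(out$candidates, pth("candidates.csv"))
  jsonlite::write_json(list(thresholds = unclass(cfg$gate),
                            stain_thresh = cfg$stain_thresh),
                       pth("gate_thresholds.json"), auto_unbox = TRUE)
  if (!is.null(out$report)) {
    jsonlite::write_json(list(
      n_reference = out$report$n_reference,
      counts = as.list(out$report$counts),
      percentages = as.list(out$report$percentages),
      recovery_pct = out$report$recovery_pct,
      recovery_pct_unrounded =
        100 * (out$report$n_reference - out$report$counts[["missed"]]) /
          out$report$n_reference),
      pth("comparison.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(out$audit, pth("audit.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(
    n_events = out$heatmap$n_events,
    edge_fraction = out$heatmap$edge_fraction,
    uniform_expected_fraction = out$heatmap$uniform_expected_fraction),
    pth("heatmap.json"), auto_unbox = TRUE, digits = NA, na = "null")
  write_heatmap_png(out$heatmap$counts, pth("heatmap.png"))
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  out$manifest$checksums <- as.list(tools::md5sum(files))
  names(out$manifest$checksums) <- basename(files)
  jsonlite::write_json(out$manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); a `RunConfig` (read).
#' @export
write_run_config_yaml <- function(cfg, path) {
  yaml::write_yaml(serialize_config(cfg), path)
  invisible(path)
}

#' @rdname write_run_config_yaml
#' @export
read_run_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(cartridge_spec, y$spec)
  sim_args <- y$sim
  cnt <- as.list(sim_args$counts)
  sim_args$counts <- NULL
  sim_args$intensity <- if (is.null(sim_args$intensity))
    default_intensity_model() else
    lapply(sim_args$intensity, function(cl) lapply(cl, unlist))
  sim_args$radius_um <- if (is.null(sim_args$radius_um))
    default_radius_model() else lapply(sim_args$radius_um, unlist)
  sim <- do.call(sim_config, c(list(n_tumor = cnt$tumor %||% 0,
                                    n_leukocyte = cnt$leukocyte %||% 0,
                                    n_tdev = cnt$tdev %||% 0,
                                    n_bare_nucleus = cnt$bare_nucleus %||% 0),
                               sim_args))
  run_config(spec = spec, sim = sim,
             seg = do.call(seg_params, y$seg),
             gate = do.call(gate_thresholds, y$gate),
             stain_thresh = y$stain_thresh,
             margin_px = y$margin_px,
             merge_overlapping = y$merge_overlapping,
             tau_min = y$tau_min, tau_cov = y$tau_cov,
             heatmap_rows = y$heatmap_rows, heatmap_cols = y$heatmap_cols,
             seed = y$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
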