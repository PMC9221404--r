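# Per-event feature extraction and the rule-based candidate-CTC gate.

#' Candidate-CTC gate thresholds
#'
#' Staining-and-morphology rule defining a possible CTC among segmented
#' events: cytokeratin-PE intensity maximum > 75 and mean > 45, DAPI maximum
#' > 60 and mean > 50, CD45-APC mean < 50 OR PE mean > 1000 (the override
#' allows for PE-to-APC spectral crosstalk in very bright PE events), total
#' event area between 36 and 1000 pixels (inclusive), and a PE-stained area
#' of at least 30 pixels. Intensity clauses are strict inequalities; the
#' area bounds are inclusive.
#'
#' @param pe_max_min,pe_mean_min PE maximum/mean lower bounds.
#' @param dapi_max_min,dapi_mean_min DAPI maximum/mean lower bounds.
#' @param apc_mean_max APC mean upper bound.
#' @param pe_mean_crosstalk_override PE mean above which the APC clause is
#'   waived.
#' @param area_min_px,area_max_px Inclusive event-area bounds in pixels.
#' @param stained_pe_area_min_px Minimum number of in-event pixels with PE
#'   above the stain threshold.
#' @return A `GateThresholds` object.
#' @export
gate_thresholds <- function(pe_max_min = 75, pe_mean_min = 45,
                            dapi_max_min = 60, dapi_mean_min = 50,
                            apc_mean_max = 50,
                            pe_mean_crosstalk_override = 1000,
                            area_min_px = 36, area_max_px = 1000,
                            stained_pe_area_min_px = 30) {
  stopifnot(area_min_px < area_max_px,
            pe_max_min >= 0, pe_mean_min >= 0, dapi_max_min >= 0,
            dapi_mean_min >= 0, apc_mean_max >= 0,
            pe_mean_crosstalk_override >= 0, area_min_px >= 0,
            stained_pe_area_min_px >= 0)
  structure(list(pe_max_min = pe_max_min, pe_mean_min = pe_mean_min,
                 dapi_max_min = dapi_max_min, dapi_mean_min = dapi_mean_min,
                 apc_mean_max = apc_mean_max,
                 pe_mean_crosstalk_override = pe_mean_crosstalk_override,
                 area_min_px = area_min_px, area_max_px = area_max_px,
                 stained_pe_area_min_px = stained_pe_area_min_px),
            class = "GateThresholds")
}

#' Extract per-event features from a label map
#'
#' One record per nonzero label: pixel centroid, area, per-channel mean and
#' max over the raw (unenhanced) channel intensities, and the PE-stained
#' area (in-event pixels with raw PE above `stain_thresh`). Gate thresholds
#' refer to instrument intensities, so features are never computed on
#' enhanced images.
#'
#' @param labels Integer label matrix (0 = background).
#' @param stack A `ChannelStack` of the same dimensions.
#' @param stain_thresh PE level above which a pixel counts as stained.
#' @param frame Frame index recorded in the output.
#' @return Data frame with columns id, frame, row, col, area_px, dapi_mean,
#'   dapi_max, pe_mean, pe_max, apc_mean, stained_pe_area_px.
#' @export
extract_features <- function(labels, stack, stain_thresh = 45, frame = 1L) {
  stopifnot(is.matrix(labels), inherits(stack, "ChannelStack"),
            all(dim(labels) == dim(stack$dapi)))
  empty <- data.frame(id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0),
                      area_px = integer(0),
                      dapi_mean = numeric(0), dapi_max = numeric(0),
                      pe_mean = numeric(0), pe_max = numeric(0),
                      apc_mean = numeric(0),
                      stained_pe_area_px = integer(0))
  idx <- which(labels > 0)
  if (length(idx) == 0) return(empty)
  l <- labels[idx]
  H <- nrow(labels)
  rr <- ((idx - 1) %% H) + 1
  cc <- ((idx - 1) %/% H) + 1
  ids <- sort(unique(l))
  lf <- factor(l, levels = ids)
  area <- as.integer(tabulate(lf))
  agg <- function(v, f) as.numeric(tapply(v, lf, f))
  data.frame(
    id = ids, frame = as.integer(frame),
    row = agg(rr, mean), col = agg(cc, mean),
    area_px = area,
    dapi_mean = agg(stack$dapi[idx], mean),
    dapi_max = agg(stack$dapi[idx], max),
    pe_mean = agg(stack$pe[idx], mean),
    pe_max = agg(stack$pe[idx], max),
    apc_mean = agg(stack$apc[idx], mean),
    stained_pe_area_px = as.integer(
      tapply(stack$pe[idx] > stain_thresh, lf, sum)))
}

gate_clauses <- c("pe_max", "pe_mean", "dapi_max", "dapi_mean",
                  "apc_mean", "area", "stained_pe_area")

#' Apply the candidate-CTC gate
#'
#' Vectorized over an event table. An event passes iff every clause of
#' [gate_thresholds()] holds; for failing events the violated clauses are
#' listed by name (`pe_max`, `pe_mean`, `dapi_max`, `dapi_mean`, `apc_mean`,
#' `area`, `stained_pe_area`).
#'
#' @param records Event table from [extract_features()].
#' @param thresholds A [gate_thresholds()].
#' @return `records` with added logical `gate_pass` and character
#'   `failed_criteria` (semicolon-separated, empty when passing).
#' @export
candidate_gate <- function(records, thresholds = gate_thresholds()) {
  stopifnot(inherits(thresholds, "GateThresholds"))
  t <- thresholds
  ok <- cbind(
    pe_max = records$pe_max > t$pe_max_min,
    pe_mean = records$pe_mean > t$pe_mean_min,
    dapi_max = records$dapi_max > t$dapi_max_min,
    dapi_mean = records$dapi_mean > t$dapi_mean_min,
    apc_mean = records$apc_mean < t$apc_mean_max |
      records$pe_mean > t$pe_mean_crosstalk_override,
    area = records$area_px >= t$area_min_px &
      records$area_px <= t$area_max_px,
    stained_pe_area = records$stained_pe_area_px >= t$stained_pe_area_min_px)
  records$gate_pass <- as.logical(rowSums(!ok) == 0)
  records$failed_criteria <- if (nrow(records) == 0) character(0) else
    apply(ok, 1, function(r) paste(gate_clauses[!r], collapse = ";"))
  records
}

#' Select novel candidates outside the reference segmentation
#'
#' Keeps gate-passing events whose centroid lies inside no reference
#' rectangle of the same frame: the events a rectangle-based reference
#' segmentation would never have presented for review.
#'
#' @param records Gated event table (from [candidate_gate()]; events without
#'   a `gate_pass` column are gated first with `thresholds`).
#' @param rectangles Reference rectangles as from
#'   [emulate_reference_segmentation()] (columns frame, r0, r1, c0, c1;
#'   1-based inclusive bounds).
#' @param thresholds A [gate_thresholds()] (used only if `records` is
#'   ungated).
#' @return The subset of `records` that passes the gate and lies outside all
#'   rectangles.
#' @export
select_candidates <- function(records, rectangles,
                              thresholds = gate_thresholds()) {
  if (is.null(records$gate_pass)) {
    records <- candidate_gate(records, thresholds)
  }
  if (nrow(records) == 0) return(records[records$gate_pass, , drop = FALSE])
  inside <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    rs <- rectangles[rectangles$frame == r$frame, , drop = FALSE]
    any(rs$r0 <= r$row & r$row <= rs$r1 & rs$c0 <= r$col & r$col <= rs$c1)
  }, logical(1))
  records[records$gate_pass & !inside, , drop = FALSE]
}
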