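# Comparison and audit statistics: recovery and split/merge/partial/missed
# classification, segmentation-size audit, event-density CDFs with
# stochastic-dominance flags, spike-in correlation, edge heatmap, and
# CTC-gain regression with risk-group conversion.

#' Match ground-truth objects against a test label map
#'
#' Classifies every reference (truth) object by how the test segmentation
#' covers it. With `o(t, l)` the fraction of truth mask `t` covered by test
#' label `l`, a truth object is:
#' \itemize{
#'   \item \code{missed}: no test label has `o >= tau_min`;
#'   \item \code{merged}: its best-matching test label also covers
#'     `>= tau_min` of another truth object;
#'   \item \code{split}: at least two test labels each cover `>= tau_min`
#'     of it;
#'   \item \code{partial}: the union of its matched labels covers less than
#'     `tau_cov` of it;
#'   \item \code{correct}: otherwise.
#' }
#' Rules are applied in that order, so every reference gets exactly one
#' quality class.
#'
#' @param truth_masks List of integer vectors: column-major linear pixel
#'   indices per truth object (see [truth_masks()]).
#' @param labels Integer test label matrix.
#' @param tau_min Minimum coverage fraction for a label to count as matching
#'   a truth object.
#' @param tau_cov Minimum union coverage for a non-partial segmentation.
#' @return Data frame with columns truth_id, quality, matched (semicolon
#'   separated test label ids), best_label, coverage.
#' @export
match_events <- function(truth_masks, labels, tau_min = 0.2,
                         tau_cov = 0.8) {
  stopifnot(is.matrix(labels), is_fraction(tau_min), is_fraction(tau_cov))
  n <- length(truth_masks)
  ids <- names(truth_masks)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  npx <- length(labels)
  matched <- vector("list", n)
  best <- integer(n)
  coverage <- numeric(n)
  for (i in seq_len(n)) {
    m <- truth_masks[[i]]
    stopifnot(all(m >= 1 & m <= npx))
    lab <- labels[m]
    lab <- lab[lab > 0]
    if (length(lab) == 0) {
      matched[[i]] <- integer(0); best[i] <- 0L; coverage[i] <- 0
      next
    }
    tab <- table(lab)
    frac <- as.numeric(tab) / length(m)
    lid <- as.integer(names(tab))
    sel <- frac >= tau_min
    matched[[i]] <- lid[sel]
    best[i] <- if (any(sel)) lid[sel][which.max(frac[sel])] else 0L
    coverage[i] <- sum(frac[sel])
  }
  # does a test label match (>= tau_min) more than one truth object?
  label_hits <- table(unlist(matched))
  quality <- character(n)
  for (i in seq_len(n)) {
    quality[i] <-
      if (length(matched[[i]]) == 0) "missed"
      else if (label_hits[as.character(best[i])] > 1) "merged"
      else if (length(matched[[i]]) >= 2) "split"
      else if (coverage[i] < tau_cov) "partial"
      else "correct"
  }
  data.frame(truth_id = ids, quality = quality,
             matched = vapply(matched, paste, character(1), collapse = ";"),
             best_label = best, coverage = coverage,
             stringsAsFactors = FALSE)
}

QUALITY_LEVELS <- c("correct", "split", "partial", "merged", "missed")

#' Recovery and segmentation-quality report
#'
#' Tallies the quality classes of a match table (or takes the tallies
#' directly) and computes the per-class percentages (1 decimal) and the
#' recovery percentage `100 * (n - missed) / n` (2 decimals), matching the
#' printed precision such reports are quoted at.
#'
#' @param matches A data frame from [match_events()], or a named numeric
#'   vector/list of counts with names among
#'   `correct, split, partial, merged, missed`.
#' @return A `ComparisonReport`: list with `n_reference`, `counts`,
#'   `percentages` (1 decimal), `recovery_pct` (2 decimals).
#' @export
recovery_report <- function(matches) {
  counts <- if (is.data.frame(matches)) {
    if (nrow(matches) == 0) stop("empty match table", call. = FALSE)
    table(factor(matches$quality, levels = QUALITY_LEVELS))
  } else {
    v <- unlist(matches)
    stopifnot(all(names(v) %in% QUALITY_LEVELS), all(v >= 0), sum(v) > 0)
    full <- stats::setNames(numeric(length(QUALITY_LEVELS)), QUALITY_LEVELS)
    full[names(v)] <- v
    full
  }
  counts <- stats::setNames(as.numeric(counts), QUALITY_LEVELS)
  n <- sum(counts)
  structure(list(
    n_reference = n,
    counts = counts,
    percentages = round(100 * counts / n, 1),
    recovery_pct = round(100 * (n - counts[["missed"]]) / n, 2)),
    class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat(sprintf("ComparisonReport: %d references, recovery %.2f%%\n",
              x$n_reference, x$recovery_pct))
  for (q in QUALITY_LEVELS) {
    cat(sprintf("  %-8s %6d  (%.1f%%)\n", q, x$counts[[q]],
                x$percentages[[q]]))
  }
  invisible(x)
}

#' Segmentation-size audit
#'
#' Summarizes per-sample segmentation areas in four size categories:
#' regular single-cell size, larger than a cell, too large to review, and
#' very large. For each category it reports the percentage of samples
#' containing at least one such segmentation, and the mean (and range) of
#' the per-sample percentage of cartridge area and of total segmented area
#' in that category.
#'
#' @param sample_areas List with one numeric vector of segmentation areas
#'   (pixels, >= 1) per sample.
#' @param bins Strictly increasing size boundaries; the default
#'   `c(2500, 25000, 100000)` gives categories `<=2500`, `2500-25,000`,
#'   `25,000-100,000`, `>100,000`.
#' @param cartridge_area_px Total cartridge area in pixels (> 0); defaults
#'   to 140 frames of 977 x 1211.
#' @return Data frame with one row per category: bin label, pct_samples,
#'   mean/min/max pct of cartridge area, mean/min/max pct of segmented area
#'   (all percentages rounded to 2 decimals).
#' @export
size_audit <- function(sample_areas,
                       bins = c(2500, 25000, 100000),
                       cartridge_area_px = 140 * 977 * 1211) {
  stopifnot(is.list(sample_areas), length(sample_areas) > 0,
            all(diff(bins) > 0), cartridge_area_px > 0)
  stopifnot(all(vapply(sample_areas, function(a)
    length(a) == 0 || all(a >= 1), logical(1))))
  edges <- c(0, bins, Inf)
  nb <- length(edges) - 1
  fmt <- function(x) format(x, big.mark = ",", scientific = FALSE,
                            trim = TRUE)
  labels <- c(sprintf("<=%s", fmt(bins[1])),
              sprintf("%s-%s", fmt(bins[-length(bins)]), fmt(bins[-1])),
              sprintf(">%s", fmt(bins[length(bins)])))
  per_sample <- t(vapply(sample_areas, function(a) {
    binned <- cut(a, edges, labels = FALSE, right = TRUE)
    vapply(seq_len(nb), function(b) sum(a[binned == b]), numeric(1))
  }, numeric(nb)))
  has_bin <- per_sample > 0
  total_seg <- rowSums(per_sample)
  pct_cart <- 100 * per_sample / cartridge_area_px
  pct_seg <- 100 * per_sample / ifelse(total_seg > 0, total_seg, NA)
  data.frame(
    bin = labels,
    pct_samples = round(100 * colMeans(has_bin), 2),
    pct_cartridge_area_mean = round(colMeans(pct_cart), 2),
    pct_cartridge_area_min = round(apply(pct_cart, 2, min), 2),
    pct_cartridge_area_max = round(apply(pct_cart, 2, max), 2),
    pct_segmented_area_mean = round(colMeans(pct_seg, na.rm = TRUE), 2),
    pct_segmented_area_min = round(apply(pct_seg, 2, min, na.rm = TRUE), 2),
    pct_segmented_area_max = round(apply(pct_seg, 2, max, na.rm = TRUE), 2))
}

#' Event-density empirical CDFs by sample age
#'
#' Groups per-sample event counts by days between collection and
#' preparation, returns per-group empirical CDFs and medians, and flags
#' pairwise first-order stochastic dominance: group A dominates group B iff
#' `CDF_A(x) >= CDF_B(x)` at every pooled x with strict inequality
#' somewhere (i.e. A's counts are stochastically smaller).
#'
#' @param counts Numeric vector of per-sample event counts.
#' @param group Grouping vector (e.g. days to prep), same length.
#' @return List with `groups`, `medians`, `ecdf` (list of functions), and
#'   `dominates` (logical matrix: `[A, B]` true iff A dominates B).
#' @export
density_cdf <- function(counts, group) {
  stopifnot(length(counts) == length(group), length(counts) > 0)
  keep <- !is.na(counts) & !is.na(group)
  counts <- counts[keep]; group <- as.character(group[keep])
  sizes <- table(group)
  if (any(sizes == 0)) warning("empty groups excluded")
  gs <- names(sizes)[sizes > 0]
  cdfs <- lapply(gs, function(g) stats::ecdf(counts[group == g]))
  names(cdfs) <- gs
  medians <- vapply(gs, function(g) stats::median(counts[group == g]),
                    numeric(1))
  xs <- sort(unique(counts))
  dom <- matrix(FALSE, length(gs), length(gs), dimnames = list(gs, gs))
  for (a in gs) for (b in gs) {
    if (a == b) next
    fa <- cdfs[[a]](xs); fb <- cdfs[[b]](xs)
    dom[a, b] <- all(fa >= fb) && any(fa > fb)
  }
  list(groups = gs, medians = medians, ecdf = cdfs, dominates = dom)
}

ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) {
    stop("degenerate predictor: zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("RegressionFit: y = %.4f x + %.4f,  R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Spike-in correlation
#'
#' Ordinary least squares of detected event counts on spiked cell counts
#' across a dilution series. The intercept estimates the excess of detected
#' events at zero spiked cells (debris, vesicles and other small events).
#'
#' @param spiked Numeric vector of spiked cell counts (>= 3 points).
#' @param detected Numeric vector of detected event counts.
#' @return A `RegressionFit` (slope, intercept, r_squared) with an extra
#'   `excess` element equal to the intercept.
#' @export
spikein_correlation <- function(spiked, detected) {
  fit <- ols_fit(spiked, detected)
  fit$excess <- fit$intercept
  fit
}

#' Edge heatmap of event positions
#'
#' Bins event positions into an `n_rows x n_cols` grid tiling the frame and
#' reports the fraction of events in an edge bin (first or last grid row or
#' column) together with the area-weighted fraction expected under a
#' uniform distribution (the edge bins' share of the frame area).
#'
#' @param positions Matrix or data frame with columns `row`, `col`
#'   (1-based pixel coordinates within one frame).
#' @param frame_dims Frame dimensions `(height, width)`.
#' @param n_rows,n_cols Grid size; 25 x 31 bins of about 25 x 25 um at the
#'   default frame geometry.
#' @return List with `counts` (n_rows x n_cols matrix), `n_events`,
#'   `edge_fraction` (NA when there are no events), and
#'   `uniform_expected_fraction`.
#' @export
edge_heatmap <- function(positions, frame_dims, n_rows = 25, n_cols = 31) {
  stopifnot(length(frame_dims) == 2, is_count(n_rows, 2), is_count(n_cols, 2))
  H <- frame_dims[1]; W <- frame_dims[2]
  if (is.data.frame(positions)) {
    positions <- cbind(positions$row, positions$col)
  }
  counts <- matrix(0L, n_rows, n_cols)
  n <- if (is.null(positions)) 0L else nrow(positions)
  if (n > 0) {
    stopifnot(all(positions[, 1] >= 0.5 & positions[, 1] <= H + 0.5),
              all(positions[, 2] >= 0.5 & positions[, 2] <= W + 0.5))
    br <- pmin(pmax(ceiling(positions[, 1] / H * n_rows), 1L), n_rows)
    bc <- pmin(pmax(ceiling(positions[, 2] / W * n_cols), 1L), n_cols)
    for (i in seq_len(n)) counts[br[i], bc[i]] <- counts[br[i], bc[i]] + 1L
  }
  edge <- matrix(FALSE, n_rows, n_cols)
  edge[c(1, n_rows), ] <- TRUE
  edge[, c(1, n_cols)] <- TRUE
  # area-weighted uniform expectation: the interior is a
  # (n_rows-2)/n_rows by (n_cols-2)/n_cols fraction of the frame
  uniform_expected <- 1 - ((n_rows - 2) / n_rows) * ((n_cols - 2) / n_cols)
  list(counts = counts,
       n_events = n,
       edge_fraction = if (n == 0) NA_real_ else sum(counts[edge]) / n,
       uniform_expected_fraction = uniform_expected)
}

#' CTC-gain regression and risk-group conversion
#'
#' Compares per-sample CTC counts from an original review with the combined
#' counts after adding the events found only by the improved segmentation.
#' Fits combined = slope * original + intercept by OLS and tabulates risk
#' conversions at the 5-CTC prognostic threshold plus zero-to-nonzero gains.
#'
#' @param original Per-sample CTC counts from the original review.
#' @param combined Per-sample combined counts; must be `>= original`
#'   element-wise (review can only add CTC).
#' @param risk_threshold CTC count defining the higher-risk group.
#' @return List with `fit` (a `RegressionFit`) and `risk` (named counts:
#'   n_samples, n_low_to_high, n_zero, n_zero_gain).
#' @export
gain_analysis <- function(original, combined, risk_threshold = 5) {
  stopifnot(length(original) == length(combined))
  if (any(combined < original)) {
    stop("combined counts must be >= original counts", call. = FALSE)
  }
  fit <- ols_fit(original, combined)
  risk <- c(n_samples = length(original),
            n_low_to_high = sum(original < risk_threshold &
                                combined >= risk_threshold),
            n_zero = sum(original == 0),
            n_zero_gain = sum(original == 0 & combined > 0))
  list(fit = fit, risk = risk)
}
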