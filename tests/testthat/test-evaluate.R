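test_that("matching classifies identity, split and merge archetypes", {
  labels <- matrix(0L, 40, 40)
  labels[5:14, 5:14] <- 1L
  labels[25:34, 25:34] <- 2L
  tm <- list(a = which(labels == 1), b = which(labels == 2))
  m <- match_events(tm, labels)
  expect_equal(m$quality, c("correct", "correct"))
  # one truth mask bisected into two labels -> split
  split_lab <- labels
  split_lab[5:14, 5:9] <- 1L; split_lab[5:14, 10:14] <- 3L
  ms <- match_events(tm["a"], split_lab)
  expect_equal(ms$quality, "split")
  # one label covering two truth objects -> both merged
  merged_lab <- matrix(0L, 40, 40)
  merged_lab[5:34, 5:34] <- 1L
  mm <- match_events(tm, merged_lab)
  expect_equal(mm$quality, c("merged", "merged"))
  # nothing segmented -> missed
  expect_equal(match_events(tm, matrix(0L, 40, 40))$quality,
               c("missed", "missed"))
  # partial: label covers just over half of the object
  part_lab <- matrix(0L, 40, 40)
  part_lab[5:14, 5:10] <- 1L
  expect_equal(match_events(tm["a"], part_lab)$quality, "partial")
})

test_that("matching agrees with a brute-force overlap oracle", {
  for (trial in 1:20) {
    set.seed(trial + 900)
    dims <- c(60, 60)
    n_truth <- sample(2:6, 1)
    tm <- lapply(seq_len(n_truth), function(i) {
      ctr <- c(sample(10:50, 1), sample(10:50, 1))
      which(disk_mask(dims, ctr, sample(4:8, 1)))
    })
    labels <- matrix(0L, dims[1], dims[2])
    for (k in seq_len(sample(2:8, 1))) {
      ctr <- c(sample(10:50, 1), sample(10:50, 1))
      px <- which(disk_mask(dims, ctr, sample(3:8, 1)))
      px <- px[labels[px] == 0]
      labels[px] <- k
    }
    got <- match_events(tm, labels)$quality
    expect_equal(got, match_oracle(tm, labels))
  }
})

test_that("quality classes partition the references", {
  set.seed(41)
  labels <- matrix(0L, 60, 60)
  for (k in 1:6) {
    px <- which(disk_mask(c(60, 60), c(sample(10:50, 1), sample(10:50, 1)), 6))
    px <- px[labels[px] == 0]
    labels[px] <- k
  }
  tm <- lapply(1:5, function(i)
    which(disk_mask(c(60, 60), c(sample(10:50, 1), sample(10:50, 1)), 6)))
  m <- match_events(tm, labels)
  r <- recovery_report(m)
  expect_equal(sum(r$counts), r$n_reference)
  expect_equal(r$n_reference, 5)
})

test_that("recovery reports round percentages at printed precision", {
  r <- recovery_report(c(correct = 1914, split = 14, partial = 8,
                         merged = 11, missed = 1))
  expect_equal(r$n_reference, 1948)
  expect_equal(r$recovery_pct, 99.95)
  expect_equal(unname(r$percentages[c("split", "partial", "merged")]),
               c(0.7, 0.4, 0.6))
  all_ok <- recovery_report(c(correct = 12))
  expect_equal(all_ok$recovery_pct, 100.00)
  expect_true(all(all_ok$percentages[c("split", "partial", "merged",
                                       "missed")] == 0))
  half <- recovery_report(c(correct = 5, missed = 5))
  expect_equal(half$recovery_pct, 50.00)
  expect_error(recovery_report(data.frame(quality = character(0))), "empty")
})

test_that("the size audit reproduces worked percentages", {
  # 55 of 601 samples contain a very large segmentation
  areas <- c(rep(list(c(1000, 150000)), 55), rep(list(c(1000)), 546))
  aud <- size_audit(areas, cartridge_area_px = 1e9)
  expect_equal(aud$pct_samples[aud$bin == ">100,000"], 9.15)
  # single sample, one small segmentation
  aud1 <- size_audit(list(100), cartridge_area_px = 1e6)
  expect_equal(aud1$pct_samples, c(100, 0, 0, 0))
  expect_equal(aud1$pct_segmented_area_mean, c(100, 0, 0, 0))
  # {1000, 30000}: segmented-area split 3.23% / 96.77%
  aud2 <- size_audit(list(c(1000, 30000)), cartridge_area_px = 1e6)
  expect_equal(aud2$pct_segmented_area_mean, c(3.23, 0, 96.77, 0))
})

test_that("segmented-area percentages always sum to 100", {
  set.seed(77)
  for (trial in 1:10) {
    areas <- lapply(seq_len(sample(3:30, 1)), function(i)
      stats::rlnorm(sample(1:40, 1), meanlog = 7, sdlog = 2))
    aud <- size_audit(areas, cartridge_area_px = 1e9)
    expect_equal(sum(aud$pct_segmented_area_mean), 100, tolerance = 0.1)
  }
})

test_that("density CDFs detect first-order stochastic dominance", {
  # identical groups: no strict dominance either way
  d0 <- density_cdf(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_false(any(d0$dominates))
  # a positive shift makes the unshifted group dominant
  set.seed(2)
  x <- stats::rpois(40, 20)
  d1 <- density_cdf(c(x, x + 15), rep(c("d1", "d4"), each = 40))
  expect_true(d1$dominates["d1", "d4"])
  expect_false(d1$dominates["d4", "d1"])
  # arithmetic on a tiny group
  d2 <- density_cdf(c(1, 2, 3), rep("g", 3))
  expect_equal(unname(d2$medians["g"]), 2)
  expect_equal(d2$ecdf$g(2), 2 / 3)
  # CDFs are nondecreasing and reach 1
  f <- d1$ecdf$d1
  xs <- sort(unique(c(x, x + 15)))
  expect_true(all(diff(f(xs)) >= 0))
  expect_equal(f(max(xs)), 1)
})

test_that("dominance is antisymmetric on random groups", {
  set.seed(9)
  for (trial in 1:10) {
    counts <- stats::rpois(60, sample(10:40, 1)) +
      rep(sample(0:10, 3, replace = TRUE), each = 20)
    d <- density_cdf(counts, rep(c("a", "b", "c"), each = 20))
    both <- d$dominates & t(d$dominates)
    expect_false(any(both))
  }
})

test_that("spike-in regression recovers exact and noisy lines", {
  spiked <- c(0, 50, 100, 150, 200, 300, 400) * 1000
  f1 <- spikein_correlation(spiked, spiked)
  expect_equal(f1$slope, 1); expect_equal(f1$intercept, 0)
  expect_equal(f1$r_squared, 1)
  f2 <- spikein_correlation(spiked, spiked + 30000)
  expect_equal(f2$slope, 1, tolerance = 1e-12)
  expect_equal(f2$excess, 30000, tolerance = 1e-9)
  set.seed(4)
  f3 <- spikein_correlation(spiked, 0.9 * spiked + stats::rnorm(7, sd = 1000))
  expect_gte(f3$slope, 0.85); expect_lte(f3$slope, 0.95)
  expect_error(spikein_correlation(rep(5, 4), 1:4), "degenerate")
})

test_that("edge heatmap counts edge bins against the uniform expectation", {
  dims <- c(500, 620)
  mid <- cbind(rep(250, 10), rep(310, 10))
  h0 <- edge_heatmap(mid, dims)
  expect_equal(h0$edge_fraction, 0)
  corner <- cbind(c(1, 1, 499.6), c(1, 619.5, 1))
  expect_equal(edge_heatmap(corner, dims)$edge_fraction, 1)
  expect_true(is.na(edge_heatmap(NULL, dims)$edge_fraction))
  # uniform positions land in edge bins at the area-weighted rate
  set.seed(10)
  u <- cbind(stats::runif(1e5, 0.5, dims[1] + 0.5),
             stats::runif(1e5, 0.5, dims[2] + 0.5))
  hu <- edge_heatmap(u, dims)
  expect_equal(hu$edge_fraction, hu$uniform_expected_fraction,
               tolerance = 0.01 / hu$uniform_expected_fraction)
  expect_equal(sum(hu$counts), 1e5)
})

test_that("gain analysis fits counts and tabulates risk conversions", {
  g0 <- gain_analysis(0:10, 0:10)
  expect_equal(g0$fit$slope, 1); expect_equal(g0$fit$intercept, 0)
  expect_equal(unname(g0$risk["n_low_to_high"]), 0)
  x <- c(0, 2, 5, 10, 20)
  g1 <- gain_analysis(x, 1.2 * x + 1)
  expect_equal(g1$fit$slope, 1.2); expect_equal(g1$fit$intercept, 1)
  expect_equal(g1$fit$r_squared, 1)
  g2 <- gain_analysis(c(4, 4, 0), c(5, 4, 1))
  expect_equal(unname(g2$risk["n_low_to_high"]), 1)
  expect_equal(unname(g2$risk["n_zero_gain"]), 1)
  expect_error(gain_analysis(c(3, 4), c(3, 2)), "combined")
})

test_that("gain regression recovers a known slope from noisy counts", {
  set.seed(11)
  original <- stats::rpois(400, 4)
  noise <- pmax(0, round(stats::rnorm(400, 0, 1)))
  combined <- round(1.2 * original + 1 + noise)
  combined <- pmax(combined, original)
  g <- gain_analysis(original, combined)
  expect_equal(g$fit$slope, 1.2, tolerance = 0.05 / 1.2)
})
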