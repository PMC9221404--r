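# Shared numeric helpers.

#' Derive a child random seed from a root seed and counters
#'
#' Counter-based stream splitting: every frame / object / series member gets
#' its own reproducible seed, so results never depend on the order in which
#' frames are generated. Values stay below 2^31 (R integer range).
#'
#' @param seed Integer root seed.
#' @param ... Integer counters identifying the stream (e.g. a stage code and
#'   a frame index).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  p <- 2147483647
  x <- as.double(seed) %% p
  for (k in c(...)) {
    k2 <- as.double(k) %% p
    # multipliers kept small enough that all products stay below 2^53
    x <- (x * 48271 + k2 * 16807 + 11) %% p
    x <- (x * 69069 + 1) %% p
  }
  as.integer(x)
}

#' Percentage of a count, rounded to a fixed number of decimals
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimals to round to.
#' @return `round(100 * k / n, digits)`.
#' @export
percent_of <- function(k, n, digits = 1) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round(100 * k / n, digits)
}

# clip values into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1
}

# running min/max over a centered odd window along rows and columns,
# truncated at the image border; doubling trick keeps it O(log w) passes
roll_extreme2d <- function(m, w, op = c("min", "max")) {
  op <- match.arg(op)
  stopifnot(w %% 2 == 1, w >= 1)
  if (w == 1) return(m)
  pad <- if (op == "min") Inf else -Inf
  f <- if (op == "min") pmin else pmax
  r <- (w - 1L) / 2L
  run1 <- function(x, margin) {
    # running extreme over window w along `margin` (1 = down columns)
    n <- dim(x)[margin]
    padded <- if (margin == 1) {
      rbind(matrix(pad, r, ncol(x)), x, matrix(pad, r, ncol(x)))
    } else {
      cbind(matrix(pad, nrow(x), r), x, matrix(pad, nrow(x), r))
    }
    # forward extreme over [i, i + w - 1] in padded coordinates by doubling
    acc <- padded
    span <- 1L
    while (span < w) {
      step <- min(span, w - span)
      np <- dim(acc)[margin]
      if (margin == 1) {
        shifted <- rbind(acc[-seq_len(step), , drop = FALSE],
                         matrix(pad, step, ncol(acc)))
      } else {
        shifted <- cbind(acc[, -seq_len(step), drop = FALSE],
                         matrix(pad, nrow(acc), step))
      }
      acc <- f(acc, shifted)
      span <- span + step
    }
    if (margin == 1) acc[seq_len(n), , drop = FALSE]
    else acc[, seq_len(n), drop = FALSE]
  }
  run1(run1(m, 1L), 2L)
}
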