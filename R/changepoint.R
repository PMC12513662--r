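# Segment cost machinery for penalized least-squares mean segmentation.
# cost(i, j) = within-segment sum of squared deviations of x[i..j] from the
# segment mean, computed in O(1) from prefix sums.

cpt_prefix <- function(x) {
  list(s1 = c(0, cumsum(x)), s2 = c(0, cumsum(x^2)))
}

# cost of segments (t+1 .. j) for a vector of starts-1 `t` and fixed end j
cpt_cost_vec <- function(pf, t, j) {
  n <- j - t
  (pf$s2[j + 1] - pf$s2[t + 1]) - (pf$s1[j + 1] - pf$s1[t + 1])^2 / n
}

# Estimate noise variance from first differences: under a piecewise-constant
# mean with few changes, var(diff(x)) ~= 2 sigma^2.
cpt_sigma2 <- function(x) {
  if (length(x) < 2) return(0)
  mean(diff(x)^2) / 2
}

cpt_backtrack <- function(prev, n) {
  bps <- integer(0)
  j <- n
  while (j > 0) {
    t <- prev[j]
    if (t > 0) bps <- c(t, bps)
    j <- t
  }
  bps
}

cpt_dp <- function(x, penalty, min_seg_len, prune) {
  n <- length(x)
  pf <- cpt_prefix(x)
  f <- c(-penalty, rep(Inf, n)) # f[t + 1] = optimal cost of x[1..t] + penalty per segment
  prev <- integer(n)
  cand <- 0L # admissible last-changepoint positions (0 = series start)
  # PELT pruning with min_seg_len > 1: the competitor split at j that makes a
  # candidate t redundant is only admissible for ends >= j + min_seg_len, so a
  # flagged candidate is retired with that delay rather than immediately.
  expiry <- rep(Inf, n + 1L)
  for (j in seq_len(n)) {
    if (prune) cand <- cand[expiry[cand + 1L] > j]
    ok <- cand[cand <= j - min_seg_len]
    if (length(ok) > 0) {
      partial <- f[ok + 1L] + cpt_cost_vec(pf, ok, j)
      best <- which.min(partial)
      f[j + 1L] <- partial[best] + penalty
      prev[j] <- ok[best]
      if (prune) {
        # t whose partial cost already exceeds F(j) can never beat a split at
        # j for any end where that split is admissible (K = 0 cost class)
        flag <- ok[partial > f[j + 1L]]
        expiry[flag + 1L] <- pmin(expiry[flag + 1L], j + min_seg_len)
      }
    }
    if (j >= min_seg_len) cand <- c(cand, j)
  }
  list(breakpoints = cpt_backtrack(prev, n), cost = f[n + 1L])
}

cpt_binseg <- function(x, penalty, min_seg_len) {
  n <- length(x)
  pf <- cpt_prefix(x)
  seg_cost <- function(i, j) cpt_cost_vec(pf, i - 1L, j)
  segs <- list(c(1L, n))
  bps <- integer(0)
  repeat {
    best_gain <- 0
    best <- NULL
    for (si in seq_along(segs)) {
      i <- segs[[si]][1]; j <- segs[[si]][2]
      if (j - i + 1 < 2 * min_seg_len) next
      ts <- (i + min_seg_len - 1L):(j - min_seg_len)
      gain <- seg_cost(i, j) - (cpt_cost_vec(pf, i - 1L, ts) + cpt_cost_vec(pf, ts, j))
      wi <- which.max(gain)
      if (gain[wi] > best_gain) {
        best_gain <- gain[wi]
        best <- c(si, ts[wi])
      }
    }
    if (is.null(best) || best_gain <= penalty) break
    si <- best[1]; t <- best[2]
    seg <- segs[[si]]
    segs[[si]] <- c(seg[1], t)
    segs[[length(segs) + 1L]] <- c(t + 1L, seg[2])
    bps <- sort(c(bps, t))
  }
  list(breakpoints = bps)
}

#' Mean-shift changepoint segmentation
#'
#' Partitions a fecundity series into segments of constant mean by
#' minimizing the within-segment sum of squared deviations plus a penalty
#' per changepoint. `"pelt"` (pruned exact linear time) and `"exhaustive"`
#' (the full dynamic program) both return the global optimum; `"binseg"`
#' (binary segmentation) is the classical greedy approximation.
#'
#' The default penalty is an MBIC-style charge `3 * sigma2 * log(n)` per
#' changepoint (the modified BIC accounts for the boundary, the new segment
#' mean, and the segment-length term), with the noise variance `sigma2`
#' estimated from first differences (`mean(diff(x)^2) / 2`), which is robust
#' to the mean shifts being sought. A plain SIC charge is
#' `penalty = 2 * log(length(x)) * sigma2`.
#'
#' @param x Numeric series (e.g. per-census egg counts), length
#'   >= `2 * min_seg_len`.
#' @param penalty Non-negative penalty per changepoint; `NULL` (default)
#'   uses the MBIC-style value above.
#' @param method `"pelt"` (default), `"exhaustive"`, or `"binseg"`.
#' @param min_seg_len Minimum segment length in observations (default 2).
#' @return Object of class `mean_cpt`: list with `breakpoints` (last index
#'   of each segment except the final one), `segment_means`,
#'   `penalty_value`, `method`, `min_seg_len`, `n`, and the series `x`.
#' @examples
#' x <- c(rep(2, 20), rep(12, 20))
#' segment_mean(x, penalty = 2 * log(40))$breakpoints # 20
#' @export
segment_mean <- function(x, penalty = NULL,
                         method = c("pelt", "exhaustive", "binseg"),
                         min_seg_len = 2) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (any(!is.finite(x))) abort("series must be finite")
  if (min_seg_len < 1) abort("min_seg_len must be >= 1")
  if (n < 2 * min_seg_len) {
    abort(paste0("series too short: need at least ", 2 * min_seg_len, " points"))
  }
  penalty <- penalty %||% (3 * cpt_sigma2(x) * log(n))
  if (penalty < 0) abort("penalty must be non-negative")
  res <- switch(method,
    pelt = cpt_dp(x, penalty, min_seg_len, prune = TRUE),
    exhaustive = cpt_dp(x, penalty, min_seg_len, prune = FALSE),
    binseg = cpt_binseg(x, penalty, min_seg_len)
  )
  bps <- res$breakpoints
  starts <- c(1L, bps + 1L)
  ends <- c(bps, n)
  means <- vapply(seq_along(starts),
                  function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  structure(
    list(breakpoints = bps, segment_means = means, penalty_value = penalty,
         method = method, min_seg_len = min_seg_len, n = n, x = x),
    class = "mean_cpt"
  )
}

#' @export
print.mean_cpt <- function(x, ...) {
  cat("<mean_cpt> ", length(x$breakpoints), " changepoint(s) in ", x$n,
      " points (", x$method, ", penalty ", format(x$penalty_value, digits = 4),
      ")\n", sep = "")
  cat("  segment means: ", paste(format(x$segment_means, digits = 4),
                                 collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Map index segments to census-day spans
#'
#' Converts a segmentation of a per-census series into day spans using the
#' census-day axis: each segment runs from the census day of its first point
#' to the census day of its last.
#'
#' @param result A `mean_cpt` from [segment_mean()].
#' @param days Census days, same length as the segmented series.
#' @return Tibble with `start_day`, `end_day`, `mean`.
#' @export
segment_durations <- function(result, days) {
  stopifnot(inherits(result, "mean_cpt"))
  if (length(days) != result$n) {
    abort("days axis length does not match the segmented series")
  }
  bps <- result$breakpoints
  starts <- c(1L, bps + 1L)
  ends <- c(bps, result$n)
  tibble::tibble(
    start_day = days[starts],
    end_day = days[ends],
    mean = result$segment_means
  )
}
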