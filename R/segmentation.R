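## Segmentation engine: recursive circular binary segmentation with
## permutation-based split significance. The arc statistic and permutation
## loop live in src/cbs.cpp; this file holds the recursion and the
## user-facing surface.

#' Midranks of a numeric vector
#'
#' Ranks 1..n with tied values receiving the mean of their rank range; the
#' rank transform applied to both mutation positions and expression values
#' before segmentation, making the procedure invariant under any strictly
#' increasing transform of the raw values.
#'
#' @param v numeric vector (finite values).
#' @return Numeric vector of midranks; empty input gives an empty vector.
#' @examples
#' midrank(c(3.1, 1.2, 2.0))  # 3 1 2
#' midrank(c(5, 5, 1))        # 2.5 2.5 1
#' @export
midrank <- function(v) {
  if (!length(v)) return(numeric(0))
  if (any(!is.finite(v))) stop("midrank: values must be finite")
  rank(v, ties.method = "average")
}

#' Normalized arc-vs-complement mean statistic
#'
#' For the arc of indices `(i, j]` of `y` (so `i = 0` means the arc starts at
#' the first observation), returns
#' \deqn{Z(i,j) = \frac{\bar y_{arc} - \bar y_{comp}}{s\sqrt{1/k + 1/(n-k)}}}
#' with `k = j - i` and `s` the overall sample standard deviation. Zero by
#' convention for constant series. Invariant under `y -> a*y + b`, `a > 0`.
#'
#' This plain-R form is the reference definition; the exhaustive scans used
#' by [maxStatistic()] run compiled code with the same formula.
#'
#' @param y numeric vector.
#' @param i,j arc bounds, `0 <= i < j <= n`, arc and complement non-empty.
#' @return The signed statistic Z(i, j).
#' @export
arcStatistic <- function(y, i, j) {
  n <- length(y)
  if (i < 0 || j <= i || j > n || (j - i) >= n)
    stop("arcStatistic: need 0 <= i < j <= n with non-empty complement")
  s <- sd(y)
  if (!is.finite(s) || s <= 0) return(0)
  k <- j - i
  arc <- y[(i + 1):j]
  comp <- y[-((i + 1):j)]
  (mean(arc) - mean(comp)) / (s * sqrt(1 / k + 1 / (n - k)))
}

#' Maximal arc statistic under the minimum-width constraint
#'
#' Maximizes |Z(i,j)| over all arcs whose induced pieces each have width at
#' least `minWidth` (a boundary-touching arc splits the series into two
#' pieces; an interior arc into three). Deterministic tie-break: smallest
#' `i`, then smallest `j`.
#'
#' @param y numeric vector.
#' @param minWidth minimum piece width.
#' @return List with `i`, `j` (arc bounds as in [arcStatistic()]; -1 when no
#'   admissible arc exists) and `statistic` (0 when none exists or the series
#'   is constant).
#' @export
maxStatistic <- function(y, minWidth) {
  res <- cbs_max_stat(as.numeric(y), as.integer(minWidth))
  res$statistic <- as.numeric(res$statistic)
  res
}

#' Permutation p-value of an observed maximal statistic
#'
#' `p = (1 + B) / (nperm + 1)` where B counts random permutations of `y`
#' whose maximal arc statistic reaches `tObs`; the add-one form keeps p
#' strictly positive. The permutation stream is governed by `params@seed`.
#'
#' @param y numeric vector.
#' @param tObs observed statistic (from [maxStatistic()] on `y`).
#' @param params a [SegmentationParams-class] object.
#' @return Scalar p-value in (0, 1].
#' @export
permutationPvalue <- function(y, tObs, params) {
  set.seed(params@seed)
  pr <- cbs_perm_test(as.numeric(y), params@minWidth, params@nperm, tObs, 0L)
  (1 + pr$count) / (params@nperm + 1)
}

#' Segment an ordered series by recursive CBS
#'
#' Tests the series with [maxStatistic()] plus a permutation p-value; if
#' `p <= alpha` the accepted arc's interior boundaries become breakpoints (an
#' arc strictly inside the piece yields two, a boundary-touching arc one) and
#' the procedure recurses into each resulting piece. Pieces narrower than
#' `2 * minWidth` are not tested further. No post-hoc pruning or undo is
#' applied.
#'
#' @param series an [OrderedSeries-class] or a plain numeric vector.
#' @param params a [SegmentationParams-class] object.
#' @return A [SegmentationResult-class]; segments tile the series, every
#'   accepted split has recorded p <= alpha.
#' @examples
#' s <- OrderedSeries(c(rep(0, 25), rep(1, 25)))
#' segmentSeries(s, SegmentationParams(nperm = 500, seed = 7))
#' @export
segmentSeries <- function(series, params = SegmentationParams()) {
  y <- if (is(series, "OrderedSeries")) series@values else as.numeric(series)
  n <- length(y)
  if (n == 0L) stop("segmentSeries: empty series")
  set.seed(params@seed)
  stopCount <- if (params@earlyStop)
    as.integer(ceiling(params@alpha * (params@nperm + 1))) else 0L

  bps <- integer(0)
  pvals <- numeric(0)
  topT <- NA_real_

  recurse <- function(lo, hi) {
    w <- hi - lo + 1L
    if (lo == 1L && hi == n) {
      cand <- maxStatistic(y[lo:hi], params@minWidth)
      topT <<- cand$statistic
    } else {
      if (w < 2L * params@minWidth) return(invisible(NULL))
      cand <- maxStatistic(y[lo:hi], params@minWidth)
    }
    if (w < 2L * params@minWidth || cand$statistic <= 0) return(invisible(NULL))
    pr <- cbs_perm_test(y[lo:hi], params@minWidth, params@nperm,
                        cand$statistic, stopCount)
    if (pr$done < params@nperm) return(invisible(NULL))  # early stop => p > alpha
    p <- (1 + pr$count) / (params@nperm + 1)
    if (p > params@alpha) return(invisible(NULL))
    cuts <- integer(0)
    if (cand$i > 0L) cuts <- c(cuts, lo - 1L + cand$i)
    if (cand$j < w) cuts <- c(cuts, lo - 1L + cand$j)
    bps <<- c(bps, cuts)
    pvals <<- c(pvals, p)
    bounds <- c(lo - 1L, cuts, hi)
    for (t in seq_len(length(bounds) - 1L))
      recurse(bounds[t] + 1L, bounds[t + 1L])
    invisible(NULL)
  }
  recurse(1L, n)

  bps <- sort(unique(as.integer(bps)))
  starts <- c(1L, bps + 1L)
  ends <- c(bps, n)
  segments <- data.frame(start = starts, end = ends,
                         mean = vapply(seq_along(starts), function(t)
                           mean(y[starts[t]:ends[t]]), numeric(1)))
  new("SegmentationResult", segments = segments, breakpoints = bps,
      splitPvalues = pvals, statistic = if (is.na(topT)) 0 else topT,
      n = as.integer(n))
}
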