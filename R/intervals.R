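#' Interval arithmetic for event trains
#'
#' Event intervals are represented throughout as a two-column numeric matrix
#' (columns `start`, `end`) of half-open intervals `[start, end)` in seconds.
#' These helpers implement the merging, clipping and overlap arithmetic used
#' by the seizure-like-event pipeline and its tests.
#'
#' @param intervals two-column numeric matrix of `[start, end)` intervals.
#' @name intervals
NULL

as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("intervals must have two columns (start, end)")
  storage.mode(x) <- "double"
  colnames(x) <- c("start", "end")
  x <- x[order(x[, 1L]), , drop = FALSE]
  if (any(x[, 2L] < x[, 1L])) stop("interval end precedes start")
  x
}

#' @describeIn intervals Merge sorted intervals whose gap is below `gap`
#'   (touching intervals always merge). Returns a disjoint sorted set.
#' @param gap gaps strictly smaller than this (seconds) are bridged.
#' @export
merge_intervals <- function(intervals, gap = 0) {
  iv <- as_intervals(intervals)
  if (nrow(iv) <= 1L) return(iv)
  out <- iv[1L, , drop = FALSE]
  for (i in 2L:nrow(iv)) {
    last <- nrow(out)
    if (iv[i, 1L] - out[last, 2L] < gap || iv[i, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' @describeIn intervals Total covered time (assumes disjoint intervals).
#' @export
interval_total <- function(intervals) {
  iv <- as_intervals(intervals)
  sum(iv[, 2L] - iv[, 1L])
}

#' @describeIn intervals Clip an interval set to a window `[from, to)`.
#' @param from,to window bounds in seconds.
#' @export
clip_intervals <- function(intervals, from, to) {
  iv <- as_intervals(intervals)
  if (nrow(iv) == 0L) return(iv)
  s <- pmax(iv[, 1L], from)
  e <- pmin(iv[, 2L], to)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

#' @describeIn intervals Overlap (seconds) between an interval set and a window.
#' @export
interval_overlap <- function(intervals, from, to) {
  interval_total(clip_intervals(intervals, from, to))
}

#' @describeIn intervals Jaccard index between two disjoint interval sets:
#'   length of the intersection over length of the union (1 when both empty).
#' @param a,b disjoint interval sets.
#' @export
interval_jaccard <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  ta <- interval_total(a)
  tb <- interval_total(b)
  if (ta == 0 && tb == 0) return(1)
  inter <- 0
  i <- 1L
  j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1L], b[j, 1L])
    hi <- min(a[i, 2L], b[j, 2L])
    if (hi > lo) inter <- inter + (hi - lo)
    if (a[i, 2L] <= b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  inter / (ta + tb - inter)
}

# Convert a logical mask sampled at `rate` Hz into half-open intervals in
# seconds; sample i (1-based) covers [(i-1)/rate, i/rate).
mask_to_intervals <- function(mask, rate) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values
  cbind(start = (starts[on] - 1L) / rate, end = ends[on] / rate)
}

# Inverse of mask_to_intervals for n samples at `rate` Hz.
intervals_to_mask <- function(intervals, n, rate) {
  iv <- as_intervals(intervals)
  mask <- logical(n)
  if (nrow(iv) == 0L) return(mask)
  # the 1e-9 guard keeps grid-aligned boundaries from flipping a sample
  # under floating-point jitter (e.g. 0.57 * 100 = 56.999...)
  for (k in seq_len(nrow(iv))) {
    i0 <- max(1L, floor(iv[k, 1L] * rate + 1e-9) + 1L)
    i1 <- min(n, ceiling(iv[k, 2L] * rate - 1e-9))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}
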