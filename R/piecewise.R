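# ---------------------------------------------------------------------------
# Split-line (two-segment breakpoint) regression: independent OLS lines on
# either side of a grid-searched breakpoint, minimizing total RSS.
# ---------------------------------------------------------------------------

# RSS of the best least-squares line through (x, y); handles constant x.
segment_stats <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    slope <- 0; intercept <- mean(y)
    rss <- sum((y - intercept)^2)
    return(list(slope = slope, intercept = intercept, rss = rss,
                r2 = 0, f = 0, p = 1, n = n))
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  df <- n - 2
  f <- if (df > 0 && rss > 0) (tss - rss) / (rss / df)
  else if (rss == 0 && tss > 0) Inf else 0
  p <- if (df > 0 && is.finite(f)) stats::pf(f, 1, df, lower.tail = FALSE)
  else if (is.infinite(f)) 0 else 1
  list(slope = slope, intercept = intercept, rss = rss, r2 = r2,
       f = f, p = p, n = n)
}

#' Split-line regression with grid-searched breakpoint
#'
#' Units with \code{x > x_cap} are excluded. For each candidate breakpoint b
#' two independent OLS lines are fitted, to the points with x <= b (points
#' exactly at the breakpoint go to the lower segment) and to those with
#' x > b; the candidate minimizing total RSS wins (ties: the smallest b).
#' Per-segment r-squared, the slope F test and its p-value are reported,
#' mirroring the usual per-segment presentation of split-line analyses.
#'
#' @param x predictor (e.g. elevational range in m).
#' @param y response (e.g. log10 species richness).
#' @param x_cap exclude units with x above this value (default 6000).
#' @param grid candidate breakpoints; default every 50 x-units from the 5th
#'   to the 95th percentile of the capped x.
#' @param grid_step spacing of the default grid.
#' @param min_per_side minimum points required on each side of an admissible
#'   candidate (default 4).
#' @return object of class \code{split_line_fit}: breakpoint, pre/post
#'   segment statistics (slope, intercept, r2, f, p, n), rss_total,
#'   rss_single_line, n_excluded, excluded (indices), grid.
#' @export
fit_split_line <- function(x, y, x_cap = 6000, grid = NULL, grid_step = 50,
                           min_per_side = 4) {
  stopifnot(length(x) == length(y))
  keep <- which(x <= x_cap & !is.na(x) & !is.na(y))
  excluded <- setdiff(seq_along(x), keep)
  x0 <- x[keep]; y0 <- y[keep]
  if (length(x0) < 2 * min_per_side)
    stop("too few units after applying the x-cap")
  if (is.null(grid)) {
    q <- stats::quantile(x0, c(0.05, 0.95), names = FALSE)
    lo <- ceiling(q[1] / grid_step) * grid_step
    grid <- seq(lo, q[2], by = grid_step)
    if (!length(grid)) grid <- mean(q)
  }
  ord <- order(x0)
  xs <- x0[ord]; ys <- y0[ord]
  n <- length(xs)
  # prefix sums for O(1) segment RSS at each split position
  cx <- cumsum(xs); cy <- cumsum(ys)
  cxx <- cumsum(xs^2); cyy <- cumsum(ys^2); cxy <- cumsum(xs * ys)
  seg_rss <- function(i, j) {  # RSS of best line on positions i..j (sorted)
    m <- j - i + 1
    if (m < 1) return(NA_real_)
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- (cxx[j] - if (i > 1) cxx[i - 1] else 0) - sx^2 / m
    syy <- (cyy[j] - if (i > 1) cyy[i - 1] else 0) - sy^2 / m
    sxy <- (cxy[j] - if (i > 1) cxy[i - 1] else 0) - sx * sy / m
    if (sxx <= 0) return(max(syy, 0))
    max(syy - sxy^2 / sxx, 0)
  }
  best <- NULL
  for (b in sort(grid)) {
    m <- findInterval(b, xs)  # points with x <= b
    if (m < min_per_side || n - m < min_per_side) next
    rss <- seg_rss(1, m) + seg_rss(m + 1, n)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(b = b, rss = rss, m = m)
  }
  if (is.null(best))
    stop("no admissible breakpoint: a segment is empty (or below the minimum size) at every candidate")
  pre <- segment_stats(xs[seq_len(best$m)], ys[seq_len(best$m)])
  post <- segment_stats(xs[seq(best$m + 1, n)], ys[seq(best$m + 1, n)])
  single <- segment_stats(xs, ys)
  structure(list(breakpoint = best$b, pre = pre, post = post,
                 rss_total = pre$rss + post$rss,
                 rss_single_line = single$rss,
                 n_pre = pre$n, n_post = post$n,
                 n_excluded = length(excluded), excluded = excluded,
                 x_cap = x_cap, grid = grid),
            class = "split_line_fit")
}

#' @export
print.split_line_fit <- function(x, ...) {
  cat(sprintf("split-line fit: breakpoint %g (%d excluded by x > %g)\n",
              x$breakpoint, x$n_excluded, x$x_cap))
  cat(sprintf("  pre : n=%d slope=%.4g R2=%.4f F=%.2f p=%.3g\n",
              x$pre$n, x$pre$slope, x$pre$r2, x$pre$f, x$pre$p))
  cat(sprintf("  post: n=%d slope=%.4g R2=%.4f F=%.2f p=%.3g\n",
              x$post$n, x$post$slope, x$post$r2, x$post$f, x$post$p))
  invisible(x)
}

split_line_report <- function(fit) {
  seg <- function(s) list(slope = s$slope, intercept = s$intercept,
                          r2 = s$r2, f = s$f, p = s$p, n = s$n)
  list(breakpoint = fit$breakpoint, pre = seg(fit$pre), post = seg(fit$post),
       rss_total = fit$rss_total, rss_single_line = fit$rss_single_line,
       n_excluded = fit$n_excluded, x_cap = fit$x_cap)
}
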