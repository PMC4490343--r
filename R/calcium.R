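#' Calcium trace container
#'
#' A single-ROI fluorescence intensity trace sampled at a fixed frame rate.
#'
#' @param raw intensity per frame, arbitrary units.
#' @param times sample times in seconds (same length as `raw`).
#' @param metadata named list of labels.
#' @return an object of class `calcium_trace`.
#' @export
calcium_trace <- function(raw, times, metadata = list()) {
  if (length(raw) != length(times)) stop("raw and times lengths differ")
  structure(list(raw = as.numeric(raw), times = as.numeric(times),
                 normalized = NULL, starts = NULL, peaks = NULL,
                 fit_order = NULL, metadata = metadata),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat("calcium_trace: ", length(x$raw), " samples over ",
      round(diff(range(x$times)), 2), " s",
      if (!is.null(x$starts)) paste0("; ", length(x$starts), " transients"),
      if (!is.null(x$normalized)) paste0("; detrended (order ", x$fit_order, ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.calcium_trace <- function(x, which = c("raw", "normalized"), ...) {
  which <- match.arg(which)
  y <- if (which == "normalized" && !is.null(x$normalized)) x$normalized else x$raw
  graphics::plot(x$times, y, type = "l", xlab = "time (s)",
                 ylab = paste(which, "intensity (a.u.)"), ...)
  if (!is.null(x$starts))
    graphics::points(x$times[x$starts], y[x$starts], col = 2, pch = 4)
  if (!is.null(x$peaks))
    graphics::points(x$times[x$peaks], y[x$peaks], col = 4, pch = 1)
  invisible(x)
}

#' Mean-ROI trace from a fluorescence stack
#'
#' Reduces a fluorescence frame stack to a single trace by averaging a square
#' region of interest in every frame.
#'
#' @param stack a [frame_stack()].
#' @param x,y top-left corner of the ROI (pixels, 1-based).
#' @param width,height ROI size in pixels (default 240 x 240).
#' @return a [calcium_trace()].
#' @export
roi_trace <- function(stack, x = 1L, y = 1L, width = 240L, height = 240L) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (y + height - 1 > d[1] || x + width - 1 > d[2])
    stop("ROI exceeds the frame")
  vals <- apply(stack$frames[y:(y + height - 1), x:(x + width - 1), ,
                             drop = FALSE], 3, mean)
  calcium_trace(vals, (seq_len(d[3]) - 1) / stack$fps,
                metadata = stack$metadata)
}

# centered moving average, edges shrunk
moving_average <- function(y, k = 5L) {
  n <- length(y)
  half <- k %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect calcium transient starts and peaks
#'
#' Detection runs on a lightly smoothed copy (5-sample moving average, which
#' suppresses shot noise without materially shifting peaks at ~15 fps);
#' reported indices refer to the raw sampling grid. A transient start is the
#' last sub-threshold sample before a sustained positive-derivative run, and
#' the peak is the maximum between consecutive starts.
#'
#' @param trace a [calcium_trace()].
#' @param min_prominence minimum relative transient height, peak/start - 1
#'   (default 0.2); scale-free, so photobleach attenuation does not change
#'   which transients qualify.
#' @param smooth_k moving-average window, samples.
#' @return the trace with `starts` and `peaks` filled in (integer indices,
#'   interleaved start < peak < next start).
#' @export
detect_transients <- function(trace, min_prominence = 0.2, smooth_k = 5L) {
  stopifnot(inherits(trace, "calcium_trace"))
  n <- length(trace$raw)
  if (n < 10) stop("need at least 10 samples")
  y <- moving_average(trace$raw, smooth_k)
  rng <- max(y) - min(y)
  if (rng <= 1e-12 * max(abs(y), 1)) {
    warning("flat trace: no transients")
    trace$starts <- integer(0); trace$peaks <- integer(0)
    return(trace)
  }
  # detect in the log domain: the multiplicative photobleach decay becomes a
  # gentle additive slope, and every transient has the same log-height
  # log(1 + a) regardless of how far the bleach has progressed
  ly <- log(pmax(y, 1e-12 * max(abs(y))))
  dy <- diff(ly)
  if (max(dy) <= 0) {
    warning("no transients found (monotone trace)")
    trace$starts <- integer(0); trace$peaks <- integer(0)
    return(trace)
  }
  thr_d <- 0.25 * max(dy)          # a "rising run" climbs at a decent rate
  rising <- dy > thr_d
  run_start <- which(rising & !c(FALSE, rising[-(n - 1)]))
  starts <- integer(0)
  for (r in run_start) {
    # start = last sub-threshold sample before the run: walk back down the
    # smoothed upstroke to its local minimum
    j <- r
    while (j > 1 && ly[j - 1] < ly[j]) j <- j - 1
    if (length(starts) && j <= starts[length(starts)]) next
    starts <- c(starts, j)
  }
  if (length(starts) == 0) {
    warning("no transients found")
    trace$starts <- integer(0); trace$peaks <- integer(0)
    return(trace)
  }
  bounds <- c(starts, n + 1L)
  peaks <- integer(0); keep <- integer(0)
  for (i in seq_along(starts)) {
    seg <- starts[i]:(bounds[i + 1] - 1L)
    pk <- seg[which.max(ly[seg])]
    # prominence: relative peak height above its own start
    if (expm1(ly[pk] - ly[starts[i]]) < min_prominence) next
    keep <- c(keep, starts[i]); peaks <- c(peaks, pk)
  }
  if (length(keep) == 0) {
    warning("no transients above prominence threshold")
    trace$starts <- integer(0); trace$peaks <- integer(0)
    return(trace)
  }
  # refine indices on the raw grid: smoothing shifts the apparent onset by up
  # to half the window, so snap each start to the (last) raw minimum between
  # it and the peak, and each peak to the raw maximum nearby
  half <- smooth_k %/% 2 + 1L
  for (i in seq_along(keep)) {
    seg <- keep[i]:min(keep[i] + smooth_k, peaks[i])
    mins <- which(trace$raw[seg] <= min(trace$raw[seg]) + 1e-12 * rng)
    keep[i] <- seg[mins[length(mins)]]
    seg <- max(1L, peaks[i] - half):min(n, peaks[i] + half)
    peaks[i] <- seg[which.max(trace$raw[seg])]
  }
  trace$starts <- keep; trace$peaks <- peaks
  trace
}

#' Photobleach detrending by polynomial baseline fit
#'
#' Fits an n-th order polynomial (n in 2..10) to the (start time, raw value)
#' points -- the signal baseline, sampled where each transient begins -- and
#' divides the raw trace by it. Residual start offsets after division are
#' removed by linearly interpolating through the post-division start values,
#' so every transient starts at exactly zero. The order is the smallest n
#' whose residual sum of squares on the start points improves by less than 5%
#' over n-1 (parsimony; high orders oscillate); orders whose fitted baseline
#' crosses zero anywhere on the trace are rejected.
#'
#' @param trace a [calcium_trace()] with detected starts (run
#'   [detect_transients()] first; done automatically if missing).
#' @param order optional fixed polynomial order (2..10) overriding selection.
#' @return the trace with `normalized` and `fit_order` filled in.
#' @export
detrend_bleach <- function(trace, order = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$starts)) trace <- detect_transients(trace)
  st <- trace$starts
  if (length(st) < 3) stop("need >= 3 detected transient starts for the baseline fit")
  ts <- trace$times[st]; vs <- trace$raw[st]
  max_order <- min(10L, length(st) - 1L)
  fit_rss <- function(n_ord) {
    fit <- stats::lm(vs ~ stats::poly(ts, n_ord, raw = TRUE))
    base <- as.numeric(cbind(1, stats::poly(trace$times, n_ord, raw = TRUE)) %*%
                         stats::coef(fit))
    list(rss = sum(stats::resid(fit)^2), baseline = base)
  }
  orders <- 2:max(2L, max_order)
  if (!is.null(order)) {
    if (order < 2 || order > 10) stop("order must be in 2..10")
    orders <- as.integer(order)
  }
  chosen <- NULL; prev_rss <- Inf
  for (n_ord in orders) {
    f <- fit_rss(n_ord)
    if (any(f$baseline <= 0)) next   # non-physical baseline, try another order
    if (is.null(chosen)) { chosen <- list(order = n_ord, baseline = f$baseline) }
    else if (f$rss < 0.95 * prev_rss) chosen <- list(order = n_ord, baseline = f$baseline)
    else break
    prev_rss <- f$rss
  }
  if (is.null(chosen)) stop("no polynomial order in 2..10 gives a positive baseline")
  norm <- trace$raw / chosen$baseline
  # pin each transient start to exactly zero via linear interpolation of the
  # residual start values
  resid_start <- norm[st]
  offset <- stats::approx(trace$times[st], resid_start, xout = trace$times,
                          rule = 2)$y
  trace$normalized <- norm - offset
  trace$fit_order <- chosen$order
  trace
}

#' Per-transient and per-acquisition calcium metrics
#'
#' On the detrended trace (each transient starting at zero): amplitude is the
#' normalized peak value; CTD90 is the time from the transient start until
#' the decaying signal first falls below 10% of that transient's amplitude
#' (sub-sample via linear interpolation); SR90 = CTD90 / amplitude; beating
#' rate is `60 * (n_transients - 1) / (last start - first start)` in
#' beats/min.
#'
#' @param trace a detrended [calcium_trace()] (detection/detrending run
#'   automatically if missing).
#' @return list with `per_transient` (data.frame: start, peak times,
#'   amplitude, ctd90, sr90) and the acquisition summary fields
#'   `beating_rate`, `amplitude`, `ctd90`, `sr90` (per-transient means;
#'   transients whose CTD90 is undefined are excluded with a warning).
#' @export
transient_metrics <- function(trace) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$normalized)) trace <- detrend_bleach(trace)
  st <- trace$starts; pk <- trace$peaks
  if (length(st) < 2) stop("need >= 2 transients for metrics")
  y <- trace$normalized; t <- trace$times
  n <- length(y)
  bounds <- c(st, n + 1L)
  rows <- NULL
  for (i in seq_along(st)) {
    seg_end <- bounds[i + 1] - 1L
    # amplitude from the detrended trace itself: the segment maximum (the
    # detected raw-grid peak can sit a sample off the normalized maximum
    # when the bleach slope tilts the raw peak)
    seg <- st[i]:seg_end
    pk_n <- seg[which.max(y[seg])]
    amp <- y[pk_n] - y[st[i]]    # start value is 0 by construction
    lvl <- y[st[i]] + 0.1 * amp
    j <- pk_n
    while (j < seg_end && y[j + 1] > lvl) j <- j + 1
    if (j == seg_end) {
      warning("transient ", i, " never decays below the 10% level; CTD90 undefined")
      ctd <- NA_real_
    } else {
      tc <- t[j] + (t[j + 1] - t[j]) * (y[j] - lvl) / (y[j] - y[j + 1])
      ctd <- tc - t[st[i]]
    }
    rows <- rbind(rows, data.frame(
      start_time = t[st[i]], peak_time = t[pk_n], amplitude = amp,
      ctd90 = ctd, sr90 = ctd / amp))
  }
  ok <- !is.na(rows$ctd90)
  list(
    per_transient = rows,
    beating_rate = 60 * (length(st) - 1) / (t[st[length(st)]] - t[st[1]]),
    amplitude = mean(rows$amplitude),
    ctd90 = mean(rows$ctd90[ok]),
    sr90 = mean(rows$sr90[ok])
  )
}
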