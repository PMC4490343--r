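#' Contractile profile container
#'
#' The one-dimensional summary of cardiomyocyte motion: the score of each
#' frame pair on the first principal component of the block motion-vector
#' field. Positive values indicate the contraction phase, negative values the
#' relaxation phase.
#'
#' @param score numeric vector of first-principal-component scores (centered).
#' @param times frame-pair times in seconds.
#' @param variance_explained fraction of flow variance captured by the first
#'   component.
#' @param metadata named list of labels.
#' @param low_confidence logical flag: `TRUE` when the profile came from an
#'   all-zero (textureless) flow field.
#' @return an object of class `contractile_profile`.
#' @export
contractile_profile <- function(score, times, variance_explained = NA_real_,
                                metadata = list(), low_confidence = FALSE) {
  if (length(score) != length(times)) stop("score and times lengths differ")
  if (!is.na(variance_explained) &&
      (variance_explained < 0 || variance_explained > 1))
    stop("variance_explained must be in [0, 1]")
  structure(list(score = as.numeric(score), times = as.numeric(times),
                 variance_explained = variance_explained,
                 metadata = metadata, low_confidence = low_confidence),
            class = "contractile_profile")
}

#' @export
print.contractile_profile <- function(x, ...) {
  cat("contractile_profile: ", length(x$score), " samples over ",
      round(diff(range(x$times)), 2), " s; variance explained ",
      if (is.na(x$variance_explained)) "NA" else
        sprintf("%.3f", x$variance_explained),
      if (x$low_confidence) " [low confidence]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.contractile_profile <- function(x, ...) {
  graphics::plot(x$times, x$score, type = "l", xlab = "time (s)",
                 ylab = "PCA score (a.u.)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Collapse a flow series into the PCA contractile profile
#'
#' Builds the frame-pair-by-feature data matrix (each block's u component,
#' then each block's v component), centres the columns, and projects onto the
#' first principal axis. Using the signed components (rather than vector
#' norms) lets the single score separate contraction from relaxation: the two
#' phases have opposite vector directions, hence opposite signs on the first
#' component.
#'
#' The principal-axis sign is intrinsically arbitrary, so the score is
#' oriented deterministically: if `sign_anchor` is given, the first extremum
#' at or after that time is made positive (the anchor marks the start of the
#' first contraction); otherwise the larger-magnitude extremum class is made
#' positive, with ties broken by the earlier extremum.
#'
#' @param flow a [flow_series()] (usually block-averaged to a 20 px grid).
#' @param sign_anchor optional time (s) of the first contraction start.
#' @return a [contractile_profile()].
#' @export
profile_from_flow <- function(flow, sign_anchor = NULL) {
  stopifnot(inherits(flow, "flow_series"))
  d <- dim(flow$u)
  n <- d[3]
  if (n < 2) stop("need flow from >= 2 frame pairs")
  # rows index frame pairs; columns are each block's u, then each block's v
  X <- cbind(t(matrix(flow$u, ncol = n)), t(matrix(flow$v, ncol = n)))
  Xc <- sweep(X, 2, colMeans(X))
  times <- if (is.null(flow$fps)) seq_len(n) else (seq_len(n) - 0.5) / flow$fps
  if (all(Xc == 0)) {
    return(contractile_profile(rep(0, n), times, variance_explained = 0,
                               metadata = flow$metadata, low_confidence = TRUE))
  }
  sv <- svd(Xc, nu = 1, nv = 0)
  score <- sv$u[, 1] * sv$d[1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  score <- orient_score(score, times, sign_anchor)
  contractile_profile(score, times, variance_explained = ve,
                      metadata = flow$metadata,
                      low_confidence = any(flow$low_confidence))
}

# deterministic sign orientation of a PC score
orient_score <- function(score, times, sign_anchor = NULL) {
  if (all(score == 0)) return(score)
  if (!is.null(sign_anchor)) {
    idx <- which(times >= sign_anchor)
    if (length(idx) == 0) idx <- seq_along(score)
    seg <- score[idx]
    # first local extremum of |score| after the anchor
    ext <- which(diff(sign(diff(abs(seg)))) < 0) + 1L
    k <- if (length(ext)) ext[1] else which.max(abs(seg))
    if (seg[k] < 0) score <- -score
    return(score)
  }
  mpos <- max(score); mneg <- max(-score)
  if (mneg > mpos) score <- -score
  else if (mneg == mpos && which.max(-score) < which.max(score)) score <- -score
  score
}

# interpolated zero crossing of y between sample i and i+1
zero_cross_time <- function(t, y, i) {
  if (y[i] == 0) return(t[i])
  t[i] + (t[i + 1] - t[i]) * y[i] / (y[i] - y[i + 1])
}

#' Segment a contractile profile into beats
#'
#' Peaks with positive score are contraction phases, troughs with negative
#' score are relaxation phases. Extrema whose magnitude is below
#' `prominence * max(|score|)` are ignored; surviving extrema are reduced to
#' an alternating +/- sequence (keeping the largest of consecutive same-sign
#' extrema). Each positive peak paired with the following negative trough
#' forms a beat; phase boundaries are placed at zero crossings of the score,
#' located sub-frame by linear interpolation. A trailing positive peak
#' without a following trough, or a relaxation that never returns to zero
#' before the recording ends, is dropped as incomplete.
#'
#' @param profile a [contractile_profile()].
#' @param prominence fraction of the acquisition's maximum absolute score
#'   below which extrema are ignored (default 0.1; scale-free, so amplitude
#'   effects do not change the beat count).
#' @return data.frame of beats with columns `index`, `c_start`, `c_peak`,
#'   `c_end`, `r_peak`, `r_end` (times in seconds) plus peak scores
#'   `c_peak_score`, `r_peak_score`. Zero rows if nothing qualifies.
#' @export
segment_beats <- function(profile, prominence = 0.1) {
  stopifnot(inherits(profile, "contractile_profile"))
  y <- profile$score; t <- profile$times
  empty <- data.frame(index = integer(), c_start = numeric(),
                      c_peak = numeric(), c_end = numeric(),
                      r_peak = numeric(), r_end = numeric(),
                      c_peak_score = numeric(), r_peak_score = numeric())
  thr <- prominence * max(abs(y))
  if (max(abs(y)) == 0) {
    warning("flat profile: no beats")
    return(empty)
  }
  n <- length(y)
  dy <- diff(y)
  # local extrema (interior samples)
  is_max <- c(FALSE, dy[-(n - 1)] > 0 & dy[-1] <= 0, FALSE)
  is_min <- c(FALSE, dy[-(n - 1)] < 0 & dy[-1] >= 0, FALSE)
  idx <- which((is_max & y > thr) | (is_min & y < -thr))
  if (length(idx) == 0) {
    warning("no peaks above the prominence threshold")
    return(empty)
  }
  sgn <- sign(y[idx])
  # collapse runs of same-sign extrema, keeping the largest magnitude
  keep <- integer(0)
  run_start <- 1L
  for (i in seq_along(idx)) {
    if (i == length(idx) || sgn[i + 1] != sgn[i]) {
      run <- run_start:i
      keep <- c(keep, idx[run][which.max(abs(y[idx[run]]))])
      run_start <- i + 1L
    }
  }
  sgn <- sign(y[keep])
  # drop a leading trough: it belongs to a beat truncated at recording start
  if (length(keep) && sgn[1] < 0) { keep <- keep[-1]; sgn <- sgn[-1] }
  # Boundary search uses a small hysteresis: sign flips within the noise
  # floor (eps * max|score|) are not treated as phase boundaries, so the
  # reported crossing is where the score actually leaves/enters its lobe.
  eps <- 0.5 * thr
  # crossing while walking away from a positive lobe: first sample with
  # y <= eps; the boundary is the interpolated zero crossing of that segment
  cross_down <- function(j0, step) {
    j <- j0
    while (j + step >= 1 && j + step <= n && y[j + step] > eps) j <- j + step
    jn <- j + step
    if (jn < 1 || jn > n) return(NA_real_)
    a <- min(j, jn); b <- max(j, jn)
    if (y[b] < 0 || y[a] < 0) zero_cross_time(t, y, a)
    else t[jn]  # still above zero but inside the noise floor
  }
  cross_up <- function(j0, step) {
    j <- j0
    while (j + step >= 1 && j + step <= n && y[j + step] < -eps) j <- j + step
    jn <- j + step
    if (jn < 1 || jn > n) return(NA_real_)
    a <- min(j, jn)
    if (y[a] < 0 && y[a + 1] > 0) zero_cross_time(t, y, a)
    else t[jn]
  }
  beats <- NULL
  i <- 1L
  while (i + 1L <= length(keep)) {
    pk <- keep[i]; tr <- keep[i + 1L]
    c_start <- cross_down(pk, -1L)
    if (is.na(c_start)) c_start <- t[1]
    c_end <- cross_down(pk, 1L)
    if (is.na(c_end)) break  # contraction never ends: incomplete
    r_end <- cross_up(tr, 1L)
    if (is.na(r_end)) { i <- i + 2L; next }  # relaxation unfinished: drop
    beats <- rbind(beats, data.frame(
      index = NA_integer_, c_start = c_start, c_peak = t[pk], c_end = c_end,
      r_peak = t[tr], r_end = r_end,
      c_peak_score = y[pk], r_peak_score = y[tr]))
    i <- i + 2L
  }
  if (is.null(beats)) return(empty)
  beats$index <- seq_len(nrow(beats))
  beats
}

# trapezoidal integral of the profile between two times, with the endpoint
# values pinned to zero (the endpoints are zero crossings)
segment_area <- function(t, y, t0, t1) {
  inside <- which(t > t0 & t < t1)
  tt <- c(t0, t[inside], t1)
  yy <- c(0, y[inside], 0)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

#' The 12 per-beat shape parameters
#'
#' Computes, for every segmented beat, the 12 parameters describing the shape
#' of the contractile profile:
#' \describe{
#'   \item{p1}{contraction peak amplitude (a.u.)}
#'   \item{p2}{relaxation peak magnitude (a.u.)}
#'   \item{p3}{contraction duration, zero crossing to zero crossing (s)}
#'   \item{p4}{relaxation duration (s)}
#'   \item{p5}{rest duration to the next beat (s)}
#'   \item{p6}{total beat duration, contraction start to next contraction
#'     start (s)}
#'   \item{p7}{contraction area (a.u. * s)}
#'   \item{p8}{relaxation area magnitude (a.u. * s)}
#'   \item{p9}{contraction-peak to relaxation-peak interval (s)}
#'   \item{p10}{upstroke slope, p1 over the rise time (a.u./s)}
#'   \item{p11}{relaxation decay slope, p2 over the time from contraction end
#'     to relaxation peak (a.u./s)}
#'   \item{p12}{frequency: the inverse of the interval between this beat's
#'     contraction peak and the next beat's (1/s)}
#' }
#' p5, p6 and p12 need a subsequent beat, so the last beat's row is flagged
#' `is_last`; rows destined for classification must exclude it (see
#' [ml_table()]).
#'
#' @param profile a [contractile_profile()].
#' @param beats the data.frame from [segment_beats()]; segmented from
#'   `profile` if missing.
#' @return data.frame with columns p1..p12, any labels found in the profile
#'   metadata (`well_id`, `condition`, `acquisition_index`), `beat` and
#'   `is_last`.
#' @export
beat_features <- function(profile, beats = NULL) {
  stopifnot(inherits(profile, "contractile_profile"))
  if (is.null(beats)) beats <- segment_beats(profile)
  if (nrow(beats) == 0) stop("no beats to featurise")
  if (nrow(beats) == 1)
    warning("single beat: its row is flagged is_last, leaving no rows for classification")
  t <- profile$times; y <- profile$score
  n <- nrow(beats)
  nxt <- c(beats$c_start[-1], NA)
  nxt_peak <- c(beats$c_peak[-1], NA)
  out <- data.frame(
    p1 = beats$c_peak_score,
    p2 = abs(beats$r_peak_score),
    p3 = beats$c_end - beats$c_start,
    p4 = beats$r_end - beats$c_end,
    p5 = nxt - beats$r_end,
    p6 = nxt - beats$c_start,
    p7 = vapply(seq_len(n), function(i)
      segment_area(t, y, beats$c_start[i], beats$c_end[i]), 0),
    p8 = vapply(seq_len(n), function(i)
      abs(segment_area(t, y, beats$c_end[i], beats$r_end[i])), 0),
    p9 = beats$r_peak - beats$c_peak,
    p10 = beats$c_peak_score / (beats$c_peak - beats$c_start),
    p11 = abs(beats$r_peak_score) / (beats$r_peak - beats$c_end),
    p12 = 1 / (nxt_peak - beats$c_peak)
  )
  md <- profile$metadata
  out$well_id <- if (!is.null(md$well_id)) md$well_id else NA_character_
  out$condition <- if (!is.null(md$condition)) md$condition else NA_character_
  out$acquisition_index <-
    if (!is.null(md$acquisition_index)) md$acquisition_index else NA_integer_
  out$beat <- beats$index
  out$is_last <- seq_len(n) == n
  out
}

#' Feature table ready for classification
#'
#' Drops rows flagged `is_last` (their frequency parameter is undefined) and
#' checks completeness.
#'
#' @param features one or more [beat_features()] data.frames (rbind-ed).
#' @return the filtered data.frame.
#' @export
ml_table <- function(features) {
  out <- features[!features$is_last, , drop = FALSE]
  pcols <- paste0("p", 1:12)
  if (nrow(out) && any(!stats::complete.cases(out[, pcols])))
    stop("feature table has missing parameter values")
  out
}
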