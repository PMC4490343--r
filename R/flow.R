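#' Frame stack container
#'
#' A grayscale time-lapse movie. Frames are stored as an `H x W x T` numeric
#' array (row = image y, column = image x, both 1-based with pixel (1,1) at
#' the top-left).
#'
#' @param frames `H x W x T` numeric array, or a list of `H x W` matrices.
#' @param fps frame rate in frames per second.
#' @param metadata optional named list (well, condition, acquisition labels).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, metadata = list()) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) stop("frames must be an H x W x T array")
  if (dim(frames)[3] < 2) stop("need >= 2 frames")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  structure(list(frames = frames, fps = fps, metadata = metadata),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("frame_stack: ", d[3], " frames of ", d[1], " x ", d[2],
      " px at ", x$fps, " fps (", round(d[3] / x$fps, 2), " s)\n", sep = "")
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# downscale an image by an arbitrary factor with bilinear interpolation
bilinear_resize <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  ys <- seq(1, H, length.out = H2)
  xs <- seq(1, W, length.out = W2)
  yy <- matrix(ys, H2, W2)
  xx <- matrix(xs, H2, W2, byrow = TRUE)
  matrix(bilinear_sample(img, xx, yy), H2, W2)
}

#' Downscale a frame stack by bilinear interpolation
#'
#' Acquisitions taken at a higher-resolution setting are downsized to the
#' working resolution before flow computation.
#'
#' @param stack a [frame_stack()].
#' @param size target c(H, W) in pixels (default `c(512, 672)`).
#' @return a [frame_stack()] at the target resolution.
#' @export
downscale_stack <- function(stack, size = c(512L, 672L)) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  out <- array(0, dim = c(size[1], size[2], d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- bilinear_resize(stack$frames[, , k], size[1], size[2])
  frame_stack(out, fps = stack$fps, metadata = stack$metadata)
}

#' Flow series container
#'
#' Per frame-pair displacement fields on a block grid. `u` is the x
#' (rightward-positive) component and `v` the y (downward-positive) component,
#' in pixels/frame, stored as `Hb x Wb x (T-1)` arrays. Flipping the image
#' vertically negates `v` only.
#'
#' @param u,v `Hb x Wb x (T-1)` arrays of displacement components.
#' @param block_size grid cell edge in pixels (1 = dense).
#' @param fps frame rate of the source stack.
#' @param low_confidence logical vector, one per frame pair; `TRUE` marks
#'   pairs with too little texture for a reliable estimate.
#' @param metadata named list carried over from the stack.
#' @return an object of class `flow_series`.
#' @export
flow_series <- function(u, v, block_size = 1L, fps = NULL,
                        low_confidence = NULL, metadata = list()) {
  if (!identical(dim(u), dim(v))) stop("u and v must have identical shape")
  if (length(dim(u)) != 3) stop("u and v must be Hb x Wb x (T-1) arrays")
  if (block_size < 1) stop("block_size must be >= 1")
  if (is.null(low_confidence)) low_confidence <- rep(FALSE, dim(u)[3])
  structure(list(u = u, v = v, block_size = as.integer(block_size), fps = fps,
                 low_confidence = low_confidence, metadata = metadata),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  d <- dim(x$u)
  cat("flow_series: ", d[3], " frame pairs on a ", d[1], " x ", d[2],
      " grid (block ", x$block_size, " px)\n", sep = "")
  invisible(x)
}

# shift a matrix by one pixel with edge replication
shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Horn-Schunck weighted neighbourhood average (the discrete Laplacian kernel)
hs_average <- function(m) {
  (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
   shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
  (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
   shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
}

# single-level Horn-Schunck between two frames, warm-started at (u, v)
hs_level <- function(f1, f2, u, v, alpha, n_iter) {
  H <- nrow(f1); W <- ncol(f1)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  # warp frame 2 back by the current estimate, then solve for the increment
  f2w <- if (any(u != 0) || any(v != 0))
    matrix(bilinear_sample(f2, xx + u, yy + v), H, W) else f2
  fx <- (shift_mat(f1, 0, 1) - shift_mat(f1, 0, -1) +
         shift_mat(f2w, 0, 1) - shift_mat(f2w, 0, -1)) / 4
  fy <- (shift_mat(f1, 1, 0) - shift_mat(f1, -1, 0) +
         shift_mat(f2w, 1, 0) - shift_mat(f2w, -1, 0)) / 4
  ft <- f2w - f1
  du <- matrix(0, H, W); dv <- matrix(0, H, W)
  denom_base <- alpha^2 + fx^2 + fy^2
  for (i in seq_len(n_iter)) {
    ua <- hs_average(du); va <- hs_average(dv)
    t1 <- (fx * ua + fy * va + ft) / denom_base
    du <- ua - fx * t1
    dv <- va - fy * t1
  }
  list(u = u + du, v = v + dv)
}

#' Dense optical flow for a frame stack
#'
#' Estimates one dense displacement field per consecutive frame pair with a
#' coarse-to-fine (pyramidal) Horn-Schunck solver: flow is computed on a
#' Gaussian pyramid, upsampled, used to warp the second frame, and refined at
#' the next finer level. Frame pairs with essentially no intensity gradient
#' are returned as zero fields flagged low-confidence rather than raising an
#' error.
#'
#' @param stack a [frame_stack()].
#' @param alpha Horn-Schunck regularisation weight (smoothness); default 1.
#' @param n_iter inner iterations per warp step; default 120.
#' @param n_warp outer warp-and-refine steps per pyramid level; default 3.
#' @param n_levels pyramid levels; default chosen from the image size so the
#'   coarsest level is about 24 px.
#' @param gradient_tol mean absolute spatial gradient below which a pair is
#'   declared textureless.
#' @return a [flow_series()] with `block_size = 1`.
#' @export
compute_flow <- function(stack, alpha = 0.5, n_iter = 120, n_levels = NULL,
                         n_warp = 3, gradient_tol = 1e-8) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  H <- d[1]; W <- d[2]; T_ <- d[3]
  if (is.null(n_levels))
    n_levels <- max(1L, floor(log2(min(H, W) / 24)) + 1L)
  u <- array(0, dim = c(H, W, T_ - 1))
  v <- array(0, dim = c(H, W, T_ - 1))
  lowconf <- rep(FALSE, T_ - 1)
  for (k in seq_len(T_ - 1)) {
    f1 <- stack$frames[, , k]; f2 <- stack$frames[, , k + 1]
    gx <- shift_mat(f1, 0, 1) - f1; gy <- shift_mat(f1, 1, 0) - f1
    if (mean(abs(gx)) + mean(abs(gy)) < gradient_tol) {
      lowconf[k] <- TRUE
      next
    }
    # build pyramids
    p1 <- list(f1); p2 <- list(f2)
    for (l in seq_len(n_levels - 1)) {
      a <- gauss_blur(p1[[l]], 1); b <- gauss_blur(p2[[l]], 1)
      p1[[l + 1]] <- bilinear_resize(a, max(2, round(nrow(a) / 2)),
                                     max(2, round(ncol(a) / 2)))
      p2[[l + 1]] <- bilinear_resize(b, max(2, round(nrow(b) / 2)),
                                     max(2, round(ncol(b) / 2)))
    }
    uk <- matrix(0, nrow(p1[[n_levels]]), ncol(p1[[n_levels]]))
    vk <- uk
    for (l in rev(seq_len(n_levels))) {
      if (l < n_levels) {
        sy <- nrow(p1[[l]]) / nrow(p1[[l + 1]])
        sx <- ncol(p1[[l]]) / ncol(p1[[l + 1]])
        uk <- bilinear_resize(uk, nrow(p1[[l]]), ncol(p1[[l]])) * sx
        vk <- bilinear_resize(vk, nrow(p1[[l]]), ncol(p1[[l]])) * sy
      }
      for (o in seq_len(n_warp)) {
        res <- hs_level(p1[[l]], p2[[l]], uk, vk, alpha, n_iter)
        uk <- res$u; vk <- res$v
      }
    }
    u[, , k] <- uk; v[, , k] <- vk
  }
  flow_series(u, v, block_size = 1L, fps = stack$fps,
              low_confidence = lowconf, metadata = stack$metadata)
}

# mean over b x b blocks of a matrix, trailing partial blocks dropped
block_mean_mat <- function(m, b) {
  Hb <- nrow(m) %/% b; Wb <- ncol(m) %/% b
  m <- m[seq_len(Hb * b), seq_len(Wb * b), drop = FALSE]
  # average rows within blocks, then columns
  rsum <- rowsum(m, rep(seq_len(Hb), each = b)) / b
  t(rowsum(t(rsum), rep(seq_len(Wb), each = b)) / b)
}

#' Coarsen a flow series onto a block grid
#'
#' Each output vector is the arithmetic mean of the vectors in its
#' `block x block` cell (matching vector-field displays that show the average
#' motion of 20 x 20 or 50 x 50 pixel regions). Trailing rows/columns that do
#' not fill a block are dropped.
#'
#' @param flow a [flow_series()].
#' @param block block edge in pixels of the *input* grid cells to merge.
#' @return a coarsened [flow_series()].
#' @export
block_average <- function(flow, block) {
  stopifnot(inherits(flow, "flow_series"))
  block <- as.integer(block)
  d <- dim(flow$u)
  if (block < 1) stop("block must be >= 1")
  if (block > d[1] || block > d[2]) stop("block larger than the field")
  if (block == 1) return(flow)
  Hb <- d[1] %/% block; Wb <- d[2] %/% block
  u2 <- array(0, dim = c(Hb, Wb, d[3]))
  v2 <- array(0, dim = c(Hb, Wb, d[3]))
  for (k in seq_len(d[3])) {
    u2[, , k] <- block_mean_mat(flow$u[, , k], block)
    v2[, , k] <- block_mean_mat(flow$v[, , k], block)
  }
  flow_series(u2, v2, block_size = flow$block_size * block, fps = flow$fps,
              low_confidence = flow$low_confidence, metadata = flow$metadata)
}

#' Per-frame flow summary
#'
#' @param flow a [flow_series()].
#' @param center optional c(row, col) centre (in input-grid pixels) for the
#'   radial component; defaults to the field centre.
#' @return data.frame with one row per frame pair: mean speed and mean radial
#'   component (positive = motion toward the centre).
#' @export
flow_summary <- function(flow, center = NULL) {
  d <- dim(flow$u)
  if (is.null(center)) center <- (d[1:2] + 1) / 2
  yy <- matrix(seq_len(d[1]), d[1], d[2])
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  r <- pmax(sqrt((yy - center[1])^2 + (xx - center[2])^2), 1e-9)
  dirx <- (xx - center[2]) / r; diry <- (yy - center[1]) / r
  data.frame(
    frame = seq_len(d[3]),
    mean_speed = vapply(seq_len(d[3]), function(k)
      mean(sqrt(flow$u[, , k]^2 + flow$v[, , k]^2)), 0),
    mean_radial = vapply(seq_len(d[3]), function(k)
      mean(-(flow$u[, , k] * dirx + flow$v[, , k] * diry)), 0)
  )
}
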