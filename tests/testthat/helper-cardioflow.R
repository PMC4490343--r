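# shared fixtures and independent oracles, all built in code

# textured test image (band-limited noise, like the generator's texture)
test_texture <- function(n = 96, seed = 3) cardioflow:::make_texture(n, n, seed)

# integer-translate an image with edge replication: content moves by
# (dx right, dy down)
translate_img <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
  img[ri, ci, drop = FALSE]
}

# FFT cross-correlation oracle: integer displacement between two frames
# (independent of the package's variational flow solver). Mild spectral
# regularisation keeps the band-limited texture's empty bands from
# dominating the correlation surface.
phase_corr_shift <- function(f1, f2) {
  F1 <- stats::fft(f1 - mean(f1)); F2 <- stats::fft(f2 - mean(f2))
  r <- Re(stats::fft(F2 * Conj(F1), inverse = TRUE))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) { i <- unname(i); if (i - 1 > n / 2) i - 1 - n else i - 1 }
  c(dx = wrap(pk[2], ncol(f1)), dy = wrap(pk[1], nrow(f1)))
}

stack_from_frames <- function(..., fps = 15.6) {
  fr <- list(...)
  frame_stack(array(unlist(fr), dim = c(dim(fr[[1]]), length(fr))), fps = fps)
}

# small rendered contraction video shared by flow/profile tests
cached_video <- local({
  st <- NULL
  function() {
    if (is.null(st)) {
      cfg <- kinematics_config(image_size = c(64, 64), fps = 15.6, duration = 4,
                               beat_period = 1.2, t_rise = 0.2, t_relax = 0.4,
                               motion_amplitude = 2.5, pixel_noise_sd = 0.005)
      st <<- render_video(cfg)
    }
    st
  }
})

# profile whose samples hit triangle vertices exactly: two triangular beats
# (contraction up/down, relaxation down/up), peaks 1.25 s apart
triangle_profile <- function() {
  dt <- 0.125
  beat <- c(0, 0.5, 1, 0.5, 0, -0.5, -1, -0.5, 0, 0)  # 1.25 s per beat
  score <- c(beat, beat, 0, 0)
  contractile_profile(score, seq_along(score) * dt - dt)
}

ar1_chol <- function(k, rho) chol(rho^abs(outer(seq_len(k), seq_len(k), "-")))

# a feature table with controllable class separation: wells x acquisitions x
# beats, 12 features drawn around per-class centroids
synthetic_table <- function(n_wells = 15, n_base_acq = 3, beats = 9,
                            shift = 0, sd = 1, seed = 1,
                            condition = "drug") {
  set.seed(seed)
  mk <- function(well, cond, acq, delta) {
    X <- matrix(stats::rnorm(beats * 12, mean = delta, sd = sd), beats, 12)
    df <- as.data.frame(X)
    names(df) <- paste0("p", 1:12)
    df$well_id <- well; df$condition <- cond; df$acquisition_index <- acq
    df$beat <- seq_len(beats); df$is_last <- FALSE
    df
  }
  rows <- list()
  for (w in seq_len(n_wells)) {
    id <- sprintf("W%02d", w)
    for (a in seq_len(n_base_acq))
      rows[[length(rows) + 1]] <- mk(id, "baseline", a - 1, 0)
    rows[[length(rows) + 1]] <- mk(id, condition, n_base_acq, shift)
  }
  do.call(rbind, rows)
}

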