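#' Kinematics configuration for synthetic contraction videos
#'
#' Describes a textured tissue patch undergoing periodic radially-convergent
#' contraction. The displacement waveform is built from raised-cosine rise and
#' relaxation segments (smooth, so the rendered video has no kinks that would
#' produce spurious optical-flow artifacts), followed by a rest phase at zero
#' displacement.
#'
#' @param image_size integer c(H, W) in pixels.
#' @param fps frame rate, frames per second.
#' @param duration acquisition length in seconds.
#' @param beat_period beat-to-beat period in seconds.
#' @param t_rise contraction upstroke duration, seconds.
#' @param t_relax relaxation duration, seconds.
#' @param t_rest rest duration, seconds; defaults to the remainder of the
#'   period. `t_rise + t_relax + t_rest` must not exceed `beat_period`.
#' @param motion_amplitude peak inward displacement, pixels.
#' @param center patch centre c(row, col) in pixels; defaults to the image
#'   centre.
#' @param texture_seed integer seed for the random texture.
#' @param pixel_noise_sd additive Gaussian pixel noise, intensity units
#'   (texture intensities span roughly \[0, 1\]).
#' @param first_beat_onset time of the first contraction start, seconds.
#' @return an object of class `kinematics_config`.
#' @export
kinematics_config <- function(image_size = c(96L, 96L),
                              fps = 15.6,
                              duration = 17.5,
                              beat_period = 1.8,
                              t_rise = 0.25,
                              t_relax = 0.45,
                              t_rest = NULL,
                              motion_amplitude = 3,
                              center = NULL,
                              texture_seed = 1L,
                              pixel_noise_sd = 0.01,
                              first_beat_onset = 0.2) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (fps * duration < 2) stop("need at least 2 frames (fps * duration >= 2)")
  if (motion_amplitude < 0) stop("motion_amplitude must be >= 0")
  if (is.null(t_rest)) t_rest <- beat_period - t_rise - t_relax
  if (t_rest < -1e-9 || t_rise + t_relax + t_rest > beat_period + 1e-9)
    stop("t_rise + t_relax + t_rest must fit within beat_period")
  if (t_rise <= 0 || t_relax <= 0) stop("t_rise and t_relax must be positive")
  if (is.null(center)) center <- (image_size + 1) / 2
  structure(list(
    image_size = as.integer(image_size), fps = fps, duration = duration,
    beat_period = beat_period, t_rise = t_rise, t_relax = t_relax,
    t_rest = t_rest, motion_amplitude = motion_amplitude, center = center,
    texture_seed = as.integer(texture_seed), pixel_noise_sd = pixel_noise_sd,
    first_beat_onset = first_beat_onset
  ), class = "kinematics_config")
}

#' Closed-form contraction displacement waveform
#'
#' Evaluates the inward displacement s(t) (pixels) of the patch: zero before
#' the first beat onset, then per period a raised-cosine rise from 0 to
#' `motion_amplitude` over `t_rise`, a raised-cosine return to 0 over
#' `t_relax`, and rest at 0 for the remainder of the period.
#'
#' @param cfg a [kinematics_config()].
#' @return a list with `time` (frame times, seconds), `s` (displacement at the
#'   frame times), `fn` (the vectorised closed-form function of time) and
#'   `beats`, a data.frame of ground-truth per-beat phase times
#'   (`c_start`, `c_peak_true` = time of peak contraction *velocity*,
#'   `disp_peak` = time of peak displacement, `r_end`).
#' @export
make_waveform <- function(cfg) {
  stopifnot(inherits(cfg, "kinematics_config"))
  n_frames <- floor(cfg$fps * cfg$duration)
  A <- cfg$motion_amplitude
  P <- cfg$beat_period
  tr <- cfg$t_rise; tx <- cfg$t_relax
  onset <- cfg$first_beat_onset
  fn <- function(t) {
    out <- numeric(length(t))
    tau <- t - onset
    ok <- tau >= 0
    ph <- tau[ok] %% P
    s <- numeric(length(ph))
    up <- ph < tr
    s[up] <- A * 0.5 * (1 - cos(pi * ph[up] / tr))
    dn <- !up & ph < tr + tx
    s[dn] <- A * 0.5 * (1 + cos(pi * (ph[dn] - tr) / tx))
    out[ok] <- s
    out
  }
  time <- (seq_len(n_frames) - 1) / cfg$fps
  # ground truth: every beat whose full rise+relax fits inside the *sampled*
  # recording (the last frame sits just short of `duration`, so a beat whose
  # relaxation ends within a frame of the nominal end is not observable)
  t_last <- (n_frames - 1) / cfg$fps
  starts <- if (onset <= t_last - tr - tx)
    seq(onset, t_last - tr - tx, by = P) else numeric(0)
  beats <- data.frame(
    index = seq_along(starts),
    c_start = starts,
    c_peak_true = starts + tr / 2,    # velocity maximum (profile peak)
    disp_peak = starts + tr,          # displacement maximum
    c_end = starts + tr,              # profile zero crossing rise -> relax
    r_end = starts + tr + tx
  )
  list(time = time, s = fn(time), fn = fn, beats = beats, cfg = cfg)
}

# separable Gaussian blur with edge replication; small helper used for the
# texture and for pyramid downsampling in the flow solver
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# vectorised bilinear sampling with border clamping; x = column, y = row
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
  dx <- x - x0; dy <- y - y0
  i00 <- (x0 - 1) * H + y0
  v00 <- img[i00];       v10 <- img[i00 + H]
  v01 <- img[i00 + 1];   v11 <- img[i00 + H + 1]
  (1 - dy) * ((1 - dx) * v00 + dx * v10) + dy * ((1 - dx) * v01 + dx * v11)
}

# band-limited random texture: white noise blurred to ~3 px correlation length,
# rescaled to mean 0.5, sd 0.15 (mimics brightfield cell texture contrast)
make_texture <- function(H, W, seed) {
  set.seed(seed)
  tex <- matrix(stats::rnorm(H * W), H, W)
  tex <- gauss_blur(tex, 1.3)
  0.5 + 0.15 * (tex - mean(tex)) / stats::sd(tex)
}

#' Render a synthetic brightfield contraction video
#'
#' A fixed random texture is warped by the radial displacement field
#' `u(p, t) = -s(t) * (p - c)/||p - c|| * g(||p - c||)` (displacement toward
#' the centre `c`, with a raised-cosine envelope `g` tapering to zero at the
#' patch border), using bilinear backward warping, plus additive Gaussian
#' pixel noise. The ground-truth waveform and beat times are attached.
#'
#' @param cfg a [kinematics_config()].
#' @return a [frame_stack()] with attribute `truth` (the [make_waveform()]
#'   output plus the patch radius).
#' @export
render_video <- function(cfg) {
  stopifnot(inherits(cfg, "kinematics_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  R <- 0.95 * min(H, W) / 2
  if (cfg$motion_amplitude >= R)
    stop("motion_amplitude must be smaller than the patch radius (", round(R, 1), " px)")
  wf <- make_waveform(cfg)
  tex <- make_texture(H, W, cfg$texture_seed)
  cy <- cfg$center[1]; cx <- cfg$center[2]
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  g <- ifelse(r < R, cos(pi * r / (2 * R))^2, 0)
  rs <- pmax(r, 1e-9)
  dirx <- (xx - cx) / rs; diry <- (yy - cy) / rs
  n_frames <- length(wf$time)
  set.seed(cfg$texture_seed + 7L)
  frames <- array(0, dim = c(H, W, n_frames))
  for (k in seq_len(n_frames)) {
    s <- wf$s[k]
    if (s == 0) {
      fr <- tex
    } else {
      # backward warp: the pixel at p came from p + s * dir * g (outward)
      fr <- matrix(bilinear_sample(tex, xx + s * dirx * g, yy + s * diry * g), H, W)
    }
    if (cfg$pixel_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(H * W, sd = cfg$pixel_noise_sd), H, W)
    frames[, , k] <- fr
  }
  st <- frame_stack(frames, fps = cfg$fps)
  attr(st, "truth") <- c(wf, list(patch_radius = R))
  st
}

#' Calcium trace configuration
#'
#' Parameters of the synthetic GCaMP6-style fluorescence trace: a baseline
#' with within-acquisition exponential photobleaching and an across-acquisition
#' multiplicative decay, carrying periodic calcium transients with a
#' raised-cosine rise and exponential decay.
#'
#' @param baseline_intensity baseline fluorescence, arbitrary units (> 0).
#' @param transient_amplitude transient peak height relative to baseline
#'   (unitless; the raw peak is `baseline * (1 + transient_amplitude)` before
#'   bleaching).
#' @param t_rise transient rise time, seconds.
#' @param t_decay exponential decay time constant, seconds.
#' @param beat_period transient period, seconds.
#' @param bleach_rate within-acquisition exponential bleach rate, 1/s (>= 0).
#' @param acquisition_scale across-acquisition multiplicative decay per
#'   acquisition index, in (0, 1].
#' @param noise_sd additive Gaussian noise, arbitrary units.
#' @param fps sampling rate, frames per second.
#' @param duration trace length, seconds.
#' @param first_onset time of the first transient start, seconds.
#' @param seed integer seed for the noise.
#' @return an object of class `trace_config`.
#' @export
trace_config <- function(baseline_intensity = 100,
                         transient_amplitude = 0.8,
                         t_rise = 0.15,
                         t_decay = 0.25,
                         beat_period = 1.8,
                         bleach_rate = 0.2,
                         acquisition_scale = 0.9,
                         noise_sd = 0.5,
                         fps = 15.6,
                         duration = 17.5,
                         first_onset = 0.5,
                         seed = 1L) {
  if (baseline_intensity <= 0) stop("baseline_intensity must be > 0")
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  if (acquisition_scale <= 0 || acquisition_scale > 1)
    stop("acquisition_scale must be in (0, 1]")
  if (fps <= 0 || duration <= 0) stop("fps and duration must be positive")
  structure(list(
    baseline_intensity = baseline_intensity,
    transient_amplitude = transient_amplitude, t_rise = t_rise,
    t_decay = t_decay, beat_period = beat_period, bleach_rate = bleach_rate,
    acquisition_scale = acquisition_scale, noise_sd = noise_sd, fps = fps,
    duration = duration, first_onset = first_onset, seed = as.integer(seed)
  ), class = "trace_config")
}

# transient kernel: raised-cosine rise 0 -> 1 over t_rise, then exponential
# decay with time constant t_decay; zero for tau < 0
transient_kernel <- function(tau, t_rise, t_decay) {
  out <- numeric(length(tau))
  up <- tau >= 0 & tau < t_rise
  out[up] <- 0.5 * (1 - cos(pi * tau[up] / t_rise))
  dn <- tau >= t_rise
  out[dn] <- exp(-(tau[dn] - t_rise) / t_decay)
  out
}

# true CTD90 of the noiseless kernel: time from transient start until the
# decaying signal first falls below 10% of the peak (closed form for this
# kernel: t_rise + t_decay * log(10), but computed by dense threshold
# crossing so it stays valid if the kernel changes)
true_ctd90 <- function(t_rise, t_decay) {
  tau <- seq(0, t_rise + 12 * t_decay, by = 1e-4)
  k <- transient_kernel(tau, t_rise, t_decay)
  pk <- which.max(k)
  below <- which(k[pk:length(k)] < 0.1 * k[pk])[1]
  tau[pk + below - 1]
}

#' Render a synthetic calcium transient trace
#'
#' `raw(t) = B * scale^index * exp(-bleach_rate * t) * (1 + a * sum_i
#' k(t - t_i)) + noise`, where `k` is a raised-cosine-rise / exponential-decay
#' transient kernel. Ground-truth transient start and peak times and the true
#' CTD90 of the noiseless kernel are attached.
#'
#' @param cfg a [trace_config()].
#' @param acquisition_index zero-based acquisition index driving the
#'   across-acquisition decay.
#' @return a [calcium_trace()] with attribute `truth` (start/peak times,
#'   true amplitude and CTD90).
#' @export
render_trace <- function(cfg, acquisition_index = 0L) {
  stopifnot(inherits(cfg, "trace_config"))
  n <- floor(cfg$fps * cfg$duration)
  times <- (seq_len(n) - 1) / cfg$fps
  onsets <- seq(cfg$first_onset, cfg$duration - cfg$t_rise, by = cfg$beat_period)
  shape <- numeric(n)
  for (t0 in onsets) shape <- shape + transient_kernel(times - t0, cfg$t_rise, cfg$t_decay)
  base <- cfg$baseline_intensity * cfg$acquisition_scale^acquisition_index *
    exp(-cfg$bleach_rate * times)
  raw <- base * (1 + cfg$transient_amplitude * shape)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed + 13L * (acquisition_index + 1L))
    raw <- raw + stats::rnorm(n, sd = cfg$noise_sd)
  }
  # bleach-free sampled amplitude per transient: what a perfect detrend can
  # recover given the finite sampling grid
  cycle <- findInterval(times, onsets)
  samp_amp <- vapply(seq_along(onsets), function(i)
    cfg$transient_amplitude * max(shape[cycle == i]), 0)
  tr <- calcium_trace(raw, times)
  attr(tr, "truth") <- list(
    starts = onsets, peaks = onsets + cfg$t_rise,
    amplitude = cfg$transient_amplitude,
    sampled_amplitude = samp_amp,
    ctd90 = true_ctd90(cfg$t_rise, cfg$t_decay),
    baseline = base, cfg = cfg, acquisition_index = acquisition_index
  )
  tr
}

#' Cohort configuration for multi-well screening experiments
#'
#' Mirrors the drug-experiment design: each well contributes
#' `n_baseline_acquisitions` baseline acquisitions plus one acquisition per
#' condition, with condition effects applied as multiplicative perturbations
#' of that well's kinematics.
#'
#' @param n_wells number of wells (>= 3).
#' @param n_baseline_acquisitions baseline acquisitions per well (default 3,
#'   matching a design with three pre-treatment measurements).
#' @param conditions named list of conditions; each element is a list with
#'   elements `rate_factor`, `relax_factor`, `amplitude_factor` (all > 0,
#'   default 1). A factor of 1 leaves that aspect of the kinematics untouched.
#' @param well_cv coefficient of variation of per-well kinematic parameters
#'   (log-normal perturbations of beat period, rise/relax durations and
#'   amplitude). Acquisition-to-acquisition jitter uses `well_cv / 2`.
#' @param base_kinematics the [kinematics_config()] around which wells vary.
#' @param profile_noise_sd additive noise on profile-fidelity scores, as a
#'   fraction of the peak score magnitude.
#' @param seed integer master seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_wells = 15L,
                          n_baseline_acquisitions = 3L,
                          conditions = list(placebo = list()),
                          well_cv = 0.10,
                          base_kinematics = kinematics_config(),
                          profile_noise_sd = 0.02,
                          seed = 1L) {
  if (n_wells < 3) stop("n_wells must be >= 3")
  if (length(conditions) == 0) stop("conditions must be a non-empty list")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list")
  conditions <- lapply(conditions, function(e) {
    e <- utils::modifyList(list(rate_factor = 1, relax_factor = 1,
                                amplitude_factor = 1), e)
    if (any(unlist(e) <= 0)) stop("all effect factors must be > 0")
    e
  })
  structure(list(
    n_wells = as.integer(n_wells),
    n_baseline_acquisitions = as.integer(n_baseline_acquisitions),
    conditions = conditions, well_cv = well_cv,
    base_kinematics = base_kinematics,
    profile_noise_sd = profile_noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# log-normal multiplicative jitter with coefficient of variation cv
lnorm_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

perturb_kinematics <- function(base, period_f, rise_f, relax_f, amp_f) {
  P <- base$beat_period * period_f
  tr <- base$t_rise * rise_f
  tx <- base$t_relax * relax_f
  # keep the waveform valid: squeeze active phases into the period if needed
  if (tr + tx > 0.95 * P) {
    sc <- 0.95 * P / (tr + tx); tr <- tr * sc; tx <- tx * sc
  }
  kinematics_config(
    image_size = base$image_size, fps = base$fps, duration = base$duration,
    beat_period = P, t_rise = tr, t_relax = tx,
    motion_amplitude = base$motion_amplitude * amp_f,
    center = base$center, texture_seed = base$texture_seed,
    pixel_noise_sd = base$pixel_noise_sd,
    first_beat_onset = base$first_beat_onset
  )
}

# contractile profile directly from the waveform (profile fidelity): the
# profile tracks contraction velocity, positive during the upstroke
profile_from_waveform <- function(cfg, noise_frac) {
  wf <- make_waveform(cfg)
  score <- diff(wf$s) * cfg$fps
  peak <- max(abs(score))
  if (noise_frac > 0 && peak > 0)
    score <- score + stats::rnorm(length(score), sd = noise_frac * peak)
  pr <- contractile_profile(score - mean(score),
                            times = wf$time[-1] - 0.5 / cfg$fps,
                            variance_explained = 1)
  attr(pr, "truth") <- wf
  pr
}

#' Generate a labelled multi-well cohort with known ground truth
#'
#' Per well, draws well-level kinematics (log-normal perturbations with CV
#' `well_cv` of period, rise, relax and amplitude), then emits
#' `n_baseline_acquisitions` baseline acquisitions and one acquisition per
#' condition with that condition's effect factors applied. Acquisition-level
#' jitter (CV `well_cv/2`) makes repeat acquisitions exchangeable but not
#' identical. At `fidelity = "profile"` each acquisition is a
#' [contractile_profile()] computed directly from the waveform (fast path);
#' at `fidelity = "video"` full frame stacks are rendered.
#'
#' @param cfg a [cohort_config()].
#' @param fidelity `"profile"` or `"video"`.
#' @return an object of class `cohort`: a list with `manifest` (data.frame of
#'   well_id, condition, acquisition_index) and `acquisitions` (parallel list;
#'   each element has the profile or stack, the ground truth and the realised
#'   kinematics config).
#' @export
make_cohort <- function(cfg, fidelity = c("profile", "video")) {
  stopifnot(inherits(cfg, "cohort_config"))
  fidelity <- match.arg(fidelity)
  set.seed(cfg$seed)
  acq_cv <- cfg$well_cv / 2
  manifest <- NULL
  acquisitions <- list()
  for (w in seq_len(cfg$n_wells)) {
    wf_fac <- lnorm_jitter(4, cfg$well_cv)  # period, rise, relax, amplitude
    emit <- function(condition, acq_idx, eff) {
      jf <- lnorm_jitter(4, acq_cv)
      kin <- perturb_kinematics(
        cfg$base_kinematics,
        period_f = wf_fac[1] * jf[1] / eff$rate_factor,
        rise_f   = wf_fac[2] * jf[2],
        relax_f  = wf_fac[3] * jf[3] * eff$relax_factor,
        amp_f    = wf_fac[4] * jf[4] * eff$amplitude_factor
      )
      kin$texture_seed <- cfg$seed + 1000L * w + acq_idx
      acq <- if (fidelity == "profile")
        profile_from_waveform(kin, cfg$profile_noise_sd)
      else
        render_video(kin)
      list(well_id = sprintf("W%02d", w), condition = condition,
           acquisition_index = acq_idx, data = acq, kinematics = kin,
           truth = attr(acq, "truth"))
    }
    null_eff <- list(rate_factor = 1, relax_factor = 1, amplitude_factor = 1)
    for (b in seq_len(cfg$n_baseline_acquisitions)) {
      acquisitions[[length(acquisitions) + 1L]] <- emit("baseline", b - 1L, null_eff)
    }
    for (cn in names(cfg$conditions)) {
      acquisitions[[length(acquisitions) + 1L]] <-
        emit(cn, cfg$n_baseline_acquisitions, cfg$conditions[[cn]])
    }
  }
  manifest <- do.call(rbind, lapply(acquisitions, function(a)
    data.frame(well_id = a$well_id, condition = a$condition,
               acquisition_index = a$acquisition_index,
               stringsAsFactors = FALSE)))
  structure(list(manifest = manifest, acquisitions = acquisitions,
                 config = cfg, fidelity = fidelity), class = "cohort")
}

#' Generate a multi-well calcium-trace cohort
#'
#' Companion to [make_cohort()] for the fluorescence pipeline: per well,
#' `n_baseline_acquisitions` baseline traces plus one trace per condition,
#' acquired sequentially so the across-acquisition photobleach decay
#' accumulates with acquisition index. Condition effects map onto trace
#' kinetics: `rate_factor` scales the transient rate, `relax_factor` the
#' decay time constant, `amplitude_factor` the transient amplitude.
#'
#' @param cfg a [cohort_config()].
#' @param base_trace the [trace_config()] around which wells vary.
#' @return a `cohort` object whose acquisitions hold [calcium_trace()]s.
#' @export
make_trace_cohort <- function(cfg, base_trace = trace_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed + 1L)
  acq_cv <- cfg$well_cv / 2
  acquisitions <- list()
  for (w in seq_len(cfg$n_wells)) {
    wf_fac <- lnorm_jitter(3, cfg$well_cv)  # period, decay, amplitude
    emit <- function(condition, acq_idx, eff) {
      jf <- lnorm_jitter(3, acq_cv)
      tc <- base_trace
      tc$beat_period <- tc$beat_period * wf_fac[1] * jf[1] / eff$rate_factor
      tc$t_decay <- tc$t_decay * wf_fac[2] * jf[2] * eff$relax_factor
      tc$transient_amplitude <-
        tc$transient_amplitude * wf_fac[3] * jf[3] * eff$amplitude_factor
      tc$seed <- cfg$seed + 1000L * w + acq_idx
      tr <- render_trace(tc, acquisition_index = acq_idx)
      list(well_id = sprintf("W%02d", w), condition = condition,
           acquisition_index = acq_idx, data = tr,
           truth = attr(tr, "truth"))
    }
    null_eff <- list(rate_factor = 1, relax_factor = 1, amplitude_factor = 1)
    for (b in seq_len(cfg$n_baseline_acquisitions)) {
      acquisitions[[length(acquisitions) + 1L]] <- emit("baseline", b - 1L, null_eff)
    }
    for (cn in names(cfg$conditions)) {
      acquisitions[[length(acquisitions) + 1L]] <-
        emit(cn, cfg$n_baseline_acquisitions, cfg$conditions[[cn]])
    }
  }
  manifest <- do.call(rbind, lapply(acquisitions, function(a)
    data.frame(well_id = a$well_id, condition = a$condition,
               acquisition_index = a$acquisition_index,
               stringsAsFactors = FALSE)))
  structure(list(manifest = manifest, acquisitions = acquisitions,
                 config = cfg, fidelity = "trace"), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort (", x$fidelity, " fidelity): ",
      x$config$n_wells, " wells, ",
      nrow(x$manifest), " acquisitions, conditions: ",
      paste(unique(x$manifest$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}
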