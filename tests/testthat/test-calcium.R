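test_that("transient detection recovers ground-truth starts and peaks", {
  tc <- trace_config(noise_sd = 0, bleach_rate = 0.2, duration = 10,
                     beat_period = 1.8, first_onset = 0.5)
  tr <- detect_transients(render_trace(tc))
  truth <- attr(tr, "truth")
  expect_identical(length(tr$starts), length(truth$starts))
  dt <- 1 / tc$fps
  expect_true(all(abs(tr$times[tr$starts] - truth$starts) <= dt + 1e-9))
  expect_true(all(abs(tr$times[tr$peaks] - truth$peaks) <= dt + 1e-9))

  expect_warning(c0 <- detect_transients(calcium_trace(rep(3, 60), (0:59) / 10)),
                 "flat|no transients")
  expect_identical(length(c0$starts), 0L)

  # single transient: exactly one (start, peak) pair
  t1 <- seq(0, 3, by = 0.02)
  y1 <- 10 * (1 + cardioflow:::transient_kernel(t1 - 1, 0.1, 0.2))
  d1 <- detect_transients(calcium_trace(y1, t1))
  expect_identical(length(d1$starts), 1L)
  expect_identical(length(d1$peaks), 1L)
})

test_that("detrending flattens constant baselines exactly and is idempotent", {
  B <- 40
  t <- seq(0, 8, by = 1 / 20)
  shape <- Reduce(`+`, lapply(c(0.5, 2.5, 4.5, 6.5), function(t0)
    cardioflow:::transient_kernel(t - t0, 0.12, 0.2)))
  tr <- detrend_bleach(detect_transients(calcium_trace(B * (1 + 0.6 * shape), t)))
  expect_true(all(abs(tr$normalized[tr$starts]) < 1e-9))
  # peaks at a/B of the raw transient height a = 0.6 * B
  seg_max <- max(tr$normalized)
  expect_equal(seg_max, 0.6 * max(shape), tolerance = 0.01)

  # second pass on an already-flat baseline changes nothing
  tr2 <- calcium_trace(tr$normalized + 1, t)
  tr2 <- detrend_bleach(detect_transients(tr2))
  expect_lt(max(abs(tr2$normalized - tr$normalized)), 1e-6)
})

test_that("photobleach-corrected amplitudes match the bleach-free truth", {
  tc <- trace_config(noise_sd = 0, bleach_rate = 0.2, duration = 12,
                     beat_period = 1.8, first_onset = 0.5)
  tr <- detrend_bleach(detect_transients(render_trace(tc)))
  truth <- attr(tr, "truth")
  m <- suppressWarnings(transient_metrics(tr))
  rel <- m$per_transient$amplitude / truth$sampled_amplitude - 1
  expect_true(all(abs(rel) < 0.05))
  # noiseless CTD90 within one sample of the kernel's true value
  ok <- !is.na(m$per_transient$ctd90)
  expect_true(all(abs(m$per_transient$ctd90[ok] - truth$ctd90) < 1 / tc$fps))
})

test_that("the piecewise-linear transient gives the analytic CTD90 and SR90", {
  fps <- 100
  t <- seq(0, 4, by = 1 / fps)
  kern <- function(tau) ifelse(tau < 0, 0,
                        ifelse(tau < 0.1, tau / 0.1, pmax(0, 1 - (tau - 0.1) / 0.9)))
  base <- 1
  for (k in c(1, 0.5, 2)) {
    y <- base + k * (kern(t - 0.3) + kern(t - 1.6) + kern(t - 2.9))
    m <- transient_metrics(detrend_bleach(detect_transients(calcium_trace(y, t))))
    # analytic crossing: rise 0.1 s + decay to the 10% level after 0.81 s
    expect_equal(m$per_transient$ctd90, rep(0.91, 3), tolerance = 1 / fps)
    expect_equal(m$per_transient$sr90, rep(0.91 / k, 3), tolerance = 0.02 / k)
  }
})

test_that("beating rate counts intervals between starts", {
  t <- seq(0, 4.6, by = 0.01)
  y <- 1 + Reduce(`+`, lapply(0:4, function(j)
    cardioflow:::transient_kernel(t - j, 0.1, 0.15)))
  m <- transient_metrics(detrend_bleach(detect_transients(calcium_trace(y, t))))
  expect_equal(m$beating_rate, 60, tolerance = 1)  # starts at 0..4 s
})

test_that("time dilation rescales CTD90 and beating rate inversely", {
  tc <- trace_config(noise_sd = 0, bleach_rate = 0.1, duration = 10)
  m1 <- suppressWarnings(transient_metrics(detrend_bleach(detect_transients(render_trace(tc)))))
  tr2 <- render_trace(tc)
  tr2$times <- tr2$times * 2   # dilate the clock
  m2 <- suppressWarnings(transient_metrics(detrend_bleach(detect_transients(tr2))))
  expect_equal(m2$ctd90 / m1$ctd90, 2, tolerance = 0.05)
  expect_equal(m1$beating_rate / m2$beating_rate, 2, tolerance = 0.05)
})

test_that("monotone bleach neither creates nor destroys transients", {
  for (br in c(0, 0.1, 0.3)) {
    tc <- trace_config(noise_sd = 0, bleach_rate = br, duration = 12)
    tr <- detect_transients(render_trace(tc))
    expect_identical(length(tr$starts), length(attr(tr, "truth")$starts))
  }
})

test_that("SR90 is stable across photobleached acquisitions where absolute-threshold CTD90 drifts", {
  tc <- trace_config(noise_sd = 0, bleach_rate = 0.15, acquisition_scale = 0.8,
                     duration = 12)
  sr <- ctd_rel <- ctd_abs <- numeric(5)
  abs_level <- NA
  for (i in 0:4) {
    tr <- detrend_bleach(detect_transients(render_trace(tc, i)))
    m <- suppressWarnings(transient_metrics(tr))
    sr[i + 1] <- m$sr90
    ctd_rel[i + 1] <- m$ctd90
    # foil: duration above an *absolute* fluorescence level fixed from the
    # first acquisition (10% of its first transient's absolute height)
    raw_amp <- (tr$raw - min(tr$raw))
    if (i == 0) abs_level <- 0.1 * max(raw_amp[tr$starts[1]:tr$peaks[2]])
    st1 <- tr$starts[1]
    above <- which(raw_amp[st1:length(raw_amp)] > abs_level)
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    ctd_abs[i + 1] <- length(runs[[1]]) * diff(tr$times[1:2])
  }
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(sr), cv(ctd_abs))       # SR90 corrects the bleach artifact
  expect_lt(cv(ctd_rel), 0.05)         # relative-threshold CTD90 is stable too
  expect_lt(cv(sr), 0.05)
})

test_that("ROI extraction averages the requested square", {
  fr <- array(0, dim = c(20, 30, 3))
  fr[3:6, 5:8, ] <- rep(c(1, 2, 3), each = 16)
  st <- frame_stack(fr, fps = 10)
  tr <- roi_trace(st, x = 5, y = 3, width = 4, height = 4)
  expect_equal(tr$raw, c(1, 2, 3))
  expect_error(roi_trace(st, x = 25, y = 1, width = 10, height = 10), "ROI")
})
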