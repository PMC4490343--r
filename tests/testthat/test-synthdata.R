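test_that("waveform obeys its phase structure", {
  cfg <- kinematics_config(beat_period = 1, duration = 5, t_rise = 0.2,
                           t_relax = 0.3, first_beat_onset = 0,
                           motion_amplitude = 2, fps = 15.6)
  wf <- make_waveform(cfg)
  tt <- seq(0, 5 - 1e-6, by = 1e-3)
  s <- wf$fn(tt)
  expect_true(all(s >= 0))
  expect_equal(max(s), 2, tolerance = 1e-6)
  # rest phase is exactly zero
  in_rest <- (tt %% 1) >= 0.5 + 1e-9
  expect_true(all(s[in_rest] == 0))
  # exactly 5 local maxima (one per period)
  n_max <- sum(diff(sign(diff(s))) < 0 & s[2:(length(s) - 1)] > 1)
  expect_identical(n_max, 5L)
  # argmax of the first beat at t_rise, within one frame interval
  first <- tt < 1
  expect_lt(abs(tt[first][which.max(s[first])] - 0.2), 1 / 15.6)
})

test_that("zero-amplitude waveform is identically zero and bad configs are rejected", {
  cfg <- kinematics_config(motion_amplitude = 0)
  expect_true(all(make_waveform(cfg)$s == 0))
  expect_error(kinematics_config(fps = 0), "fps")
  expect_error(kinematics_config(duration = -1), "duration")
  expect_error(kinematics_config(motion_amplitude = -1), "motion_amplitude")
  expect_error(kinematics_config(beat_period = 0.4, t_rise = 0.3, t_relax = 0.3),
               "beat_period")
})

test_that("rendered video matches the acquisition geometry and kinematics", {
  # static scene: no motion, no noise -> identical frames
  cfg0 <- kinematics_config(image_size = c(32, 32), motion_amplitude = 0,
                            pixel_noise_sd = 0, duration = 0.5)
  st0 <- render_video(cfg0)
  expect_equal(max(abs(st0$frames[, , 1] - st0$frames[, , 2])), 0)

  # 17.5 s at 15.6 fps gives 273 frames
  cfg1 <- kinematics_config(image_size = c(24, 24), fps = 15.6, duration = 17.5,
                            motion_amplitude = 1, pixel_noise_sd = 0)
  expect_identical(dim(render_video(cfg1)$frames)[3], 273L)

  # inter-frame pixel change peaks during the upstroke
  cfg2 <- kinematics_config(image_size = c(48, 48), duration = 2,
                            beat_period = 1.5, t_rise = 0.25, t_relax = 0.5,
                            motion_amplitude = 2, pixel_noise_sd = 0)
  st2 <- render_video(cfg2)
  truth <- attr(st2, "truth")
  d <- dim(st2$frames)[3]
  madiff <- vapply(seq_len(d - 1), function(k)
    mean(abs(st2$frames[, , k + 1] - st2$frames[, , k])), 0)
  ds <- abs(diff(truth$s))
  expect_gt(cor(madiff, ds), 0.9)
  expect_true(which.max(madiff) %in% which(ds > 0.8 * max(ds)))

  # amplitude beyond the patch radius is rejected
  expect_error(render_video(kinematics_config(image_size = c(32, 32),
                                              motion_amplitude = 20)),
               "patch radius")
})

test_that("rendered traces follow the multiplicative bleach model", {
  # no transients, no bleach, no noise: constant at baseline
  tc0 <- trace_config(transient_amplitude = 0, bleach_rate = 0, noise_sd = 0,
                      baseline_intensity = 50)
  expect_true(all(abs(render_trace(tc0)$raw - 50) < 1e-12))

  # across-acquisition scale 0.9: peak ratio between indices 1 and 0
  tc1 <- trace_config(noise_sd = 0, bleach_rate = 0, acquisition_scale = 0.9)
  r0 <- render_trace(tc1, 0); r1 <- render_trace(tc1, 1)
  expect_equal(max(r1$raw) / max(r0$raw), 0.9, tolerance = 1e-12)

  # dense-grid CTD90 of the kernel equals the closed form
  expect_equal(cardioflow:::true_ctd90(0.15, 0.25),
               0.15 + 0.25 * log(10), tolerance = 2e-4)
})

test_that("cohorts are reproducible and apply effects to ground truth", {
  cfg <- cohort_config(n_wells = 3, conditions = list(placebo = list()), seed = 9)
  c1 <- make_cohort(cfg, "profile")
  c2 <- make_cohort(cfg, "profile")
  expect_identical(c1$acquisitions[[1]]$data$score,
                   c2$acquisitions[[1]]$data$score)
  expect_identical(c1$manifest, c2$manifest)

  expect_error(cohort_config(conditions = list()), "non-empty")
  expect_error(cohort_config(n_wells = 2), "n_wells")
  expect_error(cohort_config(conditions = list(d = list(rate_factor = -1))),
               "factors")

  # relax_factor = 2 doubles the true relaxation duration on average
  cfg2 <- cohort_config(n_wells = 8, conditions = list(drug = list(relax_factor = 2)),
                        seed = 11)
  co <- make_cohort(cfg2, "profile")
  tx <- vapply(co$acquisitions, function(a) a$kinematics$t_relax, 0)
  cond <- co$manifest$condition
  ratio <- mean(tx[cond == "drug"]) / mean(tx[cond == "baseline"])
  expect_equal(ratio, 2, tolerance = 0.15)
})

test_that("null cohorts are exchangeable between baseline and placebo", {
  # measured per-beat relaxation durations, baseline vs placebo (ground-truth
  # parameters are constant within an acquisition, so the beat-level KS needs
  # the measured, noise-broken values)
  ks_p <- vapply(1:20, function(s) {
    co <- make_cohort(cohort_config(n_wells = 6,
                                    conditions = list(placebo = list()),
                                    seed = 1000 + s), "profile")
    ft <- cohort_features(co)
    suppressWarnings(stats::ks.test(ft$p4[ft$condition == "baseline"],
                                    ft$p4[ft$condition == "placebo"])$p.value)
  }, 0)
  expect_gt(median(ks_p), 0.01)
})
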