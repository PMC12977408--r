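test_that("sim_params validates fields and names the offender", {
  expect_error(sim_params(n_dyads = 0), "n_dyads")
  expect_error(sim_params(coupling_pre = 1.2), "coupling_pre")
  expect_error(sim_params(task_duration = 300, disruption_offset = 600),
               "disruption_offset")
  expect_error(sim_params(coupling_band = c(0.08, 0.01)), "coupling_band")
  expect_error(sim_params(fs_nirs = 0.1), "fs_nirs")
  expect_error(sim_params(icons_visible_after_disruption = 300), "icons_visible")
  expect_error(sim_params(noise_sd = -1), "noise_sd")
})

test_that("recordings have protocol-exact durations and positive intensities", {
  p <- sim_params(n_dyads = 1, rng_seed = 3)
  d <- generate_dyad(p, 1)
  n_expect <- round(7.81 * (180 + 1200 + 180))
  expect_equal(dim(d$recording$guide$intensity)[3], n_expect)
  expect_true(all(d$recording$guide$intensity > 0))
  expect_true(all(d$recording$drawer$intensity > 0))
  expect_equal(nrow(d$recording$trajectory), 1200 * 10)
  expect_equal(unlist(d$recording$markers), c(task_start = 180, disruption = 780,
                                              task_end = 1380))
})

test_that("identical seeds give bit-identical dyads", {
  p <- small_params(n_dyads = 1, rng_seed = 9)
  d1 <- generate_dyad(p, 1)
  d2 <- generate_dyad(p, 1)
  expect_identical(d1, d2)
})

test_that("uncoupled and fully coupled pairs bracket the coherence range", {
  fs <- 7.81
  p1 <- sim_params(n_dyads = 1, group_assignment = "control", rng_seed = 21,
                   coupling_pre = 1, noise_sd = 0,
                   artifact_spike_rate = 0, artifact_shift_rate = 0,
                   bad_channel_prob = 0)
  d1 <- generate_dyad(p1, 1, channels = FALSE)
  w <- wavelet_coherence(d1$truth$roi_o2hb$guide[1, ], d1$truth$roi_o2hb$drawer[1, ],
                         fs, freq_range = c(0.01, 0.08))
  w <- mask_and_band(w, c(0.01, 0.08), window = c(180, 1380))
  expect_gte(ibs_level(w), 0.95)

  p0 <- sim_params(n_dyads = 1, group_assignment = "control", rng_seed = 22,
                   coupling_pre = 0)
  d0 <- generate_dyad(p0, 1, channels = FALSE)
  w0 <- wavelet_coherence(d0$truth$roi_o2hb$guide[1, ], d0$truth$roi_o2hb$drawer[1, ],
                          fs, freq_range = c(0.01, 0.08))
  w0 <- mask_and_band(w0, c(0.01, 0.08), window = c(180, 1380))
  expect_lt(ibs_level(w0), ibs_level(w))
})

test_that("reference path is a deterministic axis-aligned staircase on icons", {
  p <- small_params(n_dyads = 1)
  r1 <- generate_reference_path(p)
  r2 <- generate_reference_path(p)
  expect_identical(r1, r2)
  expect_true(all(r1$vertices >= 0 & r1$vertices <= 1))
  seg <- diff(r1$vertices)
  expect_true(all(abs(seg[, 1]) < 1e-12 | abs(seg[, 2]) < 1e-12))
  turns <- r1$vertices[-c(1, nrow(r1$vertices)), , drop = FALSE]
  for (i in seq_len(nrow(turns)))
    expect_lt(min(sqrt(rowSums(sweep(r1$icons, 2, turns[i, ])^2))), 1e-9)
  expect_equal(nrow(r1$icons), p$n_icons)

  p2 <- sim_params(n_dyads = 1, n_icons = 2)
  r <- generate_reference_path(p2)
  expect_equal(nrow(r$vertices), 2L)
})

test_that("cursor follows the path exactly at zero skill noise and degrades after disruption", {
  p <- small_params(n_dyads = 1)
  ref <- generate_reference_path(p)
  tr0 <- simulate_cursor(ref, 0, 180, 0, duration = 360, fs = 10, rng_seed = 1)
  expect_equal(nrow(tr0), 3600)
  pe <- path_error(tr0, ref, split_time = 180)
  expect_lt(pe$pre$sum_error + pe$post$sum_error, 1e-9)

  deltas <- vapply(1:25, function(s) {
    tr <- simulate_cursor(ref, 0.01, 180, 0.05, duration = 360, fs = 10, rng_seed = s)
    pe <- path_error(tr, ref, split_time = 180)
    pe$post$mean_error - pe$pre$mean_error
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.9)
})

test_that("speech generator hits its stationary rates and ratio shift", {
  ratios <- vapply(1:30, function(s) {
    sp <- simulate_speech(600, 10, 0.4, 0.4, post_ratio_shift = 1,
                          disruption_time = 300, rng_seed = s)
    cf <- comm_features(sp$guide, sp$drawer, split_time = 300)
    cf$speech_ratio[1]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)

  shifts <- vapply(1:40, function(s) {
    sp <- simulate_speech(1200, 10, 0.5, 0.2, post_ratio_shift = 1.5,
                          disruption_time = 600, rng_seed = 100 + s)
    cf <- comm_features(sp$guide, sp$drawer, split_time = 600)
    cf$speech_ratio[2] / cf$speech_ratio[1]
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 1.5), 0.2)

  sp0 <- simulate_speech(60, 10, 0.5, 0, disruption_time = 30, rng_seed = 1)
  cf0 <- comm_features(sp0$guide, sp0$drawer, split_time = 30)
  expect_false(any(cf0$valid))
  expect_true(all(is.na(cf0$speech_ratio)))
})

test_that("artifact injection is reproducible, bounded and detectable", {
  x <- sin(2 * pi * 0.03 * (0:4999) / 7.81)
  r0 <- inject_artifacts(x, 7.81, 0, 0, rng_seed = 1)
  expect_identical(r0$signal, x)
  expect_equal(nrow(r0$log), 0L)

  r1 <- inject_artifacts(x, 7.81, 2, 1, rng_seed = 5)
  r2 <- inject_artifacts(x, 7.81, 2, 1, rng_seed = 5)
  expect_identical(r1, r2)
  expect_gt(nrow(r1$log), 0L)
  expect_true(all(r1$log$onset >= 0 & r1$log$onset <= length(x) / 7.81))

  ## a single spike 10x the background scale is flagged by the detector
  set.seed(8)
  bg <- bandlimited_noise(5000, 7.81, c(0.01, 0.08)) * 0.01
  spike <- inject_artifacts(bg, 7.81, spike_rate = 0, shift_rate = 0, rng_seed = 1)
  sp <- bg
  t <- (seq_along(bg) - 1) / 7.81
  sel <- t >= 300 & t <= 301
  sp[sel] <- sp[sel] + 10 * sd(bg)
  mask <- detect_motion_artifacts(make_od(sp), preprocess_params())
  expect_true(any(mask[1, sel]))
})

test_that("bad channels carry no cardiac component", {
  p <- small_params(n_dyads = 1, rng_seed = 77, bad_channel_prob = 0.5)
  d <- generate_dyad(p, 1)
  bad <- d$truth$bad_channels$guide
  expect_gt(length(bad), 0)
  raw <- d$recording$guide
  od <- intensity_to_od(raw)
  for (ch in bad) {
    w <- welch_psd(od$od[ch, 2, ], 7.81)
    inb <- w$freq >= 0.8 & w$freq <= 1.2
    expect_lt(max(w$psd[inb]) / stats::median(w$psd[w$freq > 0.4 & w$freq < 2 & !inb]), 2)
  }
})
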