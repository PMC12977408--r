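test_that("optical density conversion matches the closed form", {
  n <- 500
  I <- array(1, c(1, 2, n))
  raw <- raw_intensity(I, fs = 7.81, roi_map = c(`1` = "roi1"))
  od <- intensity_to_od(raw)
  expect_true(all(od$od == 0))

  set.seed(1)
  I2 <- array(exp(stats::rnorm(2 * n, sd = 0.2)), c(1, 2, n))
  raw2 <- raw_intensity(I2, fs = 7.81, roi_map = c(`1` = "roi1"))
  od2 <- intensity_to_od(raw2)
  for (w in 1:2) {
    x <- I2[1, w, ]
    expect_lt(max(abs(od2$od[1, w, ] - (-log(x / mean(x))))), 1e-12)
  }

  I3 <- I2
  I3[1, 1, 10] <- mean(I2[1, 1, -10]) * exp(-1) # forces OD approx 1 at sample 10
  raw3 <- raw_intensity(I3, fs = 7.81, roi_map = c(`1` = "roi1"))
  od3 <- intensity_to_od(raw3)
  expect_equal(od3$od[1, 1, 10], -log(I3[1, 1, 10] / mean(I3[1, 1, ])))

  I2[1, 1, 5] <- -1
  expect_error(intensity_to_od(raw_intensity(I2, 7.81, c(`1` = "roi1"))),
               "channel")
})

test_that("motion detection flags steps, spares clean signals, survives zeros", {
  set.seed(3)
  fs <- 7.81
  clean <- bandlimited_noise(4000, fs, c(0.01, 0.08)) * 0.01 +
    0.009 * sin(2 * pi * 1 * (0:3999) / fs)
  expect_false(any(detect_motion_artifacts(make_od(clean))))

  stepped <- clean
  stepped[2000:4000] <- stepped[2000:4000] + 10 * preprocess_params()$amp_thresh
  mask <- detect_motion_artifacts(make_od(stepped))
  k <- round(2 * fs)
  expect_true(all(mask[1, (2000 - k + 2):(2000 + k - 2)]))

  expect_false(any(detect_motion_artifacts(make_od(rep(0, 1000)))))
})

test_that("spline correction reduces baseline steps and is identity off-mask", {
  set.seed(4)
  fs <- 7.81
  x <- bandlimited_noise(4000, fs, c(0.01, 0.08)) * 0.01
  od <- make_od(x)
  empty <- matrix(FALSE, 1, 4000)
  expect_identical(correct_spline(od, empty)$od, od$od)

  step <- x
  step[1950:2050] <- step[1950:2050] + 0.5
  step[2051:4000] <- step[2051:4000] + 0.5
  mask <- matrix(FALSE, 1, 4000)
  mask[1, 1935:2065] <- TRUE
  fixed <- correct_spline(make_od(step), mask)$od[1, 1, ]
  jump_before <- abs(mean(step[2100:2400]) - mean(step[1600:1900]))
  jump_after <- abs(mean(fixed[2100:2400]) - mean(fixed[1600:1900]))
  expect_lt(jump_after, 0.2 * jump_before)

  ## degenerate smoothing parameter: segment linearly detrended, no error
  fixed0 <- correct_spline(make_od(step), mask, spline_p = 0)$od[1, 1, ]
  expect_true(all(is.finite(fixed0)))

  short_mask <- matrix(FALSE, 1, 4000)
  short_mask[1, 100:101] <- TRUE
  expect_warning(correct_spline(make_od(step), short_mask), "shorter")
})

test_that("wavelet correction: identity at infinite fence, spike suppression, low distortion", {
  set.seed(5)
  fs <- 7.81
  x <- bandlimited_noise(4000, fs, c(0.01, 0.08))
  expect_equal(correct_wavelet(make_od(x), Inf)$od[1, 1, ], x)

  const <- rep(2, 1024)
  expect_equal(correct_wavelet(make_od(const), 1.5)$od[1, 1, ], const,
               tolerance = 1e-10)

  spiked <- x
  spiked[2000:2004] <- spiked[2000:2004] + 20 * sd(x)
  cleaned <- correct_wavelet(make_od(spiked), 1.5)$od[1, 1, ]
  expect_gte(20 * sd(x) / max(abs(cleaned - x)), 5)

  rel <- sqrt(mean((correct_wavelet(make_od(x), 1.5)$od[1, 1, ] - x)^2)) / sd(x)
  expect_lt(rel, 0.05)
})

test_that("PCA filtering removes the requested leading variance", {
  set.seed(6)
  n <- 2000
  common <- stats::rnorm(n)
  X <- matrix(stats::rnorm(8 * n, sd = 0.05), 8, n) +
    outer(stats::runif(8, 0.8, 1.2), common)
  od <- make_od(X)
  filt <- remove_systemic_pca(od, 0.8, "remove")
  Y <- filt$od[, 1, ]
  cors <- stats::cor(t(Y))
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.2)

  kept <- remove_systemic_pca(od, 0.8, "keep")$od[, 1, ]
  expect_gt(abs(stats::cor(kept[1, ], common)), 0.95)

  ## removed variance tracks the requested fraction on white channels
  set.seed(7)
  W <- matrix(stats::rnorm(16 * 4000), 16, 4000)
  odw <- make_od(W)
  frac <- 0.5
  out <- remove_systemic_pca(odw, frac, "remove")$od[, 1, ]
  removed <- 1 - sum(apply(out, 1, var)) / sum(apply(W, 1, var))
  expect_lt(abs(removed - frac), 0.05)

  expect_warning(remove_systemic_pca(make_od(stats::rnorm(100)), 0.8), "single")
})

test_that("Beer-Lambert conversion matches an independent linear solve and is linear", {
  p <- preprocess_params()
  n <- 200
  od0 <- make_od(matrix(0, 1, n))
  conc0 <- od_to_concentration(od0, p)
  expect_true(all(conc0$conc == 0))

  pI <- preprocess_params(extinction = diag(2), ppf = c(1, 1))
  odI <- make_od(matrix(stats::runif(n), 1, n))
  odI$od[1, 2, ] <- odI$od[1, 1, ] / 2
  concI <- od_to_concentration(odI, pI, source_detector_distance = 1)
  expect_equal(concI$conc[1, 1, ] / 1000, odI$od[1, 1, ], tolerance = 1e-12)
  expect_equal(concI$conc[1, 2, ] / 1000, odI$od[1, 2, ], tolerance = 1e-12)

  set.seed(8)
  od <- make_od(matrix(stats::rnorm(n, sd = 0.05), 1, n))
  od$od[1, 2, ] <- stats::rnorm(n, sd = 0.05)
  conc <- od_to_concentration(od, p)
  E <- p$extinction * 3 * p$ppf
  for (i in sample(n, 20)) {
    ref <- solve(E, od$od[1, , i]) * 1000
    expect_lt(max(abs(conc$conc[1, , i] - ref)), 1e-10)
  }

  od2 <- od; od2$od <- od$od * 3.7
  conc2 <- od_to_concentration(od2, p)
  expect_equal(conc2$conc, conc$conc * 3.7, tolerance = 1e-12)

  expect_error(preprocess_params(extinction = matrix(1, 2, 2)), "singular")
})

test_that("channel quality requires a cardiac peak", {
  fs <- 7.81
  n <- round(fs * 300)
  t <- (seq_len(n) - 1) / fs
  good <- sin(2 * pi * 1 * t) + stats::rnorm(n, sd = 0.3)
  conc <- structure(list(conc = array(0, c(1, 2, n),
                                      dimnames = list(NULL, c("o2hb", "hhb"), NULL)),
                         fs = fs, roi_map = c(`1` = "r")), class = "conc_series")
  conc$conc[1, 1, ] <- good
  q <- assess_channel_quality(conc)
  expect_equal(q$verdict, "good")
  expect_lt(abs(q$peak_freq - 1), 0.05)

  verdicts <- vapply(1:50, function(s) {
    set.seed(s)
    conc$conc[1, 1, ] <- stats::rnorm(n)
    assess_channel_quality(conc)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "bad"), 0.95)

  conc_low <- conc; conc_low$fs <- 2
  expect_error(assess_channel_quality(conc_low), "sampling rate")
})

test_that("ROI averaging applies the discard and exclusion rules", {
  n <- 100
  sig <- sin(seq_len(n) / 5)
  conc <- structure(list(conc = array(0, c(4, 2, n),
                                      dimnames = list(NULL, c("o2hb", "hhb"), NULL)),
                         fs = 7.81,
                         roi_map = c(`1` = "A", `2` = "A", `3` = "B", `4` = "B"),
                         participant_id = "p", role = "guide"),
                    class = "conc_series")
  for (ch in 1:4) { conc$conc[ch, 1, ] <- sig; conc$conc[ch, 2, ] <- -sig }
  qual <- data.frame(channel = 1:4, peak_freq = 1, prominence_ratio = 10,
                     verdict = c("good", "good", "good", "good"))
  roi <- average_rois(conc, qual)
  expect_equal(roi$o2hb["A", ], sig)
  expect_equal(unname(roi$status), c("ok", "ok"))
  expect_false(roi$excluded)

  qual$verdict <- c("good", "good", "bad", "bad")
  roi2 <- average_rois(conc, qual)
  expect_equal(unname(roi2$status["B"]), "discarded")
  expect_true(all(is.na(roi2$o2hb["B", ])))
  expect_false(roi2$excluded)   # exactly one missing ROI is tolerated

  qual$verdict <- c("bad", "bad", "bad", "bad")
  roi3 <- average_rois(conc, qual)
  expect_true(roi3$excluded)
  expect_equal(roi3$n_missing, 2L)
})

test_that("full chain is deterministic and recovers in-band dynamics", {
  p <- small_params(n_dyads = 1, rng_seed = 31, bad_channel_prob = 0,
                    artifact_spike_rate = 0, artifact_shift_rate = 0)
  d <- generate_dyad(p, 1)
  r1 <- preprocess_participant(d$recording$guide)
  r2 <- preprocess_participant(d$recording$guide)
  expect_identical(r1$roi, r2$roi)

  cors <- vapply(rownames(r1$roi$o2hb), function(r) {
    stats::cor(band_filter(r1$roi$o2hb[r, ], 7.81),
               band_filter(d$truth$roi_o2hb$guide[r, ], 7.81))
  }, numeric(1))
  expect_gte(stats::median(cors), 0.9)
  expect_gte(min(cors), 0.8)
})
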