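test_that("IBS level averages valid cells only", {
  coh <- matrix(0.37, 5, 100)
  w <- make_wtc(coh, freqs = seq(0.08, 0.01, length.out = 5))
  expect_equal(ibs_level(w), 0.37)

  chk <- matrix(rep(c(0, 1), length.out = 500), 5, 100)
  w2 <- make_wtc(chk, freqs = seq(0.08, 0.01, length.out = 5))
  expect_equal(ibs_level(w2), 0.5)

  w3 <- w
  w3$valid[, 51:100] <- FALSE
  w3$coherence[, 51:100] <- 0.9
  expect_equal(ibs_level(w3), 0.37)

  expect_error(ibs_level(make_wtc(coh, seq(0.08, 0.01, length.out = 5)),
                         window = c(1e6, 2e6)), "window")
})

test_that("frequency-averaged series and slope behave as closed forms", {
  coh <- matrix(0.2, 4, 200)
  w <- make_wtc(coh, freqs = seq(0.08, 0.01, length.out = 4))
  s <- ibs_timeseries(w)
  expect_equal(s$value, rep(0.2, 200))
  expect_equal(ibs_slope(s), 0)

  ## single valid scale: the series equals that scale's row
  w2 <- w
  w2$coherence[2, ] <- seq(0, 1, length.out = 200)
  w2$valid[c(1, 3, 4), ] <- FALSE
  expect_equal(ibs_timeseries(w2)$value, w2$coherence[2, ])

  ## exact recovery of a linear ramp in coherence units per second
  fs <- 7.81
  tt <- (0:999) / fs
  s3 <- structure(list(time = tt, value = 0.2 + 1e-4 * tt,
                       valid = rep(TRUE, 1000)), class = "ibs_series")
  expect_equal(ibs_slope(s3), 1e-4, tolerance = 1e-12)

  s4 <- s3
  s4$valid[11:1000] <- FALSE
  expect_true(is.na(ibs_slope(s4, min_samples = 50)))
  expect_equal(attr(ibs_slope(s4, min_samples = 50), "flag"), "insufficient")
})

test_that("radius selection hits the target recurrence rate deterministically", {
  set.seed(21)
  x <- stats::rnorm(1500)
  r1 <- select_radius(x, rqa_params())
  r2 <- select_radius(x, rqa_params())
  expect_identical(r1, r2)
  expect_gte(r1$rr, 0.08)
  expect_lte(r1$rr, 0.12)
  expect_false(r1$degenerate)

  r10 <- select_radius(10 * x, rqa_params())
  expect_equal(r10$epsilon / r1$epsilon, 10, tolerance = 0.05)

  rc <- select_radius(rep(1, 500), rqa_params())
  expect_true(rc$degenerate)
})

test_that("recurrence counts match the exhaustive oracle exactly", {
  prm <- rqa_params(lmin = 10L)
  set.seed(22)
  for (i in 1:25) {
    n <- sample(80:300, 1)
    x <- switch(1 + i %% 3,
                stats::rnorm(n),
                sin(2 * pi * (1:n) / 37) + stats::rnorm(n, sd = 0.2),
                as.numeric(stats::arima.sim(list(ar = 0.9), n)))
    eps <- stats::quantile(abs(outer(x, x, "-")), 0.1)
    got <- recurrence(x, eps, prm)
    ref <- rqa_bruteforce(x, eps, prm$lmin, prm$theiler)
    expect_equal(got$rr, ref$rr, tolerance = 1e-12)
    expect_equal(got$pct_det, ref$pct_det, tolerance = 1e-12)
  }
})

test_that("percent determinism separates periodic, autocorrelated and white signals", {
  prm <- rqa_params()
  ## sinusoid with period >> lmin and a generous radius: recurrences sit on
  ## long diagonals
  n <- 2000
  xs <- sin(2 * pi * (1:n) / 400)
  rs <- recurrence(xs, stats::sd(xs), prm)
  expect_gte(rs$pct_det, 0.95)

  ## the three signal classes share the slow timescale of a coherence series
  ## (dynamics spanning many samples); matched recurrence rate 0.10
  dets <- t(vapply(1:30, function(s) {
    set.seed(s)
    n <- 2000
    wn <- stats::rnorm(n)
    coarse <- as.numeric(stats::arima.sim(list(ar = 0.95), ceiling(n / 25) + 1))
    ar <- stats::approx(seq_along(coarse), coarse,
                        xout = seq(1, length(coarse), length.out = n))$y
    per <- sin(2 * pi * ((1:n) + stats::runif(1, 0, 500)) / 500)
    vapply(list(per, ar, wn), function(x) {
      recurrence(x, select_radius(x, prm)$epsilon, prm)$pct_det
    }, numeric(1))
  }, numeric(3)))
  expect_gte(mean(dets[, 1] - dets[, 2]), 0.1)   # periodic > slow AR(1)
  expect_gte(mean(dets[, 2] - dets[, 3]), 0.1)   # slow AR(1) > white noise
  expect_lt(mean(dets[, 3]), 0.2)

  ## shuffling destroys determinism
  set.seed(23)
  x <- sin(2 * pi * (1:600) / 100) + stats::rnorm(600, sd = 0.1)
  eps <- select_radius(x, prm)$epsilon
  d0 <- recurrence(x, eps, prm)$pct_det
  worse <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    recurrence(sample(x), eps, prm)$pct_det <= d0
  }, logical(1))
  expect_gte(mean(worse), 0.95)

  short <- recurrence(stats::rnorm(20), 0.5, prm)
  expect_true(is.na(short$pct_det))
  expect_equal(short$flag, "too_short")
})

test_that("permuted pairings are complete, non-real, and counted n(n-1)", {
  cohort <- data.frame(dyad_id = sprintf("d%d", 1:2),
                       guide_id = sprintf("g%d", 1:2),
                       drawer_id = sprintf("w%d", 1:2))
  p2 <- build_permuted_dyads(cohort)
  expect_equal(nrow(p2), 2L)

  cohort49 <- data.frame(dyad_id = sprintf("d%d", 1:49),
                         guide_id = sprintf("g%d", 1:49),
                         drawer_id = sprintf("w%d", 1:49))
  p49 <- build_permuted_dyads(cohort49)
  expect_equal(nrow(p49), 49 * 48)
  expect_false(any(paste(p49$guide_id, p49$drawer_id) %in%
                     paste(cohort49$guide_id, cohort49$drawer_id)))
  expect_equal(anyDuplicated(paste(p49$guide_id, p49$drawer_id)), 0L)

  expect_error(build_permuted_dyads(cohort[1, ]), "2 real dyads")
})

test_that("feature table has one row per dyad-ROI-period and drops missing ROIs", {
  p <- small_params(n_dyads = 2, rng_seed = 51, bad_channel_prob = 0,
                    artifact_spike_rate = 0, artifact_shift_rate = 0)
  st <- simulate_study(p)
  prep <- lapply(st$dyads, function(d) {
    pg <- preprocess_participant(d$recording$guide)
    pd <- preprocess_participant(d$recording$drawer)
    list(dyad_id = d$recording$dyad_id, group = d$recording$group,
         guide = pg$roi, drawer = pd$roi, markers = d$recording$markers)
  })
  ft <- feature_table(prep, features = c("level", "slope"))
  expect_equal(nrow(ft), 2 * 6 * 2)
  expect_setequal(unique(ft$period), c("pre", "post"))
  expect_true(all(ft$level >= 0 & ft$level <= 1))
  expect_true(all(is.finite(ft$slope)))

  ## discarding one ROI drops both periods for it (10 rows instead of 12)
  prep1 <- prep[1]
  prep1[[1]]$guide$status["TPJ_R"] <- "discarded"
  ft1 <- feature_table(prep1, features = "level")
  expect_equal(nrow(ft1), 10L)
  expect_false("TPJ_R" %in% ft1$roi)
})
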