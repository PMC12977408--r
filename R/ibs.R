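## IBS features: level, slope and percent determinism, plus the permuted-dyad
## null pairings and the long-format feature table fed to the statistics.

#' Mean coherence level over valid cells
#'
#' @param w masked `wtc_result` (run [mask_and_band()] first).
#' @param window optional c(t0, t1) restricting the time axis (seconds).
#' @return scalar in [0, 1].
#' @export
ibs_level <- function(w, window = NULL) {
  if (is.null(w$valid)) usage_error("mask_and_band() must be applied first")
  sel <- w$valid
  if (!is.null(window))
    sel <- sel & matrix(w$time >= window[1] & w$time < window[2],
                        nrow(sel), ncol(sel), byrow = TRUE)
  if (!any(sel)) data_error("no valid coherence cell in the requested window")
  mean(w$coherence[sel])
}

#' Frequency-averaged IBS time series
#'
#' One value per time sample: the mean coherence over valid scales; samples
#' with no valid scale are flagged invalid.
#'
#' @param w masked `wtc_result`.
#' @return object of class `ibs_series`: list(time, value, valid).
#' @export
ibs_timeseries <- function(w) {
  if (is.null(w$valid)) usage_error("mask_and_band() must be applied first")
  C <- w$coherence
  C[!w$valid] <- NA_real_
  v <- colMeans(C, na.rm = TRUE)
  ok <- colSums(w$valid) > 0L
  v[!ok] <- NA_real_
  structure(list(time = w$time, value = v, valid = ok), class = "ibs_series")
}

#' Slope of an IBS time series
#'
#' Ordinary-least-squares slope of coherence against time over the valid
#' samples of a window, reported in coherence units per second.
#'
#' @param s `ibs_series`. @param window optional c(t0, t1) seconds.
#' @param min_samples minimum valid samples required (default 10); fewer
#'   yields NA with attribute `flag = "insufficient"`.
#' @return numeric slope (possibly NA).
#' @export
ibs_slope <- function(s, window = NULL, min_samples = 10L) {
  sel <- s$valid & is.finite(s$value)
  if (!is.null(window)) sel <- sel & s$time >= window[1] & s$time < window[2]
  if (sum(sel) < min_samples)
    return(structure(NA_real_, flag = "insufficient"))
  tt <- s$time[sel]; vv <- s$value[sel]
  sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
}

#' Recurrence analysis parameters
#'
#' Defaults follow the study settings: embedding dimension m = 1 to capture
#' the slow dynamics, radius selected per signal for a target recurrence rate
#' of 0.10, minimum diagonal line length 40 samples at the native coherence
#' time axis (about 5.1 s at 7.81 Hz), Theiler window 1.
#'
#' @param m embedding dimension (only m = 1 is implemented; the coherence
#'   series is analyzed in its scalar state space).
#' @param target_rr target recurrence rate for radius selection.
#' @param lmin minimum diagonal line length (samples).
#' @param theiler Theiler window (samples around the main diagonal excluded).
#' @return object of class `rqa_params`.
#' @export
rqa_params <- function(m = 1L, target_rr = 0.10, lmin = 40L, theiler = 1L) {
  if (m != 1L) usage_error("only embedding dimension m = 1 is supported")
  if (target_rr <= 0 || target_rr >= 1) param_error("target_rr must lie in (0, 1)")
  if (lmin < 2L) param_error("lmin must be >= 2")
  structure(list(m = 1L, target_rr = target_rr, lmin = as.integer(lmin),
                 theiler = as.integer(theiler)), class = "rqa_params")
}

## Exact recurrence rate for radius eps (m = 1), excluding the Theiler band,
## via sorted-neighbour counting: O(N log N).
recurrence_rate <- function(x, eps, theiler = 1L) {
  n <- length(x)
  xs <- sort(x)
  lo <- findInterval(x - eps, xs, left.open = TRUE)   # count < x - eps
  hi <- findInterval(x + eps, xs)                     # count <= x + eps
  total <- sum(hi - lo) - n                           # off-diagonal recurrences
  near <- 0L
  if (theiler >= 1L) for (d in seq_len(theiler)) {
    i <- seq_len(n - d)
    near <- near + 2L * sum(abs(x[i] - x[i + d]) <= eps)
  }
  denom <- n^2 - n - 2 * sum(n - seq_len(theiler))
  if (denom <= 0) return(NA_real_)
  (total - near) / denom
}

#' Select the recurrence radius for a target recurrence rate
#'
#' Bisection over the radius so the achieved recurrence rate matches
#' `target_rr`. The achieved rate is computed exactly (m = 1) and the search
#' is deterministic.
#'
#' @param x numeric series (an IBS coherence series; NAs dropped).
#' @param params `rqa_params`.
#' @param tol bisection tolerance on the recurrence rate.
#' @return list(epsilon, rr, degenerate); `degenerate = TRUE` for constant
#'   series, where any positive radius makes every pair recurrent.
#' @export
select_radius <- function(x, params = rqa_params(), tol = 0.005) {
  x <- x[is.finite(x)]
  rng <- diff(range(x))
  if (rng == 0)
    return(list(epsilon = NA_real_, rr = 1, degenerate = TRUE))
  lo <- 0; hi <- rng
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    rr <- recurrence_rate(x, mid, params$theiler)
    if (!is.finite(rr)) break
    if (abs(rr - params$target_rr) <= tol) break
    if (rr > params$target_rr) hi <- mid else lo <- mid
  }
  list(epsilon = mid, rr = rr, degenerate = FALSE)
}

#' Recurrence quantification (recurrence rate and percent determinism)
#'
#' With embedding dimension 1, points i, j recur when |x_i - x_j| <= eps.
#' Pairs with |i - j| <= `theiler` are excluded from all counts. Percent
#' determinism is the fraction of recurrent points lying on diagonal lines of
#' length >= `lmin` (maximal runs parallel to the main diagonal). The
#' recurrence plot is traversed diagonal by diagonal, so no N x N matrix is
#' materialized.
#'
#' @param x numeric series (NAs dropped).
#' @param eps recurrence radius (from [select_radius()]).
#' @param params `rqa_params`.
#' @return object of class `recurrence_result`: list(rr, pct_det,
#'   line_hist (table of diagonal line lengths), epsilon, n).
#' @export
recurrence <- function(x, eps, params = rqa_params()) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < params$lmin)
    return(structure(list(rr = NA_real_, pct_det = NA_real_, line_hist = NULL,
                          epsilon = eps, n = n, flag = "too_short"),
                     class = "recurrence_result"))
  rec_pts <- 0; det_pts <- 0
  lens <- integer(0)
  for (k in seq.int(params$theiler + 1L, n - 1L)) {
    i <- seq_len(n - k)
    hit <- abs(x[i] - x[i + k]) <= eps
    s <- sum(hit)
    if (s == 0L) next
    rec_pts <- rec_pts + 2 * s
    r <- rle(hit)
    runs <- r$lengths[r$values]
    det_pts <- det_pts + 2 * sum(runs[runs >= params$lmin])
    lens <- c(lens, runs)
  }
  denom <- n^2 - n - 2 * sum(n - seq_len(params$theiler))
  rr <- rec_pts / denom
  pct_det <- if (rec_pts > 0) det_pts / rec_pts else NA_real_
  structure(list(rr = rr, pct_det = pct_det,
                 line_hist = if (length(lens)) table(lens) else NULL,
                 epsilon = eps, n = n, flag = NULL),
            class = "recurrence_result")
}

#' Permuted-dyad null pairings
#'
#' All pairings of Guides and Drawers who did not interact: n (n - 1)
#' permuted pairs for n real dyads, none equal to a real pairing.
#'
#' @param cohort data.frame with columns dyad_id, guide_id, drawer_id.
#' @return data.frame (kind = "permuted", guide_id, drawer_id, guide_dyad,
#'   drawer_dyad).
#' @export
build_permuted_dyads <- function(cohort) {
  n <- nrow(cohort)
  if (is.null(n) || n < 2L) data_error("at least 2 real dyads are required")
  g <- expand.grid(gi = seq_len(n), di = seq_len(n))
  g <- g[g$gi != g$di, , drop = FALSE]
  out <- data.frame(kind = "permuted",
                    guide_id = cohort$guide_id[g$gi],
                    drawer_id = cohort$drawer_id[g$di],
                    guide_dyad = cohort$dyad_id[g$gi],
                    drawer_dyad = cohort$dyad_id[g$di],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## ---- batch coherence-level engine -----------------------------------------
## Computes band-averaged coherence levels for many (guide, drawer) pairs,
## caching each participant's CWT and smoothed auto-spectrum so permuted
## cohorts cost one cross-smoothing per pair. Participants are evicted from
## the cache after their last appearance in `pairs`.

#' Band-averaged IBS levels for many participant pairs
#'
#' @param series named list: per participant, an ROI x time matrix of O2Hb
#'   concentration.
#' @param pairs data.frame with columns guide_id, drawer_id (participant
#'   names in `series`) and any id columns to carry through.
#' @param fs sampling rate (Hz).
#' @param band analysis band (Hz).
#' @param window task time window c(t0, t1) seconds.
#' @param periods optional named list of sub-windows (e.g. list(pre = c(a,b),
#'   post = c(b,c))); default one "all" period covering `window`.
#' @param time_smooth,scale_smooth smoothing spans, as in
#'   [wavelet_coherence()].
#' @param decimate low-pass and downsample the series before the transform
#'   (default TRUE). The band tops out far below the optical Nyquist rate, so
#'   decimation leaves band-restricted coherence unchanged while cutting the
#'   cost roughly by the decimation factor.
#' @return long data.frame: pair columns + roi, period, level.
#' @export
batch_ibs_levels <- function(series, pairs, fs, band = c(0.01, 0.08),
                             window, periods = NULL,
                             time_smooth = 2.5, scale_smooth = 0.6,
                             decimate = TRUE) {
  if (is.null(periods)) periods <- list(all = window)
  dj <- 1 / 12
  ext <- 3 * dj
  f_hi <- band[2] * 2^ext
  f_lo <- band[1] * 2^(-ext)
  if (decimate) {
    fac <- max(1L, floor(fs / (5 * f_hi)))
    if (fac > 1L) {
      series <- lapply(series, function(M) {
        out <- t(apply(M, 1L, decimate_lowpass, fs = fs, fac = fac))
        rownames(out) <- rownames(M)
        out
      })
      fs <- fs / fac
    }
  }
  freqs <- f_hi * 2^(-seq(0, log2(f_hi / f_lo), by = dj))
  scales_samp <- 1 / (fourier_factor() * freqs) * fs
  n <- ncol(series[[1]])
  pad_len <- next_fft_len(n + ceiling(2 * time_smooth * max(scales_samp)))
  width <- max(3L, round(scale_smooth / dj))
  inv_s <- matrix(1 / scales_samp, n, length(freqs), byrow = TRUE)
  plan <- make_smooth_plan(n, pad_len, time_smooth * scales_samp)

  time <- (seq_len(n) - 1L) / fs
  edge <- pmax(pmin(time, max(time) - time), 1e-9)
  coi <- sqrt(2) / edge
  inband <- freqs >= band[1] & freqs <= band[2]
  base_valid <- outer(freqs, coi, `>=`) & inband       # scale x time

  cache <- new.env(parent = emptyenv())
  last_use <- list()
  for (i in seq_len(nrow(pairs))) {
    last_use[[pairs$guide_id[i]]] <- i
    last_use[[pairs$drawer_id[i]]] <- i
  }
  get_part <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    M <- series[[id]]
    if (is.null(M)) data_error(sprintf("no series for participant %s", id))
    ent <- lapply(seq_len(nrow(M)), function(r) {
      W <- morlet_cwt(M[r, ], fs, freqs, pad_len)
      P <- Re(smooth_time_gauss(Mod(W)^2 * inv_s, plan))
      P <- t(row_boxcar(t(P), width))
      list(W = W, P = P)
    })
    names(ent) <- rownames(M)
    cache[[id]] <- ent
    ent
  }
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pg <- get_part(pairs$guide_id[i])
    pd <- get_part(pairs$drawer_id[i])
    rows <- list()
    for (r in intersect(names(pg), names(pd))) {
      X <- smooth_time_gauss(pg[[r]]$W * Conj(pd[[r]]$W) * inv_s, plan)
      X <- t(row_boxcar(t(Re(X)), width)) + 1i * t(row_boxcar(t(Im(X)), width))
      R2 <- t(Mod(X)^2 / (pg[[r]]$P * pd[[r]]$P))      # scale x time
      R2[!is.finite(R2)] <- 0
      R2 <- pmin(pmax(R2, 0), 1)
      for (pn in names(periods)) {
        pw <- periods[[pn]]
        sel <- base_valid &
          matrix(time >= pw[1] & time < pw[2], length(freqs), n, byrow = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          pairs[i, , drop = FALSE], roi = r, period = pn,
          level = mean(R2[sel]), row.names = NULL)
      }
    }
    out[[i]] <- do.call(rbind, rows)
    for (id in c(pairs$guide_id[i], pairs$drawer_id[i]))
      if (last_use[[id]] <= i) rm(list = id, envir = cache)
  }
  do.call(rbind, out)
}

#' Long-format IBS feature table for a preprocessed study
#'
#' One row per (dyad, ROI, chromophore, period) with the three IBS features:
#' mean coherence level, slope of the frequency-averaged coherence series,
#' and percent determinism. ROIs discarded for either participant produce
#' absent rows, not zeros. Periods split the task at the disruption marker.
#'
#' @param prep list of per-dyad entries: list(dyad_id, group, guide
#'   (`roi_timeseries`), drawer (`roi_timeseries`), markers).
#' @param band analysis band (Hz).
#' @param chromophore `"o2hb"` (primary) or `"hhb"`.
#' @param features subset of c("level", "slope", "pct_det").
#' @param rqa `rqa_params`.
#' @return data.frame: dyad_id, group, roi, chromophore, period, level,
#'   slope, pct_det, rr, epsilon.
#' @export
feature_table <- function(prep, band = c(0.01, 0.08), chromophore = "o2hb",
                          features = c("level", "slope", "pct_det"),
                          rqa = rqa_params()) {
  slot <- match.arg(chromophore, c("o2hb", "hhb"))
  rows <- list()
  for (d in prep) {
    mk <- d$markers
    window <- c(mk$task_start, mk$task_end)
    periods <- list(pre = c(mk$task_start, mk$disruption),
                    post = c(mk$disruption, mk$task_end))
    fs <- d$guide$fs
    ok <- names(which(d$guide$status == "ok"))
    ok <- intersect(ok, names(which(d$drawer$status == "ok")))
    for (r in ok) {
      w <- wavelet_coherence(d$guide[[slot]][r, ], d$drawer[[slot]][r, ], fs,
                             freq_range = band,
                             pair = list(dyad = d$dyad_id, roi = r))
      w <- mask_and_band(w, band, window)
      s <- if (any(c("slope", "pct_det") %in% features)) ibs_timeseries(w)
      for (pn in names(periods)) {
        pw <- periods[[pn]]
        row <- data.frame(dyad_id = d$dyad_id, group = d$group, roi = r,
                          chromophore = slot, period = pn,
                          level = NA_real_, slope = NA_real_,
                          pct_det = NA_real_, rr = NA_real_,
                          epsilon = NA_real_, stringsAsFactors = FALSE)
        if ("level" %in% features) row$level <- ibs_level(w, pw)
        if ("slope" %in% features) row$slope <- as.numeric(ibs_slope(s, pw))
        if ("pct_det" %in% features) {
          xs <- s$value[s$valid & s$time >= pw[1] & s$time < pw[2]]
          xs <- xs[is.finite(xs)]
          if (length(xs) >= max(100L, rqa$lmin)) {
            rad <- select_radius(xs, rqa)
            if (!rad$degenerate) {
              rq <- recurrence(xs, rad$epsilon, rqa)
              row$pct_det <- rq$pct_det
              row$rr <- rq$rr
              row$epsilon <- rad$epsilon
            }
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
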