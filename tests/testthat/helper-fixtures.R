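## Shared fixtures: small, fast study configurations and independent oracles.

## Compact study parameters: 2-min rests, 6-min task, disruption at 3 min.
small_params <- function(n_dyads = 4L, rng_seed = 42L, ...) {
  sim_params(n_dyads = n_dyads, rest_duration = 120, task_duration = 360,
             disruption_offset = 180, rng_seed = rng_seed, ...)
}

## Wrap a plain matrix as a minimal od_series for unit tests.
make_od <- function(x, fs = 7.81) {
  if (is.null(dim(x))) x <- rbind(x)
  arr <- array(0, c(nrow(x), 2L, ncol(x)))
  arr[, 1L, ] <- x
  arr[, 2L, ] <- x
  structure(list(od = arr, fs = fs,
                 roi_map = stats::setNames(rep("roi1", nrow(x)), seq_len(nrow(x))),
                 wavelengths = c(760, 850), participant_id = "p", role = "guide"),
            class = "od_series")
}

## Minimal wtc_result with a fully valid mask (for feature unit tests).
make_wtc <- function(coh, freqs, fs = 1, t0 = 0) {
  n <- ncol(coh)
  structure(list(coherence = coh, freqs = freqs,
                 coi = rep(0, n), fs = fs, time = t0 + (seq_len(n) - 1L) / fs,
                 valid = matrix(TRUE, nrow(coh), n), pair = NULL),
            class = "wtc_result")
}

## Band-pass filter used to compare recovered and true signals in-band.
band_filter <- function(x, fs, band = c(0.01, 0.08)) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

## Exhaustive O(N^2) recurrence oracle, written independently of the
## diagonal-traversal implementation: build the full recurrence matrix and
## scan every diagonal with an explicit run loop.
rqa_bruteforce <- function(x, eps, lmin, theiler) {
  n <- length(x)
  R <- abs(outer(x, x, "-")) <= eps
  keep <- abs(outer(seq_len(n), seq_len(n), "-")) > theiler
  rec <- sum(R & keep)
  det_pts <- 0
  for (off in seq.int(-(n - 1L), n - 1L)) {
    if (abs(off) <= theiler) next
    ii <- if (off >= 0) seq_len(n - off) else seq.int(1 - off, n)
    jj <- ii + off
    run <- 0L
    for (m in seq_along(ii)) {
      if (R[ii[m], jj[m]]) run <- run + 1L
      if (!R[ii[m], jj[m]] || m == length(ii)) {
        if (run >= lmin) det_pts <- det_pts + run
        run <- 0L
      }
    }
  }
  denom <- sum(keep)
  list(rr = rec / denom, pct_det = if (rec > 0) det_pts / rec else NA_real_)
}

## Coupled band-limited pair with squared coherence kappa^4 (plus estimator
## bias), at the study band.
coupled_pair <- function(n, fs, kappa, seed, band = c(0.01, 0.08)) {
  set.seed(seed)
  s <- bandlimited_noise(n, fs, band)
  list(x = kappa * s + sqrt(1 - kappa^2) * bandlimited_noise(n, fs, band),
       y = kappa * s + sqrt(1 - kappa^2) * bandlimited_noise(n, fs, band))
}
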