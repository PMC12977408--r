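## Wavelet transform coherence between two ROI series.
##
## Analytic Morlet wavelet (omega0 = 6), 12 voices per octave; cross- and
## auto-spectra are smoothed in time with a Gaussian matched to each scale and
## across scale with a boxcar spanning 0.6 octaves, following the standard
## wavelet-coherence recipe. The cone of influence uses the convention
## tau(f) = sqrt(2) / f for the one-sided edge-effect duration.

MORLET_OMEGA0 <- 6
fourier_factor <- function(omega0 = MORLET_OMEGA0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

## Analytic Morlet CWT. Returns time x scale complex matrix (padded rows
## dropped). freqs must be in decreasing order.
morlet_cwt <- function(x, fs, freqs, pad_len = NULL, omega0 = MORLET_OMEGA0) {
  n <- length(x)
  dt <- 1 / fs
  scales <- 1 / (fourier_factor(omega0) * freqs)      # seconds
  if (is.null(pad_len))
    pad_len <- next_fft_len(n + ceiling(2 * max(scales) * fs))
  xp <- c(x - mean(x), numeric(pad_len - n))
  Fx <- stats::fft(xp)
  omega <- 2 * pi * fs * c(seq(0, floor(pad_len / 2)),
                           seq(-ceiling(pad_len / 2) + 1, -1)) / pad_len
  pos <- omega > 0
  H <- matrix(0, pad_len, length(scales))
  for (j in seq_along(scales)) {
    psi <- numeric(pad_len)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * scales[j] / dt) *
      exp(-(scales[j] * omega[pos] - omega0)^2 / 2)
    H[, j] <- Fx * psi
  }
  W <- stats::mvfft(H, inverse = TRUE) / pad_len
  W[seq_len(n), , drop = FALSE]
}

## Precompute the scale-matched Gaussian smoothing kernel (frequency domain)
## and the boundary renormalization weights shared by all smoothing calls on
## series of the same length/grid.
make_smooth_plan <- function(n, pad_len, scales_samp) {
  omega <- 2 * pi * c(seq(0, floor(pad_len / 2)),
                      seq(-ceiling(pad_len / 2) + 1, -1)) / pad_len
  K <- exp(-0.5 * outer(omega^2, scales_samp^2))      # unit-mass Gaussian FT
  ones <- matrix(0, pad_len, length(scales_samp))
  ones[seq_len(n), ] <- 1
  wgt <- Re(stats::mvfft(stats::mvfft(ones) * K, inverse = TRUE)) / pad_len
  list(n = n, pad_len = pad_len, K = K,
       wginv = 1 / wgt[seq_len(n), , drop = FALSE])
}

## Scale-matched Gaussian time smoothing with boundary renormalization.
## Q: time x scale (complex or numeric). Returns same dimensions.
smooth_time_gauss <- function(Q, plan) {
  Qp <- matrix(if (is.complex(Q)) 0i else 0, plan$pad_len, ncol(Q))
  Qp[seq_len(plan$n), ] <- Q
  sm <- stats::mvfft(stats::mvfft(Qp) * plan$K, inverse = TRUE) / plan$pad_len
  sm[seq_len(plan$n), , drop = FALSE] * plan$wginv
}

#' One-sided cone-of-influence edge-effect duration
#'
#' Duration tau(f) = sqrt(2) / f of the analytic Morlet edge effect at
#' frequency `f`, rounded up to whole seconds. At 0.01 Hz this is 142 s
#' (2 min 22 s), which motivates flanking a task with 3-minute rests.
#'
#' @param f frequency in Hz (vectorized, must be positive).
#' @return duration in seconds (integer-valued numeric).
#' @export
coi_duration <- function(f) {
  if (any(!is.finite(f) | f <= 0)) abort("frequency must be positive", "nirsync_domain_error")
  ceiling(sqrt(2) / f)
}

#' Wavelet transform coherence of two series
#'
#' Squared coherence |S(W_xy / s)|^2 / (S(|W_x|^2 / s) S(|W_y|^2 / s)) on a
#' 12-voices-per-octave frequency grid, where S denotes time smoothing with a
#' Gaussian matched to each scale followed by a boxcar across 0.6 octaves of
#' scale.
#'
#' @param x,y numeric series of equal length.
#' @param fs sampling rate (Hz).
#' @param freq_range c(f_lo, f_hi) Hz; the computed grid extends 3 voices
#'   beyond each edge so scale smoothing is untruncated inside the range.
#'   Default spans 4 cycles of the record up to 0.45 fs.
#' @param dj scale resolution in octaves (1/12 = 12 voices per octave).
#' @param time_smooth time-smoothing span in units of scale (Gaussian SD =
#'   `time_smooth` x scale). The default 2.5 sets the null coherence level of
#'   independent band-limited signals near 0.25, characteristic of
#'   non-interacting (permuted) pairings.
#' @param scale_smooth boxcar span of the scale smoothing, in octaves.
#' @param pair optional identifier list stored on the result.
#' @return object of class `wtc_result`: list(coherence = scale x time matrix
#'   in [0,1] with `freqs` strictly decreasing across rows, `freqs`, `coi`
#'   (per-sample minimum uncontaminated frequency, Hz), `fs`, `time`,
#'   `valid` (filled by [mask_and_band()]), `pair`).
#' @export
wavelet_coherence <- function(x, y, fs, freq_range = NULL, dj = 1 / 12,
                              time_smooth = 2.5, scale_smooth = 0.6,
                              pair = NULL) {
  if (length(x) != length(y)) data_error("x and y must have the same length")
  n <- length(x)
  if (is.null(freq_range))
    freq_range <- c(4 * fs / n, 0.45 * fs)
  if (freq_range[1] <= 0 || freq_range[1] >= freq_range[2])
    config_error("freq_range must be an increasing positive interval")
  if (n < 2 * fs / freq_range[1])                      # two cycles at f_lo
    data_error("series too short for the requested lowest frequency")
  ext <- 3 * dj                                        # 3 voices margin
  f_hi <- freq_range[2] * 2^ext
  f_lo <- freq_range[1] * 2^(-ext)
  n_oct <- log2(f_hi / f_lo)
  freqs <- f_hi * 2^(-seq(0, n_oct, by = dj))          # decreasing
  scales <- 1 / (fourier_factor() * freqs)             # seconds
  scales_samp <- scales * fs
  pad_len <- next_fft_len(n + ceiling(2 * time_smooth * max(scales_samp)))

  Wx <- morlet_cwt(x, fs, freqs, pad_len)
  Wy <- morlet_cwt(y, fs, freqs, pad_len)
  plan <- make_smooth_plan(n, pad_len, time_smooth * scales_samp)
  inv_s <- matrix(1 / scales_samp, n, length(freqs), byrow = TRUE)
  Sx <- Re(smooth_time_gauss(Mod(Wx)^2 * inv_s, plan))
  Sy <- Re(smooth_time_gauss(Mod(Wy)^2 * inv_s, plan))
  Sxy <- smooth_time_gauss(Wx * Conj(Wy) * inv_s, plan)
  width <- max(3L, round(scale_smooth / dj))
  Sx <- t(row_boxcar(t(Sx), width))
  Sy <- t(row_boxcar(t(Sy), width))
  Sxy <- t(row_boxcar(t(Re(Sxy)), width)) + 1i * t(row_boxcar(t(Im(Sxy)), width))
  R2 <- Mod(Sxy)^2 / (Sx * Sy)
  R2[!is.finite(R2)] <- 0
  R2 <- pmin(pmax(R2, 0), 1)

  keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
  time <- (seq_len(n) - 1L) / fs
  edge <- pmax(pmin(time, max(time) - time), 1e-9)
  structure(list(coherence = t(R2)[keep, , drop = FALSE],
                 freqs = freqs[keep],
                 coi = sqrt(2) / edge,                 # min valid frequency
                 fs = fs, time = time, valid = NULL, pair = pair),
            class = "wtc_result")
}

#' Restrict a coherence matrix to the analysis band, outside the cone of
#' influence, within a time window
#'
#' Marks invalid every cell below the cone-of-influence curve or outside
#' `band`, then crops the time axis to `window` (so rest periods flanking the
#' task absorb the edge effects before cropping).
#'
#' @param w `wtc_result`. @param band c(f_lo, f_hi) Hz.
#' @param window c(t_start, t_end) seconds, or NULL for the full record.
#' @return `wtc_result` with `valid` filled and time cropped.
#' @export
mask_and_band <- function(w, band = c(0.01, 0.08), window = NULL) {
  inband <- w$freqs >= band[1] & w$freqs <= band[2]
  if (!any(inband)) config_error("band outside the computed frequency range")
  valid <- outer(w$freqs, w$coi, `>=`) & inband
  if (!is.null(window)) {
    sel <- w$time >= window[1] & w$time <= window[2]
    if (!any(sel)) data_error("empty time window")
    w$coherence <- w$coherence[, sel, drop = FALSE]
    valid <- valid[, sel, drop = FALSE]
    w$time <- w$time[sel]
    w$coi <- w$coi[sel]
  }
  if (!any(valid)) data_error("no cell survives COI and band masking")
  w$valid <- valid
  w$band <- band
  w
}
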