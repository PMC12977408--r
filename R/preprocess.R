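## Optical-density preprocessing chain: raw two-wavelength intensity ->
## quality-controlled ROI-averaged O2Hb/HHb concentration series.
##
## Order of operations is fixed: (1) intensity to optical density, (2) motion
## artifact detection + spline correction + wavelet correction, (3) PCA-based
## systemic-noise removal (on OD, per wavelength), (4) modified Beer-Lambert
## conversion, (5) cardiac-peak channel quality check, (7) ROI averaging with
## discard/exclusion rules.

#' Default channel-to-ROI map of the 16-channel montage
#'
#' Channels 1 and 6 on left/right frontopolar PFC; channels 2-5 and 7-10 on
#' left/right dorsolateral PFC; channels 11-13 and 14-16 on left/right
#' temporoparietal junction.
#'
#' @return named character vector of length 16 mapping channel index to ROI.
#' @export
default_roi_map <- function() {
  m <- c("fpPFC_L", "dlPFC_L", "dlPFC_L", "dlPFC_L", "dlPFC_L", "fpPFC_R",
         "dlPFC_R", "dlPFC_R", "dlPFC_R", "dlPFC_R",
         "TPJ_L", "TPJ_L", "TPJ_L", "TPJ_R", "TPJ_R", "TPJ_R")
  names(m) <- as.character(seq_along(m))
  m
}

#' Extinction coefficients of hemoglobin at 760 and 850 nm
#'
#' Molar extinction coefficients (1/(mM cm)) from the standard compiled in
#' vivo absorption spectra of oxy- and deoxyhemoglobin. Rows are wavelengths
#' (760, 850 nm), columns chromophores (O2Hb, HHb). Shipped as data so users
#' can substitute their own compilation.
#'
#' @return 2 x 2 numeric matrix.
#' @export
extinction_defaults <- function() {
  matrix(c(0.5860, 1.5485,
           1.0580, 0.6913),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("760", "850"), c("o2hb", "hhb")))
}

#' Preprocessing parameters
#'
#' Defaults follow the established motion-correction settings: SDThresh = 20,
#' AMPThresh = 0.5, tMotion = 0.5 s, tMask = 2 s, smoothing-spline p = 0.99,
#' wavelet outlier fence multiplier iqr = 1.5, PCA variance fraction 0.80,
#' partial pathlength factors [6, 6].
#'
#' @param sd_thresh motion detection threshold in multiples of the SD of the
#'   first-differenced optical density.
#' @param amp_thresh absolute optical-density change threshold.
#' @param t_motion sliding detection window (s).
#' @param t_mask mask extension around each detection (s).
#' @param spline_p smoothing-spline parameter in [0, 1]; 0 degenerates to
#'   linear detrending of the flagged segment.
#' @param wavelet_iqr Tukey-fence multiplier for wavelet detail-coefficient
#'   outliers (Inf disables the correction).
#' @param pca_variance_fraction cumulative variance of the leading principal
#'   components treated as systemic noise.
#' @param pca_mode `"remove"` (default; filter the leading components out) or
#'   `"keep"` (retain only them). See Details.
#' @param ppf partial pathlength factor per wavelength.
#' @param extinction 2 x 2 extinction coefficient matrix (1/(mM cm)).
#' @param cardiac_band frequency band (Hz) in which the heartbeat peak is
#'   sought.
#' @param psd_peak_prominence_ratio a channel passes quality control when its
#'   maximal in-band Welch power exceeds this multiple of the median power of
#'   the surrounding band.
#'
#' @details PCA-based systemic-noise control is described inconsistently
#' across fNIRS pipelines: a "preserve 80% of variance" phrasing can mean
#' either retaining the leading components or removing them and keeping the
#' residual. The filtering convention removes the globally shared leading
#' components, and that is the default here; `pca_mode = "keep"` implements
#' the other reading.
#'
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(sd_thresh = 20, amp_thresh = 0.5,
                              t_motion = 0.5, t_mask = 2,
                              spline_p = 0.99, wavelet_iqr = 1.5,
                              pca_variance_fraction = 0.80,
                              pca_mode = c("remove", "keep"),
                              ppf = c(6, 6),
                              extinction = extinction_defaults(),
                              cardiac_band = c(0.8, 1.2),
                              psd_peak_prominence_ratio = 2.0) {
  pca_mode <- match.arg(pca_mode)
  if (pca_variance_fraction <= 0 || pca_variance_fraction >= 1)
    config_error("pca_variance_fraction must lie strictly between 0 and 1")
  if (any(ppf <= 0)) config_error("ppf must be positive")
  if (abs(det(extinction)) < 1e-12)
    config_error("extinction coefficient matrix is singular")
  structure(list(sd_thresh = sd_thresh, amp_thresh = amp_thresh,
                 t_motion = t_motion, t_mask = t_mask, spline_p = spline_p,
                 wavelet_iqr = wavelet_iqr,
                 pca_variance_fraction = pca_variance_fraction,
                 pca_mode = pca_mode, ppf = ppf, extinction = extinction,
                 cardiac_band = cardiac_band,
                 psd_peak_prominence_ratio = psd_peak_prominence_ratio),
            class = "preprocess_params")
}

#' Construct a raw intensity recording
#'
#' @param intensity array channel x wavelength x time (positive, arbitrary
#'   units); wavelength order 760, 850 nm.
#' @param fs sampling rate (Hz).
#' @param roi_map named character vector mapping each channel to its ROI.
#' @param role `"guide"` or `"drawer"`.
#' @param participant_id identifier.
#' @param wavelengths wavelengths in nm.
#' @return object of class `raw_intensity`.
#' @export
raw_intensity <- function(intensity, fs, roi_map = default_roi_map(),
                          role = "guide", participant_id = "p1",
                          wavelengths = c(760, 850)) {
  if (length(dim(intensity)) != 3L || dim(intensity)[2] != 2L)
    data_error("intensity must be a channel x 2-wavelength x time array")
  if (dim(intensity)[1] != length(roi_map))
    data_error("roi_map must cover every channel")
  structure(list(intensity = intensity, fs = fs, wavelengths = wavelengths,
                 roi_map = roi_map, role = role, participant_id = participant_id),
            class = "raw_intensity")
}

## Forward modified Beer-Lambert: channel concentration array (uM) -> two-
## wavelength intensity with unit baseline. Inverse of the preprocessing map.
conc_to_intensity <- function(conc, fs, p = preprocess_params(), distance = 3) {
  E <- p$extinction * distance * p$ppf       # rows scaled by d * ppf_lambda
  ncha <- dim(conc)[1]; n <- dim(conc)[3]
  out <- array(0, dim = c(ncha, 2L, n))
  for (ch in seq_len(ncha)) {
    od <- E %*% (conc[ch, , ] / 1000)        # uM -> mM
    out[ch, 1L, ] <- exp(-od[1L, ])
    out[ch, 2L, ] <- exp(-od[2L, ])
  }
  out
}

#' Convert raw intensity to optical density
#'
#' OD(t) = -ln(I(t) / mean_t I), with the per-channel mean intensity over the
#' whole recording as reference.
#'
#' @param raw `raw_intensity`.
#' @return object of class `od_series`: list(od = channel x wavelength x time
#'   array, fs, roi_map).
#' @export
intensity_to_od <- function(raw) {
  I <- raw$intensity
  bad <- which(apply(I <= 0, 1L, any))
  if (length(bad) > 0)
    data_error(sprintf("non-positive intensity in channel(s) %s",
                       paste(bad, collapse = ", ")))
  od <- I
  for (ch in seq_len(dim(I)[1])) for (w in 1:2) {
    x <- I[ch, w, ]
    od[ch, w, ] <- -log(x / mean(x))
  }
  structure(list(od = od, fs = raw$fs, roi_map = raw$roi_map,
                 wavelengths = raw$wavelengths,
                 participant_id = raw$participant_id, role = raw$role),
            class = "od_series")
}

#' Detect motion artifacts per channel
#'
#' Within sliding windows of `t_motion` seconds a channel is flagged where the
#' signal excursion (max - min over the window, either wavelength) exceeds
#' `sd_thresh` times the SD of the first-differenced signal, or exceeds
#' `amp_thresh` in absolute optical density. Flags are extended by `t_mask`
#' seconds on both sides.
#'
#' @param od `od_series`. @param p `preprocess_params`.
#' @return logical matrix channel x time.
#' @export
detect_motion_artifacts <- function(od, p = preprocess_params()) {
  X <- od$od
  ncha <- dim(X)[1]; n <- dim(X)[3]
  w <- max(2L, round(p$t_motion * od$fs))
  k <- round(p$t_mask * od$fs)
  mask <- matrix(FALSE, ncha, n)
  for (ch in seq_len(ncha)) {
    flag <- logical(n)
    for (wl in 1:2) {
      x <- X[ch, wl, ]
      sref <- stats::sd(diff(x))
      hi <- x; lo <- x
      for (s in seq_len(w - 1L)) {
        xs <- c(x[-seq_len(s)], rep(x[n], s))
        hi <- pmax(hi, xs); lo <- pmin(lo, xs)
      }
      rng <- hi - lo                        # excursion over [t, t + w)
      thr <- if (sref > 0) p$sd_thresh * sref else Inf
      flag <- flag | (rng > thr) | (rng > p$amp_thresh)
    }
    mask[ch, ] <- dilate_mask(flag, k)
  }
  mask
}

#' Spline correction of flagged motion segments
#'
#' Within each flagged segment a smoothing spline (parameter `spline_p`) is
#' fitted and subtracted; the segment is re-levelled to the mean of the
#' adjacent clean signal, and the signal after the segment is shifted so no
#' artificial step remains at the segment boundary. `spline_p = 0`
#' degenerates to removing the segment's linear trend.
#'
#' @param od `od_series`. @param mask from [detect_motion_artifacts()].
#' @param spline_p smoothing parameter in [0, 1].
#' @return corrected `od_series`.
#' @export
correct_spline <- function(od, mask, spline_p = 0.99) {
  X <- od$od
  w <- max(4L, round(10 * od$fs))           # level-matching window (10 s)
  for (ch in seq_len(dim(X)[1])) {
    runs <- mask_runs(mask[ch, ])
    if (nrow(runs) == 0) next
    short <- runs$end - runs$start + 1L < 4L
    if (any(short)) {
      warning("flagged segment shorter than 4 samples left uncorrected")
      runs <- runs[!short, , drop = FALSE]
    }
    for (wl in 1:2) {
      x <- X[ch, wl, ]
      n <- length(x)
      for (i in seq_len(nrow(runs))) {
        a <- runs$start[i]; b <- runs$end[i]
        idx <- a:b
        fit <- if (spline_p <= 0) {
          stats::fitted(stats::lm(x[idx] ~ idx))
        } else {
          stats::predict(stats::smooth.spline(idx, x[idx],
                                              lambda = (1 - spline_p) / spline_p),
                         idx)$y
        }
        seg <- x[idx] - fit
        prev_idx <- if (a > 1L) max(1L, a - w):(a - 1L) else integer(0)
        next_idx <- if (b < n) (b + 1L):min(n, b + w) else integer(0)
        level <- if (length(prev_idx)) mean(x[prev_idx])
                 else if (length(next_idx)) mean(x[next_idx]) else mean(x[idx])
        seg <- seg + level
        x[idx] <- seg
        if (length(prev_idx) && length(next_idx)) {
          ## Remove the residual baseline step across the segment, but only
          ## when it is distinguishable from clean-signal fluctuation, so
          ## spike corrections do not inject spurious level steps downstream.
          jump <- mean(x[next_idx]) - mean(x[prev_idx])
          noise <- stats::sd(c(x[prev_idx] - mean(x[prev_idx]),
                               x[next_idx] - mean(x[next_idx])))
          if (is.finite(noise) &&
              abs(jump) > 3 * noise / sqrt(length(prev_idx))) {
            x[(b + 1L):n] <- x[(b + 1L):n] - jump
          }
        }
      }
      X[ch, wl, ] <- x
    }
  }
  od$od <- X
  od
}

## ---- periodized Daubechies discrete wavelet transform ---------------------
## Implemented directly as an orthogonal pyramid (reconstruction exact to
## machine precision). The db4 (8-tap) filters give enough stopband
## attenuation that slow hemodynamic signals stay in the approximation.

db_filters <- function() {
  h <- c(0.230377813308855230, 0.714846570552541500, 0.630880767929590400,
         -0.027983769416983850, -0.187034811718881140, 0.030841381835986965,
         0.032883011666982945, -0.010597401784997278)
  g <- rev(h) * c(1, -1)
  list(h = h, g = g)
}

dwt_step <- function(x, h, g) {
  n <- length(x)
  xe <- c(x, x[seq_len(length(h) - 1L)])    # periodic extension
  a <- numeric(n %/% 2L); d <- a
  for (k in seq_along(h)) {
    idx <- seq(k, by = 2L, length.out = n %/% 2L)
    a <- a + h[k] * xe[idx]
    d <- d + g[k] * xe[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  n <- 2L * length(a)
  x <- numeric(n + length(h) - 1L)
  for (k in seq_along(h)) {
    idx <- seq(k, by = 2L, length.out = length(a))
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  head <- seq_len(length(h) - 1L)
  x[head] <- x[head] + x[n + head]          # fold periodic tail back
  x[seq_len(n)]
}

#' Wavelet-based motion correction
#'
#' Per channel and wavelength the signal is decomposed with a periodized
#' Daubechies (4-tap) wavelet; detail coefficients outside the Tukey fences
#' `[q1 - iqr * IQR, q3 + iqr * IQR]` of their level are set to zero and the
#' signal reconstructed. The decomposition depth leaves the hemodynamic band
#' (below ~0.12 Hz) in the approximation, so slow signals pass unaltered
#' while transient spikes - which spread across detail levels - are
#' suppressed. `wavelet_iqr = Inf` returns the input unchanged.
#'
#' @param od `od_series`. @param wavelet_iqr fence multiplier.
#' @return corrected `od_series`.
#' @export
correct_wavelet <- function(od, wavelet_iqr = 1.5) {
  if (!is.finite(wavelet_iqr)) return(od)
  flt <- db_filters()
  X <- od$od
  n <- dim(X)[3]
  J <- max(1L, min(floor(log2(od$fs / 0.244)), floor(log2(n)) - 2L))
  pad <- ceiling(n / 2^J) * 2^J - n
  for (ch in seq_len(dim(X)[1])) for (wl in 1:2) {
    x <- X[ch, wl, ]
    xe <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
    details <- vector("list", J)
    a <- xe
    for (j in seq_len(J)) {
      st <- dwt_step(a, flt$h, flt$g)
      a <- st$a
      details[[j]] <- st$d
    }
    for (j in seq_len(J)) {
      d <- details[[j]]
      q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- d < q[1] - wavelet_iqr * iqr | d > q[2] + wavelet_iqr * iqr
      d[out] <- 0
      details[[j]] <- d
    }
    for (j in rev(seq_len(J))) a <- idwt_step(a, details[[j]], flt$h, flt$g)
    X[ch, wl, ] <- a[seq_len(n)]
  }
  od$od <- X
  od
}

#' PCA-based systemic noise filtering
#'
#' Per wavelength, the channels x time OD matrix is decomposed by SVD and the
#' leading components whose cumulative variance first reaches
#' `pca_variance_fraction` are removed (`mode = "remove"`, the systemic-noise
#' filtering convention) or retained (`mode = "keep"`).
#'
#' @param od `od_series`.
#' @param pca_variance_fraction target cumulative variance fraction.
#' @param mode `"remove"` or `"keep"`.
#' @return filtered `od_series`; attribute `"n_components"` records how many
#'   components were involved per wavelength.
#' @export
remove_systemic_pca <- function(od, pca_variance_fraction = 0.80,
                                mode = c("remove", "keep")) {
  mode <- match.arg(mode)
  X <- od$od
  ncha <- dim(X)[1]
  if (ncha < 2L) {
    warning("single channel: PCA filtering skipped")
    return(od)
  }
  ncomp <- integer(2)
  for (wl in 1:2) {
    M <- t(X[, wl, ])                        # time x channels
    mu <- colMeans(M)
    Mc <- sweep(M, 2L, mu)
    sv <- svd(Mc)
    varprop <- sv$d^2 / sum(sv$d^2)
    k <- if (pca_variance_fraction <= 0) 0L else which(cumsum(varprop) >= pca_variance_fraction)[1]
    ncomp[wl] <- k
    if (k >= 1L) {
      lead <- sv$u[, seq_len(k), drop = FALSE] %*%
        (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
      Mc <- if (mode == "remove") Mc - lead else lead
    } else if (mode == "keep") {
      Mc[] <- 0
    }
    X[, wl, ] <- t(sweep(Mc, 2L, mu, `+`))
  }
  od$od <- X
  attr(od, "n_components") <- ncomp
  od
}

#' Modified Beer-Lambert conversion to chromophore concentrations
#'
#' Solves, per channel and sample, the 2 x 2 system
#' OD_lambda = (eps_lambda,O2Hb C_O2Hb + eps_lambda,HHb C_HHb) d ppf_lambda.
#'
#' @param od `od_series`. @param p `preprocess_params`.
#' @param source_detector_distance optode separation (cm).
#' @return object of class `conc_series`: list(conc = channel x chromophore x
#'   time array in uM, fs, roi_map).
#' @export
od_to_concentration <- function(od, p = preprocess_params(),
                                source_detector_distance = 3.0) {
  E <- p$extinction * source_detector_distance * p$ppf
  if (abs(det(E)) < 1e-12) config_error("extinction coefficient matrix is singular")
  Einv <- solve(E)
  X <- od$od
  ncha <- dim(X)[1]; n <- dim(X)[3]
  conc <- array(0, dim = c(ncha, 2L, n),
                dimnames = list(NULL, c("o2hb", "hhb"), NULL))
  for (ch in seq_len(ncha))
    conc[ch, , ] <- 1000 * (Einv %*% X[ch, , ])     # mM -> uM
  structure(list(conc = conc, fs = od$fs, roi_map = od$roi_map,
                 participant_id = od$participant_id, role = od$role),
            class = "conc_series")
}

#' Welch power spectral density
#'
#' Segmented averaged periodogram: Hann window, mean-detrended segments.
#'
#' @param x numeric series. @param fs sampling rate (Hz).
#' @param seg_s segment length (s). @param overlap fractional overlap.
#' @return list(freq, psd).
#' @export
welch_psd <- function(x, fs, seg_s = 30, overlap = 0.5) {
  L <- min(length(x), round(seg_s * fs))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  win <- hann_window(L)
  U <- sum(win^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * U * fs)
  half <- seq_len(L %/% 2L + 1L)
  list(freq = (half - 1L) * fs / L, psd = psd[half] * c(1, rep(2, length(half) - 2L), 1))
}

#' Cardiac-peak channel quality assessment
#'
#' A channel passes when the maximal Welch power of its O2Hb series inside
#' `cardiac_band` is at least `psd_peak_prominence_ratio` times the median
#' power of the surrounding band (0.4 Hz up to 2 Hz, cardiac band excluded);
#' a missing heartbeat peak indicates poor scalp contact.
#'
#' @param conc `conc_series`. @param p `preprocess_params`.
#' @return data.frame (class `channel_quality`): channel, peak_freq,
#'   prominence_ratio, verdict (`"good"`/`"bad"`).
#' @export
assess_channel_quality <- function(conc, p = preprocess_params()) {
  cb <- p$cardiac_band
  if (conc$fs < 2 * cb[2])
    config_error("sampling rate too low to observe the cardiac band")
  n <- dim(conc$conc)[3]
  if (n / conc$fs < 60) warning("recording shorter than 60 s: PSD estimate unstable")
  ncha <- dim(conc$conc)[1]
  out <- data.frame(channel = seq_len(ncha), peak_freq = NA_real_,
                    prominence_ratio = NA_real_,
                    verdict = character(ncha))
  surround_lo <- max(0.4, cb[1] - 0.4)
  surround_hi <- min(2.0, conc$fs / 2 * 0.95)
  for (ch in seq_len(ncha)) {
    w <- welch_psd(conc$conc[ch, "o2hb", ], conc$fs)
    inb <- w$freq >= cb[1] & w$freq <= cb[2]
    sur <- w$freq >= surround_lo & w$freq <= surround_hi & !inb
    peak <- max(w$psd[inb])
    ref <- stats::median(w$psd[sur])
    ratio <- if (ref > 0) peak / ref else Inf
    out$peak_freq[ch] <- w$freq[inb][which.max(w$psd[inb])]
    out$prominence_ratio[ch] <- ratio
    out$verdict[ch] <- if (ratio >= p$psd_peak_prominence_ratio) "good" else "bad"
  }
  class(out) <- c("channel_quality", "data.frame")
  out
}

#' Average good channels into ROI series
#'
#' ROI series are the mean of their good channels; ROIs composed exclusively
#' of bad channels are discarded; a participant with more than one missing
#' ROI is marked excluded.
#'
#' @param conc `conc_series`. @param quality `channel_quality`.
#' @param roi_map named character vector channel -> ROI (defaults to the one
#'   carried by `conc`).
#' @return object of class `roi_timeseries`: list(o2hb, hhb = ROI x time
#'   matrices, status = named "ok"/"discarded", excluded flag, fs).
#' @export
average_rois <- function(conc, quality, roi_map = conc$roi_map) {
  ncha <- dim(conc$conc)[1]
  if (length(roi_map) != ncha) data_error("roi_map must cover all channels")
  rois <- unique(roi_map)
  n <- dim(conc$conc)[3]
  o2 <- matrix(NA_real_, length(rois), n, dimnames = list(rois, NULL))
  hb <- o2
  status <- stats::setNames(rep("discarded", length(rois)), rois)
  good <- quality$verdict == "good"
  for (r in rois) {
    chs <- which(roi_map == r & good)
    if (length(chs) == 0) next
    o2[r, ] <- colMeans(matrix(conc$conc[chs, "o2hb", ], nrow = length(chs)))
    hb[r, ] <- colMeans(matrix(conc$conc[chs, "hhb", ], nrow = length(chs)))
    status[r] <- "ok"
  }
  n_missing <- sum(status == "discarded")
  structure(list(o2hb = o2, hhb = hb, status = status, fs = conc$fs,
                 participant_id = conc$participant_id, role = conc$role,
                 n_missing = n_missing, excluded = n_missing > 1L),
            class = "roi_timeseries")
}

#' Full preprocessing chain for one participant
#'
#' Runs steps (1)-(7) in order: optical density, motion detection, spline
#' correction, wavelet correction, PCA systemic filtering, Beer-Lambert
#' conversion, cardiac quality check, ROI averaging.
#'
#' @param raw `raw_intensity`. @param p `preprocess_params`.
#' @return list with `roi` (`roi_timeseries`), `quality`
#'   (`channel_quality`), `motion_mask` (channel x time logical), `conc`
#'   (`conc_series`).
#' @export
preprocess_participant <- function(raw, p = preprocess_params()) {
  od <- intensity_to_od(raw)
  mask <- detect_motion_artifacts(od, p)
  od <- correct_spline(od, mask, p$spline_p)
  od <- correct_wavelet(od, p$wavelet_iqr)
  od <- remove_systemic_pca(od, p$pca_variance_fraction, p$pca_mode)
  conc <- od_to_concentration(od, p)
  quality <- assess_channel_quality(conc, p)
  roi <- average_rois(conc, quality)
  list(roi = roi, quality = quality, motion_mask = mask, conc = conc)
}
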