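## Synthetic dyad studies with known ground truth.
##
## The generator emulates the recording protocol of a two-person collaborative
## navigation experiment: two groups of dyads, a 3-min rest / 20-min task /
## 3-min rest structure, an unannounced disruption at the 10-minute task mark,
## 16-channel two-wavelength fNIRS at 7.81 Hz over six regions of interest,
## 10 Hz binary speech streams, and a 10 Hz cursor trajectory scored against an
## axis-aligned reference path.

#' Simulation parameters for a synthetic hyperscanning study
#'
#' Houses the task constants (7.81 Hz optical sampling, 20-min task flanked by
#' 3-min rests, disruption at 10 min, 202 icons of which 41 stay visible) and
#' the generator's free parameters: the interbrain coupling \eqn{\kappa} of the
#' shared band-limited hemodynamic signal, physiological oscillation
#' frequencies, noise and artifact rates.
#'
#' Coupling \eqn{\kappa \in [0,1]} mixes a dyad-shared latent band-limited
#' Gaussian process \eqn{s(t)} into each participant's ROI signal as
#' \eqn{x = \kappa s + \sqrt{1-\kappa^2}\, p} with an independent private
#' process \eqn{p}; the squared wavelet coherence between the two partners'
#' homotopic ROI signals is then \eqn{\kappa^4} in expectation (plus estimator
#' bias). `coupling_post` applies after the disruption in the experimental
#' group only. `ibs_trend` adds a linear drift, in squared-coherence units per
#' second, to the target coherence within each task period.
#'
#' @param n_dyads number of dyads.
#' @param group_assignment character vector (`"control"`/`"experimental"`) per
#'   dyad; default alternates so groups are balanced.
#' @param fs_nirs optical sampling rate (Hz).
#' @param fs_behavior behavioral sampling rate (Hz).
#' @param rest_duration,task_duration,disruption_offset protocol timing (s);
#'   the disruption offset is measured from task start.
#' @param coupling_pre,coupling_post coupling \eqn{\kappa} before/after the
#'   disruption (scalar or per-dyad vector).
#' @param coupling_band frequency band (Hz) of the shared/private hemodynamic
#'   processes.
#' @param ibs_trend squared-coherence drift per second within a period.
#' @param cardiac_freq,mayer_freq,resp_freq physiological oscillation
#'   frequencies (Hz).
#' @param noise_sd white measurement noise SD on channel concentrations (uM).
#' @param artifact_spike_rate,artifact_shift_rate motion-artifact event rates
#'   (events per minute).
#' @param bad_channel_prob probability that a channel has no scalp contact
#'   (no cardiac or cortical component, inflated noise).
#' @param n_icons,icons_visible_after_disruption icon counts for the task
#'   screen; 41 of 202 icons stay visible after the disruption.
#' @param rng_seed master seed; all per-dyad streams derive from it.
#' @param amplitudes optional named list overriding internal signal amplitudes
#'   (uM): `hemo_sd`, `cardiac_amp`, `mayer_amp`, `resp_amp`, `hhb_ratio`,
#'   `spike_amp`, `shift_amp`, `bad_noise_sd`.
#' @param behavior optional named list overriding behavioral defaults; see
#'   [generate_dyad()].
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_dyads = 49L,
                       group_assignment = NULL,
                       fs_nirs = 7.81,
                       fs_behavior = 10,
                       rest_duration = 180,
                       task_duration = 1200,
                       disruption_offset = 600,
                       coupling_pre = 0.3,
                       coupling_post = 0.3,
                       coupling_band = c(0.01, 0.08),
                       ibs_trend = 0,
                       cardiac_freq = 1.0,
                       mayer_freq = 0.1,
                       resp_freq = 0.25,
                       noise_sd = 0.1,
                       artifact_spike_rate = 0.5,
                       artifact_shift_rate = 0.1,
                       bad_channel_prob = 0.05,
                       n_icons = 202L,
                       icons_visible_after_disruption = NULL,
                       rng_seed = 1L,
                       amplitudes = list(),
                       behavior = list()) {
  if (!is_count(n_dyads) || n_dyads < 1) param_error("n_dyads must be a positive count")
  if (is.null(group_assignment))
    group_assignment <- rep(c("control", "experimental"), length.out = n_dyads)
  if (length(group_assignment) != n_dyads ||
      !all(group_assignment %in% c("control", "experimental")))
    param_error("group_assignment must give 'control' or 'experimental' per dyad")
  for (nm in c("fs_nirs", "fs_behavior", "rest_duration", "task_duration",
               "disruption_offset", "cardiac_freq", "mayer_freq", "resp_freq"))
    if (!is_scalar(get(nm)) || get(nm) <= 0) param_error(sprintf("%s must be a positive scalar", nm))
  for (nm in c("noise_sd", "artifact_spike_rate", "artifact_shift_rate", "ibs_trend"))
    if (!is.numeric(get(nm)) || any(!is.finite(get(nm)))) param_error(sprintf("%s must be finite", nm))
  if (any(c(noise_sd, artifact_spike_rate, artifact_shift_rate) < 0))
    param_error("noise_sd and artifact rates must be >= 0")
  ck <- function(k, nm) {
    if (!is.numeric(k) || any(k < 0 | k > 1)) param_error(sprintf("%s must lie in [0, 1]", nm))
    rep_len(k, n_dyads)
  }
  coupling_pre <- ck(coupling_pre, "coupling_pre")
  coupling_post <- ck(coupling_post, "coupling_post")
  if (length(coupling_band) != 2L || coupling_band[1] <= 0 || coupling_band[1] >= coupling_band[2])
    param_error("coupling_band must be an increasing positive Hz interval")
  if (fs_nirs <= 2 * coupling_band[2])
    param_error("fs_nirs must exceed twice the coupling_band upper edge")
  if (disruption_offset >= task_duration)
    param_error("disruption_offset must be smaller than task_duration")
  if (!is_count(n_icons) || n_icons < 2) param_error("n_icons must be a count >= 2")
  if (is.null(icons_visible_after_disruption))
    icons_visible_after_disruption <- max(1L, round(0.2 * n_icons))  # 41 of 202
  if (!is_count(icons_visible_after_disruption) || icons_visible_after_disruption > n_icons)
    param_error("icons_visible_after_disruption must be a count <= n_icons")
  if (bad_channel_prob < 0 || bad_channel_prob > 1)
    param_error("bad_channel_prob must lie in [0, 1]")

  amp <- utils::modifyList(list(
    hemo_sd = 0.4,          # cortical band-limited signal SD (uM)
    cardiac_amp = 0.5,      # per-channel phase (pulse-arrival variation)
    mayer_amp = 3.0,        # shared phase, per-channel gain: dominant systemic PC
    resp_amp = 0.8,         # shared phase, per-channel gain
    hhb_ratio = -0.4,       # cortical HHb anticorrelation with O2Hb
    systemic_hhb_ratio = 0.5, # systemic interference drives HHb with O2Hb
    spike_amp = 30,         # motion spike scale (uM-equivalent, ~0.7 OD)
    shift_amp = 30,         # baseline step scale
    bad_noise_sd = 0.3      # noise SD of channels without scalp contact
  ), amplitudes)

  beh <- utils::modifyList(list(
    # Speech on-fractions and post/pre ratio multiplier, per group.  Chosen to
    # reproduce the observed study-scale behavior: total speaking time around
    # 460 s per 10-min period and guide-dominated speech ratios that increase
    # after the disruption in the experimental group only.
    speech = list(control      = c(guide = 0.72, drawer = 0.055, shift = 0.90),
                  experimental = c(guide = 0.65, drawer = 0.115, shift = 1.33)),
    # Cursor jitter SD (screen units; the screen is the unit square) and
    # post-disruption multiplier per group.
    cursor = list(skill_sd = 0.02, post_factor = c(control = 1.0, experimental = 2.3)),
    # Perceived difficulty (VAS 0-10): mean/SD pre and post, per group.
    difficulty = list(control      = c(4.00, 1.83, 4.20, 1.96),
                      experimental = c(3.14, 1.69, 6.36, 1.67))
  ), behavior)

  structure(list(
    n_dyads = as.integer(n_dyads), group_assignment = group_assignment,
    fs_nirs = fs_nirs, fs_behavior = fs_behavior,
    rest_duration = rest_duration, task_duration = task_duration,
    disruption_offset = disruption_offset,
    coupling_pre = coupling_pre, coupling_post = coupling_post,
    coupling_band = coupling_band, ibs_trend = ibs_trend,
    cardiac_freq = cardiac_freq, mayer_freq = mayer_freq, resp_freq = resp_freq,
    noise_sd = noise_sd,
    artifact_spike_rate = artifact_spike_rate, artifact_shift_rate = artifact_shift_rate,
    bad_channel_prob = bad_channel_prob,
    n_icons = as.integer(n_icons),
    icons_visible_after_disruption = as.integer(icons_visible_after_disruption),
    rng_seed = as.integer(rng_seed),
    amplitudes = amp, behavior = beh
  ), class = "sim_params")
}

#' Band-limited Gaussian process
#'
#' White noise filtered with a zero-phase FFT band-pass, rescaled to unit SD.
#' Gives controllable pairwise coherence with an analytic expectation.
#'
#' @param n samples. @param fs sampling rate (Hz). @param band c(f_lo, f_hi) Hz.
#' @return numeric vector, unit SD.
#' @export
bandlimited_noise <- function(n, fs, band) {
  m <- next_fft_len(n)                     # power-of-two grid for the FFT
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- (seq_len(m) - 1L) * fs / m
  f <- pmin(f, fs - f)                     # two-sided frequency magnitude
  W[f < band[1] | f > band[2]] <- 0i
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

## Channel -> ROI layout of the 16-channel montage (see default_roi_map()).
roi_names <- function() c("fpPFC_L", "fpPFC_R", "dlPFC_L", "dlPFC_R", "TPJ_L", "TPJ_R")

#' Inject motion artifacts into a concentration series
#'
#' Spikes are transient signed deflections with exponential decay (duration
#' <= 2 s); shifts are persistent baseline steps. Event counts are Poisson
#' with the stated rates.
#'
#' @param signal numeric concentration series.
#' @param fs sampling rate (Hz).
#' @param spike_rate,shift_rate events per minute (>= 0).
#' @param rng_seed integer seed (fixed seed gives an identical log).
#' @param spike_amp,shift_amp amplitude scales.
#' @return list with `signal` (corrupted series) and `log`
#'   (data.frame onset, type, amplitude).
#' @export
inject_artifacts <- function(signal, fs, spike_rate, shift_rate, rng_seed,
                             spike_amp = 20, shift_amp = 15) {
  if (spike_rate < 0 || shift_rate < 0) param_error("artifact rates must be >= 0")
  set.seed(rng_seed)
  n <- length(signal)
  mins <- n / fs / 60
  t <- (seq_len(n) - 1L) / fs
  log <- data.frame(onset = numeric(0), type = character(0), amplitude = numeric(0))
  n_spike <- stats::rpois(1L, spike_rate * mins)
  n_shift <- stats::rpois(1L, shift_rate * mins)
  if (n_spike > 0) {
    on <- sort(stats::runif(n_spike, 0, max(t)))
    amp <- sample(c(-1, 1), n_spike, replace = TRUE) * spike_amp * stats::runif(n_spike, 0.5, 1.5)
    for (i in seq_len(n_spike)) {
      sel <- t >= on[i] & t <= on[i] + 2      # transient <= 2 s
      signal[sel] <- signal[sel] + amp[i] * exp(-(t[sel] - on[i]) / 0.3)
    }
    log <- rbind(log, data.frame(onset = on, type = "spike", amplitude = amp))
  }
  if (n_shift > 0) {
    on <- sort(stats::runif(n_shift, 0, max(t)))
    amp <- sample(c(-1, 1), n_shift, replace = TRUE) * shift_amp * stats::runif(n_shift, 0.5, 1.5)
    for (i in seq_len(n_shift)) signal[t >= on[i]] <- signal[t >= on[i]] + amp[i]
    log <- rbind(log, data.frame(onset = on, type = "shift", amplitude = amp))
  }
  log <- log[order(log$onset), , drop = FALSE]
  rownames(log) <- NULL
  list(signal = signal, log = log)
}

#' Generate the reference path and icon layout
#'
#' Axis-aligned staircase polyline from the start to the end point inside the
#' unit screen rectangle. Every directional change (turn vertex) coincides
#' with an icon; the remaining icons are distractors placed uniformly at
#' random. With `n_icons = 2` only start and end exist and the path is a
#' single segment.
#'
#' @param params `sim_params`.
#' @param rng_seed seed (defaults to the study master seed so every dyad sees
#'   the same path, as in the protocol).
#' @return object of class `reference_path`: list with `vertices` (matrix,
#'   ordered polyline), `icons` (matrix of icon positions; the first rows are
#'   the turn vertices), `start`, `end`.
#' @export
generate_reference_path <- function(params, rng_seed = params$rng_seed) {
  if (params$n_icons < 2) param_error("n_icons must be >= 2")
  set.seed(rng_seed)
  start <- c(0.05, 0.50); end <- c(0.95, 0.50)
  if (params$n_icons == 2L) {
    v <- rbind(start, end)
    rownames(v) <- NULL
    return(structure(list(vertices = v, icons = v, start = start, end = end),
                     class = "reference_path"))
  }
  n_turns <- min(14L, params$n_icons - 2L)
  xs <- sort(stats::runif(n_turns %/% 2L + 1L, 0.08, 0.92))
  verts <- list(start)
  cur <- start
  for (i in seq_along(xs)) {
    cur <- c(xs[i], cur[2]); verts[[length(verts) + 1L]] <- cur   # horizontal leg
    if (i <= n_turns %/% 2L) {
      cur <- c(cur[1], stats::runif(1, 0.08, 0.92))               # vertical leg
      verts[[length(verts) + 1L]] <- cur
    }
  }
  cur <- c(end[1], cur[2]); verts[[length(verts) + 1L]] <- cur
  if (abs(cur[2] - end[2]) > 1e-12) verts[[length(verts) + 1L]] <- end
  v <- do.call(rbind, verts)
  keep <- c(TRUE, rowSums(abs(diff(v))) > 1e-12)
  v <- v[keep, , drop = FALSE]
  turns <- v[-c(1L, nrow(v)), , drop = FALSE]
  n_extra <- params$n_icons - nrow(turns) - 2L
  extra <- cbind(stats::runif(max(n_extra, 0L), 0.02, 0.98),
                 stats::runif(max(n_extra, 0L), 0.02, 0.98))
  icons <- rbind(v[1L, ], turns, v[nrow(v), ], extra)[seq_len(params$n_icons), , drop = FALSE]
  rownames(v) <- rownames(icons) <- NULL
  structure(list(vertices = v, icons = icons, start = start, end = end),
            class = "reference_path")
}

## Arc-length resample of a polyline at m equally spaced stations
polyline_points <- function(vertices, m) {
  seg <- diff(vertices)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  s <- seq(0, cum[length(cum)], length.out = m)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= nrow(vertices)] <- nrow(vertices) - 1L
  frac <- (s - cum[i]) / pmax(len[i], 1e-300)
  vertices[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
}

#' Simulate the dyad's cursor trajectory
#'
#' The cursor traverses the reference path at constant speed over the task
#' duration, with smooth (low-pass) 2-D jitter whose SD switches from
#' `skill_sd` to `post_skill_sd` at the disruption time.
#'
#' @param ref `reference_path`.
#' @param skill_sd,post_skill_sd jitter SD (screen units) before/after the
#'   disruption.
#' @param disruption_time seconds from task start.
#' @param duration task duration (s).
#' @param fs behavioral sampling rate (Hz).
#' @param rng_seed integer seed.
#' @return object of class `trajectory`: data.frame(time, x, y).
#' @export
simulate_cursor <- function(ref, skill_sd, disruption_time, post_skill_sd,
                            duration, fs = 10, rng_seed = 1L) {
  if (skill_sd < 0 || post_skill_sd < 0) param_error("skill_sd values must be >= 0")
  set.seed(rng_seed)
  n <- round(duration * fs)
  time <- (seq_len(n) - 1L) / fs
  base <- polyline_points(ref$vertices, n)
  sdv <- ifelse(time < disruption_time, skill_sd, post_skill_sd)
  jitter <- cbind(bandlimited_noise(n, fs, c(1e-6, 0.5)),
                  bandlimited_noise(n, fs, c(1e-6, 0.5))) * sdv
  if (all(sdv == 0)) jitter[] <- 0
  out <- data.frame(time = time, x = base[, 1] + jitter[, 1], y = base[, 2] + jitter[, 2])
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Simulate the binary speech streams of a dyad
#'
#' Two-state Markov chains at `fs` Hz with ~2 s mean speaking bouts whose
#' stationary on-fraction equals the requested rate. After the disruption the
#' guide/drawer rates are multiplied and divided by `sqrt(post_ratio_shift)`
#' respectively, so the expected guide-to-drawer speaking-time ratio is
#' multiplied by `post_ratio_shift`.
#'
#' @param duration task duration (s). @param fs sampling rate (Hz).
#' @param guide_rate,drawer_rate stationary speaking fractions in [0, 1].
#' @param post_ratio_shift multiplier on the expected speech ratio after
#'   `disruption_time`.
#' @param disruption_time seconds from task start.
#' @param rng_seed integer seed.
#' @return list of two data.frames (`guide`, `drawer`) with columns time,
#'   speaking (0/1), role.
#' @export
simulate_speech <- function(duration, fs = 10, guide_rate, drawer_rate,
                            post_ratio_shift = 1, disruption_time = duration,
                            rng_seed = 1L) {
  if (any(c(guide_rate, drawer_rate) < 0 | c(guide_rate, drawer_rate) > 1))
    param_error("speech rates must lie in [0, 1]")
  set.seed(rng_seed)
  n <- round(duration * fs)
  time <- (seq_len(n) - 1L) / fs
  markov <- function(p_on, n) {
    if (n <= 0L) return(integer(0))
    p_on <- min(max(p_on, 0), 1)
    if (p_on == 0) return(integer(n))
    if (p_on == 1) return(rep(1L, n))
    if (n == 1L) return(stats::rbinom(1L, 1L, p_on))
    p_off_given_on <- min(1 / (2 * fs), 1)              # ~2 s mean bouts
    p_on_given_off <- min(p_on / (1 - p_on) * p_off_given_on, 1)
    x <- integer(n)
    x[1] <- stats::rbinom(1L, 1L, p_on)
    u <- stats::runif(n)
    for (i in 2:n)
      x[i] <- if (x[i - 1L] == 1L) as.integer(u[i] >= p_off_given_on)
              else as.integer(u[i] < p_on_given_off)
    x
  }
  sft <- sqrt(post_ratio_shift)
  pre <- time < disruption_time
  g <- c(markov(guide_rate, sum(pre)), markov(min(guide_rate * sft, 1), sum(!pre)))
  d <- c(markov(drawer_rate, sum(pre)), markov(min(drawer_rate / sft, 1), sum(!pre)))
  list(guide = data.frame(time = time, speaking = g, role = "guide"),
       drawer = data.frame(time = time, speaking = d, role = "drawer"))
}

## kappa(t) profile: coupling_pre from the start of the recording until the
## disruption marker, coupling_post afterwards; within each task period the
## target squared coherence c = kappa^4 drifts by ibs_trend per second.
kappa_profile <- function(t, markers, k_pre, k_post, trend) {
  pre <- t < markers$disruption
  dt_pre <- pmax(pmin(t, markers$disruption) - markers$task_start, 0)
  dt_post <- pmax(pmin(t, markers$task_end) - markers$disruption, 0)
  c_target <- ifelse(pre,
                     k_pre^4 + trend * dt_pre,
                     k_post^4 + trend * dt_post)
  pmin(pmax(c_target, 0), 1)^(1 / 4)
}

#' Generate one synthetic dyad
#'
#' Builds the paired recording for dyad `dyad_index`: per homotopic ROI, each
#' participant's oxyhemoglobin signal is
#' \eqn{\kappa(t) s(t) + \sqrt{1-\kappa(t)^2}\, p(t)} (shared/private
#' band-limited Gaussian processes, unit SD, scaled to `hemo_sd`), plus
#' systemic Mayer and respiratory oscillations (shared phase within a
#' participant, per-channel gain), a cardiac oscillation with per-channel
#' phase, white noise, and injected motion artifacts. HHb is an anticorrelated
#' scaled copy with its own private component. Channel concentrations are
#' mapped to two-wavelength intensities by inverting the modified Beer-Lambert
#' law with the same extinction coefficients and partial pathlength factors
#' the preprocessing uses, so a preprocessing round trip recovers the ROI
#' concentrations. Bad channels (probability `bad_channel_prob`) carry neither
#' cardiac nor cortical components, only inflated noise.
#'
#' In the experimental group \eqn{\kappa} switches from `coupling_pre` to
#' `coupling_post` at the disruption marker; control dyads keep `coupling_pre`
#' throughout.
#'
#' @param params `sim_params`.
#' @param dyad_index 1-based dyad index (`<= n_dyads`).
#' @param channels if `FALSE`, skip channel-level expansion and intensity
#'   synthesis; the returned recording then carries only the ROI-level
#'   concentration truth (fast path for coherence-level simulations).
#' @return list with `recording` (dyad recording: raw intensities per
#'   participant, speech, trajectory, reference path, difficulty scores, event
#'   markers) and `truth` (ground truth: per-period coupling, ROI
#'   concentration series, artifact logs, bad channels, behavioral rates).
#' @export
generate_dyad <- function(params, dyad_index, channels = TRUE) {
  if (!inherits(params, "sim_params")) param_error("params must be a sim_params object")
  if (!is_count(dyad_index) || dyad_index < 1 || dyad_index > params$n_dyads)
    param_error("dyad_index must lie in 1..n_dyads")
  group <- params$group_assignment[dyad_index]
  fs <- params$fs_nirs
  total <- 2 * params$rest_duration + params$task_duration
  n <- round(fs * total)
  t <- (seq_len(n) - 1L) / fs
  markers <- list(task_start = params$rest_duration,
                  disruption = params$rest_duration + params$disruption_offset,
                  task_end = params$rest_duration + params$task_duration)
  amp <- params$amplitudes
  k_pre <- params$coupling_pre[dyad_index]
  k_post <- if (group == "experimental") params$coupling_post[dyad_index] else k_pre

  set.seed(derive_seed(params$rng_seed, dyad_index, salt = 1L))
  kap <- kappa_profile(t, markers, k_pre, k_post, params$ibs_trend)
  s_shared <- bandlimited_noise(n, fs, params$coupling_band)
  rois <- roi_names()
  roi_sig <- function() {
    o2 <- matrix(0, length(rois), n, dimnames = list(rois, NULL))
    hb <- o2
    for (r in seq_along(rois)) {
      p <- bandlimited_noise(n, fs, params$coupling_band)
      x <- kap * s_shared + sqrt(pmax(1 - kap^2, 0)) * p
      o2[r, ] <- amp$hemo_sd * x
      hb[r, ] <- amp$hhb_ratio * o2[r, ] +
        0.3 * amp$hemo_sd * bandlimited_noise(n, fs, params$coupling_band)
    }
    list(o2hb = o2, hhb = hb)
  }
  guide_roi <- roi_sig()
  drawer_roi <- roi_sig()

  truth <- list(
    dyad_id = sprintf("dyad%03d", dyad_index), group = group,
    kappa_pre = k_pre, kappa_post = k_post,
    coherence_trend = params$ibs_trend,
    roi_o2hb = list(guide = guide_roi$o2hb, drawer = drawer_roi$o2hb),
    roi_hhb = list(guide = guide_roi$hhb, drawer = drawer_roi$hhb),
    artifacts = list(guide = list(), drawer = list()),
    bad_channels = list(guide = integer(0), drawer = integer(0))
  )

  build_participant <- function(roi_set, role, salt) {
    set.seed(derive_seed(params$rng_seed, dyad_index, salt = salt))
    map <- default_roi_map()
    ncha <- length(map)
    bad <- which(stats::runif(ncha) < params$bad_channel_prob)
    phi_m <- stats::runif(1, 0, 2 * pi); phi_r <- stats::runif(1, 0, 2 * pi)
    conc <- array(0, dim = c(ncha, 2L, n),
                  dimnames = list(NULL, c("o2hb", "hhb"), NULL))
    logs <- vector("list", ncha)
    for (ch in seq_len(ncha)) {
      if (ch %in% bad) {
        conc[ch, 1L, ] <- stats::rnorm(n, sd = amp$bad_noise_sd)
        conc[ch, 2L, ] <- stats::rnorm(n, sd = amp$bad_noise_sd)
        logs[[ch]] <- data.frame(onset = numeric(0), type = character(0),
                                 amplitude = numeric(0))
        next
      }
      g_hemo <- stats::runif(1, 0.7, 1.3)
      ## Systemic loadings are signed: optode sensitivity to superficial flow
      ## varies in sign across the montage, which keeps the systemic subspace
      ## separable from the (positive) cortical gain pattern.
      g_m <- stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      g_r <- stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      g_c <- stats::runif(1, 0.5, 1.5); phi_c <- stats::runif(1, 0, 2 * pi)
      systemic <- amp$mayer_amp * g_m * sin(2 * pi * params$mayer_freq * t + phi_m) +
        amp$resp_amp * g_r * sin(2 * pi * params$resp_freq * t + phi_r)
      cardiac <- amp$cardiac_amp * g_c * sin(2 * pi * params$cardiac_freq * t + phi_c)
      o2 <- g_hemo * roi_set$o2hb[map[ch], ] + systemic + cardiac +
        stats::rnorm(n, sd = params$noise_sd)
      hb <- g_hemo * roi_set$hhb[map[ch], ] +
        amp$systemic_hhb_ratio * (systemic + cardiac) +
        stats::rnorm(n, sd = params$noise_sd)
      seed_ch <- derive_seed(params$rng_seed, dyad_index, salt = salt + 100L + ch)
      art <- inject_artifacts(o2, fs, params$artifact_spike_rate,
                              params$artifact_shift_rate, seed_ch,
                              spike_amp = amp$spike_amp, shift_amp = amp$shift_amp)
      ## Motion artifacts are optical-coupling events: both chromophores are
      ## driven with the same sign (systemic-like ratio), same event times.
      arth <- inject_artifacts(hb, fs, params$artifact_spike_rate,
                               params$artifact_shift_rate, seed_ch,
                               spike_amp = amp$spike_amp * amp$systemic_hhb_ratio,
                               shift_amp = amp$shift_amp * amp$systemic_hhb_ratio)
      o2 <- art$signal
      hb <- arth$signal
      logs[[ch]] <- art$log
      conc[ch, 1L, ] <- o2
      conc[ch, 2L, ] <- hb
    }
    intens <- conc_to_intensity(conc, fs)
    list(raw = raw_intensity(intens, fs = fs, roi_map = map, role = role,
                             participant_id = sprintf("dyad%03d_%s", dyad_index, role)),
         bad = bad, logs = logs)
  }

  recording <- list(dyad_id = truth$dyad_id, group = group, markers = markers,
                    fs_nirs = fs)
  if (channels) {
    pg <- build_participant(guide_roi, "guide", salt = 2L)
    pd <- build_participant(drawer_roi, "drawer", salt = 3L)
    recording$guide <- pg$raw
    recording$drawer <- pd$raw
    truth$bad_channels <- list(guide = pg$bad, drawer = pd$bad)
    truth$artifacts <- list(guide = pg$logs, drawer = pd$logs)
  }

  beh <- params$behavior
  sp <- beh$speech[[group]]
  speech <- simulate_speech(params$task_duration, params$fs_behavior,
                            sp[["guide"]], sp[["drawer"]], sp[["shift"]],
                            params$disruption_offset,
                            derive_seed(params$rng_seed, dyad_index, salt = 4L))
  ref <- generate_reference_path(params)
  cur <- beh$cursor
  post_sd <- cur$skill_sd * cur$post_factor[[group]]
  traj <- simulate_cursor(ref, cur$skill_sd, params$disruption_offset, post_sd,
                          params$task_duration, params$fs_behavior,
                          derive_seed(params$rng_seed, dyad_index, salt = 5L))
  dd <- beh$difficulty[[group]]
  set.seed(derive_seed(params$rng_seed, dyad_index, salt = 6L))
  rtrunc <- function(m, s) min(max(stats::rnorm(1L, m, s), 0), 10)
  difficulty <- data.frame(
    participant = rep(c("guide", "drawer"), each = 2L),
    period = rep(c("pre", "post"), 2L),
    score = c(rtrunc(dd[1], dd[2]), rtrunc(dd[3], dd[4]),
              rtrunc(dd[1], dd[2]), rtrunc(dd[3], dd[4])))

  recording$speech <- speech
  recording$trajectory <- traj
  recording$reference_path <- ref
  recording$difficulty <- difficulty
  truth$speech_rates <- sp
  truth$cursor_sd <- c(pre = cur$skill_sd, post = post_sd)
  class(recording) <- "dyad_recording"
  list(recording = recording, truth = truth)
}

#' Generate a whole synthetic study
#'
#' @param params `sim_params`.
#' @param channels passed to [generate_dyad()].
#' @return object of class `ibs_study`: list with `params`, `dyads` (each a
#'   `generate_dyad()` result) and a `metadata` data.frame.
#' @export
simulate_study <- function(params, channels = TRUE) {
  dyads <- lapply(seq_len(params$n_dyads), function(i)
    generate_dyad(params, i, channels = channels))
  metadata <- data.frame(
    dyad_id = vapply(dyads, function(d) d$recording$dyad_id, character(1)),
    group = vapply(dyads, function(d) d$recording$group, character(1)),
    kappa_pre = vapply(dyads, function(d) d$truth$kappa_pre, numeric(1)),
    kappa_post = vapply(dyads, function(d) d$truth$kappa_post, numeric(1)))
  structure(list(params = params, dyads = dyads, metadata = metadata),
            class = "ibs_study")
}
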