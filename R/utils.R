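## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class) {
  stop(structure(class = c(class, "nirsync_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

param_error  <- function(msg) abort(msg, "nirsync_param_error")
data_error   <- function(msg) abort(msg, "nirsync_data_error")
config_error <- function(msg) abort(msg, "nirsync_config_error")
usage_error  <- function(msg) abort(msg, "nirsync_usage_error")

#' Derive a reproducible per-unit seed from a master seed
#'
#' Stable integer hashing so that per-dyad streams are reproducible under
#' partial re-runs. Result always lies in [1, 2^31 - 2].
#'
#' @param master integer master seed.
#' @param index unit index (e.g. dyad number).
#' @param salt stream discriminator (different streams for signal, speech, ...).
#' @return integer seed.
#' @keywords internal
derive_seed <- function(master, index = 0L, salt = 0L) {
  s <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503 +
          as.numeric(salt) * 69069) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}

## FFT-friendly length (R's FFT is fastest on powers of two)
next_fft_len <- function(n) 2L^ceiling(log2(n))

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

## Running mean across columns of a matrix with truncated edges
row_boxcar <- function(M, width) {
  if (width <= 1L) return(M)
  S <- ncol(M)
  half <- width %/% 2L
  CS <- cbind(0, t(apply(M, 1L, cumsum)))
  lo <- pmax(seq_len(S) - half, 1L)
  hi <- pmin(seq_len(S) + half, S)
  out <- (CS[, hi + 1L, drop = FALSE] - CS[, lo, drop = FALSE])
  sweep(out, 2L, hi - lo + 1L, "/")
}

## Extend a logical vector by k samples on both sides of every TRUE run
dilate_mask <- function(mask, k) {
  if (k <= 0L || !any(mask)) return(mask)
  n <- length(mask)
  idx <- which(mask)
  lo <- pmax(idx - k, 1L); hi <- pmin(idx + k, n)
  out <- logical(n)
  for (i in seq_along(idx)) out[lo[i]:hi[i]] <- TRUE
  out
}

## Runs of TRUE in a logical vector -> data.frame(start, end)
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

## Zero-phase FFT low-pass at 0.9 x the new Nyquist rate, then keep every
## fac-th sample. The series is reflected up to a power-of-two length so the
## transform stays fast and the filter sees a continuous signal.
decimate_lowpass <- function(x, fs, fac) {
  if (fac <= 1L) return(x)
  n <- length(x)
  m <- next_fft_len(n)
  pad <- m - n
  xe <- if (pad > 0) c(x, rev(x)[seq_len(pad)]) else x
  X <- stats::fft(xe)
  f <- (seq_len(m) - 1L) * fs / m
  f <- pmin(f, fs - f)
  X[f > 0.9 * fs / (2 * fac)] <- 0i
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y[seq(1L, n, by = fac)]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
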