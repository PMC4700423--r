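#' Spectral estimation parameters
#'
#' @param estimator `"multitaper"` (default; sine tapers, the K = 5 taper
#'   analogue of time-bandwidth NW = 3) or `"welch"` (Hann windows, 50%
#'   overlap). Band-integrated comparisons are robust to this choice; both
#'   estimators satisfy the package's Parseval sanity checks.
#' @param window_s Welch window length, seconds.
#' @param overlap Welch fractional overlap.
#' @param n_tapers number of sine tapers for the multitaper estimator.
#' @param fmax upper frequency bound of the returned PSD, Hz.
#' @return list of parameters.
#' @export
psd_params <- function(estimator = c("multitaper", "welch"), window_s = 1,
                       overlap = 0.5, n_tapers = 5, fmax = 100) {
  list(estimator = match.arg(estimator), window_s = window_s,
       overlap = overlap, n_tapers = n_tapers, fmax = fmax)
}

#' The five canonical LFP analysis bands
#'
#' @return named list of `c(f_lo, f_hi)` pairs in Hz: delta 0-4, theta 4-8,
#'   alpha 8-12, beta 12-30, low-gamma 30-50.
#' @export
lfp_bands <- function() {
  list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), low_gamma = c(30, 50))
}

# Zero-phase low-pass FIR via frequency-domain convolution. The filter is a
# Hamming-windowed linear-phase FIR; applying it once and removing the group
# delay gives an exactly zero-phase result for the symmetric kernel.
fir_lowpass_zerophase <- function(x, fs, cutoff_hz, order = NULL) {
  if (is.null(order)) order <- max(128L, 2L * ceiling(fs / cutoff_hz) * 8L)
  if (order %% 2L == 1L) order <- order + 1L
  b <- signal::fir1(order, cutoff_hz / (fs / 2), type = "low")
  n <- length(x)
  gd <- order / 2L
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y[(gd + 1L):(gd + n)]
}

#' Preprocess a raw laminar LFP
#'
#' Zero-phase low-pass filtering below 200 Hz followed by resampling to
#' 1 kHz. Input already at 1 kHz is only filtered. The anti-alias condition
#' requires the raw sampling rate to accommodate the cutoff.
#'
#' @param raw a [laminar_lfp()].
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param target_fs output sampling rate, Hz.
#' @param fir_order FIR order (even); default scales with the sampling rate.
#' @return filtered, resampled [laminar_lfp()].
#' @export
preprocess_lfp <- function(raw, cutoff_hz = 200, target_fs = 1000,
                           fir_order = NULL) {
  stopifnot(inherits(raw, "laminar_lfp"))
  if (raw$fs < 2 * cutoff_hz)
    stop("preprocess_lfp: sampling rate too low for the requested cutoff")
  m <- raw$samples
  filt <- t(apply(m, 1, fir_lowpass_zerophase, fs = raw$fs,
                  cutoff_hz = cutoff_hz, order = fir_order))
  if (raw$fs == target_fs) {
    out <- raw; out$samples <- filt
    return(out)
  }
  n_out <- round(ncol(m) * target_fs / raw$fs)
  t_in <- (seq_len(ncol(m)) - 1) / raw$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  res <- t(apply(filt, 1, function(ch)
    stats::approx(t_in, ch, xout = t_out, rule = 2)$y))
  laminar_lfp(res, fs = target_fs, spacing_um = raw$spacing_um, t0 = raw$t0)
}

# One-sided PSD of a single tapered segment; taper must have unit energy
# after the scaling applied by the caller.
one_sided <- function(p, nf) {
  ps <- p[seq_len(nf)]
  if (nf > 2) ps[2:(nf - 1)] <- 2 * ps[2:(nf - 1)]
  ps
}

psd_welch_channel <- function(x, fs, window_s, overlap, fmax) {
  nw <- round(window_s * fs)
  if (length(x) < nw) stop("compute_psd: segment shorter than one window")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  u <- sum(w^2)
  nf <- floor(nw / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)]
    seg <- seg - mean(seg)
    X <- fft(seg * w)
    acc <- acc + one_sided(Mod(X)^2 / (fs * u), nf)
  }
  f <- (seq_len(nf) - 1) * fs / nw
  keep <- f <= fmax
  list(freq = f[keep], psd = (acc / length(starts))[keep])
}

psd_multitaper_channel <- function(x, fs, n_tapers, fmax) {
  n <- length(x)
  x <- x - mean(x)
  nf <- floor(n / 2) + 1L
  acc <- numeric(nf)
  tgrid <- seq_len(n)
  for (k in seq_len(n_tapers)) {
    v <- sqrt(2 / (n + 1)) * sin(pi * k * tgrid / (n + 1))
    X <- fft(x * v)
    acc <- acc + one_sided(Mod(X)^2 / fs, nf)
  }
  f <- (seq_len(nf) - 1) * fs / n
  keep <- f <= fmax
  list(freq = f[keep], psd = (acc / n_tapers)[keep])
}

#' Power spectral density of an LFP segment
#'
#' Per-channel one-sided PSD over 0 to `fmax` Hz (default 100), in uV^2/Hz.
#' The estimator (sine-taper multitaper, or Welch with Hann windows) is set
#' by [psd_params()].
#'
#' @param lfp a [laminar_lfp()] segment of at least 1 s.
#' @param params a [psd_params()] list.
#' @return list with `freq` (Hz) and `psd` (matrix `[n_channels x n_freq]`).
#' @export
compute_psd <- function(lfp, params = psd_params()) {
  stopifnot(inherits(lfp, "laminar_lfp"))
  if (ncol(lfp$samples) < lfp$fs)
    stop("compute_psd: segment must be at least 1 s")
  est <- function(x) {
    if (params$estimator == "welch")
      psd_welch_channel(x, lfp$fs, params$window_s, params$overlap, params$fmax)
    else
      psd_multitaper_channel(x, lfp$fs, params$n_tapers, params$fmax)
  }
  first <- est(lfp$samples[1, ])
  out <- matrix(0, nrow(lfp$samples), length(first$freq))
  out[1, ] <- first$psd
  if (nrow(lfp$samples) > 1)
    for (i in 2:nrow(lfp$samples)) out[i, ] <- est(lfp$samples[i, ])$psd
  list(freq = first$freq, psd = out)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoid rule over the grid points inside `[f_lo, f_hi]`.
#'
#' @param psd result of [compute_psd()].
#' @param band two-element numeric, Hz.
#' @return numeric vector, one band power per channel (uV^2).
#' @export
band_power <- function(psd, band) {
  if (band[2] <= band[1]) stop("band_power: empty band")
  keep <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(keep) < 2) stop("band_power: band not covered by PSD support")
  f <- psd$freq[keep]
  p <- psd$psd[, keep, drop = FALSE]
  df <- diff(f)
  as.numeric(p[, -ncol(p), drop = FALSE] %*% df / 2 +
               p[, -1, drop = FALSE] %*% df / 2)
}

#' Band powers per channel, band and state
#'
#' For each state epoch the PSD of the segment is estimated and integrated
#' over the five canonical bands; powers are averaged across epochs of the
#' same state.
#'
#' @param lfp a preprocessed [laminar_lfp()].
#' @param epochs a [state_epochs()] with synchronized/desynchronized entries.
#' @param params a [psd_params()] list.
#' @return data.frame (channel, band, state, power).
#' @export
band_power_table <- function(lfp, epochs, params = psd_params()) {
  stopifnot(inherits(lfp, "laminar_lfp"))
  bands <- lfp_bands()
  rows <- list()
  for (st in c("synchronized", "desynchronized")) {
    ep <- epochs[epochs$label == st, , drop = FALSE]
    if (nrow(ep) == 0) next
    acc <- NULL; used <- 0L
    for (i in seq_len(nrow(ep))) {
      idx <- bins_in_interval(ep$t_start[i], ep$t_end[i], lfp$t0, 1 / lfp$fs,
                              ncol(lfp$samples))
      if (length(idx) < lfp$fs) next
      seg <- lfp; seg$samples <- lfp$samples[, idx, drop = FALSE]
      psd <- compute_psd(seg, params)
      bp <- vapply(bands, function(b) band_power(psd, b),
                   numeric(nrow(lfp$samples)))
      acc <- if (is.null(acc)) bp else acc + bp
      used <- used + 1L
    }
    if (used == 0L) next
    bp <- acc / used
    for (b in names(bands))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = seq_len(nrow(lfp$samples)), band = b, state = st,
        power = bp[, b], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Low-frequency state index
#'
#' Sliding-window total power at 7 Hz and below on one (by default deep)
#' channel; the index drops during desynchronized episodes and recovers as
#' the slow oscillation returns.
#'
#' @param lfp a preprocessed [laminar_lfp()].
#' @param window_s window length, seconds (>= 1).
#' @param step_s step between window starts, seconds.
#' @param channel channel index; default four channels above the deepest.
#' @param fmax_hz upper band edge, Hz.
#' @return data.frame (time, power) with times at window centers.
#' @export
state_index <- function(lfp, window_s = 2, step_s = 0.5, channel = NULL,
                        fmax_hz = 7) {
  stopifnot(inherits(lfp, "laminar_lfp"), window_s >= 1)
  if (is.null(channel)) channel <- max(1L, nrow(lfp$samples) - 4L)
  x <- lfp$samples[channel, ]
  nw <- round(window_s * lfp$fs)
  if (nw > length(x)) stop("state_index: window longer than signal")
  starts <- seq(1L, length(x) - nw + 1L, by = max(1L, round(step_s * lfp$fs)))
  pw <- vapply(starts, function(s0) {
    seg <- x[s0:(s0 + nw - 1L)]
    sp <- psd_welch_channel(seg, lfp$fs, window_s = min(1, window_s),
                            overlap = 0.5, fmax = fmax_hz)
    f <- sp$freq; p <- sp$psd
    if (length(f) < 2) return(0)
    sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
  }, numeric(1))
  data.frame(time = lfp$t0 + (starts - 1 + nw / 2) / lfp$fs, power = pw)
}

#' State modulation index of band powers
#'
#' `(desynchronized - synchronized) / (desynchronized + synchronized)` per
#' channel and band.
#'
#' @param bp data.frame from [band_power_table()].
#' @return data.frame (channel, band, mi).
#' @export
band_power_state_mi <- function(bp) {
  s <- bp[bp$state == "synchronized", ]
  d <- bp[bp$state == "desynchronized", ]
  if (nrow(s) == 0 || nrow(d) == 0)
    stop("band_power_state_mi: both states required")
  key <- function(x) paste(x$channel, x$band)
  d <- d[match(key(s), key(d)), ]
  data.frame(channel = s$channel, band = s$band,
             mi = modulation_index(s$power, d$power),
             stringsAsFactors = FALSE)
}
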