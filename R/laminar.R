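#' CSD depth profile
#'
#' Current source density computed from a laminar LFP. Values follow the
#' convention that sinks (net inward transmembrane current, e.g. at the
#' thalamic recipient layer) are negative.
#'
#' @param values matrix `[n_channels x n_timepoints]`, uV per h^2 where h is
#'   the channel spacing.
#' @param fs sampling rate, Hz.
#' @param spacing_um channel spacing, um.
#' @param t0 session time of first sample, s.
#' @param aligned whether depth 0 has been assigned to a recipient channel.
#' @return object of class `csd_profile`.
#' @export
csd_profile <- function(values, fs, spacing_um, t0 = 0, aligned = FALSE) {
  structure(list(values = as.matrix(values), fs = fs,
                 spacing_um = spacing_um, t0 = t0, aligned = aligned),
            class = "csd_profile")
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile> %d channels x %d samples @ %g Hz%s\n",
              nrow(x$values), ncol(x$values), x$fs,
              if (x$aligned) ", aligned" else ""))
  invisible(x)
}

# Duplicate the uppermost and lowermost channels (Vaknin padding), giving a
# [n+2 x t] matrix whose interior rows are the original channels.
vaknin_pad <- function(m) rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])

#' Smooth an LFP across spatially adjacent channels
#'
#' Triangular spatial kernel applied at every channel after duplicating the
#' uppermost and lowermost channels:
#' `phi_s(r) = (phi(r - h) + 2 phi(r) + phi(r + h)) / 4`.
#' Reduces high spatial-frequency noise before the second spatial derivative.
#' The kernel sums to one, so constant and linear depth profiles pass through
#' unchanged on interior channels.
#'
#' @param lfp a [laminar_lfp()].
#' @return smoothed [laminar_lfp()] with the original channel count.
#' @export
smooth_depth <- function(lfp) {
  stopifnot(inherits(lfp, "laminar_lfp"))
  m <- lfp$samples
  if (nrow(m) < 2) stop("smooth_depth: need at least 2 channels")
  p <- vaknin_pad(m)
  n <- nrow(m)
  sm <- (p[1:n, , drop = FALSE] + 2 * p[2:(n + 1), , drop = FALSE] +
           p[3:(n + 2), , drop = FALSE]) / 4
  out <- lfp
  out$samples <- sm
  out
}

#' Compute the current source density of a laminar LFP
#'
#' Negated three-point second spatial difference,
#' `CSD(r, t) = -(phi(r + h, t) - 2 phi(r, t) + phi(r - h, t)) / h^2`,
#' with the boundary channels handled by duplicating the uppermost and
#' lowermost channels. Conductivity is taken as 1 (arbitrary units): only the
#' location of the extremum matters for laminar alignment. Negative values
#' denote current sinks. The pipeline applies [smooth_depth()] first.
#'
#' @param lfp a [laminar_lfp()] (ideally depth-smoothed).
#' @return a [csd_profile()] with the same channel count as the input.
#' @export
compute_csd <- function(lfp) {
  stopifnot(inherits(lfp, "laminar_lfp"))
  m <- lfp$samples
  if (nrow(m) < 3) stop("compute_csd: need at least 3 channels")
  p <- vaknin_pad(m)
  n <- nrow(m)
  h <- lfp$spacing_um
  d2 <- (p[3:(n + 2), , drop = FALSE] - 2 * p[2:(n + 1), , drop = FALSE] +
           p[1:n, , drop = FALSE]) / h^2
  csd_profile(-d2, fs = lfp$fs, spacing_um = h, t0 = lfp$t0)
}

#' Locate the thalamic recipient channel from click-evoked CSD
#'
#' Averages the CSD over click-triggered windows (default 0-50 ms after each
#' click) and returns the channel attaining the minimum of the average over
#' the window, i.e. the largest evoked sink. Ties break toward the more
#' superficial channel (smaller index).
#'
#' @param csd a [csd_profile()].
#' @param click_times click onset times, seconds (session clock).
#' @param window_ms two-element window relative to click onset, ms.
#' @return recipient channel index (1-based).
#' @export
find_recipient_channel <- function(csd, click_times, window_ms = c(0, 50)) {
  stopifnot(inherits(csd, "csd_profile"))
  if (length(click_times) < 1) stop("find_recipient_channel: no clicks in session")
  dt <- 1 / csd$fs
  nt <- ncol(csd$values)
  w0 <- window_ms[1] / 1000; w1 <- window_ms[2] / 1000
  acc <- matrix(0, nrow(csd$values), round((w1 - w0) * csd$fs))
  used <- 0L
  for (tc in click_times) {
    i0 <- round((tc + w0 - csd$t0) * csd$fs) + 1L
    idx <- i0:(i0 + ncol(acc) - 1L)
    if (idx[1] < 1 || idx[length(idx)] > nt) next
    acc <- acc + csd$values[, idx, drop = FALSE]
    used <- used + 1L
  }
  if (used == 0L) stop("find_recipient_channel: no clicks with a full window")
  avg <- acc / used
  prof <- apply(avg, 1, min)
  if (min(prof) >= 0 || diff(range(avg)) < 1e-12)
    stop("find_recipient_channel: no sink found")
  which.min(prof)
}

#' Assign relative depths to units from the recipient channel
#'
#' `relative_depth_um = (recipient_channel - depth_channel) * spacing_um`:
#' with channel 1 most superficial, units above the recipient layer get
#' positive depths and deeper units negative depths; a unit on the recipient
#' channel sits at 0 um.
#'
#' @param units a [unit_set()] with `depth_channel` filled.
#' @param recipient_channel channel index of the thalamic recipient layer.
#' @param spacing_um channel spacing, um.
#' @return [unit_set()] with `relative_depth_um` filled.
#' @export
assign_relative_depths <- function(units, recipient_channel, spacing_um = 50) {
  stopifnot(inherits(units, "unit_set"))
  out <- lapply(units$units, function(u) {
    if (!is.na(u$depth_channel))
      u$relative_depth_um <- (recipient_channel - u$depth_channel) * spacing_um
    u
  })
  unit_set(unname(out))
}

#' Estimate a unit's depth channel from its mean waveform
#'
#' Somatic location is taken as the channel with the maximum trough-to-peak
#' amplitude (per-channel max minus min of the mean waveform). Ties break
#' toward the superficial channel.
#'
#' @param mean_waveform matrix `[n_channels x n_wave_samples]`.
#' @return depth channel index (1-based).
#' @export
estimate_unit_depth <- function(mean_waveform) {
  m <- as.matrix(mean_waveform)
  amp <- apply(m, 1, max) - apply(m, 1, min)
  if (all(amp == 0)) stop("estimate_unit_depth: all-zero waveform")
  which.max(amp)
}
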