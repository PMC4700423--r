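#' Smoothed multiunit activity
#'
#' Population rate series: summed spike counts in fixed bins, smoothed with
#' a Gaussian kernel, expressed in Hz.
#'
#' @param rate_hz numeric vector of smoothed rates, Hz.
#' @param bin_ms bin width, ms.
#' @param kernel_ms Gaussian kernel SD, ms.
#' @param t0 time of the first bin's left edge, seconds.
#' @param n_units number of source units.
#' @return object of class `smoothed_mua`.
#' @export
smoothed_mua <- function(rate_hz, bin_ms = 1, kernel_ms = 10, t0 = 0,
                         n_units = NA_integer_) {
  if (any(rate_hz < -1e-9)) stop("smoothed_mua: rates must be >= 0")
  structure(list(rate_hz = pmax(rate_hz, 0), bin_ms = bin_ms,
                 kernel_ms = kernel_ms, t0 = t0, n_units = n_units),
            class = "smoothed_mua")
}

#' @export
print.smoothed_mua <- function(x, ...) {
  cat(sprintf("<smoothed_mua> %d bins of %g ms, kernel SD %g ms\n",
              length(x$rate_hz), x$bin_ms, x$kernel_ms))
  invisible(x)
}

#' Compute smoothed multiunit activity from spike trains
#'
#' Sums the selected units' spike counts in 1 ms bins and convolves with a
#' unit-area Gaussian kernel (SD 10 ms, truncated at +/- 4 SD), so the
#' integral of the rate over time equals the total spike count.
#'
#' @param spikes a [spike_train_set()].
#' @param unit_ids units to include; default all.
#' @param bin_ms bin width, ms.
#' @param kernel_ms kernel SD, ms.
#' @param t_end end of the binned range, seconds; default last spike.
#' @return a [smoothed_mua()].
#' @export
compute_mua <- function(spikes, unit_ids = NULL, bin_ms = 1, kernel_ms = 10,
                        t_end = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(unit_ids)) unit_ids <- names(spikes$spikes)
  unit_ids <- intersect(unit_ids, names(spikes$spikes))
  if (length(unit_ids) == 0) stop("compute_mua: empty unit set")
  all_t <- unlist(spikes$spikes[unit_ids], use.names = FALSE)
  if (is.null(t_end)) t_end <- if (length(all_t)) max(all_t) + 0.1 else 1
  dt <- bin_ms / 1000
  nb <- ceiling(t_end / dt)
  counts <- numeric(nb)
  if (length(all_t)) {
    idx <- pmin(nb, floor(all_t / dt) + 1L)
    tab <- tabulate(idx, nbins = nb)
    counts <- tab
  }
  k <- gaussian_kernel(kernel_ms / bin_ms)
  sm <- smooth_vector(counts, k)
  smoothed_mua(sm / dt, bin_ms = bin_ms, kernel_ms = kernel_ms, t0 = 0,
               n_units = length(unit_ids))
}

# Logical per-bin mask from an interval data.frame (t_start, t_end).
mask_from_intervals <- function(intervals, t0, dt, n) {
  m <- logical(n)
  for (i in seq_len(nrow(intervals)))
    m[bins_in_interval(intervals$t_start[i], intervals$t_end[i], t0, dt, n)] <- TRUE
  m
}

#' Detect UP states from smoothed multiunit activity
#'
#' The threshold is the geometric mean of the smoothed MUA over all
#' spontaneous (stimulus-free) bins; since the geometric mean is undefined
#' over silent bins, it is computed over bins exceeding a positivity floor of
#' half of a single spike's peak kernel contribution. An onset is accepted at
#' bin t if (i) the MUA crosses above the threshold (previous bin at or below
#' it, current bin above), (ii) the mean MUA over the 100 ms before t is
#' below 20% of the threshold, and (iii) the MUA stays above the threshold in
#' every bin of the 200 ms after t. Each accepted UP state is reported as the
#' 200 ms window `[t, t + 0.2]`, the window used for UP-state firing-rate
#' estimation. Detected epochs never intersect masked-out periods.
#'
#' @param mua a [smoothed_mua()].
#' @param spontaneous_mask either a logical vector (one entry per MUA bin) or
#'   a data.frame of stimulus-free intervals (`t_start`, `t_end`, seconds).
#' @param pre_ms silence window before onset, ms.
#' @param pre_frac silence criterion as a fraction of the threshold.
#' @param post_ms window after onset that must remain above threshold, ms.
#' @param post_rule `"all"` (every bin above threshold, the strict reading)
#'   or `"mean"` (mean above threshold).
#' @param floor_hz positivity floor for the geometric mean; by default half
#'   of a single spike's peak kernel contribution, appropriate for
#'   spike-count MUA. Supply a small positive value when the MUA is a
#'   deterministic rate trace rather than binned spikes.
#' @return a [state_epochs()] of `up_state` entries, plus the threshold in
#'   attribute `"threshold"`.
#' @export
detect_up_states <- function(mua, spontaneous_mask, pre_ms = 100,
                             pre_frac = 0.2, post_ms = 200,
                             post_rule = c("all", "mean"), floor_hz = NULL) {
  stopifnot(inherits(mua, "smoothed_mua"))
  post_rule <- match.arg(post_rule)
  r <- mua$rate_hz
  n <- length(r)
  dt <- mua$bin_ms / 1000
  if (all(r == 0)) stop("detect_up_states: no activity")
  mask <- if (is.logical(spontaneous_mask)) spontaneous_mask
          else mask_from_intervals(spontaneous_mask, mua$t0, dt, n)
  if (length(mask) != n) stop("detect_up_states: mask length mismatch")
  if (!any(mask)) stop("detect_up_states: empty spontaneous mask")
  if (is.null(floor_hz)) {
    k <- gaussian_kernel(mua$kernel_ms / mua$bin_ms)
    floor_hz <- 0.5 * max(k) / dt
  }
  base <- r[mask & r > floor_hz]
  if (length(base) == 0) stop("detect_up_states: no suprafloor spontaneous activity")
  theta <- exp(mean(log(base)))
  npre <- round(pre_ms / mua$bin_ms)
  npost <- round(post_ms / mua$bin_ms)
  cross <- which(r[-1] > theta & r[-n] <= theta) + 1L
  onsets <- numeric(0)
  last_end <- -Inf
  for (i in cross) {
    if (i - npre < 1 || i + npost - 1 > n) next
    if (!all(mask[(i - npre):(i + npost - 1)])) next
    if (mean(r[(i - npre):(i - 1)]) >= pre_frac * theta) next
    post <- r[i:(i + npost - 1)]
    ok <- if (post_rule == "all") all(post > theta) else mean(post) > theta
    if (!ok) next
    t_on <- mua$t0 + (i - 1) * dt
    if (t_on < last_end) next
    onsets <- c(onsets, t_on)
    last_end <- t_on + post_ms / 1000
  }
  ep <- state_epochs(data.frame(t_start = onsets,
                                t_end = onsets + post_ms / 1000,
                                label = rep("up_state", length(onsets))))
  attr(ep, "threshold") <- theta
  ep
}

#' Construct synchronized/desynchronized epochs around BF stimulations
#'
#' For spontaneous analyses each stimulation contributes a synchronized
#' window `[bf_on - w, bf_on)` and a desynchronized window starting at
#' `bf_off` of the same length `w` (default 3 s), truncated at the next
#' `bf_on` and capped by the configured duration of the desynchronized
#' episode. Trials of evoked analyses are labeled by their block kind
#' (`stim` = desynchronized, `no_stim` = synchronized); see [event_states()].
#'
#' @param events an [event_table()].
#' @param spont_window_s spontaneous window length, seconds.
#' @param desync_len_s assumed duration of the desynchronized episode after
#'   `bf_off`, seconds.
#' @return a [state_epochs()].
#' @export
define_state_epochs <- function(events, spont_window_s = 3, desync_len_s = 10) {
  on <- events$time_s[events$kind == "bf_on"]
  off <- events$time_s[events$kind == "bf_off"]
  if (length(on) == 0) {
    warning("define_state_epochs: no bf events; returning empty epochs")
    return(state_epochs())
  }
  w <- min(spont_window_s, desync_len_s)
  rows <- list()
  for (i in seq_along(on)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t_start = on[i] - spont_window_s, t_end = on[i], label = "synchronized")
    d_end <- off[i] + w
    nxt <- on[on > off[i]]
    if (length(nxt)) d_end <- min(d_end, min(nxt))
    if (d_end > off[i])
      rows[[length(rows) + 1L]] <- data.frame(
        t_start = off[i], t_end = d_end, label = "desynchronized")
  }
  state_epochs(do.call(rbind, rows))
}

#' State label of each stimulus event from its block kind
#'
#' @param events an [event_table()].
#' @param kinds event kinds to label (default clicks and train onsets).
#' @return data.frame (time_s, kind, train_hz, state).
#' @export
event_states <- function(events, kinds = c("click", "train_onset")) {
  ev <- events[events$kind %in% kinds, , drop = FALSE]
  st <- ifelse(ev$block_kind == "stim", "desynchronized", "synchronized")
  data.frame(time_s = ev$time_s, kind = ev$kind, train_hz = ev$train_hz,
             state = st, stringsAsFactors = FALSE)
}
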