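#' State modulation index
#'
#' `(desync - sync) / (desync + sync)`: a bounded, symmetric change score in
#' [-1, 1]. Undefined (NA) when both inputs are zero; such units are excluded
#' from averages rather than scored 0. The UP-state variant
#' `(up - desync) / (up + desync)` is exposed as [up_vs_desync_index()].
#'
#' @param sync_value value in the synchronized state (>= 0).
#' @param desync_value value in the desynchronized state (>= 0).
#' @return modulation index, vectorised.
#' @export
modulation_index <- function(sync_value, desync_value) {
  s <- as.numeric(sync_value); d <- as.numeric(desync_value)
  if (any(s < 0 | d < 0, na.rm = TRUE))
    stop("modulation_index: values must be >= 0")
  out <- (d - s) / (d + s)
  out[(s + d) == 0] <- NA_real_
  out
}

#' @rdname modulation_index
#' @param up_value value during UP states (>= 0).
#' @export
up_vs_desync_index <- function(up_value, desync_value) {
  u <- as.numeric(up_value); d <- as.numeric(desync_value)
  if (any(u < 0 | d < 0, na.rm = TRUE))
    stop("up_vs_desync_index: values must be >= 0")
  out <- (u - d) / (u + d)
  out[(u + d) == 0] <- NA_real_
  out
}

# Spike count of one train in a half-open window [onset + a, onset + b).
count_in_window <- function(t_spikes, onset, window_s) {
  sum(in_window(t_spikes, onset + window_s[1], onset + window_s[2]))
}

#' Per-trial spike counts by state
#'
#' Counts spikes of one unit in a half-open window relative to each event
#' onset (default the first 100 ms, the onset-response window), grouped by
#' the trial's state label.
#'
#' @param t_spikes spike times of one unit, seconds.
#' @param onsets event onset times, seconds.
#' @param states state label per onset (`synchronized`/`desynchronized`).
#' @param window_ms half-open window relative to onset, ms.
#' @return data.frame (state, onset, count).
#' @export
trial_counts <- function(t_spikes, onsets, states, window_ms = c(0, 100)) {
  stopifnot(length(onsets) == length(states))
  if (length(onsets) == 0) stop("trial_counts: no events")
  w <- window_ms / 1000
  counts <- vapply(onsets, function(o) count_in_window(t_spikes, o, w),
                   numeric(1))
  data.frame(state = states, onset = onsets, count = counts,
             stringsAsFactors = FALSE)
}

#' Fano factor of trial spike counts
#'
#' Variance over mean of per-trial counts, with the unbiased (n - 1)
#' variance; 1 for a Poisson process, 0 for deterministic counts, NA when the
#' mean count is zero.
#'
#' @param counts integer vector of per-trial spike counts.
#' @return Fano factor.
#' @export
fano <- function(counts) {
  m <- mean(counts)
  if (length(counts) < 2 || m == 0) return(NA_real_)
  var(counts) / m
}

#' Onset statistics (mean, variance, Fano) per state
#'
#' @param tc data.frame from [trial_counts()].
#' @return data.frame (state, n_trials, mu, var, fano).
#' @export
onset_stats <- function(tc) {
  do.call(rbind, lapply(split(tc, tc$state), function(g)
    data.frame(state = g$state[1], n_trials = nrow(g), mu = mean(g$count),
               var = if (nrow(g) > 1) var(g$count) else NA_real_,
               fano = fano(g$count), stringsAsFactors = FALSE)))
}

#' Keep units responsive in both states
#'
#' A unit is retained when it spiked at least once inside the onset window
#' (default 0-100 ms) in each state separately.
#'
#' @param spikes a [spike_train_set()].
#' @param onsets event onsets, seconds.
#' @param states state label per onset.
#' @param window_ms onset window, ms.
#' @return character vector of retained unit ids.
#' @export
responsive_filter <- function(spikes, onsets, states, window_ms = c(0, 100)) {
  stopifnot(inherits(spikes, "spike_train_set"))
  keep <- vapply(names(spikes$spikes), function(id) {
    tc <- trial_counts(spikes$spikes[[id]], onsets, states, window_ms)
    tot <- tapply(tc$count, tc$state, sum)
    length(tot) == 2 && all(tot > 0)
  }, logical(1))
  if (!any(keep)) warning("responsive_filter: no responsive units")
  names(spikes$spikes)[keep]
}

#' Mean spike time in a post-onset window
#'
#' Mean latency of all spikes of all trials falling in the half-open window
#' (default 80-200 ms, the suppression/rebound window), pooled over spikes.
#'
#' @param t_spikes spike times of one unit, seconds.
#' @param onsets event onsets, seconds.
#' @param window_ms window relative to onset, ms.
#' @return mean spike time, ms; NA when no spikes fall in the window.
#' @export
mean_spike_time <- function(t_spikes, onsets, window_ms = c(80, 200)) {
  w <- window_ms / 1000
  lat <- unlist(lapply(onsets, function(o) {
    d <- t_spikes - o
    d[in_window(d, w[1], w[2])]
  }))
  if (length(lat) == 0) return(NA_real_)
  mean(lat) * 1000
}

#' Peak-normalized PSTH
#'
#' Trial-averaged firing rate in 1 ms bins over a peri-stimulus window,
#' Gaussian-smoothed (SD 5 ms) and divided by its peak, together with the
#' peak latency used for sorting response profiles.
#'
#' @param t_spikes spike times of one unit, seconds.
#' @param onsets event onsets, seconds.
#' @param window_ms peri-stimulus window, ms.
#' @param bin_ms bin width, ms.
#' @param kernel_ms smoothing kernel SD, ms.
#' @return list (`time_ms`, `profile` in [0, 1], `peak_latency_ms`), or NULL
#'   when no spikes fall in the window.
#' @export
normalized_psth <- function(t_spikes, onsets, window_ms = c(-50, 300),
                            bin_ms = 1, kernel_ms = 5) {
  if (length(onsets) == 0) stop("normalized_psth: no events")
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (o in onsets) {
    d <- (t_spikes - o) * 1000
    d <- d[in_window(d, window_ms[1], window_ms[2])]
    if (length(d))
      counts <- counts + tabulate(floor((d - window_ms[1]) / bin_ms) + 1L, nb)
  }
  if (sum(counts) == 0) return(NULL)
  rate <- counts / length(onsets) / (bin_ms / 1000)
  sm <- smooth_vector(rate, gaussian_kernel(kernel_ms / bin_ms))
  pk <- which.max(sm)
  list(time_ms = edges[-length(edges)] + bin_ms / 2, profile = sm / sm[pk],
       peak_latency_ms = edges[pk] + bin_ms / 2)
}

# Binned (1 ms) and Gaussian-smoothed (SD 5 ms) spike vectors over a set of
# windows, smoothing applied within each window so nothing leaks across
# concatenation joints. Returns a [total_bins x n_units] matrix.
smoothed_count_matrix <- function(spikes, unit_ids, windows, bin_ms = 1,
                                  kernel_ms = 5) {
  dt <- bin_ms / 1000
  k <- gaussian_kernel(kernel_ms / bin_ms)
  nb <- round((windows$t_end - windows$t_start) / dt)
  out <- matrix(0, sum(nb), length(unit_ids))
  colnames(out) <- unit_ids
  for (j in seq_along(unit_ids)) {
    ts <- spikes$spikes[[unit_ids[j]]]
    pos <- 0L
    for (i in seq_len(nrow(windows))) {
      d <- ts - windows$t_start[i]
      d <- d[d >= 0 & d < nb[i] * dt]
      cnt <- if (length(d)) tabulate(floor(d / dt) + 1L, nb[i]) else numeric(nb[i])
      out[(pos + 1L):(pos + nb[i]), j] <- smooth_vector(cnt, k)
      pos <- pos + nb[i]
    }
  }
  out
}

#' Pairwise spike-count correlation over state windows
#'
#' Each train is binned at 1 ms inside each window, smoothed with a 5 ms SD
#' Gaussian kernel within the window, the windows concatenated, and the
#' Pearson correlation computed over the concatenated vectors.
#'
#' @param t_i,t_j spike times of the two units, seconds.
#' @param windows data.frame (`t_start`, `t_end`) of same-state windows.
#' @param bin_ms bin width, ms.
#' @param kernel_ms kernel SD, ms.
#' @return Pearson r, or NA when either smoothed vector has zero variance.
#' @export
spike_count_correlation <- function(t_i, t_j, windows, bin_ms = 1,
                                    kernel_ms = 5) {
  sts <- spike_train_set(list(a = t_i, b = t_j))
  m <- smoothed_count_matrix(sts, c("a", "b"), windows, bin_ms, kernel_ms)
  if (sd(m[, 1]) == 0 || sd(m[, 2]) == 0) return(NA_real_)
  cor(m[, 1], m[, 2])
}
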