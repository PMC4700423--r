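#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed to recover:
#' a synchronized state with slow (UP/DOWN) alternation and deep-weighted
#' low-frequency LFP power; a desynchronized episode of ~10 s after each
#' basal-forebrain (BF) stimulation offset with attenuated low-frequency
#' power and a superficial 30-50 Hz component; lower spontaneous rates of
#' superficial (BS1) and deep (BS4) broad-spiking cells when desynchronized;
#' onset responses decreased for broad-spiking and increased for
#' narrow-spiking cortical cells when desynchronized; an earlier
#' post-suppression rebound in cortex when desynchronized (thalamus
#' unchanged); and click-train phase locking whose von Mises concentration
#' rises with desynchronization in cortex but not in thalamus. Overrides are
#' merged into the defaults; unknown keys are rejected.
#'
#' @param ... named overrides of top-level keys or nested sub-lists.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_channels = 32L, fs = 1000, spacing_um = 50, wave_fs = 20000,
    recipient_channel = 8L,
    n_units = list(NS = 12L, BS1 = 10L, BS2 = 12L, BS3 = 14L, BS4 = 12L,
                   MGB = 20L),
    design = list(
      n_spont_stims = 8L, spont_pre_s = 10, bf_len_s = 1,
      n_click_rounds = 4L, click_trials_per_block = 10L,
      nostim_trial_s = 2, stim_trial_s = 3, stim_train_trial_s = 3.5,
      recovery_s = 12, train_hz = c(4, 8, 16, 32, 64),
      train_presentations = 10L, train_len_s = 1, click_level_db = 70,
      tail_s = 5),
    states = list(desync_len_s = 10, up_median_s = 0.4, down_median_s = 0.3,
                  updown_sdlog = 0.4),
    lfp = list(noise_amp = 20, slow_hz = 1.2, sync_slow_amp = 300,
               desync_slow_amp = 0, gamma_hz = 40, sync_gamma_amp = 0,
               desync_gamma_amp = 40, gamma_depth_sd_ch = 4,
               crossfade_ms = 100, sink_amp = 200, sink_latency_ms = 12,
               sink_width_ms = 5, sink_spatial_sd_ch = 1.2),
    rates = list(
      NS  = list(r_up = 12, r_down = 0.3, r_desync = 8),
      BS1 = list(r_up = 5, r_down = 0.1, r_desync = 1.2),
      BS2 = list(r_up = 6, r_down = 0.15, r_desync = 3.5),
      BS3 = list(r_up = 7, r_down = 0.15, r_desync = 4.5),
      BS4 = list(r_up = 4, r_down = 0.1, r_desync = 1.0),
      MGB = list(r_up = 8, r_down = 8, r_desync = 8)),
    evoked = list(
      onset_t_ms = 15, onset_sd_ms = 6, gate_down = 0.35,
      ac_ns_onset = c(sync = 50, desync = 80),
      ac_bs_onset = c(sync = 80, desync = 25),
      mgb_onset = c(sync = 70, desync = 60),
      supp_factor = 0.15, supp_start_ms = 40, supp_end_gap_ms = 30,
      rebound_amp = 20, rebound_sd_ms = 15,
      ac_rebound_t_ms = c(sync = 150, desync = 115)),
    trains = list(
      ac_spikes_per_click = 0.45, mgb_spikes_per_click = 0.5,
      ac_kappa = c(sync = 1.2, desync = 3.0),
      mgb_kappa = c(sync = 3.0, desync = 3.0)),
    waveforms = list(noise_sd = 0, spatial_sd_ch = 1.5, trough_amp = 100,
                     peak_frac = 0.45, wave_len_ms = 3),
    quality = list(min = 25, max = 60))
  ov <- list(...)
  for (k in names(ov)) {
    if (!k %in% names(cfg)) stop(sprintf("sim_config: unknown key '%s'", k))
    if (is.list(cfg[[k]]) && is.list(ov[[k]])) {
      bad <- setdiff(names(ov[[k]]), names(cfg[[k]]))
      if (length(bad)) stop(sprintf("sim_config: unknown key '%s$%s'", k, bad[1]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], ov[[k]])
    } else cfg[[k]] <- ov[[k]]
  }
  structure(cfg, class = "sim_config")
}

# Event table for the default block design: a spontaneous section of
# isolated BF stimulations, then click blocks alternating no-stim/stim, then
# click-train blocks per frequency. Deterministic (no RNG).
build_events <- function(cfg) {
  d <- cfg$design
  rows <- list()
  add <- function(time_s, kind, level_db = NA_real_, train_hz = NA_real_,
                  block_id = NA_character_, block_kind = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      time_s = time_s, kind = kind, level_db = level_db, train_hz = train_hz,
      block_id = block_id, block_kind = block_kind, stringsAsFactors = FALSE)
  }
  cur <- 0
  for (i in seq_len(d$n_spont_stims)) {
    on <- cur + d$spont_pre_s
    add(on, "bf_on", block_id = "spont", block_kind = "stim")
    add(on + d$bf_len_s, "bf_off", block_id = "spont", block_kind = "stim")
    cur <- on + d$bf_len_s + cfg$states$desync_len_s
  }
  for (r in seq_len(d$n_click_rounds)) {
    bid <- sprintf("click_ns_%d", r)
    for (k in seq_len(d$click_trials_per_block)) {
      add(cur + 0.5, "click", d$click_level_db, block_id = bid,
          block_kind = "no_stim")
      cur <- cur + d$nostim_trial_s
    }
    bid <- sprintf("click_st_%d", r)
    for (k in seq_len(d$click_trials_per_block)) {
      add(cur, "bf_on", block_id = bid, block_kind = "stim")
      add(cur + d$bf_len_s, "bf_off", block_id = bid, block_kind = "stim")
      add(cur + 1.5, "click", d$click_level_db, block_id = bid,
          block_kind = "stim")
      cur <- cur + d$stim_trial_s
    }
    cur <- cur + d$recovery_s
  }
  for (hz in d$train_hz) {
    bid <- sprintf("train%d_ns", hz)
    for (k in seq_len(d$train_presentations)) {
      add(cur + 0.5, "train_onset", d$click_level_db, hz, bid, "no_stim")
      add(cur + 0.5 + d$train_len_s, "train_offset", block_id = bid,
          block_kind = "no_stim")
      cur <- cur + d$nostim_trial_s
    }
    bid <- sprintf("train%d_st", hz)
    for (k in seq_len(d$train_presentations)) {
      add(cur, "bf_on", block_id = bid, block_kind = "stim")
      add(cur + d$bf_len_s, "bf_off", block_id = bid, block_kind = "stim")
      add(cur + 1.5, "train_onset", d$click_level_db, hz, bid, "stim")
      add(cur + 1.5 + d$train_len_s, "train_offset", block_id = bid,
          block_kind = "stim")
      cur <- cur + d$stim_train_trial_s
    }
    cur <- cur + d$recovery_s
  }
  list(events = event_table(do.call(rbind, rows)),
       duration_s = cur + d$tail_s)
}

#' Synchronized/desynchronized schedule implied by BF stimulation events
#'
#' Desynchronized intervals start at each `bf_off` and last `desync_len_s`
#' (truncated at the next `bf_on`); the remainder of the session, outside
#' stimulation pulses, is synchronized. The schedule covers the session
#' without gaps.
#'
#' @param events an [event_table()].
#' @param duration_s session length, seconds.
#' @param desync_len_s desynchronized episode length after `bf_off`, s.
#' @return data.frame (t_start, t_end, label).
#' @export
state_schedule_from_events <- function(events, duration_s, desync_len_s = 10) {
  on <- events$time_s[events$kind == "bf_on"]
  off <- events$time_s[events$kind == "bf_off"]
  des <- list()
  for (i in seq_along(off)) {
    e <- off[i] + desync_len_s
    nxt <- on[on > off[i]]
    if (length(nxt)) e <- min(e, min(nxt))
    des[[i]] <- c(off[i], min(e, duration_s))
  }
  # merge desync with the 1 s stimulation pulses treated as desynchronized
  # onset (the pulse itself is not analyzed)
  iv <- do.call(rbind, des)
  if (length(on)) iv <- rbind(iv, cbind(on, off))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(iv))) {
    if (length(merged) && iv[i, 1] <= merged[[length(merged)]][2])
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], iv[i, 2])
    else merged[[length(merged) + 1L]] <- iv[i, ]
  }
  rows <- list(); cur <- 0
  for (m in merged) {
    if (m[1] > cur)
      rows[[length(rows) + 1L]] <- data.frame(t_start = cur, t_end = m[1],
                                              label = "synchronized")
    rows[[length(rows) + 1L]] <- data.frame(t_start = m[1], t_end = m[2],
                                            label = "desynchronized")
    cur <- m[2]
  }
  if (cur < duration_s)
    rows[[length(rows) + 1L]] <- data.frame(t_start = cur, t_end = duration_s,
                                            label = "synchronized")
  do.call(rbind, rows)
}

#' Simulate an alternating UP/DOWN interval schedule
#'
#' Log-normal UP and DOWN durations (medians 400 and 300 ms by default)
#' alternate across `[t_start, t_end)`, starting with a DOWN interval; the
#' last interval is truncated at `t_end`.
#'
#' @param t_start,t_end interval bounds, seconds.
#' @param up_median_s,down_median_s median durations, seconds.
#' @param sdlog log-scale SD of both duration distributions.
#' @return data.frame (t_start, t_end) of UP intervals.
#' @export
simulate_updown_schedule <- function(t_start, t_end, up_median_s = 0.4,
                                     down_median_s = 0.3, sdlog = 0.4) {
  ups <- list()
  cur <- t_start
  up <- FALSE
  while (cur < t_end) {
    med <- if (up) up_median_s else down_median_s
    len <- rlnorm(1, meanlog = log(med), sdlog = sdlog)
    nxt <- min(cur + len, t_end)
    if (up) ups[[length(ups) + 1L]] <- data.frame(t_start = cur, t_end = nxt)
    cur <- nxt
    up <- !up
  }
  if (length(ups)) do.call(rbind, ups)
  else data.frame(t_start = numeric(0), t_end = numeric(0))
}

# 1/f-shaped noise of length n via FFT spectral shaping, unit SD.
pink_noise <- function(n, floor_hz = 1, fs = 1000) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  X <- X / sqrt(pmax(f, floor_hz))
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sd(y)
}

# Raised-edge state envelope: indicator of the given label smoothed with a
# Gaussian so the two state components cross-fade at boundaries.
state_envelope <- function(schedule, label, n, fs, crossfade_ms) {
  iv <- schedule[schedule$label == label, , drop = FALSE]
  env <- as.numeric(mask_from_intervals(iv, 0, 1 / fs, n))
  if (!any(env > 0)) return(env)
  smooth_vector(env, gaussian_kernel(crossfade_ms / 1000 * fs / 4))
}

#' Simulate a state-dependent laminar LFP
#'
#' Synchronized intervals carry a slow (~1 Hz) oscillation whose amplitude
#' grows with depth, on top of 1/f background noise on every channel;
#' desynchronized intervals suppress the slow component and add a narrowband
#' 30-50 Hz (default 40 Hz) component whose amplitude decays with depth from
#' the most superficial channel. Components cross-fade at state boundaries
#' so the trace is continuous.
#'
#' @param schedule data.frame (t_start, t_end, label) covering the session.
#' @param n_channels number of probe channels.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @param cfg a [sim_config()] (its `lfp` block is used).
#' @return a [laminar_lfp()].
#' @export
simulate_state_lfp <- function(schedule, n_channels, fs, seed,
                               cfg = sim_config()) {
  if (nrow(schedule) == 0) stop("simulate_state_lfp: empty schedule")
  set.seed(seed)
  p <- cfg$lfp
  dur <- max(schedule$t_end)
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  env_sync <- state_envelope(schedule, "synchronized", n, fs, p$crossfade_ms)
  env_des <- state_envelope(schedule, "desynchronized", n, fs, p$crossfade_ms)
  slow <- sin(2 * pi * p$slow_hz * tt + runif(1, 0, 2 * pi))
  slow_st <- slow * (p$sync_slow_amp * env_sync + p$desync_slow_amp * env_des)
  gam <- sin(2 * pi * p$gamma_hz * tt + runif(1, 0, 2 * pi))
  gam_am <- 1 + 0.3 * smooth_vector(rnorm(n), gaussian_kernel(0.2 * fs))
  gam_st <- gam * gam_am * (p$sync_gamma_amp * env_sync +
                              p$desync_gamma_amp * env_des)
  depth_w <- 0.25 + 0.75 * (seq_len(n_channels) - 1) / (n_channels - 1)
  sup_w <- exp(-(seq_len(n_channels) - 1)^2 / (2 * p$gamma_depth_sd_ch^2))
  m <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    m[ch, ] <- p$noise_amp * pink_noise(n, fs = fs) +
      depth_w[ch] * slow_st + sup_w[ch] * gam_st
  }
  laminar_lfp(m, fs = fs, spacing_um = cfg$spacing_um, t0 = 0)
}

# Add a click-evoked current sink: a negative potential deflection, Gaussian
# in time (latency/width from config) and Gaussian across channels centered
# on the recipient channel, after every click time.
add_evoked_sinks <- function(lfp, click_times, recipient_channel, cfg) {
  p <- cfg$lfp
  fs <- lfp$fs
  tk <- seq(-4 * p$sink_width_ms, 4 * p$sink_width_ms) / 1000  # s, 1 ms grid
  tk <- seq(round(-4 * p$sink_width_ms * fs / 1000),
            round(4 * p$sink_width_ms * fs / 1000)) / fs
  bump <- exp(-tk^2 / (2 * (p$sink_width_ms / 1000)^2))
  chs <- seq_len(nrow(lfp$samples))
  spat <- exp(-(chs - recipient_channel)^2 / (2 * p$sink_spatial_sd_ch^2))
  n <- ncol(lfp$samples)
  for (tc in click_times) {
    i0 <- round((tc + p$sink_latency_ms / 1000) * fs) + 1L
    idx <- i0 + seq_along(tk) - 1L - (length(tk) - 1L) %/% 2L
    ok <- idx >= 1 & idx <= n
    if (!any(ok)) next
    lfp$samples[, idx[ok]] <- lfp$samples[, idx[ok]] -
      p$sink_amp * outer(spat, bump[ok])
  }
  lfp
}

#' Simulate mean spike waveforms for a set of units
#'
#' Biphasic template (Gaussian trough followed by a smaller Gaussian peak at
#' the unit's true trough-to-peak delay), largest on the unit's true depth
#' channel with Gaussian spatial amplitude decay across channels, plus
#' optional white noise.
#'
#' @param units data.frame with columns `depth_channel` and `ttp_ms`.
#' @param n_channels probe channel count.
#' @param wave_fs waveform sampling rate, Hz.
#' @param seed RNG seed.
#' @param cfg a [sim_config()] (its `waveforms` block is used).
#' @return list of `[n_channels x n_wave_samples]` matrices.
#' @export
simulate_waveforms <- function(units, n_channels, wave_fs, seed,
                               cfg = sim_config()) {
  set.seed(seed)
  p <- cfg$waveforms
  if (any(units$depth_channel < 1 | units$depth_channel > n_channels))
    stop("simulate_waveforms: depth channel out of range")
  ns <- round(p$wave_len_ms / 1000 * wave_fs)
  tt <- (seq_len(ns) - 1) / wave_fs * 1000   # ms
  t_tr <- 0.8
  lapply(seq_len(nrow(units)), function(i) {
    ttp <- units$ttp_ms[i]
    shape <- -exp(-(tt - t_tr)^2 / (2 * 0.08^2)) +
      p$peak_frac * exp(-(tt - t_tr - ttp)^2 / (2 * 0.15^2))
    chs <- seq_len(n_channels)
    spat <- exp(-(chs - units$depth_channel[i])^2 / (2 * p$spatial_sd_ch^2))
    w <- p$trough_amp * outer(spat, shape)
    if (p$noise_sd > 0) w <- w + rnorm(length(w), sd = p$noise_sd)
    w
  })
}

# Label lookup helpers on a schedule / interval set.
in_any_interval <- function(t, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  i <- findInterval(t, iv$t_start)
  i > 0 & t < iv$t_end[pmax(i, 1)]
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson process on a 1 ms rate grid: synchronized intervals
#' alternate between the unit's UP and DOWN rates following the shared
#' population UP/DOWN schedule; desynchronized intervals are tonic at the
#' unit's desynchronized rate. Around each single click the rate follows the
#' state- and class-specific template (onset peak, suppression of the
#' background, rebound), scaled in the synchronized state by the UP/DOWN
#' gate at click time. During click trains, each click additionally evokes a
#' Poisson number of locked spikes whose phases within the inter-click
#' interval are von Mises with the unit's state-specific concentration
#' (phase 0 at click onset).
#'
#' @param unit one-row data.frame of ground-truth unit parameters (as built
#'   by [simulate_session()]).
#' @param schedule data.frame (t_start, t_end, label) including `up_state`
#'   rows for the shared UP/DOWN alternation.
#' @param events an [event_table()].
#' @param seed RNG seed for this unit.
#' @param cfg a [sim_config()].
#' @return numeric vector of strictly increasing spike times, seconds.
#' @export
simulate_spikes <- function(unit, schedule, events, seed, cfg = sim_config()) {
  set.seed(seed)
  dur <- max(schedule$t_end)
  dt <- 1e-3
  n <- round(dur / dt)
  tmid <- (seq_len(n) - 0.5) * dt
  des_iv <- schedule[schedule$label == "desynchronized", , drop = FALSE]
  up_iv <- schedule[schedule$label == "up_state", , drop = FALSE]
  des <- mask_from_intervals(des_iv, 0, dt, n)
  up <- mask_from_intervals(up_iv, 0, dt, n)
  rate <- ifelse(des, unit$r_desync, ifelse(up, unit$r_up, unit$r_down))

  ev <- cfg$evoked
  gate_at <- function(t) {
    if (unit$area == "MGB") return(rep(1, length(t)))
    ifelse(in_any_interval(t, des_iv) | in_any_interval(t, up_iv),
           1, ev$gate_down)
  }
  clicks <- events[events$kind == "click", , drop = FALSE]
  if (nrow(clicks)) {
    st <- ifelse(clicks$block_kind == "stim", "desync", "sync")
    g <- gate_at(clicks$time_s)
    for (i in seq_len(nrow(clicks))) {
      tc <- clicks$time_s[i]
      amp <- unit[[paste0("onset_", st[i])]] * g[i]
      if (unit$area == "AC") {
        reb_t <- ev$ac_rebound_t_ms[[st[i]]] / 1000
        sup_idx <- bins_in_interval(tc + ev$supp_start_ms / 1000,
                                    tc + reb_t - ev$supp_end_gap_ms / 1000,
                                    0, dt, n)
        rate[sup_idx] <- rate[sup_idx] * ev$supp_factor
      }
      bump_idx <- bins_in_interval(tc - 0.01, tc + 0.35, 0, dt, n)
      tb <- tmid[bump_idx] - tc
      add <- amp * exp(-(tb - ev$onset_t_ms / 1000)^2 /
                         (2 * (ev$onset_sd_ms / 1000)^2))
      if (unit$area == "AC") {
        reb_t <- ev$ac_rebound_t_ms[[st[i]]] / 1000
        add <- add + ev$rebound_amp * g[i] *
          exp(-(tb - reb_t)^2 / (2 * (ev$rebound_sd_ms / 1000)^2))
      }
      rate[bump_idx] <- rate[bump_idx] + add
    }
  }

  counts <- rpois(n, rate * dt)
  nz <- which(counts > 0)
  t_bg <- rep((nz - 1) * dt, counts[nz]) + runif(sum(counts[nz])) * dt

  t_lock <- numeric(0)
  tr <- events[events$kind == "train_onset", , drop = FALSE]
  if (nrow(tr)) {
    cpc <- if (unit$area == "AC") cfg$trains$ac_spikes_per_click
           else cfg$trains$mgb_spikes_per_click
    for (i in seq_len(nrow(tr))) {
      hz <- tr$train_hz[i]; T <- 1 / hz
      st <- if (tr$block_kind[i] == "stim") "desync" else "sync"
      kap <- unit[[paste0("kappa_", st)]]
      ctimes <- tr$time_s[i] + (seq_len(round(cfg$design$train_len_s * hz)) - 1) * T
      g <- gate_at(ctimes)
      nk <- rpois(length(ctimes), cpc * g)
      if (sum(nk) == 0) next
      ph <- rvonmises(sum(nk), mu = 0, kappa = kap)
      t_lock <- c(t_lock, rep(ctimes, nk) + ph / (2 * pi) * T)
    }
  }
  ts <- sort(c(t_bg, t_lock))
  ts <- ts[ts >= 0 & ts < dur]
  # enforce strict monotonicity (coincident times have measure zero but
  # guard anyway)
  if (length(ts) > 1) {
    d <- diff(ts)
    while (any(d <= 0)) {
      ts[which(d <= 0) + 1L] <- ts[which(d <= 0)] + 1e-9
      ts <- sort(ts)
      d <- diff(ts)
    }
  }
  ts
}

#' Simulate a full session with known ground truth
#'
#' Builds the block design (spontaneous BF stimulations, click blocks with
#' and without BF stimulation, click-train blocks per frequency), the state
#' schedule including the shared UP/DOWN alternation, the laminar LFP with
#' click-evoked sinks at the recipient channel, per-unit waveforms and spike
#' trains. Deterministic given `(cfg, seed)`; component RNG streams are
#' derived from the seed by fixed offsets so adding a unit does not perturb
#' the others.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with elements `session` (a [session()]) and `ground_truth`.
#' @export
simulate_session <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  be <- build_events(cfg)
  events <- be$events
  dur <- be$duration_s
  if (dur <= 0) stop("simulate_session: zero-length session")
  for (cl in names(cfg$rates))
    if (any(unlist(cfg$rates[[cl]]) < 0))
      stop("simulate_session: negative rates")

  sched <- state_schedule_from_events(events, dur, cfg$states$desync_len_s)
  set.seed(sub_seed(seed, 1))
  sync_iv <- sched[sched$label == "synchronized", , drop = FALSE]
  ups <- do.call(rbind, lapply(seq_len(nrow(sync_iv)), function(i)
    simulate_updown_schedule(sync_iv$t_start[i], sync_iv$t_end[i],
                             cfg$states$up_median_s, cfg$states$down_median_s,
                             cfg$states$updown_sdlog)))
  if (is.null(ups)) ups <- data.frame(t_start = numeric(0), t_end = numeric(0))
  full_sched <- rbind(sched,
                      if (nrow(ups)) data.frame(t_start = ups$t_start,
                                                t_end = ups$t_end,
                                                label = "up_state"))

  # ground-truth unit table
  set.seed(sub_seed(seed, 2))
  rc <- cfg$recipient_channel
  depth_pool <- list(
    NS = 4:30, BS1 = (rc - 4):rc, BS2 = (rc + 1):(rc + 6),
    BS3 = (rc + 7):(rc + 14), BS4 = (rc + 15):(rc + 22), MGB = 10:20)
  ttp_pool <- list(ns = seq(0.20, 0.45, by = 0.05),
                   bs = seq(0.60, 1.00, by = 0.05))
  rows <- list()
  for (cl in names(cfg$n_units)) {
    nu <- cfg$n_units[[cl]]
    if (nu == 0) next
    area <- if (cl == "MGB") "MGB" else "AC"
    narrow <- cl %in% c("NS", "MGB")
    on_tbl <- if (cl == "MGB") cfg$evoked$mgb_onset
              else if (cl == "NS") cfg$evoked$ac_ns_onset
              else cfg$evoked$ac_bs_onset
    kap <- if (area == "AC") cfg$trains$ac_kappa else cfg$trains$mgb_kappa
    r <- cfg$rates[[cl]]
    for (j in seq_len(nu)) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = sprintf("%s_%02d", tolower(cl), j), area = area,
        cell_class = cl,
        depth_channel = sample(depth_pool[[cl]], 1),
        ttp_ms = sample(ttp_pool[[if (narrow) "ns" else "bs"]], 1),
        quality = runif(1, cfg$quality$min, cfg$quality$max),
        r_up = r$r_up, r_down = r$r_down, r_desync = r$r_desync,
        onset_sync = on_tbl[["sync"]], onset_desync = on_tbl[["desync"]],
        kappa_sync = kap[["sync"]], kappa_desync = kap[["desync"]],
        stringsAsFactors = FALSE)
    }
  }
  gt_units <- do.call(rbind, rows)
  gt_units$relative_depth_um <- ifelse(
    gt_units$area == "AC", (rc - gt_units$depth_channel) * cfg$spacing_um,
    NA_real_)

  lfp <- simulate_state_lfp(sched, cfg$n_channels, cfg$fs,
                            sub_seed(seed, 3), cfg)
  click_times <- events$time_s[events$kind == "click"]
  tr <- events[events$kind == "train_onset", ]
  train_clicks <- unlist(lapply(seq_len(nrow(tr)), function(i)
    tr$time_s[i] + (seq_len(round(cfg$design$train_len_s * tr$train_hz[i])) - 1) /
      tr$train_hz[i]))
  lfp <- add_evoked_sinks(lfp, c(click_times, train_clicks), rc, cfg)

  waves <- simulate_waveforms(gt_units, cfg$n_channels, cfg$wave_fs,
                              sub_seed(seed, 4), cfg)
  units <- unit_set(lapply(seq_len(nrow(gt_units)), function(i)
    unit_meta(gt_units$unit_id[i], waves[[i]], cfg$wave_fs,
              area = gt_units$area[i], quality = gt_units$quality[i])))

  sp <- lapply(seq_len(nrow(gt_units)), function(i)
    simulate_spikes(gt_units[i, ], full_sched, events,
                    sub_seed(seed, 1000 + i), cfg))
  names(sp) <- gt_units$unit_id
  spikes <- spike_train_set(sp)

  gt <- structure(
    list(schedule = full_sched, units = gt_units, recipient_channel = rc,
         up_intervals = ups, duration_s = dur, seed = seed, config = cfg),
    class = "ground_truth")
  list(session = session(lfp, spikes, units, events), ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d units, %.0f s, recipient channel %d, seed %d\n",
              nrow(x$units), x$duration_s, x$recipient_channel, x$seed))
  invisible(x)
}
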