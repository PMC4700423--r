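# Shared fixtures, all generated in code. The tiny session keeps module
# tests fast; the full default session is only built by the acceptance
# tests.

tiny_sim_config <- function(...) {
  sim_config(
    n_units = list(NS = 2L, BS1 = 2L, BS2 = 2L, BS3 = 2L, BS4 = 2L, MGB = 3L),
    design = list(n_spont_stims = 4L, spont_pre_s = 6,
                  n_click_rounds = 1L, click_trials_per_block = 8L,
                  train_hz = c(8, 64), train_presentations = 4L),
    ...)
}

.fixture_env <- new.env(parent = emptyenv())

# Cached tiny simulated session (built once per test run).
tiny_session <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- simulate_session(tiny_sim_config(), seed = 11)
  .fixture_env$tiny
}

# A minimal hand-built session for IO tests.
toy_session <- function(n_units = 2) {
  lfp <- laminar_lfp(matrix(sin(seq(0, 6, length.out = 3 * 50)), nrow = 3),
                     fs = 1000, spacing_um = 50)
  waves <- lapply(seq_len(n_units), function(i)
    matrix(rnorm(3 * 20), nrow = 3))
  units <- unit_set(lapply(seq_len(n_units), function(i)
    unit_meta(sprintf("u%d", i), waves[[i]], wave_fs = 20000,
              quality = 20 + i)))
  spikes <- spike_train_set(
    setNames(lapply(seq_len(n_units), function(i) sort(runif(5, 0, 0.05))),
             sprintf("u%d", i = seq_len(n_units))))
  events <- event_table(data.frame(
    time_s = c(0.01, 0.02, 0.03), kind = c("bf_on", "bf_off", "click"),
    level_db = c(NA, NA, 70), train_hz = NA_real_,
    block_id = "b1", block_kind = c("stim", "stim", "stim")))
  session(lfp, spikes, units, events)
}

# Homogeneous Poisson spike train on [0, dur).
rpois_train <- function(rate_hz, dur_s) {
  n <- rpois(1, rate_hz * dur_s)
  sort(runif(n, 0, dur_s))
}
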