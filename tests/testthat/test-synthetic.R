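test_that("simulation is deterministic given (config, seed)", {
  cfg <- tiny_sim_config()
  a <- simulate_session(cfg, seed = 5)
  b <- simulate_session(cfg, seed = 5)
  expect_identical(a$session$lfp$samples, b$session$lfp$samples)
  expect_identical(a$session$spikes$spikes, b$session$spikes$spikes)
  expect_identical(a$ground_truth$units, b$ground_truth$units)
  c <- simulate_session(cfg, seed = 6)
  expect_false(identical(a$session$spikes$spikes, c$session$spikes$spikes))
})

test_that("tonic spiking conserves the configured rate (Poisson oracle)", {
  sched <- data.frame(t_start = 0, t_end = 100, label = "desynchronized")
  ev <- event_table(data.frame(time_s = numeric(0), kind = character(0)))
  unit <- data.frame(unit_id = "u", area = "AC", cell_class = "BS2",
                     r_up = 0, r_down = 0, r_desync = 10,
                     onset_sync = 0, onset_desync = 0,
                     kappa_sync = 1, kappa_desync = 1)
  ts <- simulate_spikes(unit, sched, ev, seed = 33)
  expect_lt(abs(length(ts) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(ts) > 0))
  # zero rates and no evoked template -> empty train
  unit$r_desync <- 0
  expect_length(simulate_spikes(unit, sched, ev, seed = 33), 0)
})

test_that("phase law: simulated vector strength matches I1(k)/I0(k)", {
  set.seed(16)
  for (kappa in c(0.5, 2)) {
    ph <- rvonmises(2000, 0, kappa)
    want <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(vector_strength(ph) - want), 3 / sqrt(2000))
  }
})

test_that("state LFP has the constructed laminar power gradients", {
  cfg <- sim_config()
  sync_only <- data.frame(t_start = 0, t_end = 20, label = "synchronized")
  lfp <- simulate_state_lfp(sync_only, 32, 1000, seed = 2, cfg)
  psd <- compute_psd(lfp)
  delta <- band_power(psd, c(0, 4))
  expect_gt(delta[30], delta[2])  # slow oscillation weighted toward depth
  # desynchronized with gamma off: 30-50 Hz power at the noise floor
  des <- data.frame(t_start = 0, t_end = 20, label = "desynchronized")
  cfg0 <- sim_config(lfp = list(desync_gamma_amp = 0))
  l0 <- simulate_state_lfp(des, 32, 1000, seed = 2, cfg0)
  l1 <- simulate_state_lfp(des, 32, 1000, seed = 2, cfg)
  g0 <- band_power(compute_psd(l0), c(30, 50))
  g1 <- band_power(compute_psd(l1), c(30, 50))
  expect_gt(g1[1], 3 * g0[1])           # superficial gamma well above floor
  expect_lt(abs(g0[1] / g0[30] - 1), 0.5)  # floor flat across depth
  expect_error(simulate_state_lfp(sync_only[0, ], 32, 1000, 1, cfg),
               "empty schedule")
})

test_that("superficial low-gamma power rises in the desynchronized state", {
  cfg <- sim_config()
  two <- data.frame(t_start = c(0, 15), t_end = c(15, 30),
                    label = c("synchronized", "desynchronized"))
  lfp <- simulate_state_lfp(two, 32, 1000, seed = 3, cfg)
  seg <- function(a, b) {
    l <- lfp; l$samples <- lfp$samples[, (a * 1000 + 1):(b * 1000)]; l
  }
  g_sync <- band_power(compute_psd(seg(2, 13)), c(30, 50))
  g_des <- band_power(compute_psd(seg(17, 28)), c(30, 50))
  expect_gt(g_des[1] / g_sync[1], 1)
})

test_that("waveform templates encode depth channel and width exactly", {
  gt <- data.frame(depth_channel = c(5, 20), ttp_ms = c(0.3, 0.9))
  w <- simulate_waveforms(gt, 32, 20000, seed = 4)
  for (i in 1:2) {
    expect_equal(estimate_unit_depth(w[[i]]), gt$depth_channel[i])
    expect_lt(abs(trough_to_peak(w[[i]][gt$depth_channel[i], ], 20000) -
                    gt$ttp_ms[i]), 0.051)
  }
  expect_error(simulate_waveforms(data.frame(depth_channel = 40,
                                             ttp_ms = 0.7), 32, 20000, 1),
               "out of range")
  # small waveform noise does not change classification
  cfgn <- sim_config(waveforms = list(noise_sd = 1))
  wn <- simulate_waveforms(gt, 32, 20000, seed = 4, cfgn)
  for (i in 1:2) {
    ch <- estimate_unit_depth(wn[[i]])
    expect_equal(ch, gt$depth_channel[i])
    expect_identical(
      classify_unit(trough_to_peak(wn[[i]][ch, ], 20000), 0, "AC"),
      classify_unit(gt$ttp_ms[i], 0, "AC"))
  }
})

test_that("ground-truth directions are encoded in the default config", {
  gt <- tiny_session()$ground_truth
  duty <- 0.4 / 0.7
  for (cl in c("BS1", "BS4")) {
    u <- gt$units[gt$units$cell_class == cl, ][1, ]
    expect_lt(u$r_desync / (u$r_up * duty + u$r_down * (1 - duty)), 1)
  }
  u <- gt$units[gt$units$cell_class == "MGB", ][1, ]
  expect_equal(u$kappa_sync, u$kappa_desync)
  u <- gt$units[gt$units$cell_class == "BS2", ][1, ]
  expect_gt(u$kappa_desync, u$kappa_sync)
})

test_that("a null configuration (states identical) gives near-zero band MIs", {
  cfg <- tiny_sim_config(
    lfp = list(sync_slow_amp = 150, desync_slow_amp = 150,
               sync_gamma_amp = 25, desync_gamma_amp = 25))
  sim <- simulate_session(cfg, seed = 9)
  lfp <- preprocess_lfp(sim$session$lfp)
  ev <- sim$session$events
  ep <- define_state_epochs(event_table(
    as.data.frame(ev[ev$block_id == "spont", ])))
  bp <- band_power_table(lfp, ep)
  mi <- band_power_state_mi(bp)
  for (b in c("delta", "low_gamma"))
    expect_lt(abs(mean(mi$mi[mi$band == b])), 0.05)
})

test_that("config validation rejects unknown keys and bad values", {
  expect_error(sim_config(nonsense = 1), "unknown key")
  expect_error(sim_config(lfp = list(zap = 1)), "unknown key")
  cfg <- tiny_sim_config()
  cfg$rates$BS1$r_up <- -1
  expect_error(simulate_session(cfg, 1), "negative rates")
})
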