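test_that("smoothed MUA integrates to the spike count", {
  sts <- spike_train_set(list(a = 0.5))
  mua <- compute_mua(sts, t_end = 1)
  expect_equal(sum(mua$rate_hz) * 1e-3, 1, tolerance = 1e-6)
  two <- spike_train_set(list(a = 0.5, b = 0.5))
  mua2 <- compute_mua(two, t_end = 1)
  expect_equal(sum(mua2$rate_hz) * 1e-3, 2, tolerance = 1e-6)
})

test_that("MUA is translation-equivariant", {
  sts <- spike_train_set(list(a = c(0.2, 0.35, 0.5)))
  sh <- spike_train_set(list(a = c(0.2, 0.35, 0.5) + 0.1))
  m1 <- compute_mua(sts, t_end = 1)$rate_hz
  m2 <- compute_mua(sh, t_end = 1)$rate_hz
  expect_equal(m2[101:1000], m1[1:900], tolerance = 1e-9)
  expect_error(compute_mua(sts, unit_ids = "nope"), "empty unit set")
})

square_mua <- function(n_cycles = 6, up_s = 0.4, down_s = 0.3,
                       r_up = 20, r_down = 0.2) {
  rate <- rep(c(rep(r_down, round(down_s * 1000)), rep(r_up, round(up_s * 1000))),
              n_cycles)
  sm <- statecortex:::smooth_vector(rate, statecortex:::gaussian_kernel(10))
  onsets <- seq_len(n_cycles) * (up_s + down_s) - up_s
  list(mua = smoothed_mua(sm), true_onsets = onsets)
}

test_that("square-wave MUA yields one detection near each UP onset", {
  sq <- square_mua()
  mask <- data.frame(t_start = 0, t_end = length(sq$mua$rate_hz) / 1000)
  ep <- detect_up_states(sq$mua, mask, floor_hz = 0.01)
  expect_identical(nrow(ep), length(sq$true_onsets) - 0L)
  err <- abs(ep$t_start - sq$true_onsets[seq_len(nrow(ep))])
  expect_lt(max(err), 0.03)  # bounded by the 10 ms kernel width
})

test_that("constant MUA yields zero detections and silence errors are raised", {
  const <- smoothed_mua(rep(5, 5000))
  mask <- data.frame(t_start = 0, t_end = 5)
  ep <- detect_up_states(const, mask, floor_hz = 0.01)
  expect_identical(nrow(ep), 0L)
  expect_error(detect_up_states(smoothed_mua(rep(0, 1000)), mask), "no activity")
  sq <- square_mua()
  expect_error(detect_up_states(sq$mua, logical(length(sq$mua$rate_hz))),
               "empty spontaneous mask")
})

test_that("scaling the MUA scales the threshold and leaves detections fixed", {
  sq <- square_mua()
  mask <- data.frame(t_start = 0, t_end = length(sq$mua$rate_hz) / 1000)
  e1 <- detect_up_states(sq$mua, mask, floor_hz = 0)
  scaled <- sq$mua; scaled$rate_hz <- scaled$rate_hz * 7
  e2 <- detect_up_states(scaled, mask, floor_hz = 0)
  expect_equal(e2$t_start, e1$t_start)
  expect_equal(attr(e2, "threshold"), 7 * attr(e1, "threshold"),
               tolerance = 1e-12)
})

test_that("detected UP epochs stay inside the spontaneous mask and never overlap", {
  sq <- square_mua(n_cycles = 10)
  dur <- length(sq$mua$rate_hz) / 1000
  mask <- data.frame(t_start = c(0, 4), t_end = c(3, dur))
  ep <- detect_up_states(sq$mua, mask, floor_hz = 0.01)
  expect_true(all(ep$t_start >= 0))
  for (i in seq_len(nrow(ep)))
    expect_true(any(ep$t_start[i] >= mask$t_start - 1e-9 &
                      ep$t_end[i] <= mask$t_end + 1e-9))
  if (nrow(ep) > 1) expect_true(all(diff(ep$t_start) >= 0.2))
})

test_that("state epochs around a single BF stimulation match the 3 s windows", {
  ev <- event_table(data.frame(time_s = c(100, 101),
                               kind = c("bf_on", "bf_off")))
  ep <- define_state_epochs(ev)
  sync <- ep[ep$label == "synchronized", ]
  des <- ep[ep$label == "desynchronized", ]
  expect_equal(c(sync$t_start, sync$t_end), c(97, 100))
  expect_equal(c(des$t_start, des$t_end), c(101, 104))
})

test_that("desynchronized epochs truncate at the next stimulation", {
  ev <- event_table(data.frame(time_s = c(100, 101, 103, 104),
                               kind = c("bf_on", "bf_off", "bf_on", "bf_off")))
  ep <- define_state_epochs(ev)
  des <- ep[ep$label == "desynchronized", ]
  expect_equal(des$t_end[1], 103)
  expect_warning(
    empty <- define_state_epochs(
      event_table(data.frame(time_s = 1, kind = "click"))),
    "no bf events")
  expect_identical(nrow(empty), 0L)
})

test_that("trial state labels follow the block kind", {
  ev <- event_table(data.frame(
    time_s = c(1, 2), kind = "click", level_db = 70, train_hz = NA_real_,
    block_id = c("a", "b"), block_kind = c("no_stim", "stim")))
  es <- event_states(ev)
  expect_identical(es$state, c("synchronized", "desynchronized"))
})

test_that("UP states in the simulated session are recovered from the MUA", {
  # spontaneous-only session at the default cortical population size; the
  # strict all-bins rule rejects true UP states on single-bin dips of the
  # Poisson MUA, so the mean-over-window rule is used here
  cfg <- sim_config(
    n_units = list(NS = 12L, BS1 = 10L, BS2 = 12L, BS3 = 14L, BS4 = 12L,
                   MGB = 0L),
    design = list(n_spont_stims = 6L, spont_pre_s = 10, n_click_rounds = 0L,
                  train_hz = numeric(0), train_presentations = 0L))
  sim <- simulate_session(cfg, seed = 11)
  gt <- sim$ground_truth
  ac_ids <- gt$units$unit_id[gt$units$area == "AC"]
  mua <- compute_mua(sim$session$spikes, ac_ids, t_end = gt$duration_s)
  on <- sim$session$events$time_s[sim$session$events$kind == "bf_on"]
  mask <- data.frame(t_start = on - 9, t_end = on)
  ep <- detect_up_states(mua, mask, post_rule = "mean")
  # ground-truth UP intervals >= 300 ms fully inside the mask
  ups <- gt$up_intervals
  inside <- vapply(seq_len(nrow(ups)), function(i)
    any(ups$t_start[i] >= mask$t_start + 0.1 & ups$t_end[i] <= mask$t_end),
    logical(1))
  long <- ups[inside & (ups$t_end - ups$t_start) >= 0.3, ]
  hit <- vapply(seq_len(nrow(long)), function(i)
    any(abs(ep$t_start - long$t_start[i]) < 0.05), logical(1))
  expect_gte(mean(hit), 0.8)
  err <- vapply(which(hit), function(i)
    min(abs(ep$t_start - long$t_start[i])), numeric(1))
  expect_lt(median(err), 0.02)
})
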