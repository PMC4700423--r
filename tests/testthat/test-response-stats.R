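test_that("modulation index arithmetic, bounds and antisymmetry", {
  expect_equal(modulation_index(2, 6), 0.5)
  expect_equal(modulation_index(4, 4), 0)
  expect_equal(modulation_index(5, 0), -1)
  expect_equal(modulation_index(0, 5), 1)
  expect_true(is.na(modulation_index(0, 0)))
  expect_error(modulation_index(-1, 2), ">= 0")
  set.seed(1)
  a <- runif(50); b <- runif(50)
  mi <- modulation_index(a, b)
  expect_true(all(mi >= -1 & mi <= 1))
  expect_equal(modulation_index(b, a), -mi)
  expect_equal(up_vs_desync_index(6, 2), 0.5)
})

test_that("trial counts use half-open windows relative to onset", {
  on <- 10
  ts <- c(10, 10.099, 10.1)
  tc <- trial_counts(ts, on, "synchronized", c(0, 100))
  expect_identical(tc$count, 2)
  expect_identical(trial_counts(numeric(0), c(1, 2), c("a", "b"))$count,
                   c(0, 0))
  expect_error(trial_counts(ts, numeric(0), character(0)), "no events")
})

test_that("trial counts of a Poisson process match the rate oracle", {
  set.seed(7)
  onsets <- seq(0, by = 1, length.out = 1000)
  ts <- rpois_train(50, 1000)
  tc <- trial_counts(ts, onsets, rep("synchronized", 1000), c(0, 100))
  # rate 50 Hz over 100 ms -> mean 5; SEM sqrt(5/1000)
  expect_equal(mean(tc$count), 5, tolerance = 3 * sqrt(5 / 1000) / 5)
})

test_that("Fano factor: zero variance, hand case, Poisson", {
  expect_equal(fano(c(3, 3, 3, 3)), 0)
  expect_equal(fano(c(0, 2)), 2)  # var 2 (n-1), mean 1
  expect_true(is.na(fano(c(0, 0, 0))))
  set.seed(8)
  expect_true(abs(fano(rpois(1000, 5)) - 1) < 0.1)
})

test_that("responsive filter requires spiking in both states", {
  onsets <- c(1, 2, 3, 4)
  states <- c("synchronized", "synchronized", "desynchronized",
              "desynchronized")
  sts <- spike_train_set(list(
    both = c(1.01, 3.01), sync_only = c(1.02, 2.02), silent = numeric(0)))
  keep <- responsive_filter(sts, onsets, states)
  expect_identical(keep, "both")
  expect_warning(
    responsive_filter(spike_train_set(list(a = numeric(0))), onsets, states),
    "no responsive")
})

test_that("mean spike time pools spikes over trials", {
  expect_equal(mean_spike_time(c(0.100, 0.150), 0), 125)
  expect_true(is.na(mean_spike_time(c(0.01), 0)))
  set.seed(9)
  ts <- sort(runif(4000, 0.08, 0.2))
  expect_equal(mean_spike_time(ts, 0), 140, tolerance = 0.02)
})

test_that("normalized PSTH peaks at one and is scale invariant", {
  set.seed(10)
  onsets <- seq(0, by = 1, length.out = 50)
  ts <- sort(onsets + 0.02 + rnorm(50, sd = 1e-4))
  p <- normalized_psth(ts, onsets)
  expect_equal(max(p$profile), 1)
  expect_equal(p$peak_latency_ms, 20, tolerance = 6)
  # doubling every trial's spikes leaves the normalized profile unchanged
  ts2 <- sort(c(ts, ts + 1e-4))
  p2 <- normalized_psth(ts2, onsets)
  expect_equal(p2$profile, p$profile, tolerance = 0.05)
  expect_null(normalized_psth(numeric(0), onsets))
})

test_that("spike count correlation: identity, independence, symmetry, shifts", {
  win <- data.frame(t_start = c(0, 10), t_end = c(3, 13))
  set.seed(11)
  a <- sort(c(runif(30, 0, 3), runif(30, 10, 13)))
  expect_equal(spike_count_correlation(a, a, win), 1)
  b <- sort(c(runif(30, 0, 3), runif(30, 10, 13)))
  expect_equal(spike_count_correlation(a, b, win),
               spike_count_correlation(b, a, win))
  shift <- 0.5
  win_s <- win + shift
  expect_equal(spike_count_correlation(a + shift, b + shift, win_s),
               spike_count_correlation(a, b, win), tolerance = 1e-9)
  expect_true(is.na(spike_count_correlation(a, numeric(0), win)))
})

test_that("independent Poisson trains are uncorrelated", {
  set.seed(12)
  win <- data.frame(t_start = seq(0, 57, by = 3), t_end = seq(3, 60, by = 3))
  r <- replicate(5, {
    a <- rpois_train(10, 60); b <- rpois_train(10, 60)
    spike_count_correlation(a, b, win)
  })
  expect_true(all(abs(r) < 0.05))
})

test_that("shared UP/DOWN gating raises synchronized-state correlations", {
  sim <- tiny_session()
  ses <- sim$session
  udf <- sim$ground_truth$units
  ep <- define_state_epochs(event_table(
    as.data.frame(ses$events[ses$events$block_id == "spont", ])))
  bs <- udf$unit_id[grepl("^BS", udf$cell_class)]
  for (st in c("synchronized", "desynchronized")) {
    iv <- ep[ep$label == st, ]
    m <- statecortex:::smoothed_count_matrix(ses$spikes, bs, iv)
    cm <- suppressWarnings(cor(m))
    assign(paste0("r_", substr(st, 1, 1)), mean(cm[upper.tri(cm)], na.rm = TRUE))
  }
  expect_gt(r_s, r_d)
  expect_gt(r_s, 0.01)
})
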