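lfp_from_profile <- function(profile, nt = 5, fs = 1000, h = 50) {
  laminar_lfp(matrix(profile, nrow = length(profile), ncol = nt), fs = fs,
              spacing_um = h)
}

test_that("depth smoothing kernel preserves constants and linear profiles", {
  const <- lfp_from_profile(rep(3.5, 8))
  expect_equal(smooth_depth(const)$samples, const$samples)
  lin <- lfp_from_profile(2.5 * (1:8))
  sm <- smooth_depth(lin)
  # interior channels unchanged; boundary channels pulled by duplication
  expect_equal(sm$samples[2:7, ], lin$samples[2:7, ])
  expect_false(isTRUE(all.equal(sm$samples[1, ], lin$samples[1, ])))
})

test_that("depth smoothing spreads an isolated deflection as 1/4,1/2,1/4", {
  prof <- rep(0, 9); prof[5] <- 4
  sm <- smooth_depth(lfp_from_profile(prof))
  expect_equal(sm$samples[4:6, 1], c(1, 2, 1))
  expect_equal(sm$samples[c(1, 2, 8, 9), 1], rep(0, 4))
})

test_that("CSD of affine depth profiles vanishes on interior channels", {
  for (ab in list(c(0, 1), c(5, -2.5), c(100, 0))) {
    lfp <- lfp_from_profile(ab[1] + ab[2] * (1:12) * 50)
    csd <- compute_csd(lfp)
    expect_lt(max(abs(csd$values[2:11, ])) /
                max(1, max(abs(lfp$samples))), 1e-9)
  }
})

test_that("CSD of a quadratic profile is the constant closed-form value", {
  # phi(r) = r^2 (uV, r in units of h): second difference 2 h^2 -> CSD -2
  h <- 50
  lfp <- lfp_from_profile(((1:10) * h)^2, h = h)
  csd <- compute_csd(lfp)
  expect_equal(csd$values[2:9, 1], rep(-2, 8), tolerance = 1e-12)
})

test_that("a constructed Gaussian potential trough is localized as a sink", {
  k <- 12
  prof <- -80 * exp(-((1:32) - k)^2 / (2 * 1.5^2))
  lfp <- lfp_from_profile(prof, nt = 200)
  csd <- compute_csd(smooth_depth(lfp))
  expect_identical(which.min(csd$values[, 100]), as.integer(k))
  rec <- find_recipient_channel(csd, click_times = 0.05,
                                window_ms = c(0, 50))
  expect_identical(rec, as.integer(k))
})

test_that("recipient-channel ties break toward the superficial channel", {
  nt <- 100
  vals <- matrix(0, 32, nt)
  vals[10, ] <- -5; vals[14, ] <- -5
  csd <- csd_profile(vals, fs = 1000, spacing_um = 50)
  expect_identical(find_recipient_channel(csd, 0.01), 10L)
})

test_that("flat CSD raises a no-sink error", {
  csd <- csd_profile(matrix(0, 32, 100), fs = 1000, spacing_um = 50)
  expect_error(find_recipient_channel(csd, 0.01), "no sink")
  expect_error(find_recipient_channel(csd, numeric(0)), "no clicks")
})

test_that("relative depth arithmetic follows the superficial-positive convention", {
  mk <- function(id, ch) unit_meta(id, matrix(rnorm(96), 32), 20000,
                                   depth_channel = ch)
  us <- unit_set(list(mk("on_rec", 8), mk("above", 4), mk("below", 14)))
  us <- assign_relative_depths(us, recipient_channel = 8, spacing_um = 50)
  d <- units_df(us)
  expect_equal(d$relative_depth_um[d$unit_id == "on_rec"], 0)
  expect_equal(d$relative_depth_um[d$unit_id == "above"], 200)
  expect_equal(d$relative_depth_um[d$unit_id == "below"], -300)
})

test_that("unit depth is the channel of maximum trough-to-peak amplitude", {
  gt <- data.frame(depth_channel = 20, ttp_ms = 0.7)
  w <- simulate_waveforms(gt, n_channels = 32, wave_fs = 20000, seed = 1)[[1]]
  expect_identical(estimate_unit_depth(w), 20L)
  m <- matrix(0, 8, 10); m[5, 3] <- -2; m[5, 6] <- 1; m[6, 3] <- -2; m[6, 6] <- 1
  expect_identical(estimate_unit_depth(m), 5L)  # tie toward superficial
  expect_error(estimate_unit_depth(matrix(0, 4, 10)), "all-zero")
})

test_that("smoothing changes non-linear profiles (idempotence only on linear)", {
  lin <- lfp_from_profile(3 * (1:10))
  quad <- lfp_from_profile((1:10)^2)
  expect_equal(smooth_depth(smooth_depth(lin))$samples[3:8, ],
               smooth_depth(lin)$samples[3:8, ])
  expect_false(isTRUE(all.equal(smooth_depth(quad)$samples[2:9, ],
                                quad$samples[2:9, ])))
})

test_that("sink localization recovers the ground-truth recipient channel", {
  sim <- tiny_session()
  lfp <- preprocess_lfp(sim$session$lfp)
  csd <- compute_csd(smooth_depth(lfp))
  clicks <- sim$session$events$time_s[sim$session$events$kind == "click"]
  rec <- find_recipient_channel(csd, clicks)
  expect_identical(rec, as.integer(sim$ground_truth$recipient_channel))
})
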