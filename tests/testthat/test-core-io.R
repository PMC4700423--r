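test_that("session write/read roundtrips field by field", {
  set.seed(1)
  s <- toy_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_equal(r$lfp$samples, s$lfp$samples, tolerance = 1e-6)
  expect_identical(r$lfp$fs, s$lfp$fs)
  expect_identical(r$lfp$spacing_um, s$lfp$spacing_um)
  expect_equal(sort(names(r$spikes$spikes)), sort(names(s$spikes$spikes)))
  for (id in names(s$spikes$spikes))
    expect_equal(r$spikes$spikes[[id]], s$spikes$spikes[[id]],
                 tolerance = 1e-8)
  expect_identical(names(r$units$units), names(s$units$units))
  for (id in names(s$units$units)) {
    expect_equal(r$units$units[[id]]$mean_waveform,
                 s$units$units[[id]]$mean_waveform, tolerance = 1e-6)
    expect_equal(r$units$units[[id]]$quality, s$units$units[[id]]$quality)
  }
  expect_equal(r$events$time_s, s$events$time_s)
  expect_identical(r$events$kind, s$events$kind)
  expect_identical(r$events$block_kind, s$events$block_kind)
})

test_that("roundtrip holds over random small sessions", {
  for (seed in 1:4) {
    set.seed(seed)
    s <- toy_session(n_units = sample(0:3, 1))
    dir <- withr::local_tempdir()
    write_session(s, dir)
    r <- read_session(dir)
    expect_equal(r$lfp$samples, s$lfp$samples, tolerance = 1e-6)
    expect_equal(length(r$units), length(s$units))
    expect_equal(sum(lengths(r$spikes$spikes)), sum(lengths(s$spikes$spikes)))
  }
})

test_that("lfp.bin payload is float32 row-major (channels x samples x 4 bytes)", {
  s <- toy_session()
  s$lfp <- laminar_lfp(matrix(as.numeric(1:30), nrow = 3, ncol = 10),
                       fs = 1000)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_identical(file.size(file.path(dir, "lfp.bin")), 3 * 10 * 4)
  # row-major: first 10 floats are channel 1
  first <- readBin(file.path(dir, "lfp.bin"), numeric(), n = 10, size = 4)
  expect_equal(first, s$lfp$samples[1, ], tolerance = 1e-6)
})

test_that("empty spike train set roundtrips", {
  s <- toy_session(n_units = 0)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  r <- read_session(dir)
  expect_length(r$spikes$spikes, 0)
  expect_length(r$units$units, 0)
})

test_that("validation rejects constructed invariant violations", {
  expect_error(spike_train_set(list(a = c(0.2, 0.1))),
               "non-increasing spike times")
  expect_error(spike_train_set(list(a = c(-0.1, 0.2))), "negative")
  expect_error(event_table(data.frame(time_s = 1, kind = "bf_on")),
               "matching later bf_off")
  expect_error(event_table(data.frame(time_s = c(2, 1),
                                      kind = c("click", "click"))),
               "non-decreasing")
  expect_error(event_table(data.frame(time_s = 1, kind = "train_onset")),
               "train_hz")
  expect_error(laminar_lfp(matrix(NA_real_, 3, 5), fs = 1000), "missing")
  expect_error(laminar_lfp(matrix(0, 2, 5), fs = 1000), "n_channels")
  expect_error(state_epochs(data.frame(t_start = c(0, 1), t_end = c(2, 3),
                                       label = "up_state")), "overlapping")
  expect_error(unit_meta("u", matrix(0, 3, 5), 20000, quality = -1),
               "quality")
})

test_that("read_session names the missing component", {
  dir <- withr::local_tempdir()
  write_session(toy_session(), dir)
  file.remove(file.path(dir, "spikes.tsv"))
  expect_error(read_session(dir), "missing component: spikes.tsv")
})

test_that("filter_units keeps quality >= threshold, preserving order", {
  mk <- function(id, q) unit_meta(id, matrix(rnorm(9), 3), 20000, quality = q)
  us <- unit_set(list(mk("a", 19.9), mk("b", 20), mk("c", 25)))
  kept <- filter_units(us, 20)
  expect_identical(names(kept$units), c("b", "c"))
  expect_length(filter_units(unit_set(), 20), 0)
  expect_length(filter_units(us, 0), 3)
})

test_that("simulated session roundtrips through disk", {
  ses <- tiny_session()$session
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  r <- read_session(dir)
  expect_equal(dim(r$lfp$samples), dim(ses$lfp$samples))
  expect_equal(r$lfp$samples[5, 1:100], ses$lfp$samples[5, 1:100],
               tolerance = 1e-5)
  id <- names(ses$spikes$spikes)[1]
  expect_equal(r$spikes$spikes[[id]], ses$spikes$spikes[[id]],
               tolerance = 1e-7)
  expect_identical(nrow(r$events), nrow(ses$events))
})
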