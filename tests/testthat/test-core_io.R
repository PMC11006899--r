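test_that("configuration defaults carry the pipeline's canonical constants", {
  cfg <- analysis_config()
  expect_identical(cfg$spike_band_hz, c(300, 3000))
  expect_identical(cfg$lfp_cutoff_hz, 1000)
  expect_identical(cfg$spike_threshold_sigma, 5)
  expect_identical(cfg$burst_min_spikes, 5L)
  expect_identical(cfg$burst_window_s, 0.1)
  expect_identical(cfg$avalanche_bin_s, 0.003)
  expect_identical(cfg$pac_n_bins, 36L)
  expect_identical(cfg$bands$slow, c(0.2, 0.5))
  expect_identical(cfg$bands$delta, c(0.5, 4))
  expect_identical(cfg$bands$theta, c(4, 8))
  expect_identical(cfg$bands$gamma, c(30, 300))
  expect_error(analysis_config(bands = list(bad = c(5, 2))), "low < high")
})

test_that("recording construction validates channel/map agreement", {
  em <- two_compartment_map(4)
  sig <- matrix(rnorm(4 * 100), nrow = 4)
  rec <- recording(sig, 1000, em)
  expect_s3_class(rec, "Recording")
  expect_equal(rec_duration(rec), 0.1)
  expect_error(recording(sig[1:3, ], 1000, em), "does not match")
  expect_error(electrode_map(c(1, 1), 0, 0, "LEFT"), "unique")
  expect_error(electrode_map(1, Inf, 0, "LEFT"), "finite")
  expect_error(electrode_map(1, 0, 0, "MIDDLE"), "compartment")
})

test_that("a 64-channel 20 kHz 60 s recording has the expected shape", {
  em <- two_compartment_map(64)
  sig <- matrix(0, nrow = 64, ncol = 20000 * 60)
  rec <- recording(sig, 20000, em)
  expect_equal(dim(rec$samples), c(64, 1200000))
  expect_equal(rec_duration(rec), 60)
})

test_that("container write/load round-trips every field", {
  set.seed(11)
  em <- two_compartment_map(4)
  sl <- stimulus_log(c(1, 2, 3), 0.2, 1, "EXCITE_470",
                     epochs = data.frame(start_s = 0, end_s = 5,
                                         state = "STIM"))
  rec <- recording(matrix(rnorm(4 * 5000), nrow = 4), 1000, em,
                   stimlog = sl, annotations = list(subject = "synthetic"))
  path <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, path)
  back <- load_recording(path)
  expect_equal(back, rec)
  # empty annotations survive
  rec2 <- recording(matrix(0, 1, 10), 100, electrode_map(1))
  write_recording(rec2, path)
  expect_identical(load_recording(path)$annotations, list())
  expect_error(load_recording(file.path(tempdir(), "nope.rds")),
               "no such file")
})

test_that("segment_recording slices half-open windows and re-zeroes events", {
  em <- two_compartment_map(2)
  fs <- 1000
  sl <- stimulus_log(c(0.5, 1.5, 2.5), 0.01, 1, "EXCITE_470")
  rec <- recording(matrix(seq_len(2 * 3 * fs), nrow = 2), fs, em,
                   stimlog = sl)
  seg <- segment_recording(rec, 1, 2)
  expect_equal(ncol(seg$samples), fs)
  expect_equal(seg$stimlog$pulse_onsets_s, 0.5)
  expect_equal(seg$samples[, 1], rec$samples[, fs + 1])
  # identity slice
  expect_equal(segment_recording(rec, 0, 3)$samples, rec$samples)
  # composition: slicing twice equals slicing once
  a <- segment_recording(segment_recording(rec, 0.5, 2.5), 0, 1)
  b <- segment_recording(rec, 0.5, 1.5)
  expect_equal(a$samples, b$samples)
  expect_error(segment_recording(rec, 2, 2), "out of range")
  expect_error(segment_recording(rec, -1, 2), "out of range")
})

test_that("a 60 s 20 kHz slice of 10 s has 200000 samples per channel", {
  em <- electrode_map(1)
  rec <- recording(matrix(0, 1, 20000 * 60), 20000, em)
  seg <- segment_recording(rec, 10, 20)
  expect_equal(ncol(seg$samples), 200000)
})

test_that("electrode map and stimulus log CSV round-trip", {
  em <- two_compartment_map(8)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_electrode_map_csv(em, p1)
  expect_equal(read_electrode_map_csv(p1), em)
  sl <- stimulus_log(seq(1, 10), 0.02, 20, "INHIBIT_565")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_stimlog_csv(sl, p2)
  back <- read_stimlog_csv(p2)
  expect_equal(back$pulse_onsets_s, sl$pulse_onsets_s)
  expect_equal(back$pulse_width_s, 0.02)
  expect_equal(back$label, "INHIBIT_565")
})

test_that("bundled example side-car files load", {
  em <- read_electrode_map_csv(
    system.file("extdata", "example_electrode_map.csv", package = "meadyn"))
  expect_equal(nrow(em), 16)
  expect_setequal(unique(em$compartment), c("LEFT", "RIGHT"))
  sl <- read_stimlog_csv(
    system.file("extdata", "example_stimlog_470nm.csv", package = "meadyn"))
  expect_equal(sl$label, "EXCITE_470")
  expect_equal(sl$train_frequency_hz, 0.5)
  expect_equal(length(sl$pulse_onsets_s), 150)
})

test_that("sampled TTL import keeps rising edges only", {
  fs <- 1000
  ttl <- rep(0, 1000)
  ttl[c(101:150, 301:350, 601:650)] <- 5
  sl <- stimlog_from_ttl(ttl, fs, logic_level = 5)
  expect_equal(sl$pulse_onsets_s, c(0.100, 0.300, 0.600))
  expect_error(stimulus_log(c(2, 1)), "increasing")
  expect_error(stimulus_log(1, epochs = data.frame(
    start_s = c(0, 1), end_s = c(2, 3), state = c("A", "B"))), "overlap")
})
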