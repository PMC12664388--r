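test_that("OpenBCI text parsing keeps EEG columns and drops malformed rows", {
  path <- withr::local_tempfile(fileext = ".txt")
  header <- c("%OpenBCI Raw EXG Data", "%Number of channels = 16")
  cols <- paste(c("Sample Index", sprintf("EXG Channel %d", 0:15),
                  "Accel Channel 0", "Timestamp"), collapse = ",")
  row <- function(i, bad = FALSE) {
    eeg <- if (bad) c("oops", sprintf("%.2f", rnorm(15)))
    else sprintf("%.2f", rnorm(16))
    paste(c(i, eeg, "0", sprintf("%.1f", 1.7e12 + i * 8)), collapse = ",")
  }
  withr::with_seed(1, writeLines(c(header, cols, sapply(0:2, row)), path))
  rec <- parse_openbci_txt(path)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(n_samples(rec), 3)
  expect_equal(n_channels(rec), 16)
  expect_equal(rec$channel_labels, sprintf("EXG Channel %d", 0:15))

  withr::with_seed(1, writeLines(
    c(header, cols, sapply(1:100, function(i) row(i, bad = i == 50))), path))
  rec <- parse_openbci_txt(path)
  expect_equal(n_samples(rec), 99)
  expect_equal(rec$history[[1]]$n_dropped_rows, 1)
})

test_that("parsing errors name the missing timestamp column and empty files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("%hdr", "Sample Index,EXG Channel 0,Clock", "0,1.0,2"), path)
  expect_error(parse_openbci_txt(path), "Timestamp")
  writeLines(c("%hdr", "Sample Index,EXG Channel 0,Timestamp", "0,oops,1"),
             path)
  expect_error(parse_openbci_txt(path), "No valid data rows")
})

test_that("synthetic sessions round-trip through the OpenBCI text dialect", {
  ss <- generate_session(synth_spec(seed = 21, duration_s = 4))
  path <- withr::local_tempfile(fileext = ".txt")
  write_openbci_txt(ss$recording, path)
  rec <- parse_openbci_txt(path)
  expect_equal(dim(rec$data), dim(ss$recording$data))
  expect_lt(max(abs(rec$data - ss$recording$data)), 1e-6)
  expect_equal(rec$start_time, ss$recording$start_time)
})

test_that("CSV round trip preserves shape, order, and values", {
  rec <- eeg_recording(matrix(rnorm(8), nrow = 2), fs = 125,
                       channel_labels = c("b", "a"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  expect_length(readLines(path), 5L)  # header + 4 samples
  back <- read_recording_csv(path)
  expect_equal(back$channel_labels, c("b", "a"))
  expect_lt(max(abs(back$data - rec$data)), 1e-6)

  ss <- generate_session(synth_spec(seed = 22, duration_s = 3))
  write_recording_csv(ss$recording, path)
  back <- read_recording_csv(path)
  expect_lt(max(abs(back$data - ss$recording$data)), 1e-6)
  expect_equal(back$fs, 125)
})

test_that("gameplay trimming keeps the buffered interval and is idempotent", {
  t0 <- 1.7e12
  rec <- noise_recording(k = 2, dur = 100)
  rec$start_time <- t0
  meta <- session_meta("P01", "GT", t0 + 10000, t0 + 90000, buffer_s = 2)
  out <- trim_to_gameplay(rec, meta)
  expect_equal(duration_s(out), 84)                      # [8, 92) s
  expect_equal(out$data[, 1], rec$data[, 8 * 125 + 1])   # starts at 8 s
  again <- trim_to_gameplay(out, meta)
  expect_identical(again$data, out$data)                 # idempotent

  meta0 <- session_meta("P01", "GT", t0 + 10000, t0 + 90000, buffer_s = 0)
  expect_equal(duration_s(trim_to_gameplay(rec, meta0)), 80)

  late <- session_meta("P01", "GT", t0 + 50000, t0 + 150000, buffer_s = 0)
  expect_warning(clip <- trim_to_gameplay(rec, late), "clipped")
  expect_equal(duration_s(clip), 50)

  none <- session_meta("P01", "GT", t0 + 2e5, t0 + 3e5, buffer_s = 0)
  expect_error(trim_to_gameplay(rec, none), "does not overlap")
})

test_that("mini-game segmentation labels, shifts, and skips correctly", {
  t0 <- 1.7e12
  rec <- noise_recording(k = 2, dur = 60)
  rec$start_time <- t0
  mg <- function(label, idx, s, e, adj = 0)
    list(label = label, index = idx, start = t0 + s * 1000,
         end = t0 + e * 1000, adjustment_s = adj)
  meta <- session_meta("P07", "MVMT", t0, t0 + 60000, buffer_s = 0,
                       minigames = list(mg("memory", 1, 0, 20),
                                        mg("attention", 1, 20, 40),
                                        mg("memory", 2, 40, 60)))
  segs <- segment_minigames(rec, meta)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$label, c("MVMT/P07/memory_1", "MVMT/P07/attention_1",
                             "MVMT/P07/memory_2"))
  # every output sample maps to exactly one input sample
  expect_identical(segs$recording[[1]]$data, rec$data[, 1:2500])

  shifted <- segment_minigames(rec, session_meta(
    "P07", "MVMT", t0, t0 + 60000, buffer_s = 0,
    minigames = list(mg("memory", 1, 0, 20, adj = 1))))
  expect_equal(shifted$start_s, 1)  # whole interval shifts; length is kept
  expect_identical(shifted$recording[[1]]$data, rec$data[, 126:2625])

  # overlap allowed; fully-outside interval skipped with a warning
  meta2 <- session_meta("P07", "MVMT", t0, t0 + 60000, buffer_s = 0,
                        minigames = list(mg("a", 1, 0, 30), mg("b", 1, 10, 40),
                                         mg("c", 1, 70, 80)))
  expect_warning(segs2 <- segment_minigames(rec, meta2), "skipped")
  expect_equal(nrow(segs2), 2)
})

test_that("session metadata survives a JSON round trip", {
  t0 <- 1.7e12
  meta <- session_meta("P03", "MVMT", t0, t0 + 9e4, buffer_s = 1.5,
                       minigames = list(list(label = "logic", index = 2,
                                             start = t0 + 1000,
                                             end = t0 + 5000,
                                             adjustment_s = -0.5)))
  path <- withr::local_tempfile(fileext = ".json")
  write_session_meta(meta, path)
  back <- read_session_meta(path)
  expect_equal(back$participant_id, "P03")
  expect_equal(back$buffer_s, 1.5)
  expect_equal(back$minigames[[1]]$adjustment_s, -0.5)
  expect_error(session_meta("x", "GT", 10, 5), "precede")
})
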