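# WFDB I/O, annotation mapping, Fourier resampling, segment store.

test_that("WFDB write/read round-trips signal and annotations bit-exactly", {
  rec <- quick_record(seed = 7)
  d <- tempfile("wfdb")
  stored <- write_wfdb_record(rec, d)   # returns the quantized record
  back <- read_wfdb_record(file.path(d, rec$record_id), "MLII")
  expect_identical(back$signal, stored$signal)
  expect_identical(back$annotations$sample_index,
                   rec$annotations$sample_index)
  expect_identical(back$annotations$raw_symbol, rec$annotations$raw_symbol)
  expect_equal(back$fs, rec$fs)
  # quantization error bounded by half an ADC step at gain 200
  expect_lt(max(abs(stored$signal - rec$signal)), 0.5 / 200 + 1e-12)
  unlink(d, recursive = TRUE)
})

test_that("format 16 round-trips and long annotation gaps use SKIP words", {
  sig <- sin(2 * pi * 1.3 * (0:9999) / 360)
  ann <- data.frame(sample_index = c(5L, 9000L),  # gap > 1023 forces SKIP
                    raw_symbol = c("N", "V"), mapped_class = NA_character_)
  rec <- ecg_record("skiptest", 360, sig, annotations = ann)
  d <- tempfile("wfdb16")
  stored <- write_wfdb_record(rec, d, gain = 2000, format = "16")
  back <- read_wfdb_record(file.path(d, "skiptest"), "MLII")
  expect_identical(back$signal, stored$signal)
  expect_identical(back$annotations$sample_index, c(5L, 9000L))
  expect_identical(back$annotations$raw_symbol, c("N", "V"))
  unlink(d, recursive = TRUE)
})

test_that("missing files and absent channels raise typed errors", {
  expect_error(read_wfdb_record(tempfile(), "MLII"), class = "ecgan_io_error")
  rec <- quick_record(seed = 1)
  d <- tempfile("wfdb")
  write_wfdb_record(rec, d)
  err <- tryCatch(read_wfdb_record(file.path(d, rec$record_id), "V5"),
                  ecgan_channel_error = function(e) e)
  expect_s3_class(err, "ecgan_channel_error")
  expect_match(conditionMessage(err), "MLII")   # names available channels
  unlink(d, recursive = TRUE)
})

test_that("record constructor enforces the annotation and mask invariants", {
  expect_error(ecg_record("r", 360, numeric(3),
                          annotations = data.frame(sample_index = 5L,
                                                   raw_symbol = "N")),
               class = "ecgan_argument_error")
  expect_error(ecg_record("r", 0, numeric(3)),
               class = "ecgan_argument_error")
  expect_error(ecg_record("r", 360, numeric(3), valid_mask = c(TRUE, FALSE)),
               class = "ecgan_argument_error")
})

test_that("annotation mapping folds L/R into B and drops unknown codes", {
  ann <- data.frame(sample_index = c(10L, 20L, 30L, 40L, 50L, 60L),
                    raw_symbol = c("N", "L", "R", "V", "/", "A"),
                    mapped_class = NA_character_)
  rec <- ecg_record("r", 360, numeric(100), annotations = ann)
  mapped <- suppressMessages(map_annotations(rec))
  expect_equal(mapped$annotations$mapped_class, c("N", "B", "B", "V", "A"))
  expect_equal(sum(attr(mapped$annotations, "dropped")), 1)
  expect_lte(nrow(mapped$annotations), nrow(ann))
  expect_true(all(mapped$annotations$mapped_class %in%
                    c("N", "B", "V", "A", "F")))
  # empty and single-class cases
  empty <- map_annotations(ecg_record("r", 360, numeric(10)), quiet = TRUE)
  expect_equal(nrow(empty$annotations), 0L)
  allf <- ecg_record("r", 360, numeric(100),
                     annotations = data.frame(sample_index = c(1L, 2L),
                                              raw_symbol = c("F", "F")))
  expect_equal(map_annotations(allf, quiet = TRUE)$annotations$mapped_class,
               c("F", "F"))
})

test_that("default label map retains six codes onto five classes, excludes 102/104", {
  lm <- label_map()
  expect_length(lm$mapping, 6L)
  expect_setequal(unique(unname(lm$mapping)), c("N", "B", "V", "A", "F"))
  expect_setequal(lm$excluded_records, c("102", "104"))
})

test_that("Fourier resampling rescales length, annotations and content", {
  n <- 2500
  rec <- ecg_record("r", 250, sin(2 * pi * 5 * (0:(n - 1)) / 250),
                    annotations = data.frame(sample_index = c(0L, 1250L, 2499L),
                                             raw_symbol = "N",
                                             mapped_class = "N"))
  up <- resample_record(rec, 360)
  expect_equal(length(up$signal), 3600L)
  expect_equal(up$fs, 360)
  expect_equal(up$annotations$sample_index, c(0L, 1800L, 3599L))
  # band-limited content preserved: compare with the analytic sinusoid
  ref <- sin(2 * pi * 5 * (0:3599) / 360)
  expect_gte(cor(up$signal, ref), 0.999)

  same <- resample_record(rec, 250)
  expect_equal(same$signal, rec$signal, tolerance = 1e-9)
  expect_error(resample_record(rec, -1), class = "ecgan_argument_error")
})

test_that("down-then-up resampling recovers band-limited signals", {
  set.seed(4)
  # a signal band-limited well below the lower Nyquist (125 Hz)
  t <- (0:7199) / 360
  x <- rowSums(vapply(c(1, 3.7, 9.2, 20),
                      function(f) sin(2 * pi * f * t + f), numeric(7200)))
  rec <- ecg_record("r", 360, x)
  down <- resample_record(rec, 250)
  back <- resample_record(down, 360)
  expect_equal(length(back$signal), 7200L)
  rms <- sqrt(mean((back$signal - x)^2))
  expect_lt(rms, 1e-6 * sqrt(mean(x^2)) + 1e-6)
})

test_that("segment store round-trips pairs, labels and provenance", {
  pairs <- make_bw_pairs(n_records = 1, duration_s = 10, seed = 2)
  expect_length(pairs, 15L)   # floor((3600-1024)/180) + 1
  f <- tempfile(fileext = ".rds")
  write_segment_store(pairs, f)
  back <- read_segment_store(f)
  expect_identical(back$segments, pairs)
  expect_equal(back$window_length, 1024L)

  # empty store is valid
  f0 <- tempfile(fileext = ".rds")
  write_segment_store(list(), f0)
  expect_length(read_segment_store(f0)$segments, 0L)

  # labeled segments round-trip with labels intact
  rec <- quick_record(seed = 9, duration_s = 20)
  segs <- make_labeled_segments(
    make_segment_pairs(rec, noise_recipe(c(BW = 1), 0), quick_bank(1),
                       seed = 1),
    rec$annotations)$segments
  f2 <- tempfile(fileext = ".rds")
  write_segment_store(segs, f2)
  expect_identical(read_segment_store(f2)$segments, segs)
  file.remove(f, f0, f2)
})

test_that("corrupted or inconsistent stores raise format errors", {
  f <- tempfile(fileext = ".rds")
  saveRDS(list(magic = "something-else"), f)
  expect_error(read_segment_store(f), class = "ecgan_format_error")
  # tamper with the header so the window length disagrees
  pairs <- make_bw_pairs(n_records = 1, duration_s = 10, seed = 3)
  write_segment_store(pairs, f)
  obj <- readRDS(f)
  obj$window_length <- 512L
  saveRDS(obj, f)
  expect_error(read_segment_store(f), class = "ecgan_format_error")
  expect_error(read_segment_store(tempfile()), class = "ecgan_io_error")
  file.remove(f)
})
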