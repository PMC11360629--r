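# Window slicing, labeling, normalization and splitting.

test_that("window counts match the closed form and brute force", {
  rec <- ecg_record("r", 360, numeric(2884))
  w <- slice_windows(rec, 1024L, 180L)
  expect_length(w, 11L)
  expect_equal(vapply(w, function(s) s$start_index, 0L), seq(0L, 1800L, 180L))

  expect_length(slice_windows(ecg_record("r", 360, numeric(1024)), 1024L), 1L)
  expect_warning(
    out <- slice_windows(ecg_record("r", 360, numeric(1023)), 1024L),
    "shorter"
  )
  expect_length(out, 0L)
})

test_that("window count formula equals enumeration across lengths and strides", {
  for (stride in c(1L, 180L, 512L)) {
    for (L in c(0L, 1L, 511L, 512L, 513L, 1023L, 1024L, 1025L,
                seq(600L, 5000L, by = 97L))) {
      # brute-force enumeration of valid starts
      starts <- 0L
      expected <- 0L
      s <- 0L
      while (s + 512L <= L) {
        expected <- expected + 1L
        s <- s + stride
      }
      got <- if (L >= 512L) {
        suppressWarnings(length(slice_windows(
          ecg_record("r", 360, numeric(max(L, 1))), 512L, stride)))
      } else {
        suppressWarnings(length(slice_windows(
          ecg_record("r", 360, numeric(max(L, 1))), 512L, stride)))
      }
      expect_identical(got, as.integer(expected))
    }
  }
})

test_that("windows overlapping lead-off samples are discarded", {
  mask <- rep(TRUE, 3000)
  mask[1500:1550] <- FALSE
  rec <- ecg_record("r", 360, numeric(3000), valid_mask = mask)
  w <- slice_windows(rec, 1024L, 180L)
  starts <- vapply(w, function(s) s$start_index, 0L)
  # any window with [start, start+1024) intersecting 1499..1549 (0-based) is gone
  bad <- vapply(seq(0L, 3000L - 1024L, 180L), function(s)
    s <= 1549L && s + 1024L > 1499L, TRUE)
  expect_equal(starts, setdiff(seq(0L, 3000L - 1024L, 180L),
                               seq(0L, 3000L - 1024L, 180L)[bad]))
})

test_that("assign_label picks the earliest in-window beat, half-open bounds", {
  ann <- data.frame(sample_index = c(100L, 300L),
                    raw_symbol = c("N", "V"),
                    mapped_class = c("N", "V"))
  expect_equal(assign_label(window_spec("r", 0L, 512L), ann), "N")
  expect_true(is.na(assign_label(window_spec("r", 400L, 512L),
                                 ann[ann$sample_index < 300, ])))
  # boundary: annotation exactly at start+511 included, at start+512 excluded
  ann2 <- data.frame(sample_index = 511L, raw_symbol = "A", mapped_class = "A")
  expect_equal(assign_label(window_spec("r", 0L, 512L), ann2), "A")
  ann3 <- data.frame(sample_index = 512L, raw_symbol = "A", mapped_class = "A")
  expect_true(is.na(assign_label(window_spec("r", 0L, 512L), ann3)))
})

test_that("first-beat labeling matches a linear-scan oracle on random sets", {
  set.seed(11)
  for (i in 1:300) {
    n_ann <- sample(0:12, 1)
    idx <- sort(sample(0:2000, n_ann))
    cls <- sample(c("N", "B", "V", "A", "F"), n_ann, replace = TRUE)
    ann <- data.frame(sample_index = idx, raw_symbol = cls,
                      mapped_class = cls)
    start <- sample(0:1500, 1)
    len <- sample(c(256L, 512L), 1)
    got <- assign_label(window_spec("r", start, len), ann)
    # oracle: scan annotations in order, first inside wins
    oracle <- NA_character_
    for (j in seq_len(n_ann)) {
      if (idx[j] >= start && idx[j] < start + len) { oracle <- cls[j]; break }
    }
    expect_identical(got, oracle)
  }
})

test_that("min-max normalization uses the noisy range, inverts exactly", {
  noisy <- c(0, 1, 2, 3)
  clean <- c(0.5, 1, 2, 4)    # exceeds the noisy max
  pair <- minmax_normalize(clean, noisy)
  expect_equal(pair$noisy, c(0, 1, 2, 3) / 3)
  expect_equal(pair$clean[4], 4 / 3)       # outside [0,1], not clamped
  expect_equal(denormalize(pair$clean, pair), clean, tolerance = 1e-12)
  expect_equal(denormalize(pair$noisy, pair), noisy, tolerance = 1e-12)
  # order preserved
  expect_true(all(diff(pair$noisy) > 0))
  expect_error(minmax_normalize(clean, rep(1, 4)),
               class = "ecgan_degenerate_error")
})

test_that("split_halves labels halves independently and drops unlabeled ones", {
  spec <- window_spec("r", 0L, 1024L)
  set.seed(3)
  x <- rnorm(1024)
  pair <- structure(list(clean = x, noisy = x, norm_min = 0, norm_max = 1,
                         spec = spec, recipe = NULL), class = "segment_pair")
  ann_both <- data.frame(sample_index = c(100L, 700L),
                         raw_symbol = c("N", "V"), mapped_class = c("N", "V"))
  segs <- split_halves(pair, ann_both)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) s$label, ""), c("N", "V"))
  expect_equal(vapply(segs, function(s) s$spec$start_index, 0L), c(0L, 512L))
  # classifier preprocessing: each half normalized on its own range
  expect_equal(range(segs[[1]]$window), c(0, 1))
  expect_equal(segs[[2]]$window,
               (x[513:1024] - min(x[513:1024])) / diff(range(x[513:1024])))
  # renormalize = FALSE keeps raw member values
  raw <- split_halves(pair, ann_both, renormalize = FALSE)
  expect_identical(raw[[1]]$window, x[1:512])

  ann_second <- ann_both[2, ]
  expect_length(split_halves(pair, ann_second), 1L)
  expect_length(split_halves(pair, ann_both[0, ]), 0L)
  # a labeled but constant half is dropped as degenerate
  flat <- pair; flat$clean <- rep(1, 1024)
  expect_length(split_halves(flat, ann_both), 0L)
})

test_that("train/test split is deterministic, 8:2, and record-disjoint", {
  items <- as.list(1:10)
  sp <- train_test_split(items, 0.8, seed = 5)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  sp2 <- train_test_split(items, 0.8, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:10)

  # stratified: each class keeps its ratio
  labs <- rep(c("N", "V"), c(40, 10))
  sp3 <- train_test_split(as.list(1:50), 0.8, seed = 2, labels = labs)
  expect_equal(sum(labs[sp3$train_idx] == "N"), 32)
  expect_equal(sum(labs[sp3$train_idx] == "V"), 8)

  # record mode: no record contributes to both sides
  ids <- rep(c("a", "b", "c", "d", "e"), each = 6)
  sp4 <- train_test_split(as.list(1:30), 0.8, seed = 3, mode = "record",
                          record_ids = ids)
  expect_length(intersect(unique(ids[sp4$train_idx]),
                          unique(ids[sp4$test_idx])), 0L)
})

test_that("volume report counts windowed labels against original beats", {
  rec <- quick_record(seed = 3, duration_s = 30)
  rep <- segment_volume_report(list(rec))
  expect_true(attr(rep, "factor") > 1)   # overlap multiplies labeled data
  expect_equal(rep$class, c("N", "B", "V", "A", "F"))
  expect_equal(sum(rep$original), nrow(rec$annotations))
})
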