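# Shared fixtures: everything is generated in code at test time.

# a short all-purpose synthetic record (10 s, mixed classes)
quick_record <- function(seed = 7, duration_s = 10,
                         class_mix = c(N = 0.6, B = 0.1, V = 0.15,
                                       A = 0.1, F = 0.05)) {
  generate_clean_ecg(synthetic_ecg_config(
    duration_s = duration_s, seed = seed, class_mix = class_mix))
}

quick_bank <- function(seed = 3, n = 360L * 30L) {
  make_noise_bank(n_samples = n, seed = seed)
}

# small architecture specs used by all learning tests
tiny_gen_spec <- function(len = 1024L) {
  generator_spec(input_len = len, depth = 4L, filters = c(4L, 8L, 16L, 16L),
                 kernel = 7L)
}

tiny_disc_spec <- function() {
  discriminator_spec(list(c(4L, 8L, 2L), c(8L, 8L, 2L)))
}

tiny_resnet_spec <- function(classes = c("N", "B", "V", "A"), len = 512L) {
  resnet_spec(input_len = len, classes = classes,
              stages = list(c(1L, 8L, 1L), c(1L, 16L, 2L), c(1L, 32L, 2L)),
              kernel = 7L)
}

# normalized clean/noisy pairs from BW contamination at 0 dB
make_bw_pairs <- function(n_records = 2, duration_s = 60, seed = 1,
                          snr_db = 0) {
  bank <- quick_bank(seed = seed + 1000)
  recipe <- noise_recipe(c(BW = 1), snr_db)
  unlist(lapply(seq_len(n_records), function(i) {
    rec <- generate_clean_ecg(synthetic_ecg_config(
      duration_s = duration_s, seed = seed + i))
    make_segment_pairs(rec, recipe, bank, stride = 180, seed = seed * 100 + i)
  }), recursive = FALSE)
}

# a separable labeled-segment set: one record per class mix, cut to halves
make_labeled_set <- function(n_per_class_records = 2, duration_s = 60,
                             seed = 1,
                             classes = c("N", "B", "V", "A")) {
  segs <- list()
  for (i in seq_len(n_per_class_records)) {
    rec <- generate_clean_ecg(synthetic_ecg_config(
      duration_s = duration_s, seed = seed + i,
      class_mix = setNames(rep(1 / length(classes), length(classes)),
                           classes)))
    specs <- slice_windows(rec, 1024L, 180L)
    for (s in specs) {
      w <- rec$signal[(s$start_index + 1L):(s$start_index + s$length)]
      pair <- minmax_normalize(w, w, spec = s)
      segs <- c(segs, split_halves(pair, rec$annotations))
    }
  }
  segs
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}

# lazily trained tiny models, shared across test files to keep the suite fast
.model_cache <- new.env(parent = emptyenv())

cached_tiny_denoiser <- function() {
  if (is.null(.model_cache$den)) {
    pairs <- make_bw_pairs(n_records = 1, duration_s = 60, seed = 41)
    .model_cache$den_pairs <- pairs
    .model_cache$den <- train_denoiser(
      pairs, epochs = 2, gen_spec = tiny_gen_spec(),
      disc_spec = tiny_disc_spec(), seed = 5)
  }
  .model_cache$den
}

cached_tiny_classifier <- function() {
  if (is.null(.model_cache$cls)) {
    segs <- make_labeled_set(n_per_class_records = 1, duration_s = 60,
                             seed = 21)
    .model_cache$cls_segs <- segs
    .model_cache$cls <- train_classifier(
      segs, epochs = 3, spec = tiny_resnet_spec(), seed = 5)
  }
  .model_cache$cls
}
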