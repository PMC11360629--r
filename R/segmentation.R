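# Fixed-window segmentation.
#
# Records are cut into 1024-sample denoising windows at a 180-sample stride
# (2.84 s windows shifted by 0.50 s at 360 Hz) — fixed time-based
# segmentation, deliberately *not* R-peak-centred. Each 1024-window is
# normalized to the noisy member's min-max range and later split into two
# 512-sample halves for beat classification; a half's label is the class of
# the earliest annotation inside it (half-open [start, start+len)), and
# unlabeled halves are discarded and counted.

#' Window specification
#' @param record_id record the window came from
#' @param start_index 0-based start sample
#' @param length window length in samples
#' @return a `window_spec`
#' @export
window_spec <- function(record_id, start_index, length) {
  structure(list(record_id = as.character(record_id),
                 start_index = as.integer(start_index),
                 length = as.integer(length)),
            class = "window_spec")
}

#' Slice a record into fixed-stride windows
#'
#' Windows start at 0 and advance by `stride`; the count is
#' `floor((L - window_len)/stride) + 1` for `L >= window_len`, else 0 (with
#' a warning). Windows overlapping any invalid (lead-off) sample are
#' removed.
#'
#' @param rec an [ecg_record()]
#' @param window_len window length in samples (1024 for denoising pairs)
#' @param stride shift between consecutive windows in samples
#' @return list of [window_spec()]
#' @export
slice_windows <- function(rec, window_len = 1024L, stride = 180L) {
  stopifnot(inherits(rec, "ecg_record"))
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  if (window_len <= 0L || stride <= 0L) {
    stop_argument("`window_len` and `stride` must be positive")
  }
  L <- length(rec$signal)
  if (L < window_len) {
    warning(sprintf("record %s (%d samples) is shorter than one %d-sample window",
                    rec$record_id, L, window_len))
    return(list())
  }
  starts <- seq.int(0L, L - window_len, by = stride)
  if (!is.null(rec$valid_mask)) {
    bad_cum <- cumsum(!rec$valid_mask)
    nbad <- bad_cum[starts + window_len] - c(0, bad_cum)[starts + 1L]
    starts <- starts[nbad == 0L]
  }
  lapply(starts, function(s) window_spec(rec$record_id, s, window_len))
}

#' Label a window by its earliest contained beat annotation
#'
#' @param spec a [window_spec()]
#' @param annotations annotation data frame (sorted by `sample_index`,
#'   with `mapped_class` filled in)
#' @return the class of the first annotation inside
#'   `[start, start+length)`, or `NA_character_` when none falls inside
#' @export
assign_label <- function(spec, annotations) {
  stopifnot(inherits(spec, "window_spec"))
  if (!nrow(annotations)) return(NA_character_)
  inside <- annotations$sample_index >= spec$start_index &
    annotations$sample_index < spec$start_index + spec$length
  if (!any(inside)) return(NA_character_)
  annotations$mapped_class[which(inside)[1L]]
}

#' Min-max normalize a clean/noisy window pair
#'
#' Both members are mapped by `(x - min(noisy)) / (max(noisy) - min(noisy))`.
#' The parameters come from the *noisy* member only (the clean signal is
#' unknown at inference time), so clean values may fall outside `[0, 1]`;
#' they are not clamped. Parameters are stored for exact inversion.
#'
#' @param clean,noisy numeric windows of equal length
#' @param spec optional [window_spec()] provenance
#' @param recipe optional [noise_recipe()] provenance
#' @return a `segment_pair`: `clean`, `noisy` (normalized), `norm_min`,
#'   `norm_max`, `spec`, `recipe`
#' @export
minmax_normalize <- function(clean, noisy, spec = NULL, recipe = NULL) {
  if (length(clean) != length(noisy)) {
    stop_argument("`clean` and `noisy` must have equal length")
  }
  lo <- min(noisy); hi <- max(noisy)
  if (hi <= lo) stop_degenerate("constant noisy window; min-max scale is undefined")
  structure(
    list(clean = (clean - lo) / (hi - lo), noisy = (noisy - lo) / (hi - lo),
         norm_min = lo, norm_max = hi, spec = spec, recipe = recipe),
    class = "segment_pair"
  )
}

# min-max normalize a window on its own range (identity for constant input)
normalize_window <- function(x) {
  rng <- range(x)
  if (rng[2] <= rng[1]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Invert min-max normalization
#' @param x normalized values
#' @param pair the `segment_pair` holding `norm_min`/`norm_max`
#' @return values back in mV
#' @export
denormalize <- function(x, pair) {
  x * (pair$norm_max - pair$norm_min) + pair$norm_min
}

#' Split a 1024-sample pair into two labeled 512-sample halves
#'
#' Halves cover `[0, 512)` and `[512, 1024)` of the window; each is labeled
#' by [assign_label()] against the record's annotations and unlabeled
#' halves are dropped. By default each half is min-max normalized on its
#' own range — the classifier's preprocessing — so segments from clean,
#' contaminated and denoised corpora all reach the model on one scale.
#' Degenerate (constant) halves are dropped like unlabeled ones.
#'
#' @param pair a `segment_pair`
#' @param annotations the source record's mapped annotation table
#' @param member which member of the pair to cut (`"clean"`, `"noisy"`)
#'   or a numeric vector of the window's length (e.g. a denoised window)
#' @param renormalize min-max normalize each half on its own range
#' @return list of 0-2 `labeled_segment` objects (`window`, `label`, `spec`)
#' @export
split_halves <- function(pair, annotations, member = "clean",
                         renormalize = TRUE) {
  stopifnot(inherits(pair, "segment_pair"))
  x <- if (is.character(member)) pair[[member]] else as.numeric(member)
  n <- length(x)
  if (n %% 2L != 0L) stop_argument("window length must be even")
  half <- n %/% 2L
  out <- list()
  for (h in 0:1) {
    hspec <- window_spec(pair$spec$record_id,
                         pair$spec$start_index + h * half, half)
    lab <- assign_label(hspec, annotations)
    if (is.na(lab)) next
    w <- x[(h * half + 1L):((h + 1L) * half)]
    if (renormalize) {
      rng <- range(w)
      if (rng[2] <= rng[1]) next
      w <- (w - rng[1]) / (rng[2] - rng[1])
    }
    out[[length(out) + 1L]] <- structure(
      list(window = w, label = lab, spec = hspec),
      class = "labeled_segment"
    )
  }
  out
}

#' Deterministic train/test split
#'
#' In `segment` mode items are split individually, stratified by label when
#' labels are supplied; in `record` mode whole records are assigned to one
#' side so no record leaks across the split.
#'
#' @param items list of segments (or any objects)
#' @param ratio train fraction (default 0.8, the 8:2 protocol)
#' @param seed integer seed
#' @param mode `"segment"` or `"record"`
#' @param labels optional character vector (stratification, segment mode)
#' @param record_ids character vector of record ids (required in record mode;
#'   defaults to each item's `spec$record_id` when available)
#' @return list with `train` and `test` item lists and the index vectors
#'   `train_idx`, `test_idx`
#' @export
train_test_split <- function(items, ratio = 0.8, seed = 1L,
                             mode = c("segment", "record"),
                             labels = NULL, record_ids = NULL) {
  mode <- match.arg(mode)
  n <- length(items)
  if (n == 0L) stop_argument("nothing to split")
  if (ratio <= 0 || ratio >= 1) stop_argument("`ratio` must be in (0, 1)")
  if (mode == "segment") {
    idx <- seq_len(n)
    if (is.null(labels)) {
      n_train <- round(ratio * n)
      train_idx <- with_seed(derive_seed(seed, "split"),
                             sort(sample.int(n, n_train)))
    } else {
      stopifnot(length(labels) == n)
      train_idx <- integer(0)
      for (cl in unique(labels)) {
        sub <- idx[labels == cl]
        k <- round(ratio * length(sub))
        pick <- with_seed(derive_seed(seed, paste0("split-", cl)),
                          sample(sub, k))
        train_idx <- c(train_idx, pick)
      }
      train_idx <- sort(train_idx)
    }
  } else {
    if (is.null(record_ids)) {
      record_ids <- vapply(items, function(s) s$spec$record_id, "")
    }
    stopifnot(length(record_ids) == n)
    recs <- unique(record_ids)
    k <- max(1L, round(ratio * length(recs)))
    if (k >= length(recs)) k <- length(recs) - 1L
    train_recs <- with_seed(derive_seed(seed, "split-records"),
                            sample(recs, k))
    train_idx <- which(record_ids %in% train_recs)
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = items[train_idx], test = items[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}

#' Build normalized denoising pairs from a record and a noise recipe
#'
#' Slices the record at `stride`, contaminates each window at the recipe's
#' target SNR (fresh bank offsets per window, seeded), and min-max
#' normalizes each pair. The noise weight is recomputed per window, so the
#' target SNR holds window by window.
#'
#' @param rec an [ecg_record()] (annotations already mapped if labels are
#'   needed downstream)
#' @param recipe a [noise_recipe()]
#' @param noise_bank bank as in [synthesize_noisy()]
#' @param window_len,stride segmentation parameters
#' @param seed integer seed
#' @return list of `segment_pair` objects
#' @export
make_segment_pairs <- function(rec, recipe, noise_bank,
                               window_len = 1024L, stride = 180L, seed = 1L) {
  specs <- slice_windows(rec, window_len, stride)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    clean <- rec$signal[(s$start_index + 1L):(s$start_index + s$length)]
    syn <- synthesize_noisy(clean, recipe, noise_bank,
                            seed = derive_seed(seed, paste0("win-", i)))
    out[[i]] <- minmax_normalize(clean, syn$noisy, spec = s, recipe = recipe)
  }
  out
}

#' Cut labeled classification segments out of denoising pairs
#'
#' @param pairs list of `segment_pair`
#' @param annotations the record's mapped annotation table
#' @param member which member to cut (see [split_halves()]); pass a list of
#'   numeric windows (e.g. denoised output) to cut those instead
#' @param renormalize min-max normalize each half on its own range
#' @return list with `segments` (labeled) and `n_dropped` (unlabeled or
#'   degenerate halves)
#' @export
make_labeled_segments <- function(pairs, annotations, member = "clean",
                                  renormalize = TRUE) {
  segs <- list(); dropped <- 0L
  for (i in seq_along(pairs)) {
    mem <- if (is.list(member)) member[[i]] else member
    got <- split_halves(pairs[[i]], annotations, mem, renormalize)
    dropped <- dropped + (2L - length(got))
    segs <- c(segs, got)
  }
  list(segments = segs, n_dropped = dropped)
}

#' Data-volume bookkeeping for fixed-window relabeling
#'
#' Compares the number of original beat annotations with the number of
#' labeled 512-sample segments the sliding-window protocol produces — the
#' overlap of adjacent windows multiplies the labeled data volume.
#'
#' @param records list of mapped [ecg_record()]s
#' @param window_len,stride segmentation parameters
#' @return data frame with per-class original and windowed counts and the
#'   overall multiplication factor as attribute `"factor"`
#' @export
segment_volume_report <- function(records, window_len = 1024L, stride = 180L) {
  orig <- setNames(numeric(5), BEAT_CLASSES)
  prop <- setNames(numeric(5), BEAT_CLASSES)
  for (rec in records) {
    tab <- table(rec$annotations$mapped_class)
    orig[names(tab)] <- orig[names(tab)] + as.numeric(tab)
    for (s in slice_windows(rec, window_len, stride)) {
      half <- s$length %/% 2L
      for (h in 0:1) {
        lab <- assign_label(
          window_spec(s$record_id, s$start_index + h * half, half),
          rec$annotations
        )
        if (!is.na(lab)) prop[lab] <- prop[lab] + 1
      }
    }
  }
  out <- data.frame(class = BEAT_CLASSES, original = as.numeric(orig),
                    windowed = as.numeric(prop))
  attr(out, "factor") <- sum(prop) / max(1, sum(orig))
  out
}
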