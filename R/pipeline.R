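# Offline pipeline plumbing: corpus evaluation in the noisy / original /
# denoised layout, state (de)serialization, and a stream simulator that
# replays a record window-by-window — an in-process stand-in for the
# deployed parsing/slicing/normalization/denoising/classification service.

#' Save / load a trained denoiser
#' @param state a `denoiser_state`
#' @param path file path
#' @return `path` invisibly (`save`), the state (`load`)
#' @export
save_denoiser <- function(state, path) {
  stopifnot(inherits(state, "denoiser_state"))
  saveRDS(list(format = "ecgan-denoiser", version = 1L,
               generator = net_to_list(state$generator),
               discriminator = net_to_list(state$discriminator),
               history = state$history, seed = state$seed), path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  if (!file.exists(path)) stop_io("denoiser checkpoint not found: " %+% path)
  l <- readRDS(path)
  if (!identical(l$format, "ecgan-denoiser")) stop_format("not a denoiser checkpoint")
  structure(list(generator = net_from_list(l$generator),
                 discriminator = net_from_list(l$discriminator),
                 history = l$history, seed = l$seed),
            class = "denoiser_state")
}

#' Save / load a trained classifier
#' @param state a `classifier_state`
#' @param path file path
#' @return `path` invisibly (`save`), the state (`load`)
#' @export
save_classifier <- function(state, path) {
  stopifnot(inherits(state, "classifier_state"))
  nl <- net_to_list(state$net)
  nl$classes <- state$net$classes
  nl$stage_nodes <- state$net$stage_nodes
  saveRDS(list(format = "ecgan-classifier", version = 1L, net = nl,
               classes = state$classes, history = state$history,
               class_counts = state$class_counts, seed = state$seed), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop_io("classifier checkpoint not found: " %+% path)
  l <- readRDS(path)
  if (!identical(l$format, "ecgan-classifier")) stop_format("not a classifier checkpoint")
  net <- net_from_list(l$net)
  net$classes <- l$net$classes
  net$stage_nodes <- l$net$stage_nodes
  structure(list(net = net, classes = l$classes, history = l$history,
                 class_counts = l$class_counts, seed = l$seed),
            class = "classifier_state")
}

#' Evaluate classification on noisy, original and denoised corpora
#'
#' Builds the three parallel corpora from one record: clean windows, their
#' contaminated versions at the recipe's SNR, and the denoised versions,
#' cuts each into labeled 512-sample halves, classifies them with the given
#' model, and returns one [classification_report()] per corpus plus the
#' mean denoising metrics.
#'
#' @param rec a mapped [ecg_record()]
#' @param recipe a [noise_recipe()]
#' @param noise_bank noise bank (see [synthesize_noisy()])
#' @param denoiser a `denoiser_state`
#' @param classifier a `classifier_state`
#' @param stride window stride in samples
#' @param seed integer seed
#' @return list: `reports` (named list noisy/original/denoised),
#'   `denoise_metrics` (data frame), `table` (aligned-text lines)
#' @export
evaluate_corpora <- function(rec, recipe, noise_bank, denoiser, classifier,
                             stride = 180L, seed = 1L) {
  pairs <- make_segment_pairs(rec, recipe, noise_bank, stride = stride,
                              seed = seed)
  den <- denoise(denoiser, lapply(pairs, function(p) p$noisy))
  ann <- rec$annotations
  clean_segs <- make_labeled_segments(pairs, ann, member = "clean")$segments
  noisy_segs <- make_labeled_segments(pairs, ann, member = "noisy")$segments
  den_segs <- make_labeled_segments(pairs, ann, member = den)$segments

  rep_for <- function(segs) {
    truth <- vapply(segs, function(s) s$label, "")
    pred <- predict(classifier, segs)$labels
    classification_report(truth, pred, classes = classifier$classes)
  }
  reports <- list(noisy = rep_for(noisy_segs), original = rep_for(clean_segs),
                  denoised = rep_for(den_segs))
  dm <- evaluate_denoiser(denoiser, pairs)
  list(reports = reports, denoise_metrics = dm,
       table = format_report_table(reports))
}

#' Replay a record through the pipeline window-by-window
#'
#' Simulates streaming arrival: each 1024-sample window is normalized to
#' its own min-max range, denoised, split into two 512-sample halves, and
#' classified — one window per step, in arrival order. Because inference is
#' batch-order invariant, the emitted predictions are identical to batch
#' processing of the same windows. Windows overlapping lead-off samples are
#' skipped and counted.
#'
#' @param rec an [ecg_record()]
#' @param denoiser a trained `denoiser_state`
#' @param classifier a trained `classifier_state`
#' @param stride stride between arriving windows, in samples
#' @param window_len window length in samples
#' @return list: `events` — data frame with one row per window
#'   (`window_index`, `start_index`, `t_arrive_s`, `label_half1`,
#'   `label_half2`) — `denoised` (matrix, one row per window, normalized
#'   scale) and `n_skipped` (lead-off windows dropped)
#' @export
stream_simulate <- function(rec, denoiser, classifier, stride = 180L,
                            window_len = 1024L) {
  if (!inherits(denoiser, "denoiser_state")) {
    stop_argument("`denoiser` must be a trained denoiser_state")
  }
  if (!inherits(classifier, "classifier_state")) {
    stop_argument("`classifier` must be a trained classifier_state")
  }
  stopifnot(inherits(rec, "ecg_record"))
  specs <- slice_windows(rec, window_len, stride)
  n_total <- if (length(rec$signal) >= window_len) {
    (length(rec$signal) - window_len) %/% stride + 1L
  } else 0L
  n_skipped <- n_total - length(specs)
  if (n_skipped > 0L) {
    message(sprintf("stream: skipped %d window(s) overlapping lead-off gaps",
                    n_skipped))
  }
  half <- window_len %/% 2L
  events <- data.frame(window_index = integer(0), start_index = integer(0),
                       t_arrive_s = numeric(0), label_half1 = character(0),
                       label_half2 = character(0))
  den_out <- matrix(0, length(specs), window_len)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    w <- rec$signal[(s$start_index + 1L):(s$start_index + window_len)]
    pair <- minmax_normalize(w, w, spec = s)
    d <- denoise(denoiser, pair$noisy)
    den_out[i, ] <- d
    # classifier preprocessing: each half min-max normalized on its range
    h1 <- normalize_window(d[1:half])
    h2 <- normalize_window(d[(half + 1L):window_len])
    pr <- predict(classifier, rbind(h1, h2))
    events <- rbind(events, data.frame(
      window_index = i, start_index = s$start_index,
      t_arrive_s = (s$start_index + window_len) / rec$fs,
      label_half1 = pr$labels[1], label_half2 = pr$labels[2],
      stringsAsFactors = FALSE
    ))
  }
  list(events = events, denoised = den_out, n_skipped = n_skipped)
}
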