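#' Construct a single-lead ECG record
#'
#' The central container of the package: one channel of ECG in physical
#' units (mV), its sampling rate, beat annotations, and an optional
#' per-sample validity mask marking lead-off stretches.
#'
#' Annotations are a data frame with 0-based `sample_index`, the original
#' annotation code `raw_symbol`, and (after [map_annotations()]) a
#' `mapped_class` in `{N, B, V, A, F}` or `NA`.
#'
#' @param record_id character record identifier (e.g. `"100"`)
#' @param fs sampling rate in Hz, positive
#' @param signal numeric vector of amplitudes in mV
#' @param channel_name channel label, e.g. `"MLII"`
#' @param annotations data frame with columns `sample_index` (0-based,
#'   within `[0, length(signal))`, sorted), `raw_symbol` (character) and
#'   optionally `mapped_class`
#' @param valid_mask optional logical vector, same length as `signal`;
#'   `FALSE` marks invalid (lead-off) samples
#' @return an object of class `ecg_record`
#' @export
ecg_record <- function(record_id, fs, signal, channel_name = "MLII",
                       annotations = NULL, valid_mask = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0) {
    stop_argument("`fs` must be a single positive number")
  }
  signal <- as.numeric(signal)
  if (anyNA(signal)) stop_argument("`signal` must not contain NA")
  if (is.null(annotations)) {
    annotations <- empty_annotations()
  } else {
    annotations <- as.data.frame(annotations)
    if (!all(c("sample_index", "raw_symbol") %in% names(annotations))) {
      stop_argument("`annotations` needs columns sample_index and raw_symbol")
    }
    if (!"mapped_class" %in% names(annotations)) {
      annotations$mapped_class <- NA_character_
    }
    annotations <- annotations[, c("sample_index", "raw_symbol", "mapped_class")]
    annotations$sample_index <- as.integer(annotations$sample_index)
    annotations$raw_symbol <- as.character(annotations$raw_symbol)
    annotations$mapped_class <- as.character(annotations$mapped_class)
    if (nrow(annotations)) {
      if (is.unsorted(annotations$sample_index)) {
        annotations <- annotations[order(annotations$sample_index), , drop = FALSE]
        rownames(annotations) <- NULL
      }
      bad <- annotations$sample_index < 0L |
        annotations$sample_index >= length(signal)
      if (any(bad)) {
        stop_argument(sprintf(
          "annotation sample_index out of range [0, %d): %s",
          length(signal),
          paste(annotations$sample_index[bad], collapse = ", ")
        ))
      }
    }
  }
  if (!is.null(valid_mask)) {
    valid_mask <- as.logical(valid_mask)
    if (length(valid_mask) != length(signal) || anyNA(valid_mask)) {
      stop_argument("`valid_mask` must be a complete logical vector the same length as `signal`")
    }
  }
  structure(
    list(
      record_id = as.character(record_id),
      fs = as.numeric(fs),
      signal = signal,
      channel_name = as.character(channel_name),
      annotations = annotations,
      valid_mask = valid_mask
    ),
    class = "ecg_record"
  )
}

empty_annotations <- function() {
  data.frame(
    sample_index = integer(0),
    raw_symbol = character(0),
    mapped_class = character(0),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$signal) / x$fs
  cat(sprintf(
    "<ecg_record %s> channel %s, %d samples @ %g Hz (%.1f s), %d annotations%s\n",
    x$record_id, x$channel_name, length(x$signal), x$fs, dur,
    nrow(x$annotations),
    if (is.null(x$valid_mask)) "" else
      sprintf(", %d invalid samples", sum(!x$valid_mask))
  ))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$signal)

# The five retained beat classes.
BEAT_CLASSES <- c("N", "B", "V", "A", "F")

#' Beat-label mapping from raw annotation codes to retained classes
#'
#' The default keeps the six raw MIT-BIH beat codes N, L, R, V, A, F and
#' folds left and right bundle-branch block beats (L, R) into one
#' interventricular-block class B, giving five classes; records 102 and 104
#' (no MLII channel) are excluded by default.
#'
#' @param mapping named character vector: names are raw annotation codes,
#'   values the retained class
#' @param excluded_records character vector of record ids to exclude
#' @return an object of class `label_map`
#' @export
label_map <- function(mapping = c(N = "N", L = "B", R = "B",
                                  V = "V", A = "A", F = "F"),
                      excluded_records = c("102", "104")) {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop_argument("`mapping` must be a fully named character vector")
  }
  if (!all(mapping %in% BEAT_CLASSES)) {
    stop_argument("mapped classes must lie in {N, B, V, A, F}")
  }
  structure(
    list(mapping = mapping, excluded_records = as.character(excluded_records)),
    class = "label_map"
  )
}

#' Map raw beat annotations to the retained class alphabet
#'
#' Annotations whose raw code is outside the map are dropped; kept ones get
#' `mapped_class` filled in (L and R both become B under the default map).
#' The number of dropped annotations per raw symbol is recorded in the
#' `dropped` attribute of the returned record's annotation table and
#' reported via `message()`.
#'
#' @param rec an [ecg_record()]
#' @param map a [label_map()]
#' @param quiet suppress the drop-count message
#' @return the record with mapped, filtered annotations
#' @export
map_annotations <- function(rec, map = label_map(), quiet = FALSE) {
  stopifnot(inherits(rec, "ecg_record"), inherits(map, "label_map"))
  ann <- rec$annotations
  keep <- ann$raw_symbol %in% names(map$mapping)
  dropped <- table(ann$raw_symbol[!keep])
  ann_out <- ann[keep, , drop = FALSE]
  ann_out$mapped_class <- unname(map$mapping[ann_out$raw_symbol])
  rownames(ann_out) <- NULL
  attr(ann_out, "dropped") <- dropped
  if (!quiet && length(dropped)) {
    message(sprintf(
      "record %s: dropped %d annotation(s) outside the label map (%s)",
      rec$record_id, sum(dropped),
      paste(sprintf("%s=%d", names(dropped), as.integer(dropped)), collapse = ", ")
    ))
  }
  rec$annotations <- ann_out
  rec
}
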