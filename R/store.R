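# Segment store: a single-file container for denoising pairs and labeled
# classification segments. One file holds a header (magic, schema version,
# window length, sampling rate, count) plus the payload; the header is
# validated on read so truncated or foreign files fail loudly instead of
# producing silently wrong windows.

STORE_MAGIC <- "ecgan-segment-store"
STORE_VERSION <- 1L

#' Write segment pairs or labeled segments to a single-file store
#'
#' @param segments a list of `segment_pair` or `labeled_segment` objects
#'   (may be empty); all windows must share one length
#' @param path output file path
#' @param fs sampling rate the segments were cut at (metadata)
#' @return `path`, invisibly
#' @export
write_segment_store <- function(segments, path, fs = 360) {
  stopifnot(is.list(segments))
  kinds <- unique(vapply(segments, function(s) class(s)[[1]], ""))
  if (length(kinds) > 1L) {
    stop_argument("a store holds one segment type, got: " %+% paste(kinds, collapse = ", "))
  }
  wl <- unique(unlist(lapply(segments, segment_window_length)))
  if (length(wl) > 1L) {
    stop_argument("segments have differing window lengths: " %+%
                    paste(wl, collapse = ", "))
  }
  obj <- list(
    magic = STORE_MAGIC,
    version = STORE_VERSION,
    kind = if (length(kinds)) kinds else NA_character_,
    window_length = if (length(wl)) wl else NA_integer_,
    fs = fs,
    n = length(segments),
    segments = segments
  )
  saveRDS(obj, path)
  invisible(path)
}

#' Read a segment store written by [write_segment_store()]
#'
#' @param path file path
#' @return list with elements `segments`, `window_length`, `fs`, `kind`
#' @export
read_segment_store <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("segment store not found: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop_format(sprintf("not a readable segment store: %s", path))
  })
  if (!is.list(obj) || !identical(obj$magic, STORE_MAGIC)) {
    stop_format("file lacks the segment-store signature")
  }
  if (!identical(obj$version, STORE_VERSION)) {
    stop_format(sprintf("unsupported store schema version: %s", obj$version))
  }
  if (!identical(obj$n, length(obj$segments))) {
    stop_format("store header count does not match payload")
  }
  wl <- unique(unlist(lapply(obj$segments, segment_window_length)))
  if (length(wl) > 1L || (length(wl) == 1L && !identical(wl, obj$window_length))) {
    stop_format("segment window lengths do not match the store header")
  }
  obj[c("segments", "window_length", "fs", "kind")]
}

segment_window_length <- function(s) {
  if (inherits(s, "segment_pair")) length(s$clean)
  else if (inherits(s, "labeled_segment")) length(s$window)
  else stop_argument("unknown segment type: " %+% class(s)[[1]])
}

`%+%` <- function(a, b) paste0(a, b)
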