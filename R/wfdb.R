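# WFDB record I/O.
#
# Implements the subset of the WFDB specification the pipeline needs:
# text .hea headers, signal files in format 212 (two 12-bit two's-complement
# samples packed into 3 bytes, frames interleaved across channels) and
# format 16 (little-endian int16), and MIT-format .atr beat annotations
# (6-bit type / 10-bit interval words with SKIP/NUM/SUB/CHN/AUX pseudo
# annotations). Physical units: physical = (digital - baseline) / gain.

# MIT annotation code table (subset; beat codes 1-13 plus the non-beat
# codes that occur in mitdb records).
WFDB_ANN_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L,
  "~" = 14L, "|" = 16L, "x" = 37L, "f" = 38L, "e" = 34L,
  "+" = 28L, "\"" = 22L, "!" = 31L, "[" = 32L, "]" = 33L
)

wfdb_symbol_for <- function(code) {
  sym <- names(WFDB_ANN_CODES)[match(code, WFDB_ANN_CODES)]
  sym[is.na(sym)] <- "?"
  sym
}

#' Read a WFDB record
#'
#' Reads a `.hea`/`.dat` pair (formats 212 and 16) plus, when present, the
#' `.atr` annotation file, and returns the requested channel as an
#' [ecg_record()] in physical units (mV).
#'
#' @param path record path *without* extension, e.g. `"data/100"`
#' @param channel channel name to extract (matched against the signal
#'   description field), e.g. `"MLII"`
#' @return an [ecg_record()]
#' @export
read_wfdb_record <- function(path, channel = "MLII") {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop_io(sprintf("header file not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rl <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  record_id <- rl[[1]]
  nsig <- as.integer(rl[[2]])
  fs <- if (length(rl) >= 3) as.numeric(sub("/.*$", "", rl[[3]])) else 250
  nsamp <- if (length(rl) >= 4) as.numeric(rl[[4]]) else NA_real_

  if (length(lines) < 1 + nsig) stop_format("header shorter than its signal count")
  sigs <- lapply(lines[2:(1 + nsig)], parse_wfdb_signal_line)
  descs <- vapply(sigs, `[[`, "", "description")
  ch <- which(descs == channel)
  if (length(ch) == 0L) {
    ecgan_stop(sprintf(
      "channel \"%s\" not found in record %s (available: %s)",
      channel, record_id, paste(descs, collapse = ", ")
    ), "ecgan_channel_error")
  }
  ch <- ch[[1]]

  datfile <- file.path(dirname(path), sigs[[ch]]$file)
  if (!file.exists(datfile)) stop_io(sprintf("signal file not found: %s", datfile))
  fmt <- sigs[[ch]]$format
  digital <- switch(as.character(fmt),
    "212" = read_dat_212(datfile, nsig, nsamp),
    "16"  = read_dat_16(datfile, nsig, nsamp),
    stop_format(sprintf("unsupported WFDB signal format: %s", fmt))
  )
  d <- digital[, ch]
  phys <- (d - sigs[[ch]]$baseline) / sigs[[ch]]$gain

  ann <- empty_annotations()
  atr <- paste0(path, ".atr")
  if (file.exists(atr)) {
    ann <- read_atr(atr)
    ann <- ann[ann$sample_index < length(phys), , drop = FALSE]
  }
  ecg_record(record_id, fs, phys, channel_name = channel, annotations = ann)
}

parse_wfdb_signal_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  fmt <- sub("x.*$", "", sub(":.*$", "", f[[2]]))
  gain <- 200; baseline <- NA_real_; adczero <- 0
  if (length(f) >= 3) {
    gspec <- f[[3]]
    base <- regmatches(gspec, regexpr("\\(([-0-9]+)\\)", gspec))
    if (length(base)) baseline <- as.numeric(gsub("[()]", "", base))
    g <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gspec))
    if (!is.na(g) && g != 0) gain <- g
  }
  if (length(f) >= 5) adczero <- as.numeric(f[[5]])
  if (is.na(baseline)) baseline <- adczero
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(
    file = f[[1]], format = fmt, gain = gain, baseline = baseline,
    adczero = adczero, description = desc
  )
}

read_dat_212 <- function(file, nsig, nsamp) {
  raw <- readBin(file, "raw", n = file.size(file))
  b <- as.integer(raw)
  ntrip <- length(b) %/% 3L
  b <- b[seq_len(ntrip * 3L)]
  b1 <- b[seq(1L, by = 3L, length.out = ntrip)]
  b2 <- b[seq(2L, by = 3L, length.out = ntrip)]
  b3 <- b[seq(3L, by = 3L, length.out = ntrip)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  total <- if (is.na(nsamp)) (length(flat) %/% nsig) * nsig else nsamp * nsig
  if (length(flat) < total) stop_format("signal file shorter than header declares")
  matrix(flat[seq_len(total)], ncol = nsig, byrow = TRUE)
}

read_dat_16 <- function(file, nsig, nsamp) {
  v <- readBin(file, "integer", n = file.size(file) %/% 2L,
               size = 2L, signed = TRUE, endian = "little")
  total <- if (is.na(nsamp)) (length(v) %/% nsig) * nsig else nsamp * nsig
  if (length(v) < total) stop_format("signal file shorter than header declares")
  matrix(v[seq_len(total)], ncol = nsig, byrow = TRUE)
}

read_atr <- function(file) {
  raw <- readBin(file, "raw", n = file.size(file))
  b <- as.integer(raw)
  n <- length(b) %/% 2L
  idx <- i <- 1L
  times <- integer(0); codes <- integer(0)
  t_now <- 0
  while (i + 1L <= 2L * n) {
    w <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    typ <- bitwShiftR(w, 10L)
    interval <- bitwAnd(w, 1023L)
    if (typ == 0L && interval == 0L) break  # EOF
    if (typ == 59L) {                       # SKIP: 4-byte interval follows
      if (interval == 0L) {
        hi <- b[i] + 256L * b[i + 1L]
        lo <- b[i + 2L] + 256L * b[i + 3L]
        i <- i + 4L
        jump <- hi * 65536 + lo
        if (jump > 2^31) jump <- jump - 2^32
        t_now <- t_now + jump
      }
    } else if (typ == 63L) {                # AUX: skip payload (even-padded)
      i <- i + interval + (interval %% 2L)
    } else if (typ %in% c(60L, 61L, 62L)) { # NUM/SUB/CHN: no time advance
      # field value ignored
    } else {
      t_now <- t_now + interval
      times <- c(times, t_now)
      codes <- c(codes, typ)
    }
  }
  data.frame(
    sample_index = as.integer(times),
    raw_symbol = wfdb_symbol_for(codes),
    mapped_class = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write an ECG record in WFDB format
#'
#' Writes `<record_id>.hea` and a format-212 (default) or format-16 `.dat`
#' into `dir`, plus an MIT-format `.atr` when the record carries
#' annotations. The signal is quantized to `round(mV * gain)` ADC units;
#' the returned record contains the signal as stored, so
#' `read_wfdb_record()` round-trips it bit-exactly.
#'
#' @param rec an [ecg_record()]
#' @param dir output directory (created if missing)
#' @param gain ADC units per mV (default 200, the mitdb convention)
#' @param format `"212"` or `"16"`
#' @return invisibly, the record with the quantized signal as written
#' @export
write_wfdb_record <- function(rec, dir, gain = 200, format = c("212", "16")) {
  stopifnot(inherits(rec, "ecg_record"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- as.integer(round(rec$signal * gain))
  lim <- if (format == "212") c(-2048L, 2047L) else c(-32768L, 32767L)
  if (any(d < lim[1] | d > lim[2])) {
    stop_argument(sprintf(
      "signal exceeds the %s-format ADC range after applying gain %g",
      format, gain
    ))
  }
  id <- rec$record_id
  datname <- paste0(id, ".dat")
  adcres <- if (format == "212") 11L else 16L
  checksum <- sum(d) %% 65536
  if (checksum > 32767) checksum <- checksum - 65536
  hea <- c(
    sprintf("%s 1 %g %d", id, rec$fs, length(d)),
    sprintf("%s %s %g(0)/mV %d 0 %d %d 0 %s",
            datname, format, gain, adcres,
            if (length(d)) d[[1]] else 0L, checksum, rec$channel_name)
  )
  writeLines(hea, file.path(dir, paste0(id, ".hea")))
  if (format == "212") {
    write_dat_212(d, file.path(dir, datname))
  } else {
    writeBin(d, file.path(dir, datname), size = 2L, endian = "little")
  }
  if (nrow(rec$annotations)) {
    write_atr(rec$annotations, file.path(dir, paste0(id, ".atr")))
  }
  out <- rec
  out$signal <- d / gain
  invisible(out)
}

write_dat_212 <- function(d, file) {
  if (length(d) %% 2L) d <- c(d, 0L)
  u <- ifelse(d < 0L, d + 4096L, d)  # 12-bit two's complement
  s1 <- u[seq(1L, length(u), by = 2L)]
  s2 <- u[seq(2L, length(u), by = 2L)]
  b1 <- bitwAnd(s1, 255L)
  b2 <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
  b3 <- bitwAnd(s2, 255L)
  writeBin(as.raw(as.vector(rbind(b1, b2, b3))), file)
}

write_atr <- function(ann, file) {
  codes <- WFDB_ANN_CODES[ann$raw_symbol]
  if (anyNA(codes)) {
    stop_argument(sprintf(
      "annotation symbol(s) outside the supported code table: %s",
      paste(unique(ann$raw_symbol[is.na(codes)]), collapse = ", ")
    ))
  }
  words <- integer(0)
  t_prev <- 0L
  for (k in seq_len(nrow(ann))) {
    dt <- ann$sample_index[k] - t_prev
    while (dt > 1023L) {  # SKIP pseudo-annotation carries a 32-bit jump
      words <- c(words, bitwShiftL(59L, 10L),
                 dt %/% 65536L, dt %% 65536L)
      t_prev <- t_prev + dt
      dt <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(codes[[k]], 10L), dt))
    t_prev <- ann$sample_index[k]
  }
  words <- c(words, 0L)  # EOF
  lo <- words %% 256L
  hi <- words %/% 256L
  writeBin(as.raw(as.vector(rbind(lo, hi))), file)
}
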