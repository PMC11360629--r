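# Fourier-method resampling.
#
# The classifier and denoiser assume a common 360 Hz rate; wearable records
# (e.g. 250 Hz patches) are up-sampled by zero-padding/truncating the DFT —
# the "Fourier method". This preserves frequency content below the original
# Nyquist exactly for band-limited signals, unlike polyphase filtering.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Resample a numeric vector from length n to length m via the DFT.
# Mirrors the standard FFT resampling algorithm including the split/merge
# of the Nyquist bin when either length is even.
fourier_resample <- function(x, m) {
  n <- length(x)
  m <- as.integer(m)
  if (m < 1L) stop_argument("target length must be >= 1")
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  k <- min(m, n)
  half <- k %/% 2L
  Y[seq_len(half + 1L)] <- X[seq_len(half + 1L)]
  nneg <- if (k %% 2L == 0L) half - 1L else half
  if (nneg > 0L) {
    Y[(m - nneg + 1L):m] <- X[(n - nneg + 1L):n]
  }
  if (k %% 2L == 0L) {
    if (m < n) {
      # folding: add the bin that aliases onto the new Nyquist
      Y[half + 1L] <- Y[half + 1L] + X[n - half + 1L]
    } else {
      # splitting: share the old Nyquist bin between +/- frequencies
      Y[half + 1L] <- 0.5 * Y[half + 1L]
      Y[m - half + 1L] <- Y[half + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample an ECG record with the Fourier method
#'
#' The output has `round(length * target_fs / fs)` samples; annotation
#' indices are rescaled by the same ratio and rounded to the nearest sample
#' (ties away from zero); the validity mask, when present, is carried over
#' by nearest-sample lookup.
#'
#' @param rec an [ecg_record()]
#' @param target_fs target sampling rate in Hz
#' @return the resampled [ecg_record()]
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      is.na(target_fs) || target_fs <= 0) {
    stop_argument("`target_fs` must be a single positive number")
  }
  n <- length(rec$signal)
  ratio <- target_fs / rec$fs
  m <- as.integer(round_half_away(n * ratio))
  y <- fourier_resample(rec$signal, m)
  ann <- rec$annotations
  if (nrow(ann)) {
    ann$sample_index <- pmin(
      m - 1L, pmax(0L, as.integer(round_half_away(ann$sample_index * ratio)))
    )
    ann <- ann[order(ann$sample_index), , drop = FALSE]
    rownames(ann) <- NULL
  }
  mask <- rec$valid_mask
  if (!is.null(mask)) {
    src <- pmin(n, pmax(1L, as.integer(floor((seq_len(m) - 1L) / ratio)) + 1L))
    mask <- mask[src]
  }
  ecg_record(rec$record_id, target_fs, y, rec$channel_name, ann, mask)
}
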