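# Synthetic single-lead ECG and noise archetypes.
#
# Every pipeline stage is testable without PhysioNet downloads: beats are
# additive Gaussian P-QRS-T wave sums with fixed per-class morphology
# presets (a deliberately simple, separable model — not a physiological
# simulator), and the three noise kinds reproduce the *spectral signatures*
# of the real noise-stress-test records: baseline wander (BW) as sub-0.5 Hz
# sinusoids, muscle artifact (MA) as burst-gated 5-50 Hz Gaussian noise,
# electrode motion (EM) as sparse baseline steps and spike transients.

# Per-class wave presets. Each wave: amplitude (mV), width sigma (s),
# offset from the R peak (s). Classes are morphologically separable by
# construction so classifier tests have known structure.
beat_presets <- function() {
  N <- list(
    P = c(0.15, 0.025, -0.20), Q = c(-0.10, 0.010, -0.035),
    R = c(1.00, 0.012, 0.00), S = c(-0.15, 0.010, 0.035),
    T = c(0.30, 0.060, 0.25)
  )
  B <- list(                    # bundle-branch block: widened, notched QRS
    P = c(0.15, 0.025, -0.20), Q = c(-0.08, 0.012, -0.050),
    R = c(0.80, 0.030, 0.00), R2 = c(0.55, 0.020, 0.055),
    S = c(-0.25, 0.018, 0.100), T = c(-0.20, 0.070, 0.30)
  )
  V <- list(                    # ventricular ectopic: wide QRS, no P
    R = c(1.20, 0.050, 0.00), S = c(-0.50, 0.040, 0.090),
    T = c(-0.45, 0.080, 0.30)
  )
  A <- list(                    # atrial premature: early, shifted P
    P = c(0.12, 0.030, -0.12), Q = c(-0.10, 0.010, -0.035),
    R = c(0.95, 0.012, 0.00), S = c(-0.15, 0.010, 0.035),
    T = c(0.28, 0.055, 0.24)
  )
  # fusion beat: average of the N and V presets, wave by wave
  FF <- list(
    P = c(0.075, 0.025, -0.20),
    R = c(1.10, 0.031, 0.00), S = c(-0.325, 0.025, 0.0625),
    T = c(-0.075, 0.070, 0.275)
  )
  list(N = N, B = B, V = V, A = A, F = FF)
}

# raw WFDB symbol emitted for each synthetic class (B beats are written as
# left-bundle "L" so the default label map exercises the L/R -> B fold)
SYNTH_RAW_SYMBOL <- c(N = "N", B = "L", V = "V", A = "A", F = "F")

#' Configuration for the synthetic ECG generator
#'
#' @param fs sampling rate in Hz
#' @param duration_s record duration in seconds
#' @param mean_rr_s mean RR interval in seconds (default 0.8 s = 75 bpm)
#' @param rr_jitter coefficient of variation of the RR interval
#' @param class_mix named proportions over `{N,B,V,A,F}`; must sum to 1
#' @param seed integer master seed (named streams for beats/jitter)
#' @return a `synthetic_ecg_config` list
#' @export
synthetic_ecg_config <- function(fs = 360, duration_s = 60, mean_rr_s = 0.8,
                                 rr_jitter = 0.05,
                                 class_mix = c(N = 1, B = 0, V = 0, A = 0, F = 0),
                                 seed = 1L) {
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% BEAT_CLASSES)) {
    stop_argument("`class_mix` must be named with classes among {N,B,V,A,F}")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop_argument("`class_mix` must sum to 1")
  }
  if (any(class_mix < 0)) stop_argument("`class_mix` must be non-negative")
  if (fs * duration_s < 1024) {
    stop_argument("record must cover at least one 1024-sample window")
  }
  mix <- setNames(numeric(5), BEAT_CLASSES)
  mix[names(class_mix)] <- class_mix
  structure(
    list(fs = fs, duration_s = duration_s, mean_rr_s = mean_rr_s,
         rr_jitter = rr_jitter, class_mix = mix, seed = as.integer(seed)),
    class = "synthetic_ecg_config"
  )
}

#' Generate an annotated synthetic clean ECG record
#'
#' Beats are placed at jittered RR intervals; each beat adds its class's
#' Gaussian wave sum. A (atrial premature) beats arrive early and V beats
#' are followed by a compensatory pause. One annotation is written per beat
#' at the R-peak sample, carrying both the raw symbol and the generating
#' class. Identical configuration and seed give a bit-identical record.
#'
#' @param config a [synthetic_ecg_config()]
#' @return an [ecg_record()] with `mapped_class` already filled in
#' @export
generate_clean_ecg <- function(config) {
  stopifnot(inherits(config, "synthetic_ecg_config"))
  fs <- config$fs
  n <- as.integer(round(fs * config$duration_s))
  sig <- numeric(n)
  presets <- beat_presets()

  classes <- BEAT_CLASSES[config$class_mix > 0]
  probs <- config$class_mix[config$class_mix > 0]

  # enough draws to cover the record even with shortened intervals
  n_max <- ceiling(config$duration_s / (0.5 * config$mean_rr_s)) + 4L
  beat_class <- with_seed(derive_seed(config$seed, "beats"),
                          sample(classes, n_max, replace = TRUE, prob = probs))
  jit <- with_seed(derive_seed(config$seed, "jitter"),
                   pmax(0.5, 1 + config$rr_jitter * rnorm(n_max)))

  t <- config$mean_rr_s          # first beat after one mean interval
  times <- numeric(0); labs <- character(0)
  for (k in seq_len(n_max)) {
    cls <- beat_class[[k]]
    rr <- config$mean_rr_s * jit[[k]]
    if (cls == "A") rr <- rr * 0.75          # premature atrial beat
    if (k > 1L && labs[[length(labs)]] == "V") rr <- rr * 1.30  # pause after V
    if (k > 1L) t <- t + rr
    if (t > config$duration_s - 0.40) break
    times <- c(times, t); labs <- c(labs, cls)
  }

  tt <- (seq_len(n) - 1L) / fs
  for (k in seq_along(times)) {
    for (w in presets[[labs[[k]]]]) {
      ctr <- times[[k]] + w[[3]]
      lo <- max(1L, floor((ctr - 5 * w[[2]]) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * w[[2]]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      sig[idx] <- sig[idx] + w[[1]] * exp(-((tt[idx] - ctr)^2) / (2 * w[[2]]^2))
    }
  }

  ann_idx <- as.integer(round_half_away(times * fs))
  keep <- ann_idx >= 0L & ann_idx < n
  ann <- data.frame(
    sample_index = ann_idx[keep],
    raw_symbol = unname(SYNTH_RAW_SYMBOL[labs[keep]]),
    mapped_class = labs[keep],
    stringsAsFactors = FALSE
  )
  ecg_record(sprintf("synth-%d", config$seed), fs, sig,
             channel_name = "MLII", annotations = ann)
}

NOISE_KINDS <- c("BW", "EM", "MA")

#' Generate a synthetic noise trace
#'
#' * `BW`: sum of five sinusoids with random frequencies below 0.45 Hz and
#'   random phases — essentially all power below 0.5 Hz.
#' * `MA`: Gaussian noise band-limited to 5-50 Hz by FFT masking, gated by
#'   a smooth random burst envelope.
#' * `EM`: sparse random baseline steps plus exponentially decaying spike
#'   transients — a heavy-tailed amplitude distribution.
#'
#' All traces are scaled to unit standard deviation; the noise weight of
#' [synthesize_noisy()] sets the actual level, so only the shape matters.
#'
#' @param kind one of `"BW"`, `"EM"`, `"MA"`
#' @param n_samples trace length (> 0)
#' @param fs sampling rate in Hz
#' @param seed integer seed (stream-scoped per kind)
#' @return a `noise_trace` list: `kind`, `samples`, `fs`, `seed`
#' @export
generate_noise <- function(kind, n_samples, fs = 360, seed = 1L) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% NOISE_KINDS)) {
    stop_argument("`kind` must be one of \"BW\", \"EM\", \"MA\"")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples <= 0L) {
    stop_argument("`n_samples` must be a positive integer")
  }
  x <- with_seed(derive_seed(seed, paste0("noise-", kind)), {
    tt <- (seq_len(n_samples) - 1L) / fs
    switch(kind,
      BW = {
        f <- runif(5, 0.05, 0.45)
        ph <- runif(5, 0, 2 * pi)
        a <- runif(5, 0.4, 1)
        rowSums(vapply(1:5, function(i) a[i] * sin(2 * pi * f[i] * tt + ph[i]),
                       numeric(n_samples)))
      },
      MA = {
        w <- rnorm(n_samples)
        W <- stats::fft(w)
        fr <- (seq_len(n_samples) - 1L) * fs / n_samples
        fr <- pmin(fr, fs - fr)
        W[fr < 5 | fr > 50] <- 0
        band <- Re(stats::fft(W, inverse = TRUE)) / n_samples
        env <- rep(0.25, n_samples)
        n_burst <- max(1L, rbinom(1L, n_samples, 1 / (3 * fs)))
        ctr <- runif(n_burst, 0, max(tt))
        for (c0 in ctr) {
          dur <- runif(1, 0.5, 2)
          env <- env + exp(-((tt - c0)^2) / (2 * (dur / 2)^2))
        }
        band * env
      },
      EM = {
        steps <- rbinom(n_samples, 1L, 0.002) *
          rnorm(n_samples, sd = 1) * sample(c(-1, 1), n_samples, replace = TRUE)
        base <- cumsum(steps)
        spikes <- numeric(n_samples)
        at <- which(rbinom(n_samples, 1L, 0.0015) == 1L)
        for (i in at) {
          amp <- runif(1, 2, 6) * sample(c(-1, 1), 1L)
          len <- min(n_samples - i + 1L, 30L)
          spikes[i:(i + len - 1L)] <- spikes[i:(i + len - 1L)] +
            amp * exp(-(0:(len - 1L)) / 6)
        }
        base + spikes
      }
    )
  })
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    # degenerate draw (e.g. EM with no events on a very short trace):
    # fall back to tiny white noise so the trace keeps positive energy
    x <- x + with_seed(derive_seed(seed, paste0("noise-fallback-", kind)),
                       rnorm(n_samples, sd = 1e-3))
    s <- stats::sd(x)
  }
  structure(list(kind = kind, samples = x / s, fs = fs, seed = as.integer(seed)),
            class = "noise_trace")
}

#' Write a bank of synthetic fixture records and noise traces
#'
#' Convenience wrapper used by tests and the `fixtures` command: generates
#' a clean annotated record per requested seed plus one trace per noise
#' kind, all written through the WFDB writer so downstream code paths are
#' identical for synthetic and real data.
#'
#' @param dir output directory
#' @param seeds integer vector; one record per seed
#' @param config_fn function(seed) returning a [synthetic_ecg_config()]
#' @param noise_duration_s duration of each noise record in seconds
#' @return list with record paths and noise paths
#' @export
write_fixture_bank <- function(dir, seeds = 1:3,
                               config_fn = function(s)
                                 synthetic_ecg_config(
                                   duration_s = 60, seed = s,
                                   class_mix = c(N = 0.7, B = 0.1, V = 0.1,
                                                 A = 0.07, F = 0.03)),
                               noise_duration_s = 120) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_paths <- character(0)
  for (s in seeds) {
    rec <- generate_clean_ecg(config_fn(s))
    write_wfdb_record(rec, dir)
    rec_paths <- c(rec_paths, file.path(dir, rec$record_id))
  }
  noise_paths <- character(0)
  for (k in NOISE_KINDS) {
    tr <- generate_noise(k, as.integer(noise_duration_s * 360), 360,
                         seed = seeds[[1]])
    nrec <- ecg_record(tolower(k), 360, tr$samples / 4, channel_name = "noise")
    write_wfdb_record(nrec, dir)
    noise_paths <- c(noise_paths, file.path(dir, tolower(k)))
  }
  list(records = rec_paths, noise = noise_paths)
}
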