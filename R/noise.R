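# SNR-exact noise synthesis.
#
# A clean window S is contaminated as  noisy = S + alpha * n  where the
# noise weight  alpha = sqrt( sum(S^2) / (10^(SNR/10) * sum(n^2)) )  makes
# the achieved SNR of S against alpha*n equal the target *identically*
# (up to floating point), for any window and any noise trace. For mixed
# recipes the components are weighted and summed first and alpha is then
# computed for the composite trace, so the stated SNR governs the mixture.

#' Noise recipe: components, mix weights and target SNR
#'
#' @param components named numeric vector of mix weights, names in
#'   `{"BW","EM","MA"}` (e.g. `c(BW = 0.3, MA = 0.7)`); weights must be
#'   strictly positive and sum to 1
#' @param target_snr_db target signal-to-noise ratio in dB
#' @return a `noise_recipe`
#' @export
noise_recipe <- function(components, target_snr_db) {
  if (is.null(names(components)) || !all(names(components) %in% NOISE_KINDS)) {
    stop_argument("`components` must be named with kinds among BW/EM/MA")
  }
  if (length(components) < 1L || any(components <= 0)) {
    stop_argument("mix weights must be strictly positive")
  }
  if (abs(sum(components) - 1) > 1e-8) {
    stop_argument("mix weights must sum to 1")
  }
  if (!is.numeric(target_snr_db) || length(target_snr_db) != 1L ||
      !is.finite(target_snr_db)) {
    stop_argument("`target_snr_db` must be a single finite number")
  }
  structure(list(components = components, target_snr_db = target_snr_db),
            class = "noise_recipe")
}

#' @export
format.noise_recipe <- function(x, ...) {
  sprintf("%s @ %g dB",
          paste(sprintf("%.2g*%s", x$components, names(x$components)),
                collapse = " + "),
          x$target_snr_db)
}

#' @export
print.noise_recipe <- function(x, ...) {
  cat("<noise_recipe>", format(x), "\n"); invisible(x)
}

#' Noise weight for a target SNR
#'
#' `alpha = sqrt( sum(clean^2) / (10^(snr_db/10) * sum(noise^2)) )`, the
#' scale at which `clean + alpha*noise` attains exactly `snr_db` decibels
#' of clean-signal energy over injected-noise energy.
#'
#' @param clean,noise numeric vectors of equal length
#' @param target_snr_db target SNR in dB
#' @return the dimensionless noise weight
#' @export
compute_alpha <- function(clean, noise, target_snr_db) {
  if (length(clean) != length(noise)) {
    stop_argument("`clean` and `noise` must have equal length")
  }
  es <- sum(clean^2)
  en <- sum(noise^2)
  if (en <= 0) stop_degenerate("noise has zero energy; alpha is undefined")
  sqrt(es / (10^(target_snr_db / 10) * en))
}

#' Pointwise weighted sum of noise traces
#'
#' @param traces list of `noise_trace` objects of equal length
#' @param weights numeric weights, strictly positive, summing to 1
#' @return a `noise_trace` of kind `"MIXED"` (or the single input kind)
#' @export
mix_noise_components <- function(traces, weights) {
  if (length(traces) != length(weights) || length(traces) < 1L) {
    stop_argument("`traces` and `weights` must be non-empty and match in length")
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-8) {
    stop_argument("weights must be strictly positive and sum to 1")
  }
  lens <- vapply(traces, function(t) length(t$samples), 0L)
  if (length(unique(lens)) != 1L) {
    stop_argument("all traces must have the same length")
  }
  mixed <- numeric(lens[[1]])
  for (i in seq_along(traces)) mixed <- mixed + weights[[i]] * traces[[i]]$samples
  structure(
    list(kind = if (length(traces) == 1L) traces[[1]]$kind else "MIXED",
         samples = mixed, fs = traces[[1]]$fs, seed = traces[[1]]$seed),
    class = "noise_trace"
  )
}

#' Contaminate a clean window at an exact target SNR
#'
#' Draws one segment per recipe component from the noise bank at a seeded
#' random offset, forms the weighted composite, computes the noise weight
#' for the composite, and returns `clean + alpha * noise`.
#'
#' @param clean numeric clean window
#' @param recipe a [noise_recipe()]
#' @param noise_bank named list of `noise_trace` objects (or plain numeric
#'   vectors) covering every kind in the recipe, each at least as long as
#'   `clean`
#' @param seed integer seed for the offset draws
#' @return list (`noise_synthesis_result`): `noisy`, `alpha`, `recipe`,
#'   `noise_used` (the composite trace segment), `offsets`
#' @export
synthesize_noisy <- function(clean, recipe, noise_bank, seed = 1L) {
  stopifnot(inherits(recipe, "noise_recipe"))
  n <- length(clean)
  kinds <- names(recipe$components)
  missing <- setdiff(kinds, names(noise_bank))
  if (length(missing)) {
    stop_argument("noise bank lacks kind(s): " %+% paste(missing, collapse = ", "))
  }
  segs <- vector("list", length(kinds))
  offsets <- integer(length(kinds))
  for (i in seq_along(kinds)) {
    tr <- noise_bank[[kinds[[i]]]]
    samp <- if (inherits(tr, "noise_trace")) tr$samples else as.numeric(tr)
    if (length(samp) < n) {
      stop_argument(sprintf(
        "bank trace for %s has %d samples; window needs %d",
        kinds[[i]], length(samp), n
      ))
    }
    off <- with_seed(derive_seed(seed, paste0("offset-", i, "-", kinds[[i]])),
                     sample.int(length(samp) - n + 1L, 1L)) - 1L
    offsets[[i]] <- off
    segs[[i]] <- structure(
      list(kind = kinds[[i]], samples = samp[(off + 1L):(off + n)],
           fs = NA_real_, seed = seed),
      class = "noise_trace"
    )
  }
  composite <- mix_noise_components(segs, unname(recipe$components))
  alpha <- compute_alpha(clean, composite$samples, recipe$target_snr_db)
  structure(
    list(noisy = clean + alpha * composite$samples, alpha = alpha,
         recipe = recipe, noise_used = composite, offsets = offsets),
    class = "noise_synthesis_result"
  )
}

#' Achieved SNR of a synthesis result
#'
#' `10*log10( sum(clean^2) / sum((alpha*noise)^2) )` — by construction this
#' equals the recipe's target for every window.
#'
#' @param clean the clean window
#' @param result a `noise_synthesis_result`
#' @return achieved SNR in dB
#' @export
achieved_snr <- function(clean, result) {
  injected <- result$noisy - clean
  10 * log10(sum(clean^2) / sum(injected^2))
}

#' Assemble a noise bank
#'
#' Either from WFDB records (e.g. the noise stress-test `bw`/`em`/`ma`
#' records, if available locally) or from synthetic traces.
#'
#' @param paths optional named character vector of WFDB record paths
#'   (names among BW/EM/MA); when `NULL`, synthetic traces are generated
#' @param n_samples length of each synthetic trace
#' @param fs sampling rate for synthetic traces
#' @param seed seed for synthetic traces
#' @return named list of `noise_trace` objects
#' @export
make_noise_bank <- function(paths = NULL, n_samples = 360L * 120L,
                            fs = 360, seed = 1L) {
  if (!is.null(paths)) {
    bank <- lapply(seq_along(paths), function(i) {
      rec <- read_wfdb_record(paths[[i]],
                              channel = available_first_channel(paths[[i]]))
      structure(list(kind = names(paths)[[i]], samples = rec$signal,
                     fs = rec$fs, seed = NA_integer_),
                class = "noise_trace")
    })
    return(setNames(bank, names(paths)))
  }
  setNames(
    lapply(NOISE_KINDS, generate_noise, n_samples = n_samples, fs = fs,
           seed = seed),
    NOISE_KINDS
  )
}

available_first_channel <- function(path) {
  lines <- readLines(paste0(path, ".hea"), warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parse_wfdb_signal_line(lines[[2]])$description
}
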