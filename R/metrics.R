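# Denoising and classification metrics.
#
# PRD, SNR and RMSE share one residual energy, so they are mutually
# consistent: SNR = -20*log10(PRD/100) and RMSE = (PRD/100)*sqrt(sum(x^2)/N)
# hold identically. These identities double as validation of reported
# numbers. Classification metrics are one-vs-rest precision/recall/F1 with
# *unweighted* macro averages over the declared class alphabet: a class that
# never occurs contributes zeros, it is not skipped.

#' Percent root-mean-squared difference
#' @param x reference (clean) signal
#' @param x_hat reconstruction (denoised) signal
#' @return PRD in percent
#' @export
prd <- function(x, x_hat) {
  check_pair(x, x_hat)
  ex <- sum(x^2)
  if (ex <= 0) stop_degenerate("reference signal has zero energy")
  sqrt(sum((x - x_hat)^2) / ex) * 100
}

#' Signal-to-noise ratio of a reconstruction
#'
#' `10*log10( sum(x^2) / sum((x_hat - x)^2) )`. A perfect reconstruction
#' has zero residual energy; `Inf` is returned as the sentinel for that.
#'
#' @inheritParams prd
#' @return SNR in dB (`Inf` when `x_hat == x`)
#' @export
snr <- function(x, x_hat) {
  check_pair(x, x_hat)
  ex <- sum(x^2)
  if (ex <= 0) stop_degenerate("reference signal has zero energy")
  er <- sum((x_hat - x)^2)
  if (er == 0) return(Inf)
  10 * log10(ex / er)
}

#' Root-mean-squared error
#' @inheritParams prd
#' @return RMSE in the amplitude units of the inputs
#' @export
rmse <- function(x, x_hat) {
  check_pair(x, x_hat)
  sqrt(mean((x_hat - x)^2))
}

#' SNR implied by a PRD value
#'
#' The two metrics share the residual energy, so `snr = -20*log10(prd/100)`
#' whenever both are computed from the same window pair. Used to validate
#' reported (PRD, SNR) pairs.
#'
#' @param prd_percent PRD in percent
#' @return implied SNR in dB
#' @export
snr_from_prd <- function(prd_percent) {
  if (any(prd_percent <= 0)) stop_argument("PRD must be positive")
  -20 * log10(prd_percent / 100)
}

#' All three denoising metrics for one window pair
#' @inheritParams prd
#' @param pair optional `segment_pair`; when given together with
#'   `scale = "mv"`, both signals are inverse-normalized before measuring
#' @param scale `"normalized"` (default; matches the training scale) or
#'   `"mv"`
#' @return list with `prd_percent`, `snr_db`, `rmse`
#' @export
denoise_metrics <- function(x, x_hat, pair = NULL,
                            scale = c("normalized", "mv")) {
  scale <- match.arg(scale)
  if (scale == "mv") {
    if (is.null(pair)) stop_argument("`pair` is required for scale = \"mv\"")
    x <- denormalize(x, pair); x_hat <- denormalize(x_hat, pair)
  }
  list(prd_percent = prd(x, x_hat), snr_db = snr(x, x_hat),
       rmse = rmse(x, x_hat))
}

check_pair <- function(x, x_hat) {
  if (length(x) != length(x_hat)) {
    stop_argument("signals must have equal length")
  }
  if (length(x) == 0L) stop_argument("signals must be non-empty")
  invisible(TRUE)
}

#' Per-class and macro precision/recall/F1
#'
#' One-vs-rest TP/FP/FN counts per class of the declared alphabet;
#' precision, recall and F1 in percent (full precision; rounding is left to
#' reporting). F1 is the harmonic mean `2*P*R/(P+R)`, defined as 0 when
#' `P + R = 0`. Macro rows are unweighted means over the whole alphabet,
#' including classes with no true or predicted instances (which contribute
#' zeros).
#'
#' @param y_true,y_pred character vectors of equal, positive length
#' @param classes class alphabet (default: the five beat classes)
#' @return a `classification_report`: data frame with one row per class
#'   plus a `"macro"` row; columns `class`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (percent)
#' @export
classification_report <- function(y_true, y_pred, classes = BEAT_CLASSES) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop_argument("`y_true` and `y_pred` must be non-empty and equal length")
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown)) {
    stop_argument("labels outside the class alphabet: " %+%
                    paste(unknown, collapse = ", "))
  }
  rows <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1)
  })
  out <- do.call(rbind, rows)
  macro <- data.frame(class = "macro", tp = sum(out$tp), fp = sum(out$fp),
                      fn = sum(out$fn), precision = mean(out$precision),
                      recall = mean(out$recall), f1 = mean(out$f1))
  out <- rbind(out, macro)
  rownames(out) <- NULL
  class(out) <- c("classification_report", "data.frame")
  out
}

#' Macro F1 of a report
#' @param report a [classification_report()]
#' @return macro F1 in percent
#' @export
macro_f1 <- function(report) {
  report$f1[report$class == "macro"]
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$precision <- round(y$precision, digits)
  y$recall <- round(y$recall, digits)
  y$f1 <- round(y$f1, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Aligned-text comparison table of several reports
#'
#' Lays out per-class precision/recall/F1 for several corpora (e.g. noisy /
#' original / denoised) in one table, classes as blocks, one row per
#' corpus, percentages rounded half-even to two decimals.
#'
#' @param reports named list of [classification_report()]s
#' @return character vector of formatted lines (also printed as a side
#'   effect when auto-printed via `cat`)
#' @export
format_report_table <- function(reports) {
  stopifnot(length(reports) >= 1L, !is.null(names(reports)))
  classes <- reports[[1]]$class
  lines <- sprintf("%-6s %-14s %10s %10s %10s",
                   "Class", "Data", "Precision", "Recall", "F1")
  for (cl in classes) {
    for (nm in names(reports)) {
      r <- reports[[nm]]
      i <- which(r$class == cl)
      lines <- c(lines, sprintf("%-6s %-14s %10.2f %10.2f %10.2f",
                                cl, nm, r$precision[i], r$recall[i], r$f1[i]))
    }
  }
  lines
}

#' Write a report (or several) as CSV
#' @param reports named list of [classification_report()]s
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_report_csv <- function(reports, path) {
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- as.data.frame(reports[[nm]])
    r$precision <- round(r$precision, 2)
    r$recall <- round(r$recall, 2)
    r$f1 <- round(r$f1, 2)
    cbind(data = nm, r)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
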