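# PRD / SNR / RMSE and the classification report.

test_that("prd, snr and rmse match hand-computed values and sentinels", {
  x <- c(1, 0, -1, 0)
  xh <- c(1.1, 0, -1, 0)
  expect_equal(prd(x, xh), sqrt(0.01 / 2) * 100)     # 7.0711 %
  expect_equal(prd(x, x), 0)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, xh), sqrt(0.01 / 4))
  expect_identical(snr(x, x), Inf)                   # perfect reconstruction
  # residual energy equal to signal energy -> 0 dB
  expect_equal(snr(c(1, 1), c(2, 0)), 0)
  expect_error(prd(x, xh[1:3]), class = "ecgan_argument_error")
  expect_error(prd(numeric(0), numeric(0)), class = "ecgan_argument_error")
  expect_error(prd(c(0, 0), c(1, 1)), class = "ecgan_degenerate_error")
})

test_that("PRD, SNR and RMSE identities hold on random window pairs", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(16:1024, 1)
    x <- rnorm(n)
    xh <- x + rnorm(n, sd = runif(1, 0.01, 2))
    p <- prd(x, xh)
    expect_equal(snr(x, xh), -20 * log10(p / 100), tolerance = 1e-12)
    expect_equal(rmse(x, xh), (p / 100) * sqrt(sum(x^2) / n),
                 tolerance = 1e-12)
  }
})

test_that("snr_from_prd inverts the PRD relation at reference points", {
  expect_equal(snr_from_prd(100), 0)
  expect_equal(snr_from_prd(2.51), 32.02, tolerance = 0.02 / 32.02)
  expect_equal(snr_from_prd(1.65), 35.65, tolerance = 0.02 / 35.65)
  expect_error(snr_from_prd(0), class = "ecgan_argument_error")
})

test_that("classification_report matches a brute-force confusion scan", {
  set.seed(7)
  classes <- c("N", "B", "V", "A", "F")
  for (rep_i in 1:20) {
    n <- sample(50:2000, 1)
    y <- sample(classes, n, replace = TRUE,
                prob = c(0.8, 0.08, 0.06, 0.04, 0.02))
    p <- sample(classes, n, replace = TRUE)
    rpt <- classification_report(y, p, classes)
    for (cl in classes) {
      tp <- 0; fp <- 0; fn <- 0
      for (i in seq_len(n)) {   # deliberate scalar scan as the oracle
        if (y[i] == cl && p[i] == cl) tp <- tp + 1
        if (y[i] != cl && p[i] == cl) fp <- fp + 1
        if (y[i] == cl && p[i] != cl) fn <- fn + 1
      }
      row <- rpt[rpt$class == cl, ]
      expect_equal(c(row$tp, row$fp, row$fn), c(tp, fp, fn))
      pr <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
      rc <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
      expect_equal(row$precision, pr)
      expect_equal(row$recall, rc)
      expect_equal(row$f1, if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0)
    }
    macro <- rpt[rpt$class == "macro", ]
    expect_equal(macro$f1, mean(rpt$f1[rpt$class != "macro"]))
  }
})

test_that("report handles perfect prediction, absent classes and errors", {
  y <- c("N", "V", "N", "A")
  rpt <- classification_report(y, y)
  expect_true(all(rpt[rpt$class %in% y, c("precision", "recall", "f1")] == 100))
  # F never occurs and is never predicted: zeros, still averaged in
  frow <- rpt[rpt$class == "F", ]
  expect_equal(c(frow$precision, frow$recall, frow$f1), c(0, 0, 0))
  expect_equal(macro_f1(rpt), mean(rpt$f1[rpt$class != "macro"]))
  expect_error(classification_report(character(0), character(0)),
               class = "ecgan_argument_error")
  expect_error(classification_report("N", "Z"),
               class = "ecgan_argument_error")
})

test_that("harmonic-mean F1 reproduces published-style percentages", {
  # a precision/recall pair printed to 2 decimals reproduces its F1 cell
  expect_equal(round(2 * 75.60 * 99.35 / (75.60 + 99.35), 2), 85.86)
  r <- classification_report(c("N", "N", "V"), c("N", "V", "V"))
  expect_equal(r$f1[r$class == "N"],
               2 * r$precision[r$class == "N"] * r$recall[r$class == "N"] /
                 (r$precision[r$class == "N"] + r$recall[r$class == "N"]))
})

test_that("denoise_metrics can report on the mV scale via inversion", {
  set.seed(1)
  clean <- rnorm(64); noisy <- clean + rnorm(64, sd = 0.3)
  pair <- minmax_normalize(clean, noisy)
  dm_norm <- denoise_metrics(pair$clean, pair$noisy)
  dm_mv <- denoise_metrics(pair$clean, pair$noisy, pair = pair, scale = "mv")
  # PRD changes with the scale (different reference energy), RMSE scales by
  # the window range
  expect_equal(dm_mv$rmse,
               dm_norm$rmse * (pair$norm_max - pair$norm_min))
  expect_equal(dm_mv$prd_percent, prd(clean, denormalize(pair$noisy, pair)))
})

test_that("report table and CSV round-trip the rounded percentages", {
  y <- rep(c("N", "V"), 30)
  p <- c(rep("N", 30), rep("V", 30))
  reports <- list(noisy = classification_report(y, p, c("N", "V")),
                  original = classification_report(y, y, c("N", "V")))
  lines <- format_report_table(reports)
  expect_true(any(grepl("original", lines)))
  expect_equal(length(lines), 1 + 2 * 3)   # header + 2 corpora x (2 cls + macro)
  f <- tempfile(fileext = ".csv")
  write_report_csv(reports, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 6)   # 2 corpora x (2 classes + macro)
  expect_equal(back$f1[back$data == "original" & back$class == "macro"], 100)
})
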