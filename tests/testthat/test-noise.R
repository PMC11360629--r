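# SNR-exact noise synthesis.

test_that("compute_alpha matches the closed form", {
  clean <- c(10, 0, 0)         # energy 100
  noise <- c(5, 0, 0)          # energy 25
  expect_equal(compute_alpha(clean, noise, 0), 2)
  expect_equal(compute_alpha(clean, noise, 5),
               sqrt(100 / (10^0.5 * 25)))  # ~1.12468
  expect_equal(compute_alpha(clean, noise, 5), 1.12468, tolerance = 1e-5)
  expect_error(compute_alpha(clean, c(0, 0, 0), 0),
               class = "ecgan_degenerate_error")
  expect_error(compute_alpha(clean, c(1, 2), 0),
               class = "ecgan_argument_error")
})

test_that("alpha scales as 10^(-SNR/20)", {
  set.seed(1)
  clean <- rnorm(256); noise <- rnorm(256)
  a0 <- compute_alpha(clean, noise, 0)
  expect_equal(compute_alpha(clean, noise, 20), a0 / 10, tolerance = 1e-12)
  expect_equal(compute_alpha(clean, noise, -20), a0 * 10, tolerance = 1e-12)
})

test_that("mixing is convex, pointwise, and variance behaves additively", {
  set.seed(2)
  tr <- function(kind, x) structure(list(kind = kind, samples = x, fs = 360,
                                         seed = 1), class = "noise_trace")
  x <- rnorm(512)
  one <- mix_noise_components(list(tr("BW", x)), 1)
  expect_identical(one$samples, x)
  expect_identical(one$kind, "BW")
  half <- mix_noise_components(list(tr("BW", x), tr("MA", x)), c(0.5, 0.5))
  expect_equal(half$samples, x)
  expect_identical(half$kind, "MIXED")

  # independent unit-variance components: var = sum(w^2) in expectation
  n <- 200000
  a <- rnorm(n); b <- rnorm(n); c <- rnorm(n)
  m <- mix_noise_components(list(tr("BW", a), tr("EM", b), tr("MA", c)),
                            c(0.25, 0.25, 0.5))
  expect_equal(var(m$samples), 0.25^2 + 0.25^2 + 0.5^2, tolerance = 0.02)

  expect_error(mix_noise_components(list(tr("BW", x), tr("MA", x[1:10])),
                                    c(0.5, 0.5)),
               class = "ecgan_argument_error")
  expect_error(mix_noise_components(list(tr("BW", x)), 0.9),
               class = "ecgan_argument_error")
})

test_that("synthesize_noisy achieves the target SNR exactly for any recipe", {
  bank <- quick_bank(seed = 5)
  rec <- quick_record(seed = 2)
  clean <- rec$signal[1:1024]
  for (recipe in list(noise_recipe(c(BW = 1), 0),
                      noise_recipe(c(EM = 1), 5),
                      noise_recipe(c(BW = 0.3, MA = 0.7), 0),
                      noise_recipe(c(BW = 0.25, EM = 0.25, MA = 0.5), -3.7))) {
    res <- synthesize_noisy(clean, recipe, bank, seed = 9)
    expect_equal(achieved_snr(clean, res), recipe$target_snr_db,
                 tolerance = 1e-9)
    expect_length(res$noisy, length(clean))
  }
})

test_that("very high target SNR leaves the window essentially clean", {
  bank <- quick_bank(seed = 6)
  clean <- quick_record(seed = 3)$signal[1:1024]
  res <- synthesize_noisy(clean, noise_recipe(c(MA = 1), 60), bank, seed = 2)
  expect_lt(prd(clean, res$noisy), 0.2)
})

test_that("synthesis is deterministic under seed and validates the bank", {
  bank <- quick_bank(seed = 7)
  clean <- quick_record(seed = 4)$signal[1:1024]
  r1 <- synthesize_noisy(clean, noise_recipe(c(BW = 1), 0), bank, seed = 3)
  r2 <- synthesize_noisy(clean, noise_recipe(c(BW = 1), 0), bank, seed = 3)
  expect_identical(r1$noisy, r2$noisy)
  r3 <- synthesize_noisy(clean, noise_recipe(c(BW = 1), 0), bank, seed = 4)
  expect_false(identical(r1$noisy, r3$noisy))

  short <- list(BW = generate_noise("BW", 100L, seed = 1))
  expect_error(synthesize_noisy(clean, noise_recipe(c(BW = 1), 0), short),
               class = "ecgan_argument_error")
  expect_error(synthesize_noisy(clean, noise_recipe(c(EM = 1), 0),
                                bank["BW"]),
               class = "ecgan_argument_error")
})

test_that("recipe invariants are enforced", {
  expect_error(noise_recipe(c(BW = 0.5, MA = 0.6), 0),
               class = "ecgan_argument_error")
  expect_error(noise_recipe(c(XX = 1), 0), class = "ecgan_argument_error")
  expect_error(noise_recipe(c(BW = -0.2, MA = 1.2), 0),
               class = "ecgan_argument_error")
  expect_error(noise_recipe(c(BW = 1), NA), class = "ecgan_argument_error")
})

test_that("mixing then scaling equals scaling components with shared alpha", {
  bank <- quick_bank(seed = 8)
  clean <- quick_record(seed = 5)$signal[1:1024]
  recipe <- noise_recipe(c(BW = 0.3, MA = 0.7), 5)
  res <- synthesize_noisy(clean, recipe, bank, seed = 11)
  # rebuild from the stored composite: linearity of Eq. 6
  rebuilt <- clean + res$alpha * res$noise_used$samples
  expect_equal(res$noisy, rebuilt, tolerance = 1e-12)
})
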