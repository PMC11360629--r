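# The network engine: shape contracts, gradient correctness, determinism.

ns <- asNamespace("ecgan")

# numerical gradient check of every parameter class in a network
check_gradients <- function(net, x, dout_fn, n_per_param = 3, eps = 1e-5) {
  # probe with a fixed random linear functional, so dL/dout is constant
  fw0 <- ns$net_forward(net, x, train = TRUE)
  w <- dout_fn(fw0$out)
  lossfn <- function() {
    fw <- ns$net_forward(net, x, train = TRUE)
    sum(fw$out * w)
  }
  bk <- ns$net_backward(net, fw0, w)
  worst <- 0
  for (i in seq_along(net$nodes)) {
    g <- bk$grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- net$nodes[[i]]$layer$params[[nm]]
      for (j in sample(length(p), min(n_per_param, length(p)))) {
        net$nodes[[i]]$layer$params[[nm]][j] <- p[j] + eps
        lp <- lossfn()
        net$nodes[[i]]$layer$params[[nm]][j] <- p[j] - eps
        lm <- lossfn()
        net$nodes[[i]]$layer$params[[nm]][j] <- p[j]
        num <- (lp - lm) / (2 * eps)
        ana <- g[[nm]][j]
        worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

test_that("generator honours its shape contract and the identity init", {
  spec <- generator_spec(input_len = 64L, depth = 3L, filters = c(3L, 4L, 5L),
                         kernel = 5L)
  G <- build_generator(spec, seed = 1)
  set.seed(2)
  x <- array(rnorm(64 * 3), c(1, 64, 3))
  y <- ns$net_forward(G, x, train = FALSE)$out
  expect_equal(dim(y), c(1L, 64L, 3L))
  expect_true(all(is.finite(y)))
  # zero-initialized final projection: output equals the skip path exactly
  expect_identical(y, x)
  # concat variant keeps the contract too
  Gc <- build_generator(generator_spec(64L, 3L, c(3L, 4L, 5L), 5L,
                                       skip = "concat"), seed = 1)
  expect_identical(ns$net_forward(Gc, x)$out, x)
  expect_error(generator_spec(input_len = 100L, depth = 3L,
                              filters = c(2L, 2L, 2L), kernel = 3L),
               class = "ecgan_argument_error")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(5)
  x <- array(rnorm(32 * 2), c(1, 32, 2))
  wfun <- function(out) array(rnorm(length(out)), dim(out))

  G <- build_generator(generator_spec(32L, 2L, c(3L, 4L), 3L), seed = 2)
  expect_lt(check_gradients(G, x, wfun), 1e-3)

  Gc <- build_generator(generator_spec(32L, 2L, c(3L, 4L), 3L,
                                       skip = "concat"), seed = 3)
  expect_lt(check_gradients(Gc, x, wfun), 1e-3)

  D <- build_discriminator(discriminator_spec(list(c(3L, 3L, 2L),
                                                   c(4L, 3L, 2L))), seed = 4)
  expect_lt(check_gradients(D, x, function(out) matrix(rnorm(length(out)),
                                                       nrow(out))), 1e-3)

  R <- build_resnet(resnet_spec(input_len = 32L, classes = c("N", "V"),
                                stages = list(c(1L, 3L, 1L), c(1L, 4L, 2L)),
                                kernel = 3L), seed = 5)
  expect_lt(check_gradients(R, x, function(out) matrix(rnorm(length(out)),
                                                       nrow(out))), 1e-3)
})

test_that("gradient through the network input is correct (generator path)", {
  # needed for backpropagating the adversarial term into the generator
  set.seed(6)
  D <- build_discriminator(discriminator_spec(list(c(3L, 3L, 2L))), seed = 7)
  x <- array(rnorm(16), c(1, 16, 1))
  fw <- ns$net_forward(D, x, train = TRUE)
  bk <- ns$net_backward(D, fw, matrix(1, 1, 1))
  eps <- 1e-5
  for (j in sample(16, 5)) {
    xp <- x; xp[1, j, 1] <- x[1, j, 1] + eps
    xm <- x; xm[1, j, 1] <- x[1, j, 1] - eps
    num <- (sum(ns$net_forward(D, xp, train = TRUE)$out) -
              sum(ns$net_forward(D, xm, train = TRUE)$out)) / (2 * eps)
    expect_equal(bk$dinput[1, j, 1], num, tolerance = 1e-4)
  }
})

test_that("discriminator emits one finite score per window, seeded init", {
  spec <- tiny_disc_spec()
  D1 <- build_discriminator(spec, seed = 11)
  D2 <- build_discriminator(spec, seed = 11)
  D3 <- build_discriminator(spec, seed = 12)
  set.seed(1)
  x <- array(rnorm(1024 * 4), c(1, 1024, 4))
  s1 <- ns$net_forward(D1, x)$out
  expect_equal(dim(s1), c(1L, 4L))
  expect_true(all(is.finite(s1)))
  expect_identical(s1, ns$net_forward(D2, x)$out)
  expect_false(identical(s1, ns$net_forward(D3, x)$out))
})

test_that("checkpoints round-trip a network exactly", {
  G <- build_generator(generator_spec(32L, 2L, c(3L, 4L), 3L), seed = 2)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(G, f)
  G2 <- load_checkpoint(f)
  set.seed(3)
  x <- array(rnorm(32), c(1, 32, 1))
  expect_identical(ns$net_forward(G, x)$out, ns$net_forward(G2, x)$out)
  expect_error(load_checkpoint(tempfile()), class = "ecgan_io_error")
  saveRDS(list(a = 1), f)
  expect_error(load_checkpoint(f), class = "ecgan_format_error")
  file.remove(f)
})

test_that("batch normalization tracks running statistics for inference", {
  set.seed(8)
  bn <- ns$nn_batchnorm(2)
  # feed several training batches with known moments
  for (i in 1:200) {
    x <- array(rnorm(2 * 50 * 4, mean = 3, sd = 2), c(2, 50, 4))
    r <- ns$bn_forward(bn, x, train = TRUE)
    bn <- r$layer
  }
  expect_equal(bn$state$mean, c(3, 3), tolerance = 0.15)
  expect_equal(bn$state$var, c(4, 4), tolerance = 0.5)
  # eval mode normalizes with the running stats
  x0 <- array(rep(3, 2 * 10 * 1), c(2, 10, 1))
  y <- ns$bn_forward(bn, x0, train = FALSE)$y
  expect_lt(max(abs(y)), 0.2)
})
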