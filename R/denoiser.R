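# Least-squares GAN denoiser.
#
# Generator: a 1D U-Net whose levels are residual blocks
# (conv-BN-PReLU-conv-BN plus identity shortcut), encoder levels joined to
# decoder levels of equal depth by skip concatenation, downsampling by
# strided convolution, upsampling by nearest-neighbour doubling plus
# convolution. The final projection is zero-initialized and added to the
# network input (a global identity skip): an untrained generator passes the
# noisy window through unchanged, and training learns the correction.
#
# Discriminator: strided conv / batch-norm / leaky-ReLU stack ending in one
# scalar score per window. It scores single windows (clean vs denoised),
# unconditioned on the generator input.
#
# Losses (least-squares adversarial targets real=1, fake=0):
#   V_D = 1/2 mean((D(x)-1)^2) + 1/2 mean(D(G(z))^2)
#   L_G = 1/2 mean((D(G(z))-1)^2) + a*L_dist + b*L_dist_max
# with L_dist the mean squared sample difference between denoised and clean
# windows, L_dist_max the maximum absolute sample difference (per window,
# averaged over the batch), and default weights a = 0.7, b = 0.3.

#' Generator architecture specification
#'
#' @param input_len window length (must be divisible by `2^depth`)
#' @param depth number of encoder levels
#' @param filters integer vector of length `depth`: channels per level
#' @param kernel convolution kernel size
#' @param skip how encoder levels join decoder levels of equal depth:
#'   `"add"` (element-wise sum; default — halves decoder width for the same
#'   accuracy at desk scale) or `"concat"` (classic channel concatenation)
#' @return a `generator_spec`
#' @export
generator_spec <- function(input_len = 1024L, depth = 5L,
                           filters = c(4L, 8L, 16L, 32L, 32L), kernel = 7L,
                           skip = c("add", "concat")) {
  input_len <- as.integer(input_len); depth <- as.integer(depth)
  skip <- match.arg(skip)
  if (length(filters) != depth) {
    stop_argument("`filters` must have one entry per level")
  }
  if (input_len %% (2L^depth) != 0L) {
    stop_argument(sprintf("input_len %d is not divisible by 2^%d",
                          input_len, depth))
  }
  structure(list(input_len = input_len, depth = depth,
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 skip = skip),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' @param layers list of integer triplets `c(filters, kernel, stride)`
#' @return a `discriminator_spec`
#' @export
discriminator_spec <- function(layers = list(c(16L, 16L, 2L), c(32L, 16L, 2L),
                                             c(64L, 16L, 2L))) {
  structure(list(layers = layers), class = "discriminator_spec")
}

#' Generator loss weights
#'
#' @param loss_weight_dist weight of the mean-squared distance term
#'   (default 0.7)
#' @param loss_weight_max weight of the maximum-absolute-difference term
#'   (default 0.3)
#' @param real_target,fake_target least-squares adversarial targets
#' @return a `gan_loss_config`
#' @export
gan_loss_config <- function(loss_weight_dist = 0.7, loss_weight_max = 0.3,
                            real_target = 1, fake_target = 0) {
  if (loss_weight_dist < 0 || loss_weight_max < 0) {
    stop_argument("loss weights must be non-negative")
  }
  structure(list(loss_weight_dist = loss_weight_dist,
                 loss_weight_max = loss_weight_max,
                 real_target = real_target, fake_target = fake_target),
            class = "gan_loss_config")
}

# residual block: conv-BN-PReLU-conv-BN (+ 1x1-conv shortcut when the
# channel count changes), add, PReLU
add_resblock <- function(net, input_id, in_ch, out_ch, k, seed) {
  c1 <- add_node(net, "layer", input_id,
                 nn_conv1d(in_ch, out_ch, k, seed = derive_seed(seed, "c1")))
  b1 <- add_node(net, "layer", c1, nn_batchnorm(out_ch))
  p1 <- add_node(net, "layer", b1, nn_prelu(out_ch))
  c2 <- add_node(net, "layer", p1,
                 nn_conv1d(out_ch, out_ch, k, seed = derive_seed(seed, "c2")))
  b2 <- add_node(net, "layer", c2, nn_batchnorm(out_ch))
  short <- if (in_ch != out_ch) {
    add_node(net, "layer", input_id,
             nn_conv1d(in_ch, out_ch, 1L, seed = derive_seed(seed, "sc")))
  } else input_id
  s <- add_node(net, "add", c(b2, short))
  add_node(net, "layer", s, nn_prelu(out_ch))
}

#' Build the U-Net residual generator
#'
#' @param spec a [generator_spec()]
#' @param seed integer seed for weight initialization
#' @return an `ecgan_net` mapping `(input_len, 1, batch)` tensors to same
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  net <- new_net("generator", spec)
  inp <- add_node(net, "input")
  k <- spec$kernel
  f <- spec$filters
  skips <- integer(spec$depth)

  cur <- add_resblock(net, inp, 1L, f[1], k, derive_seed(seed, "enc-1"))
  skips[1] <- cur
  for (i in seq_len(spec$depth - 1L) + 1L) {
    dn <- add_node(net, "layer", cur,
                   nn_conv1d(f[i - 1L], f[i], k, stride = 2L,
                             seed = derive_seed(seed, paste0("down-", i))))
    dbn <- add_node(net, "layer", dn, nn_batchnorm(f[i]))
    dpr <- add_node(net, "layer", dbn, nn_prelu(f[i]))
    cur <- add_resblock(net, dpr, f[i], f[i], k,
                        derive_seed(seed, paste0("enc-", i)))
    skips[i] <- cur
  }
  for (i in rev(seq_len(spec$depth - 1L))) {
    up <- add_node(net, "layer", cur, nn_upsample2())
    uc <- add_node(net, "layer", up,
                   nn_conv1d(f[i + 1L], f[i], k,
                             seed = derive_seed(seed, paste0("up-", i))))
    ub <- add_node(net, "layer", uc, nn_batchnorm(f[i]))
    upr <- add_node(net, "layer", ub, nn_prelu(f[i]))
    if (spec$skip == "concat") {
      cc <- add_node(net, "concat", c(upr, skips[i]))
      cur <- add_resblock(net, cc, 2L * f[i], f[i], k,
                          derive_seed(seed, paste0("dec-", i)))
    } else {
      cc <- add_node(net, "add", c(upr, skips[i]))
      cur <- add_resblock(net, cc, f[i], f[i], k,
                          derive_seed(seed, paste0("dec-", i)))
    }
  }
  proj <- add_node(net, "layer", cur,
                   nn_conv1d(f[1], 1L, k, init = "zero"))
  add_node(net, "add", c(proj, inp))   # global identity skip
  net
}

#' Build the convolutional discriminator
#'
#' @param spec a [discriminator_spec()]
#' @param seed integer seed for weight initialization
#' @return an `ecgan_net` mapping `(len, 1, batch)` to a `(1, batch)` score
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  net <- new_net("discriminator", spec)
  cur <- add_node(net, "input")
  in_ch <- 1L
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    cur <- add_node(net, "layer", cur,
                    nn_conv1d(in_ch, l[1], l[2], stride = l[3],
                              seed = derive_seed(seed, paste0("d-", i))))
    if (i > 1L) cur <- add_node(net, "layer", cur, nn_batchnorm(l[1]))
    cur <- add_node(net, "layer", cur, nn_leaky(0.2))
    in_ch <- l[1]
  }
  gp <- add_node(net, "layer", cur, nn_gap())
  add_node(net, "layer", gp,
           nn_dense(in_ch, 1L, seed = derive_seed(seed, "d-head")))
  net
}

#' Least-squares discriminator loss
#'
#' `1/2 mean((D(real) - 1)^2) + 1/2 mean(D(fake)^2)`.
#'
#' @param scores_real,scores_fake numeric score vectors
#' @return scalar loss
#' @export
discriminator_loss <- function(scores_real, scores_fake) {
  0.5 * mean((as.numeric(scores_real) - 1)^2) +
    0.5 * mean(as.numeric(scores_fake)^2)
}

#' Composite generator loss
#'
#' Adversarial term `1/2 mean((D(G(z)) - 1)^2)` plus the weighted distance
#' terms: `l_dist`, the summed squared sample difference between the
#' denoised and clean window (averaged over the batch), and `l_dist_max`,
#' the per-window maximum absolute difference (averaged over the batch).
#'
#' `l_dist` sums over the window rather than averaging: with a
#' 1024-sample window this makes the distance term dominate the gradient
#' by roughly the window length, so the adversarial term acts as a
#' regularizer on top of an essentially reconstruction-driven objective —
#' which is what makes the composite loss able to reach reconstruction
#' SNRs far above what adversarial pressure alone permits.
#'
#' @param scores_fake discriminator scores of the denoised windows
#' @param s_hat denoised window(s): vector, `(len, batch)` matrix or
#'   `(len, 1, batch)` tensor
#' @param s clean window(s), same shape
#' @param cfg a [gan_loss_config()]
#' @return list `total`, `adversarial`, `l_dist`, `l_dist_max`
#' @export
generator_loss <- function(scores_fake, s_hat, s, cfg = gan_loss_config()) {
  s_hat <- as_window_matrix(s_hat)
  s <- as_window_matrix(s)
  if (!identical(dim(s_hat), dim(s))) {
    stop_argument("`s_hat` and `s` must have identical shape")
  }
  r <- s_hat - s
  adversarial <- 0.5 * mean((as.numeric(scores_fake) - cfg$real_target)^2)
  l_dist <- mean(colSums(r^2))
  l_dist_max <- mean(apply(abs(r), 2, max))
  list(total = adversarial + cfg$loss_weight_dist * l_dist +
         cfg$loss_weight_max * l_dist_max,
       adversarial = adversarial, l_dist = l_dist, l_dist_max = l_dist_max)
}

as_window_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 1L)
  else if (length(dim(x)) == 3L) matrix(x, dim(x)[2], dim(x)[3])  # (1,len,B)
  else x
}

#' Train the adversarial denoiser
#'
#' Alternating 1:1 discriminator/generator updates with Adam; per-epoch
#' means of the discriminator loss and the generator loss components are
#' logged. Deterministic for a fixed seed.
#'
#' @param pairs list of `segment_pair` objects (normalized)
#' @param epochs training epochs
#' @param batch_size minibatch size
#' @param lr generator Adam learning rate
#' @param lr_disc discriminator learning rate; the default trains the
#'   discriminator more slowly than the generator (two-timescale updates),
#'   which keeps the adversarial game from destabilizing the distance terms
#' @param gen_spec,disc_spec architecture specs
#' @param loss_cfg a [gan_loss_config()]
#' @param lr_decay_epochs epochs at whose start both learning rates are
#'   halved (step decay); empty for a constant rate
#' @param pretrain_epochs number of initial epochs during which only the
#'   generator is updated, on the distance terms alone (no adversarial
#'   gradient, no discriminator updates). Distance-first warm-up is the
#'   usual stabilizer for reconstruction GANs; the adversarial game starts
#'   from an already-sensible generator
#' @param seed integer master seed (streams: init, batching)
#' @param checkpoint_path optional path; the model is saved there after
#'   every epoch and on divergence
#' @param verbose print a line per epoch
#' @return a `denoiser_state`: `generator`, `discriminator`, `history`
#'   (data frame epoch/v_d/l_g/l_dist/l_dist_max), `seed`
#' @export
train_denoiser <- function(pairs, epochs = 5L, batch_size = 32L, lr = 1e-3,
                           lr_disc = lr / 5,
                           gen_spec = generator_spec(),
                           disc_spec = discriminator_spec(),
                           loss_cfg = gan_loss_config(),
                           lr_decay_epochs = integer(0),
                           pretrain_epochs = 0L, seed = 1L,
                           checkpoint_path = NULL, verbose = FALSE) {
  if (length(pairs) == 0L) stop_argument("training set is empty")
  len <- length(pairs[[1]]$clean)
  if (len != gen_spec$input_len) {
    stop_argument(sprintf("pairs have %d-sample windows; generator expects %d",
                          len, gen_spec$input_len))
  }
  G <- build_generator(gen_spec, seed = derive_seed(seed, "init-g"))
  D <- build_discriminator(disc_spec, seed = derive_seed(seed, "init-d"))
  # generator momentum follows the distance-dominated objective (0.9);
  # the discriminator keeps the conservative GAN setting (0.5) and a
  # slower rate so the adversarial game stays stable
  optG <- adam_init(G, lr = lr, beta1 = 0.9)
  optD <- adam_init(D, lr = lr_disc, beta1 = 0.5)

  clean <- vapply(pairs, function(p) p$clean, numeric(len))
  noisy <- vapply(pairs, function(p) p$noisy, numeric(len))
  n <- length(pairs)
  hist <- data.frame(epoch = integer(0), v_d = numeric(0), l_g = numeric(0),
                     l_dist = numeric(0), l_dist_max = numeric(0))
  last_good <- NULL

  for (ep in seq_len(epochs)) {
    # each occurrence of the epoch halves the rates (repeat an epoch in the
    # list for a sharper drop, e.g. c(6, 6) quarters them at epoch 6)
    for (e in lr_decay_epochs) {
      if (e == ep) {
        optG$lr <- optG$lr / 2
        optD$lr <- optD$lr / 2
      }
    }
    ord <- with_seed(derive_seed(seed, paste0("batch-", ep)), sample.int(n))
    sums <- c(v_d = 0, l_g = 0, l_dist = 0, l_dist_max = 0)
    nb <- 0L
    for (start in seq.int(1L, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1L, n)]
      B <- length(take)
      z <- array(noisy[, take], c(1L, len, B))
      sx <- array(clean[, take], c(1L, len, B))
      pre <- ep <= pretrain_epochs

      # one generator forward serves both updates (G is unchanged by the
      # discriminator step)
      fwG <- net_forward(G, z, train = TRUE)
      s_hat <- fwG$out

      # --- discriminator update (also during warm-up, so the adversarial
      # phase starts near the discriminator's equilibrium)
      fr <- net_forward(D, sx, train = TRUE)
      ff <- net_forward(D, s_hat, train = TRUE)
      sr <- as.numeric(fr$out); sf <- as.numeric(ff$out)
      v_d <- discriminator_loss(sr, sf)
      gr <- net_backward(D, fr, matrix((sr - 1) / B, 1L, B))$grads
      gf <- net_backward(D, ff, matrix(sf / B, 1L, B))$grads
      optD <- adam_step(D, optD, merge_grads(gr, gf))

      if (!pre) {
        # adversarial part of the generator update (through the updated D)
        fwD <- net_forward(D, s_hat, train = FALSE)
        sc <- as.numeric(fwD$out)
        gl <- generator_loss(sc, s_hat, sx, loss_cfg)
        dadv <- net_backward(D, fwD, matrix((sc - 1) / B, 1L, B))$dinput
      } else {
        # warm-up: the generator sees the distance terms only
        gl <- generator_loss(1, s_hat, sx, loss_cfg)  # adversarial term = 0
        dadv <- 0
      }

      # --- generator update
      rmat <- matrix(s_hat - sx, len, B)
      dfake <- dadv +
        array(loss_cfg$loss_weight_dist * 2 * rmat / B, c(1L, len, B))
      amax <- max.col(t(abs(rmat)), ties.method = "first")
      dmax <- matrix(0, len, B)
      dmax[cbind(amax, seq_len(B))] <-
        sign(rmat[cbind(amax, seq_len(B))]) * loss_cfg$loss_weight_max / B
      dfake <- dfake + array(dmax, c(1L, len, B))
      gG <- net_backward(G, fwG, dfake)$grads
      optG <- adam_step(G, optG, gG)

      if (!is.finite(v_d) || !is.finite(gl$total)) {
        if (!is.null(checkpoint_path) && !is.null(last_good)) {
          saveRDS(last_good, checkpoint_path)
        }
        ecgan_stop(sprintf("training diverged at epoch %d (non-finite loss)", ep),
                   "ecgan_diverged_error")
      }
      sums <- sums + c(v_d, gl$total, gl$l_dist, gl$l_dist_max)
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, v_d = sums[[1]] / nb,
                                   l_g = sums[[2]] / nb,
                                   l_dist = sums[[3]] / nb,
                                   l_dist_max = sums[[4]] / nb))
    if (verbose) {
      message(sprintf("epoch %d: V_D %.5f  L_G %.5f  L_dist %.5f  L_max %.5f",
                      ep, sums[[1]] / nb, sums[[2]] / nb, sums[[3]] / nb,
                      sums[[4]] / nb))
    }
    last_good <- list(generator = net_to_list(G), discriminator = net_to_list(D),
                      history = hist, seed = seed)
    if (!is.null(checkpoint_path)) saveRDS(last_good, checkpoint_path)
  }
  structure(list(generator = G, discriminator = D, history = hist, seed = seed),
            class = "denoiser_state")
}

merge_grads <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) { a[i] <- b[i]; next }
    if (is.null(b[[i]])) next
    for (nm in names(a[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

#' Denoise windows with a trained generator
#'
#' Runs the generator in inference mode (batch normalization uses running
#' statistics), so results are independent of batch composition and order.
#'
#' @param state a `denoiser_state` from [train_denoiser()], or the
#'   generator `ecgan_net` itself
#' @param noisy a numeric vector (one window), a matrix with windows in
#'   rows, or a list of windows — all on the normalized scale
#' @param batch_size inference batch size
#' @return denoised windows, same container shape as the input
#' @export
denoise <- function(state, noisy, batch_size = 64L) {
  G <- if (inherits(state, "denoiser_state")) state$generator
       else if (inherits(state, "ecgan_net")) state
       else stop_argument("`state` must be a denoiser_state or ecgan_net")
  single <- is.numeric(noisy) && is.null(dim(noisy))
  as_list <- is.list(noisy)
  x <- if (single) matrix(noisy, nrow = 1L)
       else if (as_list) do.call(rbind, noisy)
       else noisy
  len <- ncol(x)
  out <- matrix(0, nrow(x), len)
  for (start in seq.int(1L, nrow(x), by = batch_size)) {
    take <- start:min(start + batch_size - 1L, nrow(x))
    z <- array(t(x[take, , drop = FALSE]), c(1L, len, length(take)))
    y <- net_forward(G, z, train = FALSE, keep_caches = FALSE)$out
    out[take, ] <- t(matrix(y, len, length(take)))
  }
  if (single) out[1L, ] else if (as_list) asplit_rows(out) else out
}

asplit_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

#' Mean denoising metrics of a model over held-out pairs
#'
#' @param state a `denoiser_state` or generator net
#' @param pairs list of `segment_pair`
#' @return data frame with per-window `snr_noisy`, `snr_denoised`,
#'   `prd_denoised`, `rmse_denoised`
#' @export
evaluate_denoiser <- function(state, pairs) {
  noisy <- lapply(pairs, function(p) p$noisy)
  den <- denoise(state, noisy)
  data.frame(
    snr_noisy = vapply(seq_along(pairs), function(i)
      snr(pairs[[i]]$clean, pairs[[i]]$noisy), 0),
    snr_denoised = vapply(seq_along(pairs), function(i)
      snr(pairs[[i]]$clean, den[[i]]), 0),
    prd_denoised = vapply(seq_along(pairs), function(i)
      prd(pairs[[i]]$clean, den[[i]]), 0),
    rmse_denoised = vapply(seq_along(pairs), function(i)
      rmse(pairs[[i]]$clean, den[[i]]), 0)
  )
}
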