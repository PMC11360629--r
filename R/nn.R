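# Minimal 1D neural-network toolkit.
#
# Tensors are dense arrays of dim (channels, length, batch) — channel
# fastest, so a per-channel parameter vector broadcasts onto a tensor by
# plain R recycling, and im2col reduces to contiguous slab copies with no
# transposition. Convolutions are one BLAS matrix multiply over the im2col
# matrix; every layer has a hand-written backward pass, verified against
# numerical differentiation in the test suite. Networks are small DAGs
# (needed for U-Net skips and residual shortcuts) executed in topological
# order; nodes are appended in that order by the builders, so no explicit
# sort is required.
#
# This is deliberately a small engine, not a framework: only the layer
# kinds the generator, discriminator and ResNet need are implemented.

# ---- layer constructors ----------------------------------------------------

# He-normal weight init scaled by fan-in; `init = "zero"` for the
# generator's final projection so an untrained generator is the identity.
nn_conv1d <- function(in_ch, out_ch, k, stride = 1L, seed = 1L,
                      init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") {
    matrix(0, out_ch, k * in_ch)
  } else {
    with_seed(seed, matrix(rnorm(out_ch * k * in_ch, sd = sqrt(2 / (k * in_ch))),
                           out_ch, k * in_ch))
  }
  list(kind = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride),
       params = list(W = W, b = numeric(out_ch)))
}

nn_batchnorm <- function(ch, momentum = 0.9, eps = 1e-5) {
  list(kind = "bn", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       state = list(mean = numeric(ch), var = rep(1, ch)))
}

nn_prelu <- function(ch, a0 = 0.25) {
  list(kind = "prelu", ch = ch, params = list(a = rep(a0, ch)))
}

nn_leaky <- function(slope = 0.2) list(kind = "leaky", slope = slope, params = NULL)
nn_relu <- function() list(kind = "relu", params = NULL)
nn_upsample2 <- function() list(kind = "upsample2", params = NULL)
nn_gap <- function() list(kind = "gap", params = NULL)

nn_dense <- function(in_dim, out_dim, seed = 1L) {
  W <- with_seed(seed, matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                              out_dim, in_dim))
  list(kind = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = W, b = numeric(out_dim)))
}

# per-channel sum over length and batch: channels are the fastest dimension
sum_ch <- function(x) rowSums(x, dims = 1L)

# ---- forward / backward per layer ------------------------------------------

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$kind,
    conv = conv_forward(layer, x),
    bn = bn_forward(layer, x, train),
    prelu = {
      list(y = cpp_prelu_forward(x, layer$params$a),
           cache = list(x = x), layer = layer)
    },
    leaky = {
      list(y = cpp_lrelu_forward(x, layer$slope),
           cache = list(x = x), layer = layer)
    },
    relu = {
      list(y = cpp_lrelu_forward(x, 0), cache = list(x = x), layer = layer)
    },
    upsample2 = {
      d <- dim(x)
      y <- x[, rep(seq_len(d[2]), each = 2L), , drop = FALSE]
      list(y = y, cache = list(len = d[2]), layer = layer)
    },
    gap = {
      d <- dim(x)
      y <- matrix(0, d[1], d[3])
      for (b in seq_len(d[3])) {
        m <- x[, , b, drop = FALSE]
        dim(m) <- d[1:2]
        y[, b] <- rowMeans(m)
      }
      list(y = y, cache = list(d = d), layer = layer)
    },
    dense = {
      y <- layer$params$W %*% x + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    stop_argument("unknown layer kind: " %+% layer$kind)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    conv = conv_backward(layer, cache, dy),
    bn = bn_backward(layer, cache, dy),
    prelu = {
      r <- cpp_prelu_backward(cache$x, layer$params$a, dy)
      list(dx = r$dx, grads = list(a = as.numeric(r$da)))
    },
    leaky = {
      list(dx = cpp_lrelu_backward(cache$x, layer$slope, dy), grads = NULL)
    },
    relu = {
      list(dx = cpp_lrelu_backward(cache$x, 0, dy), grads = NULL)
    },
    upsample2 = {
      n2 <- 2L * cache$len
      dx <- dy[, seq.int(1L, n2, 2L), , drop = FALSE] +
        dy[, seq.int(2L, n2, 2L), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache$d
      dx <- array(0, d)
      for (b in seq_len(d[3])) dx[, , b] <- matrix(dy[, b] / d[2], d[1], d[2])
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = crossprod(layer$params$W, dy),
           grads = list(W = tcrossprod(dy, cache$x), b = rowSums(dy)))
    },
    stop_argument("unknown layer kind: " %+% layer$kind)
  )
}

# "same"-style padding: out_len = ceiling(len / stride); the compiled
# kernels treat out-of-range taps as zeros, so no explicit pad array exists.
conv_geometry <- function(len, k, s) {
  out_len <- as.integer(ceiling(len / s))
  pad <- max(0L, (out_len - 1L) * s + k - len)
  list(out_len = out_len, pad_l = pad %/% 2L)
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  if (d[1] != layer$in_ch) {
    stop_argument(sprintf("conv expected %d input channels, got %d",
                          layer$in_ch, d[1]))
  }
  g <- conv_geometry(d[2], layer$k, layer$stride)
  r <- cpp_conv1d_forward(x, layer$params$W, layer$params$b, layer$k,
                          layer$stride, g$pad_l, g$out_len)
  list(y = r$y,
       cache = list(P = r$P, pad_l = g$pad_l, inc = d[1], len = d[2]),
       layer = layer)
}

conv_backward <- function(layer, cache, dy) {
  r <- cpp_conv1d_backward(cache$P, layer$params$W, dy, layer$k,
                           layer$stride, cache$pad_l, cache$inc, cache$len)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  m <- d[2] * d[3]
  if (train) {
    mom <- cpp_ch_moments(x)
    mu <- as.numeric(mom$sum) / m
    v <- pmax(0, as.numeric(mom$sumsq) / m - mu^2)
    layer$state$mean <- layer$momentum * layer$state$mean + (1 - layer$momentum) * mu
    layer$state$var <- layer$momentum * layer$state$var + (1 - layer$momentum) * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  inv <- 1 / sqrt(v + layer$eps)
  r <- cpp_bn_apply(x, mu, inv, layer$params$gamma, layer$params$beta)
  list(y = r$y, cache = list(xhat = r$xhat, inv = inv, train = train),
       layer = layer)
}

bn_backward <- function(layer, cache, dy) {
  r <- cpp_bn_backward(cache$xhat, cache$inv, layer$params$gamma, dy,
                       cache$train)
  list(dx = r$dx,
       grads = list(gamma = as.numeric(r$dgamma), beta = as.numeric(r$dbeta)))
}

# ---- network graph ----------------------------------------------------------

new_net <- function(kind, spec) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$kind <- kind
  e$spec <- spec
  class(e) <- "ecgan_net"
  e
}

#' @export
print.ecgan_net <- function(x, ...) {
  np <- sum(vapply(x$nodes, function(n) {
    if (is.null(n$layer$params)) 0L else
      sum(vapply(n$layer$params, length, 0L))
  }, 0L))
  cat(sprintf("<ecgan_net %s> %d nodes, %d parameters\n",
              x$kind, length(x$nodes), np))
  invisible(x)
}

add_node <- function(net, op, inputs = integer(0), layer = NULL,
                     trainable = TRUE) {
  stopifnot(all(inputs < length(net$nodes) + 1L))
  net$nodes[[length(net$nodes) + 1L]] <-
    list(op = op, inputs = as.integer(inputs), layer = layer,
         trainable = trainable)
  length(net$nodes)
}

# keep_caches = FALSE drops the per-layer backward caches (notably the
# im2col matrices) as soon as each node is computed — inference mode.
net_forward <- function(net, x, train = FALSE, keep_caches = TRUE) {
  n <- length(net$nodes)
  outs <- vector("list", n)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    node <- net$nodes[[i]]
    if (node$op == "input") {
      outs[[i]] <- x
    } else if (node$op == "layer") {
      r <- layer_forward(node$layer, outs[[node$inputs[1]]], train)
      outs[[i]] <- r$y
      if (keep_caches) caches[[i]] <- r$cache
      if (train && node$layer$kind == "bn") {
        net$nodes[[i]]$layer <- r$layer   # running-stat update
      }
    } else if (node$op == "add") {
      outs[[i]] <- outs[[node$inputs[1]]] + outs[[node$inputs[2]]]
    } else if (node$op == "concat") {
      a <- outs[[node$inputs[1]]]; b <- outs[[node$inputs[2]]]
      da <- dim(a); db <- dim(b)
      y <- array(0, c(da[1] + db[1], da[2], da[3]))
      y[seq_len(da[1]), , ] <- a
      y[da[1] + seq_len(db[1]), , ] <- b
      outs[[i]] <- y
    } else {
      stop_argument("unknown graph op: " %+% node$op)
    }
  }
  list(out = outs[[n]], outs = outs, caches = caches)
}

net_backward <- function(net, fw, dout) {
  n <- length(net$nodes)
  douts <- vector("list", n)
  grads <- vector("list", n)
  douts[[n]] <- dout
  acc <- function(j, d) {
    douts[[j]] <<- if (is.null(douts[[j]])) d else douts[[j]] + d
  }
  dinput <- NULL
  for (i in rev(seq_len(n))) {
    d <- douts[[i]]
    if (is.null(d)) next
    node <- net$nodes[[i]]
    if (node$op == "input") {
      dinput <- d
    } else if (node$op == "layer") {
      r <- layer_backward(node$layer, fw$caches[[i]], d)
      grads[i] <- list(r$grads)
      acc(node$inputs[1], r$dx)
    } else if (node$op == "add") {
      acc(node$inputs[1], d)
      acc(node$inputs[2], d)
    } else if (node$op == "concat") {
      ca <- dim(fw$outs[[node$inputs[1]]])[1]
      acc(node$inputs[1], d[seq_len(ca), , , drop = FALSE])
      acc(node$inputs[2], d[-seq_len(ca), , , drop = FALSE])
    }
    douts[i] <- list(NULL)  # free as we go (keep list length)
  }
  list(grads = grads, dinput = dinput)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(net, lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = vector("list", length(net$nodes)),
             v = vector("list", length(net$nodes)))
  for (i in seq_along(net$nodes)) {
    p <- net$nodes[[i]]$layer$params
    if (!is.null(p)) {
      st$m[[i]] <- lapply(p, function(q) q * 0)
      st$v[[i]] <- lapply(p, function(q) q * 0)
    }
  }
  st
}

adam_step <- function(net, opt, grads, freeze = NULL) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(net$nodes)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (!net$nodes[[i]]$trainable) next
    if (!is.null(freeze) && i %in% freeze) next
    for (nm in names(g)) {
      opt$m[[i]][[nm]] <- opt$beta1 * opt$m[[i]][[nm]] + (1 - opt$beta1) * g[[nm]]
      opt$v[[i]][[nm]] <- opt$beta2 * opt$v[[i]][[nm]] + (1 - opt$beta2) * g[[nm]]^2
      mhat <- opt$m[[i]][[nm]] / c1
      vhat <- opt$v[[i]][[nm]] / c2
      net$nodes[[i]]$layer$params[[nm]] <-
        net$nodes[[i]]$layer$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  opt
}

# ---- (de)serialization ------------------------------------------------------

# networks live in environments (so running statistics can be updated in
# place); checkpoints flatten them to plain lists.
net_to_list <- function(net) {
  list(format = "ecgan-checkpoint", version = 1L, kind = net$kind,
       spec = net$spec, nodes = net$nodes)
}

net_from_list <- function(l) {
  if (!identical(l$format, "ecgan-checkpoint")) {
    stop_format("not an ecgan checkpoint")
  }
  e <- new_net(l$kind, l$spec)
  e$nodes <- l$nodes
  e
}

#' Save a model checkpoint
#' @param net an `ecgan_net`
#' @param path file path
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net_to_list(net), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file path
#' @return an `ecgan_net`
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: " %+% path)
  net_from_list(readRDS(path))
}

# deep copy (environments are reference semantics)
net_clone <- function(net) net_from_list(net_to_list(net))

# stack windows (list of numeric vectors or a matrix with windows in rows)
# into a (1, len, batch) tensor
windows_to_tensor <- function(w) {
  if (is.matrix(w)) w <- lapply(seq_len(nrow(w)), function(i) w[i, ])
  if (is.numeric(w)) w <- list(w)
  len <- length(w[[1]])
  array(unlist(w), c(1L, len, length(w)))
}
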