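# 1D ResNet beat classifier.
#
# Residual stages over 512-sample normalized segments, global average
# pooling and a softmax output over the beat-class alphabet. Transfer
# learning warm-starts from a pretrained model, optionally freezing early
# stages and re-mapping the output layer when the new data uses a subset of
# the class alphabet (e.g. no fusion beats in wearable recordings).

#' ResNet architecture specification
#'
#' @param input_len segment length in samples
#' @param classes class alphabet (character); the output dimension
#' @param stages list of integer triplets `c(blocks, filters, stride)`;
#'   the stride applies to the first block of the stage
#' @param kernel convolution kernel size
#' @return a `resnet_spec`
#' @export
resnet_spec <- function(input_len = 512L, classes = BEAT_CLASSES,
                        stages = list(c(2L, 32L, 1L), c(2L, 64L, 2L),
                                      c(2L, 128L, 2L)),
                        kernel = 7L) {
  if (length(classes) < 2L) stop_argument("need at least two classes")
  structure(list(input_len = as.integer(input_len),
                 classes = as.character(classes),
                 stages = stages, kernel = as.integer(kernel)),
            class = "resnet_spec")
}

# residual block: conv(+stride)-BN-ReLU-conv-BN + shortcut (1x1 strided
# conv when shape changes), add, ReLU
add_resnet_block <- function(net, input_id, in_ch, out_ch, k, stride, seed) {
  c1 <- add_node(net, "layer", input_id,
                 nn_conv1d(in_ch, out_ch, k, stride = stride,
                           seed = derive_seed(seed, "c1")))
  b1 <- add_node(net, "layer", c1, nn_batchnorm(out_ch))
  r1 <- add_node(net, "layer", b1, nn_relu())
  c2 <- add_node(net, "layer", r1,
                 nn_conv1d(out_ch, out_ch, k, seed = derive_seed(seed, "c2")))
  b2 <- add_node(net, "layer", c2, nn_batchnorm(out_ch))
  short <- if (in_ch != out_ch || stride != 1L) {
    add_node(net, "layer", input_id,
             nn_conv1d(in_ch, out_ch, 1L, stride = stride,
                       seed = derive_seed(seed, "sc")))
  } else input_id
  s <- add_node(net, "add", c(b2, short))
  add_node(net, "layer", s, nn_relu())
}

#' Build the 1D ResNet classifier
#'
#' @param spec a [resnet_spec()]
#' @param seed integer seed for weight initialization
#' @return an `ecgan_net` mapping `(input_len, 1, batch)` tensors to
#'   `(n_classes, batch)` logits; `net$classes` holds the alphabet and
#'   `net$stage_nodes` the node ids per stage (used for freezing)
#' @export
build_resnet <- function(spec = resnet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "resnet_spec"))
  net <- new_net("resnet", spec)
  inp <- add_node(net, "input")
  k <- spec$kernel
  f0 <- spec$stages[[1]][2]
  st <- add_node(net, "layer", inp,
                 nn_conv1d(1L, f0, k, seed = derive_seed(seed, "stem")))
  sb <- add_node(net, "layer", st, nn_batchnorm(f0))
  cur <- add_node(net, "layer", sb, nn_relu())
  stage_nodes <- list(stem = st:cur)
  in_ch <- f0
  for (si in seq_along(spec$stages)) {
    s <- spec$stages[[si]]
    first <- length(net$nodes) + 1L
    for (bi in seq_len(s[1])) {
      cur <- add_resnet_block(net, cur, in_ch, s[2], k,
                              stride = if (bi == 1L) s[3] else 1L,
                              seed = derive_seed(seed, sprintf("s%d-b%d", si, bi)))
      in_ch <- s[2]
    }
    stage_nodes[[paste0("stage", si)]] <- first:cur
  }
  gp <- add_node(net, "layer", cur, nn_gap())
  head <- add_node(net, "layer", gp,
                   nn_dense(in_ch, length(spec$classes),
                            seed = derive_seed(seed, "head")))
  stage_nodes$head <- c(gp, head)
  net$classes <- spec$classes
  net$stage_nodes <- stage_nodes
  net
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# shared minibatch cross-entropy trainer
train_softmax_net <- function(net, x, y_idx, epochs, batch_size, lr, seed,
                              freeze_ids = NULL, verbose = FALSE) {
  n <- ncol(x)
  len <- nrow(x)
  opt <- adam_init(net, lr = lr, beta1 = 0.9)
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("cls-batch-", ep)), sample.int(n))
    tot_loss <- 0; tot_correct <- 0L; nb <- 0L
    for (start in seq.int(1L, n, by = batch_size)) {
      take <- ord[start:min(start + batch_size - 1L, n)]
      B <- length(take)
      xb <- array(x[, take], c(1L, len, B))
      fw <- net_forward(net, xb, train = TRUE)
      p <- softmax_cols(fw$out)
      iy <- cbind(y_idx[take], seq_len(B))
      loss <- -mean(log(pmax(p[iy], 1e-12)))
      if (!is.finite(loss)) {
        ecgan_stop(sprintf("classifier training diverged at epoch %d", ep),
                   "ecgan_diverged_error")
      }
      dlog <- p
      dlog[iy] <- dlog[iy] - 1
      g <- net_backward(net, fw, dlog / B)$grads
      opt <- adam_step(net, opt, g, freeze = freeze_ids)
      tot_loss <- tot_loss + loss
      tot_correct <- tot_correct + sum(apply(p, 2, which.max) == y_idx[take])
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / nb,
                                   acc = tot_correct / n))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f  acc %.3f",
                      ep, tot_loss / nb, tot_correct / n))
    }
  }
  hist
}

segments_to_xy <- function(segments, classes) {
  len <- length(segments[[1]]$window)
  x <- vapply(segments, function(s) s$window, numeric(len))
  labs <- vapply(segments, function(s) s$label, "")
  unknown <- setdiff(unique(labs), classes)
  if (length(unknown)) {
    stop_argument("segment label(s) outside the class alphabet: " %+%
                    paste(unknown, collapse = ", "))
  }
  list(x = x, y_idx = match(labs, classes), labels = labs)
}

#' Train the beat classifier
#'
#' Minibatch cross-entropy with Adam; per-epoch loss and training accuracy
#' are logged, and the class distribution of the training set is attached
#' (class imbalance is reported, not resampled).
#'
#' @param segments list of `labeled_segment` objects
#' @param epochs,batch_size,lr training hyperparameters
#' @param spec a [resnet_spec()]; its alphabet must cover the labels
#' @param seed integer master seed
#' @param verbose print a line per epoch
#' @return a `classifier_state`: `net`, `classes`, `history`,
#'   `class_counts`, `seed`
#' @export
train_classifier <- function(segments, epochs = 10L, batch_size = 32L,
                             lr = 1e-3, spec = resnet_spec(), seed = 1L,
                             verbose = FALSE) {
  if (length(segments) == 0L) stop_argument("training set is empty")
  dat <- segments_to_xy(segments, spec$classes)
  if (length(unique(dat$labels)) < 2L) {
    stop_argument("training data contains a single class")
  }
  if (nrow(dat$x) != spec$input_len) {
    stop_argument(sprintf("segments are %d samples; spec expects %d",
                          nrow(dat$x), spec$input_len))
  }
  net <- build_resnet(spec, seed = derive_seed(seed, "cls-init"))
  hist <- train_softmax_net(net, dat$x, dat$y_idx, epochs, batch_size, lr,
                            seed, verbose = verbose)
  structure(list(net = net, classes = spec$classes, history = hist,
                 class_counts = table(factor(dat$labels, levels = spec$classes)),
                 seed = seed),
            class = "classifier_state")
}

#' Fine-tune a pretrained classifier on new data
#'
#' Warm-starts from the pretrained weights. When the new data uses a strict
#' subset of the pretrained alphabet, the output layer is re-mapped to the
#' present classes (rows of the dense head are carried over). Earlier
#' stages can be frozen; the default freezes the stem and first stage and
#' fine-tunes the rest at a reduced learning rate.
#'
#' @param state a `classifier_state` (pretrained)
#' @param new_segments list of `labeled_segment` objects
#' @param epochs,batch_size training hyperparameters
#' @param lr fine-tuning learning rate (default: a tenth of the usual 1e-3)
#' @param freeze `"none"`, `"first_stage"` or `"all_but_head"`
#' @param classes class alphabet of the new data; default: the classes
#'   present in `new_segments`, in pretrained order
#' @param seed integer seed
#' @return an updated `classifier_state`
#' @export
transfer_fit <- function(state, new_segments, epochs = 5L, batch_size = 32L,
                         lr = 1e-4, freeze = c("first_stage", "none",
                                               "all_but_head"),
                         classes = NULL, seed = 1L) {
  stopifnot(inherits(state, "classifier_state"))
  freeze <- match.arg(freeze)
  labs <- vapply(new_segments, function(s) s$label, "")
  unknown <- setdiff(unique(labs), state$classes)
  if (length(unknown)) {
    stop_argument("new data contains class(es) unknown to the model: " %+%
                    paste(unknown, collapse = ", "))
  }
  if (is.null(classes)) classes <- state$classes[state$classes %in% labs]
  net <- net_clone(state$net)
  net$classes <- classes
  net$stage_nodes <- state$net$stage_nodes
  if (!identical(classes, state$classes)) {
    head_id <- tail(net$stage_nodes$head, 1L)
    keep <- match(classes, state$classes)
    dl <- net$nodes[[head_id]]$layer
    dl$params$W <- dl$params$W[keep, , drop = FALSE]
    dl$params$b <- dl$params$b[keep]
    dl$out_dim <- length(classes)
    net$nodes[[head_id]]$layer <- dl
  }
  freeze_ids <- switch(freeze,
    none = NULL,
    first_stage = c(net$stage_nodes$stem, net$stage_nodes$stage1),
    all_but_head = setdiff(seq_along(net$nodes), net$stage_nodes$head)
  )
  dat <- segments_to_xy(new_segments, classes)
  hist <- train_softmax_net(net, dat$x, dat$y_idx, epochs, batch_size, lr,
                            seed, freeze_ids = freeze_ids)
  structure(list(net = net, classes = classes, history = hist,
                 class_counts = table(factor(labs, levels = classes)),
                 seed = seed),
            class = "classifier_state")
}

#' Predict beat classes
#'
#' Inference mode (running batch-norm statistics), so predictions are
#' batch-order invariant.
#'
#' @param object a `classifier_state`
#' @param segments list of `labeled_segment` objects, a matrix with
#'   segments in rows, or a single numeric window
#' @param batch_size inference batch size
#' @param ... unused
#' @return list with `labels` (character) and `probabilities`
#'   (`n x n_classes` matrix, rows summing to 1)
#' @export
predict.classifier_state <- function(object, segments, batch_size = 64L, ...) {
  x <- if (is.list(segments)) {
    vapply(segments, function(s)
      if (inherits(s, "labeled_segment")) s$window else as.numeric(s),
      numeric(object$net$spec$input_len))
  } else if (is.matrix(segments)) {
    t(segments)
  } else {
    matrix(segments, ncol = 1L)
  }
  len <- nrow(x); n <- ncol(x)
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (start in seq.int(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    xb <- array(x[, take], c(1L, len, length(take)))
    out <- net_forward(object$net, xb, train = FALSE, keep_caches = FALSE)$out
    probs[take, ] <- t(softmax_cols(out))
  }
  list(labels = object$classes[max.col(probs, ties.method = "first")],
       probabilities = probs)
}
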