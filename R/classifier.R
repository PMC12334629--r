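#' Numerically stable softmax
#'
#' `t_u = exp(a_u) / sum(exp(a_v))`, computed with max subtraction so huge
#' logits do not overflow. The outputs are positive and sum to 1.
#'
#' @param logits Numeric vector a.
#' @return Probability vector of the same length.
#' @export
softmax <- function(logits) {
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Adaptive error-similarity (weighted cross-entropy) loss
#'
#' Cross-entropy against the one-hot true class, scaled by the gap between
#' the largest predicted probability and the true-class probability:
#' `loss = -(t_max - t_eps) * log(t_eps)`. The weight is treated as a
#' detached constant in differentiation. Confidently correct samples
#' (`t_eps = t_max`) contribute exactly zero; ambiguous or misclassified
#' samples dominate. The log is guarded at `1e-12`.
#'
#' @param t Probability vector (softmax output).
#' @param true_class Index of the true class (1-based).
#' @return Scalar loss >= 0.
#' @examples
#' ces_loss(c(0.7, 0.3), 2)  # 0.4 * -log(0.3)
#' @export
ces_loss <- function(t, true_class) {
  tmax <- max(t)
  teps <- t[true_class]
  -(tmax - teps) * log(max(teps, 1e-12))
}

#' Gradient of the error-similarity loss with respect to the logits
#'
#' Per class u: `t_u * (t_max - t_eps) - (t_max - t_u) * ttilde_u`, which is
#' algebraically the frozen-weight cross-entropy gradient
#' `(t_max - t_eps) * (t - ttilde)`; both forms are computed and asserted
#' equal. Exactly zero whenever the prediction is confidently correct.
#'
#' @param t Probability vector.
#' @param true_class Index of the true class (1-based).
#' @return Gradient vector, same length as `t`.
#' @export
ces_gradient <- function(t, true_class) {
  tmax <- max(t)
  teps <- t[true_class]
  ttilde <- numeric(length(t))
  ttilde[true_class] <- 1
  g1 <- t * (tmax - teps) - (tmax - t) * ttilde
  g2 <- (tmax - teps) * (t - ttilde)
  stopifnot(max(abs(g1 - g2)) < 1e-12)
  g1
}

#' Classifier configuration
#'
#' The classifier has a dual input: the scalar feature vector through a
#' one-hidden-layer dense branch, and the stacked multi-channel feature image
#' through a small convolutional stack (two 3x3 convolution + ReLU + 2x
#' average-pool stages, then global average pooling). Either branch can be
#' disabled. The softmax output layer is trained by the CAViaR-style lagged
#' update of [caviar_update()]; interior layers use plain gradient descent
#' through the same loss.
#'
#' @param n_classes Number of classes (2 here; the loss and update are
#'   written for any number).
#' @param use_dense,use_conv Enable the two input branches.
#' @param hidden Dense-branch hidden width.
#' @param conv_channels Two conv-stage widths.
#' @param learning_rate Step size mu.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size for the interior-layer updates.
#' @param phi0 CAViaR constant (default 0).
#' @param phi_max Clamp for the error-similarity ratios (default 10).
#' @param normalize_ratios Normalize the two ratios to sum to 1 (default);
#'   the raw unnormalized recursion is available for experimentation.
#' @param adaptive Use the CAViaR recursion for the output layer (default);
#'   `FALSE` forces plain gradient descent there (ablation mode).
#' @param init_scale Half-width of the seeded uniform weight initialization.
#' @param seed Integer seed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_classes = 2, use_dense = TRUE, use_conv = FALSE,
                              hidden = 16, conv_channels = c(4, 8),
                              learning_rate = 0.2, epochs = 60, batch_size = 16,
                              phi0 = 0, phi_max = 10, normalize_ratios = TRUE,
                              adaptive = TRUE, init_scale = 0.3, seed = 1L) {
  check_that(is_count(n_classes) && n_classes >= 2, "n_classes", "must be >= 2")
  check_that(use_dense || use_conv, "use_dense/use_conv", "at least one branch must be enabled")
  check_that(is_count(hidden) && hidden >= 1, "hidden", "must be >= 1")
  check_that(is.numeric(conv_channels) && length(conv_channels) == 2 && all(conv_channels >= 1),
             "conv_channels", "must be two positive widths")
  check_that(is_num1(learning_rate) && learning_rate > 0, "learning_rate", "must be > 0")
  check_that(is_count(epochs) && epochs >= 1, "epochs", "must be >= 1")
  check_that(is_count(batch_size) && batch_size >= 1, "batch_size", "must be >= 1")
  check_that(is_num1(phi0), "phi0", "must be a number")
  check_that(is_num1(phi_max) && phi_max > 0, "phi_max", "must be > 0")
  structure(list(n_classes = as.integer(n_classes), use_dense = use_dense,
                 use_conv = use_conv, hidden = as.integer(hidden),
                 conv_channels = as.integer(conv_channels),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), phi0 = phi0,
                 phi_max = phi_max, normalize_ratios = normalize_ratios,
                 adaptive = adaptive, init_scale = init_scale,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' CAViaR-style output-layer update
#'
#' The output weights follow a lagged autoregressive recursion driven by the
#' similarity of recent epoch errors: with ratios `phi1 = e_i / e_{i-1}` and
#' `phi2 = e_i / e_{i-2}` (each clamped to `[0, phi_max]`; a zero lagged
#' error gives the maximal ratio), normalized to sum to one, the new weights
#' are
#' `G_i = phi0 + phi1n * G_{i-1} + phi2n * G_{i-2}
#'        - mu * (phi1n * grad(G_{i-1}) + phi2n * grad(G_{i-2}))`.
#' With fewer than two recorded past errors the update degrades to a plain
#' gradient step. Lag registers and the error history are shifted after
#' every call.
#'
#' @param state A `classifier_state` (see [train_classifier()]).
#' @param gradient Gradient of the loss at the current output weights (same
#'   shape as `state$output_weights`).
#' @param error Current epoch error e_i (positive scalar).
#' @return The updated `classifier_state`.
#' @export
caviar_update <- function(state, gradient, error) {
  cfg <- state$config
  mu <- cfg$learning_rate
  G1 <- state$output_weights       # G^{i-1}
  G2 <- state$lag_weights          # G^{i-2}
  F1 <- gradient                   # grad at G^{i-1}
  F2 <- state$lag_gradient         # grad at G^{i-2}
  e1 <- state$errors[1]            # e_{i-1}
  e2 <- state$errors[2]            # e_{i-2}

  if (!isTRUE(cfg$adaptive) || is.na(e1) || is.na(e2) || is.null(G2) || is.null(F2)) {
    Gnew <- G1 - mu * F1
  } else {
    ratio <- function(den) {
      if (den == 0) cfg$phi_max else clamp(error / den, 0, cfg$phi_max)
    }
    phi1 <- ratio(e1); phi2 <- ratio(e2)
    if (cfg$normalize_ratios) {
      s <- phi1 + phi2
      if (s == 0) { phi1 <- 0.5; phi2 <- 0.5 } else { phi1 <- phi1 / s; phi2 <- phi2 / s }
    }
    Gnew <- cfg$phi0 + phi1 * G1 + phi2 * G2 - mu * (phi1 * F1 + phi2 * F2)
  }
  state$lag_weights <- G1
  state$lag_gradient <- F1
  state$output_weights <- Gnew
  state$errors <- c(error, e1)
  state
}

# ---- internal network plumbing ---------------------------------------------

conv_forward <- function(channels, W, b) {
  patches <- im2col3(channels)
  z <- sweep(patches %*% W, 2, b, `+`)
  nr <- nrow(channels[[1]])
  pre <- lapply(seq_len(ncol(z)), function(o) matrix(z[, o], nr, nr))
  list(pre = pre, act = lapply(pre, relu), patches = patches)
}

# Index map turning conv weights (9*Cin x Cout) into the matrix that
# backpropagates through im2col3 of the OUTPUT gradients (9*Cout x Cin).
conv_backward_weightmap <- function(W, cin, cout) {
  W2 <- matrix(0, 9 * cout, cin)
  for (ci in seq_len(cin)) for (co in seq_len(cout)) {
    for (dx in 0:2) for (dy in 0:2) {
      W2[(co - 1) * 9 + dx * 3 + dy + 1, ci] <- W[(ci - 1) * 9 + (2 - dx) * 3 + (2 - dy) + 1, co]
    }
  }
  W2
}

pool2_backward <- function(grad) {
  kronecker(grad, matrix(1, 2, 2)) / 4
}

init_mat <- function(nr, nc, scale) matrix(runif(nr * nc, -scale, scale), nr, nc)

forward_sample <- function(state, x, stack) {
  cfg <- state$config
  cache <- list()
  z <- numeric(0)
  if (cfg$use_dense) {
    # standardized features clipped at +-8 sd: the mean-power-normalized
    # statistics can produce extreme outliers on near-degenerate maps
    xs <- clamp((x - state$center) / state$scale, -8, 8)
    xin <- c(xs, 1)
    pre1 <- as.vector(state$W1 %*% xin)
    h1 <- relu(pre1)
    z <- c(z, h1)
    cache$xin <- xin; cache$pre1 <- pre1
  }
  if (cfg$use_conv) {
    chans <- stack
    c1 <- conv_forward(chans, state$C1W, state$C1b)
    p1 <- lapply(c1$act, avg_pool2)
    c2 <- conv_forward(p1, state$C2W, state$C2b)
    p2 <- lapply(c2$act, avg_pool2)
    gap <- vapply(p2, mean, numeric(1))
    z <- c(z, gap)
    cache$chans <- chans; cache$c1 <- c1; cache$p1 <- p1; cache$c2 <- c2; cache$p2 <- p2
  }
  zin <- c(z, 1)
  logits <- as.vector(state$output_weights %*% zin)
  cache$zin <- zin
  list(t = softmax(logits), cache = cache)
}

# Backprop from the logit gradient; returns interior-layer gradients and the
# output-layer gradient for this sample.
backward_sample <- function(state, grad_a, cache) {
  cfg <- state$config
  grads <- list(G = outer(grad_a, cache$zin))
  p <- length(cache$zin) - 1L
  grad_z <- as.vector(t(state$output_weights[, seq_len(p), drop = FALSE]) %*% grad_a)
  off <- 0L
  if (cfg$use_dense) {
    nh <- cfg$hidden
    gh <- grad_z[seq_len(nh)] * (cache$pre1 > 0)
    grads$W1 <- outer(gh, cache$xin)
    off <- nh
  }
  if (cfg$use_conv) {
    c2n <- cfg$conv_channels[2]
    ggap <- grad_z[off + seq_len(c2n)]
    np2 <- length(cache$p2[[1]])
    g_p2 <- lapply(seq_len(c2n), function(o) matrix(ggap[o] / np2, nrow(cache$p2[[1]]), ncol(cache$p2[[1]])))
    g_a2 <- lapply(seq_len(c2n), function(o) pool2_backward(g_p2[[o]]) * (cache$c2$pre[[o]] > 0))
    gmat2 <- vapply(g_a2, as.vector, numeric(length(g_a2[[1]])))
    grads$C2W <- t(cache$c2$patches) %*% gmat2
    grads$C2b <- colSums(gmat2)
    c1n <- cfg$conv_channels[1]
    W2map <- conv_backward_weightmap(state$C2W, c1n, c2n)
    g_p1_mat <- im2col3(g_a2) %*% W2map
    nr1 <- nrow(cache$p1[[1]])
    g_a1 <- lapply(seq_len(c1n), function(o) {
      pool2_backward(matrix(g_p1_mat[, o], nr1, nr1)) * (cache$c1$pre[[o]] > 0)
    })
    gmat1 <- vapply(g_a1, as.vector, numeric(length(g_a1[[1]])))
    grads$C1W <- t(cache$c1$patches) %*% gmat1
    grads$C1b <- colSums(gmat1)
  }
  grads
}

#' Train the classifier
#'
#' Epochs over shuffled minibatches. Each sample's forward pass feeds the
#' enabled branches into the softmax output layer; the loss is
#' [ces_loss()]. Interior layers (dense hidden and conv stack) take plain
#' gradient-descent steps per minibatch while the output layer is held
#' fixed; at the end of each epoch the output layer takes one
#' [caviar_update()] step driven by the epoch-mean loss and epoch-mean
#' output-layer gradient. Fully seeded.
#'
#' @param features Tibble from [extract_features()] (columns `label`, feature
#'   columns, optionally `stack`).
#' @param config A [classifier_config()].
#' @return A `classifier_state` list with weights, lag registers, feature
#'   standardization constants and the per-epoch `loss_history`.
#' @export
train_classifier <- function(features, config = classifier_config()) {
  cfg <- config
  labels <- features$label
  check_that(all(labels %in% 0:(cfg$n_classes - 1)), "label",
             "labels must be 0..n_classes-1")
  feat_cols <- setdiff(names(features), c("id", "label", "stack"))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  stacks <- if ("stack" %in% names(features)) features$stack else NULL
  if (cfg$use_conv && is.null(stacks)) {
    abort("use_conv requires features extracted with keep_stack = TRUE",
          class = "bcdnet_validation_error")
  }

  with_seed(cfg$seed, {
    center <- colMeans(X)
    scale_ <- apply(X, 2, sd)
    scale_[scale_ < 1e-9] <- 1

    p <- 0L
    state <- list(config = cfg, center = center, scale = scale_, feat_cols = feat_cols)
    if (cfg$use_dense) {
      state$W1 <- init_mat(cfg$hidden, ncol(X) + 1L, cfg$init_scale)
      p <- p + cfg$hidden
    }
    if (cfg$use_conv) {
      nch <- length(stacks[[1]])
      state$C1W <- init_mat(9L * nch, cfg$conv_channels[1], cfg$init_scale)
      state$C1b <- numeric(cfg$conv_channels[1])
      state$C2W <- init_mat(9L * cfg$conv_channels[1], cfg$conv_channels[2], cfg$init_scale)
      state$C2b <- numeric(cfg$conv_channels[2])
      p <- p + cfg$conv_channels[2]
    }
    state$output_weights <- init_mat(cfg$n_classes, p + 1L, cfg$init_scale)
    state$lag_weights <- NULL
    state$lag_gradient <- NULL
    state$errors <- c(NA_real_, NA_real_)

    n <- nrow(X)
    loss_history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (batch in batches) {
        acc <- NULL
        batch_loss <- 0
        batch_gradG <- state$output_weights * 0
        for (i in batch) {
          stk <- if (cfg$use_conv) normalize_stack(stacks[[i]]) else NULL
          fw <- forward_sample(state, X[i, ], stk)
          tc <- labels[i] + 1L
          loss <- ces_loss(fw$t, tc)
          if (!is.finite(loss)) {
            abort(sprintf("non-finite loss at epoch %d", ep), class = "bcdnet_fitness_error")
          }
          ep_loss <- ep_loss + loss
          batch_loss <- batch_loss + loss
          grad_a <- ces_gradient(fw$t, tc)
          g <- backward_sample(state, grad_a, fw$cache)
          batch_gradG <- batch_gradG + g$G
          g$G <- NULL
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        for (nm in names(acc)) {
          state[[nm]] <- state[[nm]] - cfg$learning_rate * acc[[nm]] / length(batch)
        }
        # one training iteration of the output layer per minibatch: the
        # CAViaR recursion is indexed by weight-update iterations
        state <- caviar_update(state, batch_gradG / length(batch),
                               batch_loss / length(batch))
      }
      loss_history[ep] <- ep_loss / n
    }
    state$loss_history <- loss_history
    class(state) <- "classifier_state"
    state
  })
}

# Scale feature-image channels to comparable magnitudes before the conv
# stack (per-channel min-max to [0, 1]).
normalize_stack <- function(stack) lapply(stack, rescale_range, lo = 0, hi = 1)

#' Predict labels and probabilities
#'
#' @param object A `classifier_state` from [train_classifier()].
#' @param features Feature tibble (same columns as training).
#' @param ... Unused.
#' @return A tibble with `id` (if present), `.pred_label` (argmax, ties to
#'   the lower class index) and one `.prob_<k>` column per class.
#' @export
predict.classifier_state <- function(object, features, ...) {
  cfg <- object$config
  X <- as.matrix(features[, object$feat_cols, drop = FALSE])
  stacks <- if ("stack" %in% names(features)) features$stack else NULL
  probs <- t(vapply(seq_len(nrow(X)), function(i) {
    stk <- if (cfg$use_conv) normalize_stack(stacks[[i]]) else NULL
    forward_sample(object, X[i, ], stk)$t
  }, numeric(cfg$n_classes)))
  pred <- apply(probs, 1, which.max) - 1L  # which.max takes the first (lowest) on ties
  out <- tibble::tibble(.pred_label = as.integer(pred))
  if ("id" %in% names(features)) out <- dplyr::bind_cols(tibble::tibble(id = features$id), out)
  colnames(probs) <- paste0(".prob_", seq_len(cfg$n_classes) - 1L)
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf("<classifier_state> %d classes, branches:%s%s, %d epochs, final loss %.5g\n",
              x$config$n_classes,
              if (x$config$use_dense) " dense" else "",
              if (x$config$use_conv) " conv" else "",
              length(x$loss_history), tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
#' @rdname train_classifier
#' @param x A `classifier_state`.
#' @param ... Unused.
tidy.classifier_state <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
#' @rdname train_classifier
glance.classifier_state <- function(x, ...) {
  tibble::tibble(epochs = length(x$loss_history),
                 initial_loss = x$loss_history[1],
                 final_loss = tail(x$loss_history, 1))
}

#' Plot the training-loss curve
#' @param object A `classifier_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_state <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean error-similarity loss")
}
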