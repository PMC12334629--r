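#' Segmentation network architecture
#'
#' Describes the compact pyramid-pooling segmentation network: a small
#' convolutional encoder (3x3 convolutions, affine batch-norm, ReLU, with a
#' 2x average pool between stages), a pyramid module that adaptively
#' average-pools the encoder output at several bin counts, reduces each
#' branch with a 1x1 convolution + ReLU, bilinearly upsamples and
#' concatenates with the pre-pooling feature map, and a 1x1 convolution +
#' sigmoid head upsampled to the input size. Batch norm is a learnable
#' affine scale and shift only (no running statistics), since the
#' population-based trainer provides no minibatch statistics protocol.
#'
#' @param encoder_channels Integer vector of encoder stage widths.
#' @param pyramid_scales Strictly increasing bin counts of the pyramid.
#' @param reduction_channels Channels per pyramid branch after reduction.
#' @param input_size Input side in pixels (images are resized to this).
#' @param preset Optional shortcut: `"tiny"` (77 parameters, 32 px,
#'   single-stage encoder — small enough for the population-based trainer to
#'   optimize well) or `"small"` (~1600 parameters, 64 px); overrides the
#'   other arguments.
#' @return A `seg_architecture` list.
#' @export
seg_architecture <- function(encoder_channels = c(8, 16),
                             pyramid_scales = c(1, 2, 3, 6),
                             reduction_channels = 4,
                             input_size = 64,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("tiny", "small"))
    if (preset == "tiny") {
      encoder_channels <- 4; pyramid_scales <- c(1, 2)
      reduction_channels <- 2; input_size <- 32
    } else {
      encoder_channels <- c(8, 16); pyramid_scales <- c(1, 2, 3, 6)
      reduction_channels <- 4; input_size <- 64
    }
  }
  check_that(is.numeric(encoder_channels) && length(encoder_channels) >= 1 &&
               all(encoder_channels >= 1), "encoder_channels", "must be positive integers")
  check_that(is.numeric(pyramid_scales) && all(pyramid_scales >= 1) &&
               all(diff(pyramid_scales) > 0), "pyramid_scales",
             "must be strictly increasing and >= 1")
  check_that(is_count(reduction_channels) && reduction_channels >= 1,
             "reduction_channels", "must be an integer >= 1")
  check_that(is_count(input_size) && input_size >= 8 &&
               input_size %% 2^(length(encoder_channels) - 1) == 0,
             "input_size", "must be divisible by 2^(stages - 1)")
  feat_size <- input_size / 2^(length(encoder_channels) - 1)
  check_that(max(pyramid_scales) <= feat_size, "pyramid_scales",
             "largest scale cannot exceed the encoder feature-map size")
  structure(list(encoder_channels = as.integer(encoder_channels),
                 pyramid_scales = as.integer(pyramid_scales),
                 reduction_channels = as.integer(reduction_channels),
                 input_size = as.integer(input_size)),
            class = "seg_architecture")
}

#' Number of learnable parameters of a segmentation architecture
#'
#' The flat parameter vector holds, in this fixed order: for each encoder
#' stage the 3x3 convolution weights (rows indexed by kernel offset within
#' input channel, columns by output channel, column-major), the biases, the
#' batch-norm scales and shifts; then for each pyramid scale the 1x1
#' reduction weights and biases; then the head weights and bias.
#'
#' @param arch A [seg_architecture()].
#' @return Integer parameter count (the length of the flat vector).
#' @export
seg_param_count <- function(arch) {
  chans <- c(1L, arch$encoder_channels)
  enc <- sum(9L * chans[-length(chans)] * chans[-1] + 3L * chans[-1])
  last <- tail(arch$encoder_channels, 1)
  pyr <- length(arch$pyramid_scales) * (last * arch$reduction_channels + arch$reduction_channels)
  concat <- last + length(arch$pyramid_scales) * arch$reduction_channels
  as.integer(enc + pyr + concat + 1L)
}

# Split the flat vector into structured weights. Internal.
seg_unpack <- function(theta, arch) {
  expected <- seg_param_count(arch)
  if (length(theta) != expected) {
    abort(sprintf("parameter vector has length %d, expected %d", length(theta), expected),
          class = "bcdnet_params_error")
  }
  pos <- 0L
  take <- function(n) {
    v <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    v
  }
  chans <- c(1L, arch$encoder_channels)
  stages <- lapply(seq_along(arch$encoder_channels), function(k) {
    cin <- chans[k]; cout <- chans[k + 1]
    list(W = matrix(take(9L * cin * cout), 9L * cin, cout),
         b = take(cout), bn_scale = take(cout), bn_shift = take(cout))
  })
  last <- tail(arch$encoder_channels, 1)
  pyramid <- lapply(arch$pyramid_scales, function(s) {
    list(W = matrix(take(last * arch$reduction_channels), last, arch$reduction_channels),
         b = take(arch$reduction_channels))
  })
  concat <- last + length(arch$pyramid_scales) * arch$reduction_channels
  head_w <- take(concat); head_b <- take(1L)
  list(stages = stages, pyramid = pyramid, head_w = head_w, head_b = head_b)
}

#' Segmenter forward pass
#'
#' A pure function of the image and the flat parameter vector: produces a
#' lesion probability map in (0, 1) the same size as `input_size`.
#'
#' @param image A `gray_image` or numeric matrix; resized to the
#'   architecture's input size and rescaled to `[0, 1]`.
#' @param theta Flat numeric parameter vector (see [seg_param_count()]).
#' @param arch A [seg_architecture()].
#' @return Numeric matrix of probabilities, `input_size x input_size`.
#' @export
seg_forward <- function(image, theta, arch) {
  seg_forward_impl(seg_precompute(image, arch), theta, arch)
}

# Normalize/resize once per image and cache the first convolution's im2col
# patches: they depend only on the input, so the population trainer reuses
# them across thousands of fitness evaluations. Internal.
seg_precompute <- function(image, arch) {
  img <- as_gray(image)
  # per-image min-max normalization: lesion intensities land at a consistent
  # position of [0, 1] regardless of the slice's brightness range, which the
  # population-based trainer exploits
  m <- rescale_range(as_pixel_matrix(img), 0, 1)
  m <- bilinear_resize(m, c(arch$input_size, arch$input_size))
  list(m = m, patches1 = im2col3(list(m)))
}

seg_forward_impl <- function(pre, theta, arch) {
  w <- seg_unpack(theta, arch)

  channels <- list(pre$m)
  n_stage <- length(w$stages)
  for (k in seq_len(n_stage)) {
    st <- w$stages[[k]]
    patches <- if (k == 1) pre$patches1 else im2col3(channels)
    z <- patches %*% st$W
    nr <- nrow(channels[[1]])
    cout <- ncol(z)
    channels <- lapply(seq_len(cout), function(o) {
      relu(matrix(z[, o] + st$b[o], nr, nr) * st$bn_scale[o] + st$bn_shift[o])
    })
    if (k < n_stage) channels <- lapply(channels, avg_pool2)
  }

  feat_size <- nrow(channels[[1]])
  pyr_channels <- list()
  for (i in seq_along(arch$pyramid_scales)) {
    s <- arch$pyramid_scales[i]
    pooled <- lapply(channels, adaptive_avg_pool, s = s)
    pw <- w$pyramid[[i]]
    pooled_mat <- vapply(pooled, as.vector, numeric(s * s))  # (s*s) x last
    red <- pooled_mat %*% pw$W
    for (o in seq_len(ncol(red))) {
      branch <- relu(matrix(red[, o] + pw$b[o], s, s))
      pyr_channels <- c(pyr_channels, list(bilinear_resize(branch, c(feat_size, feat_size))))
    }
  }
  all_ch <- c(channels, pyr_channels)

  logits <- Reduce(`+`, Map(function(ch, wt) ch * wt, all_ch, as.list(w$head_w))) + w$head_b
  prob <- sigmoid(logits)
  bilinear_resize(prob, c(arch$input_size, arch$input_size))
}

#' Segmentation fitness (mean squared error against target masks)
#'
#' The training objective: the per-sample mean over pixels of the squared
#' difference between the ground-truth mask and the predicted probability
#' map, averaged over samples. Zero iff every prediction equals its mask.
#'
#' @param theta Flat parameter vector.
#' @param arch A [seg_architecture()].
#' @param samples Tibble from [generate_phantoms()] (columns `image`, `mask`).
#' @return Finite scalar >= 0.
#' @export
seg_fitness <- function(theta, arch, samples) {
  pres <- lapply(samples$image, seg_precompute, arch = arch)
  tgts <- lapply(samples$mask, resize_mask,
                 out_dim = c(arch$input_size, arch$input_size))
  seg_fitness_impl(theta, arch, pres, tgts)
}

seg_fitness_impl <- function(theta, arch, pres, tgts) {
  errs <- vapply(seq_along(pres), function(i) {
    mean((tgts[[i]] - seg_forward_impl(pres[[i]], theta, arch))^2)
  }, numeric(1))
  mean(errs)
}

# Nearest-neighbor mask resize. Internal.
resize_mask <- function(mask, out_dim) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (nr == out_dim[1] && nc == out_dim[2]) return(mask)
  ridx <- pmin(pmax(round((seq_len(out_dim[1]) - 0.5) * nr / out_dim[1] + 0.5), 1), nr)
  cidx <- pmin(pmax(round((seq_len(out_dim[2]) - 0.5) * nc / out_dim[2] + 0.5), 1), nc)
  mask[ridx, cidx, drop = FALSE]
}

#' Train the segmenter with jellyfish search
#'
#' Optimizes the full flat parameter vector over the box `[-bound, bound]`
#' with [jso_optimize()] against [seg_fitness()] on the supplied training
#' samples. The parameter count is capped so the population search stays
#' effective at desk scale.
#'
#' @param samples Training tibble (columns `image`, `mask`).
#' @param arch A [seg_architecture()].
#' @param config A [jso_config()].
#' @param bound Box half-width for every parameter (default 2).
#' @param param_cap Maximum allowed parameter count (default 5000).
#' @return A `bcdnet_segmenter` list: `theta`, `arch`, `result` (the
#'   `jso_result`), `train_dice`.
#' @export
train_segmenter <- function(samples, arch, config = jso_config(population = 20, iterations = 300),
                            bound = 2, param_cap = 5000) {
  npar <- seg_param_count(arch)
  if (npar > param_cap) {
    abort(sprintf("architecture has %d parameters, above the cap of %d; use a smaller architecture",
                  npar, param_cap), class = "bcdnet_params_error")
  }
  pres <- lapply(samples$image, seg_precompute, arch = arch)
  tgts <- lapply(samples$mask, resize_mask,
                 out_dim = c(arch$input_size, arch$input_size))
  res <- jso_optimize(function(theta) seg_fitness_impl(theta, arch, pres, tgts),
                      dim = npar, lower = -bound, upper = bound, config = config)
  dice <- mean(purrr::map2_dbl(samples$image, samples$mask, function(img, msk) {
    pred <- binarize(seg_forward(img, res$best_position, arch))
    dice_coef(pred, resize_mask(msk, dim(pred)))
  }))
  structure(list(theta = res$best_position, arch = arch, result = res, train_dice = dice),
            class = "bcdnet_segmenter")
}

#' @export
print.bcdnet_segmenter <- function(x, ...) {
  cat(sprintf("<bcdnet_segmenter> %d parameters, best fitness %.5g, train Dice %.3f\n",
              length(x$theta), x$result$best_fitness, x$train_dice))
  invisible(x)
}

#' @export
#' @rdname train_segmenter
#' @param x A `bcdnet_segmenter`.
#' @param ... Unused.
glance.bcdnet_segmenter <- function(x, ...) {
  tibble::tibble(n_params = length(x$theta), best_fitness = x$result$best_fitness,
                 train_dice = x$train_dice, evaluations = x$result$evaluations)
}

#' @export
#' @rdname train_segmenter
tidy.bcdnet_segmenter <- function(x, ...) x$result$history

#' Threshold a probability map into a binary mask
#'
#' @param prob Numeric probability matrix.
#' @param threshold Cut value; pixels with `prob >= threshold` become 1.
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(prob, threshold = 0.5) {
  out <- matrix(0L, nrow(prob), ncol(prob))
  out[prob >= threshold] <- 1L
  out
}

#' Dice overlap coefficient between two binary masks
#' @param a,b Binary matrices of equal shape.
#' @return `2 |a & b| / (|a| + |b|)`; defined as 1 when both masks are empty.
#' @export
dice_coef <- function(a, b) {
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}
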