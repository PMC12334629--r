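#' Specification of the synthetic breast-MRI phantom
#'
#' Defines the statistical model of the synthetic slices every stage of the
#' pipeline is exercised on: a smooth anatomical background (blurred white
#' noise rescaled to `[40, 160]`), one filled elliptical lesion per image with
#' a class-dependent intensity offset and sinusoidal texture, and additive
#' Gaussian (or Rician magnitude) noise applied last. When a benign lesion
#' is configured it sits `20` intensity units above the local background,
#' the malignant lesion a further `class_contrast` units above that, and
#' the two classes use different texture frequencies, so the
#' intensity, texture, shape and histogram feature families all receive
#' class signal. By default benign images are lesion-free (healthy controls,
#' empty masks), mirroring the sick/healthy structure of clinical MRI
#' screening sets; set `benign_lesion = TRUE` to give benign images a
#' low-contrast lesion of their own.
#'
#' @param image_size Side of the square image in pixels (>= 16).
#' @param lesion_axis_range Length-2 numeric in (0, 0.5): min and max ellipse
#'   semi-axis as a fraction of `image_size`.
#' @param background_smoothness Gaussian blur sigma (pixels) of the background
#'   random field.
#' @param noise_sigma Noise standard deviation on the 0-255 intensity scale.
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of the
#'   signal plus a complex Gaussian, the MRI magnitude-noise model).
#' @param class_contrast Intensity offset between the benign and malignant
#'   lesion textures (0-255 scale).
#' @param texture_frequency Length-2 numeric, cycles/pixel of the sinusoidal
#'   lesion texture for (benign, malignant).
#' @param benign_lesion Logical; if `FALSE` benign images are lesion-free
#'   (healthy) and their masks are empty.
#' @param seed Integer seed; equal seeds give bit-identical datasets.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(image_size = 64,
                         lesion_axis_range = c(0.08, 0.20),
                         background_smoothness = 6,
                         noise_sigma = 10,
                         noise_model = c("gaussian", "rician"),
                         class_contrast = 40,
                         texture_frequency = c(0.15, 0.35),
                         benign_lesion = FALSE,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  check_that(is_count(image_size) && image_size >= 16, "image_size", "must be an integer >= 16")
  check_that(is.numeric(lesion_axis_range) && length(lesion_axis_range) == 2 &&
               all(lesion_axis_range > 0) && all(lesion_axis_range < 0.5) &&
               lesion_axis_range[1] <= lesion_axis_range[2],
             "lesion_axis_range", "must be (min, max) within (0, 0.5)")
  check_that(is_num1(background_smoothness) && background_smoothness >= 0,
             "background_smoothness", "must be a nonnegative number")
  check_that(is_num1(noise_sigma) && noise_sigma >= 0, "noise_sigma", "must be >= 0")
  check_that(is_num1(class_contrast) && class_contrast >= 0, "class_contrast", "must be >= 0")
  check_that(is.numeric(texture_frequency) && length(texture_frequency) == 2 &&
               all(texture_frequency > 0) && all(texture_frequency <= 0.5),
             "texture_frequency", "must be two frequencies in (0, 0.5] cycles/pixel")
  check_that(isTRUE(benign_lesion) || isFALSE(benign_lesion), "benign_lesion", "must be TRUE/FALSE")
  check_that(is_count(seed), "seed", "must be an integer")
  structure(list(image_size = as.integer(image_size),
                 lesion_axis_range = as.numeric(lesion_axis_range),
                 background_smoothness = background_smoothness,
                 noise_sigma = noise_sigma,
                 noise_model = noise_model,
                 class_contrast = class_contrast,
                 texture_frequency = as.numeric(texture_frequency),
                 benign_lesion = benign_lesion,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Benign lesions sit this far above the local background; malignant add
# class_contrast on top. Texture amplitude of the in-lesion sinusoid.
.phantom_base_offset <- 20
.phantom_texture_amplitude <- 20

# One lesion geometry + rendered image. Internal.
render_phantom <- function(spec, label) {
  n <- spec$image_size
  bg <- gaussian_blur(matrix(rnorm(n * n), n, n), spec$background_smoothness)
  bg <- rescale_range(bg, 40, 160)

  mask <- matrix(0L, n, n)
  img <- bg
  has_lesion <- (label == 1L) || spec$benign_lesion
  if (has_lesion) {
    ax <- runif(2, spec$lesion_axis_range[1], spec$lesion_axis_range[2]) * n
    a <- max(ax); b <- min(ax)
    alpha <- runif(1, 0, pi)
    margin <- ceiling(a) + 2
    if (2 * margin >= n) margin <- floor((n - 1) / 2)  # very large lesions: center
    cy <- if (n - margin > margin) runif(1, margin, n - margin) else n / 2
    cx <- if (n - margin > margin) runif(1, margin, n - margin) else n / 2
    yy <- matrix(seq_len(n), n, n)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE)
    xr <- (xx - cx) * cos(alpha) + (yy - cy) * sin(alpha)
    yr <- -(xx - cx) * sin(alpha) + (yy - cy) * cos(alpha)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    mask[inside] <- 1L
    freq <- spec$texture_frequency[label + 1L]
    phase <- runif(1, 0, 2 * pi)
    tex_angle <- runif(1, 0, pi)
    tex <- .phantom_texture_amplitude *
      sin(2 * pi * freq * (xx * cos(tex_angle) + yy * sin(tex_angle)) + phase)
    offset <- .phantom_base_offset + label * spec$class_contrast
    img[inside] <- img[inside] + offset + tex[inside]
  }

  if (spec$noise_sigma > 0) {
    if (spec$noise_model == "gaussian") {
      img <- img + matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
    } else {
      n1 <- matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
      n2 <- matrix(rnorm(n * n, 0, spec$noise_sigma), n, n)
      img <- sqrt((img + n1)^2 + n2^2)
    }
  }
  img <- clamp(img, 0, 255)
  list(image = gray_image(img, c(0, 255), "phantom"), mask = mask)
}

#' Generate a balanced synthetic phantom dataset
#'
#' Returns a tibble with one row per sample and list-columns holding the
#' image, the ground-truth lesion mask and the class label (0 = benign,
#' 1 = malignant). The generator is fully seeded: equal specs give
#' bit-identical datasets.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_class Samples per class (>= 1).
#' @return A tibble with columns `id`, `label`, `image` (list of
#'   `gray_image`), `mask` (list of integer matrices).
#' @examples
#' ds <- generate_phantoms(phantom_spec(seed = 7), n_per_class = 2)
#' table(ds$label)
#' @export
generate_phantoms <- function(spec, n_per_class) {
  check_that(inherits(spec, "phantom_spec"), "spec", "must be a phantom_spec")
  check_that(is_count(n_per_class) && n_per_class >= 1, "n_per_class", "must be an integer >= 1")
  labels <- rep(c(0L, 1L), each = n_per_class)
  samples <- with_seed(spec$seed, lapply(labels, function(lb) render_phantom(spec, lb)))
  out <- tibble::tibble(
    id = sprintf("s%04d", seq_along(labels)),
    label = labels,
    image = lapply(samples, `[[`, "image"),
    mask = lapply(samples, `[[`, "mask")
  )
  class(out) <- c("bcdnet_phantoms", class(out))
  out
}

#' Plot a set of phantom samples
#'
#' Renders images (and mask outlines as semi-transparent overlays) with
#' ggplot2, faceted by sample id.
#'
#' @param object A tibble from [generate_phantoms()].
#' @param max_samples Number of samples to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcdnet_phantoms <- function(object, max_samples = 8, ...) {
  plot_phantoms(object, max_samples = max_samples)
}

#' @rdname autoplot.bcdnet_phantoms
#' @param samples A tibble from [generate_phantoms()].
#' @export
plot_phantoms <- function(samples, max_samples = 8) {
  keep <- head(seq_len(nrow(samples)), max_samples)
  df <- purrr::map_dfr(keep, function(i) {
    img <- as_pixel_matrix(samples$image[[i]])
    msk <- samples$mask[[i]]
    tibble::tibble(
      id = paste0(samples$id[i], " (label ", samples$label[i], ")"),
      row = rep(seq_len(nrow(img)), times = ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      intensity = as.vector(img),
      lesion = as.vector(msk) > 0
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$lesion),
                        color = "red", alpha = 0.08, size = 0.1) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~id) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
}
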