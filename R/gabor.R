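#' Parameters of one complex 2-D Gabor filter
#'
#' The kernel at displacement `(x, y)` from the center is
#' `(f^2 / (pi * w * h)) * exp(-(f^2/w^2) x'^2 - (f^2/h^2) y'^2) * exp(i 2 pi f x')`
#' with the rotated frame `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`. With this parametrization the
#' Gaussian envelope scales with the wavelength, so one `(w, h)` pair yields
#' a self-similar bank across frequencies.
#'
#' @param frequency Central frequency f in cycles/pixel (> 0).
#' @param sharpness_major,sharpness_minor Envelope sharpness along the major
#'   and minor axes (> 0).
#' @param orientation Rotation angle theta in radians.
#' @return A `gabor_params` list.
#' @export
gabor_params <- function(frequency, sharpness_major = 1, sharpness_minor = 1,
                         orientation = 0) {
  check_that(is_num1(frequency) && frequency > 0, "frequency", "must be > 0")
  check_that(is_num1(sharpness_major) && sharpness_major > 0, "sharpness_major", "must be > 0")
  check_that(is_num1(sharpness_minor) && sharpness_minor > 0, "sharpness_minor", "must be > 0")
  check_that(is_num1(orientation), "orientation", "must be a number")
  structure(list(frequency = frequency, sharpness_major = sharpness_major,
                 sharpness_minor = sharpness_minor, orientation = orientation),
            class = "gabor_params")
}

#' Evaluate a complex Gabor kernel on an odd-sized grid
#'
#' @param params A [gabor_params()].
#' @param size Odd kernel side in pixels; the filter is centered on the
#'   middle pixel. When `NULL`, the side covers 3 envelope standard
#'   deviations.
#' @return A complex `size x size` matrix.
#' @export
gabor_kernel <- function(params, size = NULL) {
  f <- params$frequency; w <- params$sharpness_major; h <- params$sharpness_minor
  th <- params$orientation
  if (is.null(size)) {
    sigma <- max(w, h) / (sqrt(2) * f)
    size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  }
  if (size %% 2 == 0) abort("gabor kernel size must be odd", class = "bcdnet_validation_error")
  half <- (size - 1) / 2
  x <- matrix(seq(-half, half), size, size, byrow = TRUE)
  y <- matrix(seq(-half, half), size, size)
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  amp <- (f^2 / (pi * w * h)) * exp(-(f^2 / w^2) * xr^2 - (f^2 / h^2) * yr^2)
  amp * exp(1i * 2 * pi * f * xr)
}

#' Gabor magnitude maps over a bank of frequencies and orientations
#'
#' Correlates the image with one complex kernel per (frequency, orientation)
#' pair (reflect padding) and returns the magnitude responses, each the same
#' shape as the input. Map order is fixed: frequencies outer, orientations
#' inner.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param frequencies Frequencies in cycles/pixel.
#' @param orientations Orientations in degrees.
#' @param sharpness_major,sharpness_minor Envelope sharpness (shared).
#' @return Named list of nonnegative magnitude matrices
#'   (`gabor_f{f}_t{deg}`).
#' @export
gabor_bank <- function(image, frequencies = c(0.1, 0.2, 0.3, 0.4),
                       orientations = c(0, 45, 90, 135),
                       sharpness_major = 1, sharpness_minor = 1) {
  m <- if (inherits(image, "gray_image")) as_pixel_matrix(image) else image
  out <- list()
  for (f in frequencies) {
    for (deg in orientations) {
      k <- gabor_kernel(gabor_params(f, sharpness_major, sharpness_minor, deg * pi / 180))
      resp <- xcorr2_reflect(m, k)
      out[[sprintf("gabor_f%g_t%g", f, deg)]] <- Mod(resp)
    }
  }
  out
}
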