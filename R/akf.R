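#' Adaptive Kalman filter configuration
#'
#' Controls the per-scanline scalar Kalman recursion used to denoise images.
#' The state is the underlying true intensity, modeled as a random walk with
#' process variance `q`; the measurement is the observed pixel. The
#' measurement-noise variance is re-estimated at every pixel from the last
#' `window` innovations: the mean squared innovation minus the predicted
#' state variance, clamped from below at `min_meas_variance` because the
#' raw estimate can go negative.
#'
#' @param window Innovation window length (lambda), in pixels (>= 1).
#' @param process_variance Random-walk state noise q (>= 0).
#' @param min_meas_variance Positive lower clamp for the estimated
#'   measurement variance.
#' @param passes `"bidirectional"` (average of a forward and a backward sweep
#'   along each scanline; removes directional lag) or `"single"`.
#' @return An `akf_config` list.
#' @export
akf_config <- function(window = 15, process_variance = 200,
                       min_meas_variance = 1e-6,
                       passes = c("bidirectional", "single")) {
  passes <- match.arg(passes)
  check_that(is_count(window) && window >= 1, "window", "must be an integer >= 1")
  check_that(is_num1(process_variance) && process_variance >= 0,
             "process_variance", "must be >= 0")
  check_that(is_num1(min_meas_variance) && min_meas_variance > 0,
             "min_meas_variance", "must be > 0")
  structure(list(window = as.integer(window), process_variance = process_variance,
                 min_meas_variance = min_meas_variance, passes = passes),
            class = "akf_config")
}

#' Innovation-based measurement-noise variance estimate
#'
#' The adaptive step of the filter: the measurement-noise variance is the
#' mean of the squared recent innovations minus a correction equal to the
#' predicted state variance (the scalar form of h' P h with h = 1), clamped
#' from below so it stays positive.
#'
#' @param buffer Numeric vector of recent innovations (nonempty).
#' @param correction Scalar correction term (predicted state variance).
#' @param min_var Positive lower clamp.
#' @return The estimated measurement variance (scalar, >= `min_var`).
#' @examples
#' estimate_measurement_variance(c(3, 4), 0, 1e-6)  # 12.5
#' @export
estimate_measurement_variance <- function(buffer, correction, min_var) {
  if (length(buffer) == 0) abort("innovation buffer is empty", class = "bcdnet_state_error")
  max(mean(buffer^2) - correction, min_var)
}

# One directional sweep of the scalar adaptive Kalman recursion over every
# row of `m` simultaneously (the recursion is sequential along columns but
# independent across rows, so rows are vectorized). Returns the matrix of
# posterior estimates. reverse = TRUE sweeps right-to-left.
akf_sweep <- function(m, config, reverse = FALSE) {
  if (reverse) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  nr <- nrow(m); nc <- ncol(m)
  q <- config$process_variance
  smin <- config$min_meas_variance
  lam <- config$window
  out <- matrix(0, nr, nc)

  xhat <- m[, 1]                       # state init: first pixel of the line
  P <- rep(max(var(as.vector(m)), smin), nr)  # init variance: global image variance
  out[, 1] <- xhat
  buf <- matrix(NA_real_, nr, lam)     # circular innovation buffer per row
  nbuf <- 0L; pos <- 0L
  for (o in 2:nc) {
    Ppred <- P + q
    nu <- m[, o] - xhat
    pos <- (pos %% lam) + 1L
    buf[, pos] <- nu
    nbuf <- min(nbuf + 1L, lam)
    msq <- if (nbuf < lam) rowMeans(buf[, seq_len(nbuf), drop = FALSE]^2)
           else rowMeans(buf^2)
    svar <- pmax(msq - Ppred, smin)
    K <- Ppred / (Ppred + svar)
    xhat <- xhat + K * nu
    P <- (1 - K) * Ppred
    out[, o] <- xhat
  }
  if (reverse) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  out
}

#' Adaptive Kalman filtering of an image
#'
#' Denoises an image by running the scalar adaptive Kalman recursion along
#' every row: predict (random walk), re-estimate the measurement variance
#' from the recent innovations via [estimate_measurement_variance()], then
#' the standard Kalman update. In bidirectional mode the forward and
#' backward sweeps are averaged.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param config An [akf_config()].
#' @return A `gray_image` of the same shape.
#' @examples
#' img <- gray_image(matrix(100, 8, 8))
#' range(akf_filter(img, akf_config()))  # constant image is a fixed point
#' @export
akf_filter <- function(image, config = akf_config()) {
  img <- as_gray(image)
  check_that(inherits(config, "akf_config"), "config", "must be an akf_config")
  m <- as_pixel_matrix(img)
  fwd <- akf_sweep(m, config, reverse = FALSE)
  res <- if (config$passes == "bidirectional") {
    (fwd + akf_sweep(m, config, reverse = TRUE)) / 2
  } else fwd
  gray_image(res, attr(img, "value_range"), "akf")
}
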