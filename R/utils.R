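#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif sd var fft quantile setNames
#' @importFrom utils head tail
NULL

# Internal validation helper: abort with the offending field name.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) abort(sprintf("invalid `%s`: %s", field, msg), class = "bcdnet_validation_error")
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic stages go through this so a single
# pipeline seed fans out reproducibly.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Fixed per-stage offsets from the single pipeline seed, so each stage is
# independently reproducible. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(phantom = 101L, akf = 202L, segment = 303L, augment = 404L,
               features = 505L, classify = 606L, folds = 707L)
  if (!stage %in% names(offsets)) abort(paste("unknown stage:", stage))
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Construct a grayscale image
#'
#' The universal pixel carrier of the pipeline: a plain numeric matrix with a
#' declared intensity range and a provenance tag naming the stage that
#' produced it. All coordinates are row-major with origin at the top-left.
#'
#' @param pixels Numeric matrix of intensities, all finite, at least 3x3.
#' @param value_range Length-2 numeric `(lo, hi)` declared scale.
#' @param provenance Free-text stage tag.
#' @return An object of class `gray_image` (a matrix with attributes).
#' @export
gray_image <- function(pixels, value_range = c(0, 255), provenance = "unknown") {
  check_that(is.matrix(pixels) && is.numeric(pixels), "pixels", "must be a numeric matrix")
  check_that(all(is.finite(pixels)), "pixels", "all values must be finite")
  check_that(nrow(pixels) >= 3 && ncol(pixels) >= 3, "pixels", "shape must be at least 3x3")
  check_that(is.numeric(value_range) && length(value_range) == 2 && value_range[1] < value_range[2],
             "value_range", "must be (lo, hi) with lo < hi")
  structure(pixels, value_range = as.numeric(value_range),
            provenance = as.character(provenance)[1], class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range declared [%g, %g], observed [%.3g, %.3g], stage: %s\n",
              nrow(x), ncol(x), attr(x, "value_range")[1], attr(x, "value_range")[2],
              min(x), max(x), attr(x, "provenance")))
  invisible(x)
}

as_pixel_matrix <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# Coerce matrices or gray_image objects uniformly.
as_gray <- function(x, value_range = c(0, 255), provenance = "unknown") {
  if (inherits(x, "gray_image")) x else gray_image(x, value_range, provenance)
}
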