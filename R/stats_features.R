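#' Histogram statistics of a texture map
#'
#' Builds a normalized gray-level histogram over `levels` bins and returns
#' the five moments used by the feature bank. Values already inside
#' `[0, levels - 1]` (e.g. 8-bit local-pattern codes) are binned by rounding
#' so integer maps have an exact histogram; other maps are first min-max
#' scaled onto `[0, levels - 1]`. Skewness and kurtosis are normalized by
#' powers of the MEAN (not the standard deviation) — that is the convention
#' of this feature bank, kept deliberately and documented here; both are
#' defined as 0 when the mean is 0.
#'
#' @param map Numeric matrix (a texture map).
#' @param levels Number of gray levels E (default 256).
#' @return Named numeric vector `c(mean, variance, sd, skewness, kurtosis)`.
#' @examples
#' m <- matrix(c(0, 1), 4, 4)
#' statistical_features(m, levels = 2)  # mean .5, var .25, sd .5, skew 0
#' @export
statistical_features <- function(map, levels = 256) {
  check_that(is.numeric(map) && all(is.finite(map)), "map", "must be finite numeric")
  check_that(is_count(levels) && levels >= 2, "levels", "must be an integer >= 2")
  v <- as.vector(map)
  if (min(v) < 0 || max(v) > levels - 1) v <- rescale_range(v, 0, levels - 1)
  bins <- round(v)
  h <- tabulate(bins + 1L, nbins = levels)
  A <- h / sum(h)
  lev <- 0:(levels - 1)
  y1 <- sum(lev * A)
  y2 <- sum((lev - y1)^2 * A)
  y3 <- sqrt(y2)
  if (y1 == 0) {
    y4 <- 0; y5 <- 0
  } else {
    y4 <- y1^(-3) * sum((lev - y1)^3 * A)
    y5 <- y1^(-4) * sum((lev - y1)^4 * A)
  }
  c(mean = y1, variance = y2, sd = y3, skewness = y4, kurtosis = y5)
}

#' All texture maps of one image
#'
#' Computes the three texture families in a fixed order: Gabor magnitude
#' maps (frequencies outer, orientations inner), the local binary pattern
#' map, and the four local vector pattern maps.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param frequencies,orientations Gabor bank layout.
#' @return Named list of matrices.
#' @export
texture_maps <- function(image, frequencies = c(0.1, 0.2, 0.3, 0.4),
                         orientations = c(0, 45, 90, 135)) {
  c(gabor_bank(image, frequencies, orientations),
    list(lbp = lbp_map(image)),
    lvp_maps(image))
}

#' Assemble the feature vector of one sample
#'
#' Concatenates, in a fixed documented order, the five histogram statistics
#' of every texture map (Gabor maps by frequency then orientation, then LBP,
#' then the four LVP directions) and appends the four shape features of the
#' segmentation mask. With the default 16-filter Gabor bank the vector has
#' `5 * (16 + 1 + 4) + 4 = 109` entries. An empty mask yields zero shape
#' features (a lesion-free image has no region to describe).
#'
#' Also returns the stacked multi-channel feature image (original intensity,
#' LBP, four LVP maps, mean Gabor magnitude) consumed by the classifier's
#' convolutional branch.
#'
#' @param maps Named list from [texture_maps()].
#' @param mask Binary segmentation mask.
#' @param image Original (preprocessed) image, for the feature stack.
#' @param levels Histogram levels for [statistical_features()].
#' @return List with `vector` (named numeric) and `stack` (list of matrices).
#' @export
assemble_features <- function(maps, mask, image, levels = 256) {
  stat_names <- c("mean", "variance", "sd", "skewness", "kurtosis")
  vecs <- purrr::imap(maps, function(m, nm) {
    setNames(statistical_features(m, levels), paste0(nm, "_", stat_names))
  })
  shape <- if (sum(mask > 0) == 0) {
    c(compactness = 0, eccentricity = 0, rectangularity = 0, solidity = 0)
  } else {
    shape_features(mask)
  }
  names(shape) <- paste0("shape_", names(shape))
  img <- if (inherits(image, "gray_image")) as_pixel_matrix(image) else image
  gab <- maps[grepl("^gabor_", names(maps))]
  mean_gabor <- Reduce(`+`, gab) / length(gab)
  stack <- c(list(intensity = img, lbp = maps$lbp + 0),
             lapply(maps[grepl("^lvp_", names(maps))], `+`, 0),
             list(mean_gabor = mean_gabor))
  list(vector = c(unlist(unname(vecs)), shape), stack = stack)
}

#' Extract features for every sample of a dataset
#'
#' Runs [texture_maps()] and [assemble_features()] per sample and returns a
#' wide tibble (one row per sample, one column per feature, plus `id`,
#' `label`). Masks are taken from the `mask` column — in the full pipeline
#' these are predicted segmentation masks, not ground truth.
#'
#' @param samples Tibble with columns `id`, `label`, `image`, `mask`.
#' @param frequencies,orientations Gabor bank layout.
#' @param levels Histogram levels.
#' @param keep_stack Keep the multi-channel feature image as a list-column
#'   (needed by the classifier's convolutional branch).
#' @return A tibble of features.
#' @export
extract_features <- function(samples, frequencies = c(0.1, 0.2, 0.3, 0.4),
                             orientations = c(0, 45, 90, 135), levels = 256,
                             keep_stack = FALSE) {
  rows <- purrr::map(seq_len(nrow(samples)), function(i) {
    maps <- texture_maps(samples$image[[i]], frequencies, orientations)
    msk <- samples$mask[[i]]
    if (is.null(msk)) msk <- matrix(0L, 3, 3)
    asm <- assemble_features(maps, msk, samples$image[[i]], levels)
    row <- tibble::as_tibble(as.list(asm$vector))
    row <- dplyr::bind_cols(tibble::tibble(id = samples$id[i], label = samples$label[i]), row)
    if (keep_stack) row$stack <- list(asm$stack)
    row
  })
  dplyr::bind_rows(rows)
}
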