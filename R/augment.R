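#' Augmentation specification
#'
#' Configures the geometric augmentation families: rotation by angles in
#' `[1, 359]` degrees about the image center, random erasing of one square
#' patch, and the three flips (vertical = row reversal, horizontal = column
#' reversal, both = 180-degree rotation). Erasing alters only the image, not
#' the mask (it models occlusion of appearance, not anatomy); geometric
#' operators transform image and mask identically; labels are always
#' preserved.
#'
#' @param rotation_angles Numeric vector of allowed angles in degrees
#'   (each within `[1, 359]`).
#' @param erase_fraction_range Length-2 numeric in (0, 1): min and max square
#'   side as a fraction of the image side.
#' @param erase_fill `"zero"`, `"mean"`, or `"random"`.
#' @param flips Subset of `c("vertical", "horizontal", "both")`.
#' @param copies_per_image Augmented variants per input sample (>= 0).
#' @param seed Integer seed.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(rotation_angles = c(90, 180, 270, 15, 345),
                         erase_fraction_range = c(0.1, 0.3),
                         erase_fill = c("zero", "mean", "random"),
                         flips = c("vertical", "horizontal", "both"),
                         copies_per_image = 3,
                         seed = 1L) {
  erase_fill <- match.arg(erase_fill)
  check_that(is.numeric(rotation_angles) && all(rotation_angles >= 1) &&
               all(rotation_angles <= 359), "rotation_angles", "must lie in [1, 359]")
  check_that(is.numeric(erase_fraction_range) && length(erase_fraction_range) == 2 &&
               all(erase_fraction_range > 0) && all(erase_fraction_range < 1) &&
               erase_fraction_range[1] <= erase_fraction_range[2],
             "erase_fraction_range", "must be (min, max) within (0, 1)")
  check_that(all(flips %in% c("vertical", "horizontal", "both")) && length(flips) >= 1,
             "flips", "must be a subset of vertical/horizontal/both")
  check_that(is_count(copies_per_image) && copies_per_image >= 0,
             "copies_per_image", "must be an integer >= 0")
  check_that(is_count(seed), "seed", "must be an integer")
  structure(list(rotation_angles = rotation_angles,
                 erase_fraction_range = erase_fraction_range,
                 erase_fill = erase_fill, flips = flips,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# Rotate one matrix about its center. Right angles are exact index
# permutations; arbitrary angles use inverse-mapping resampling (bilinear for
# images, nearest for masks), fill 0 outside the frame.
rotate_matrix <- function(m, angle_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  ang <- angle_deg %% 360
  if (ang == 0) return(m)
  if (ang == 90) return(t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
  if (ang == 180) return(m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
  if (ang == 270) return(t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
  nr <- nrow(m); nc <- ncol(m)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- ang * pi / 180
  # inverse map: source coords of each output pixel (rotation by -th)
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  out <- matrix(0, nr, nc)
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= nc & iy >= 1 & iy <= nr
    out[ok] <- m[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & (x0 + 1) <= nc & y0 >= 1 & (y0 + 1) <= nr
    get <- function(r, c_) {
      v <- m[cbind(as.vector(clamp(r, 1, nr)), as.vector(clamp(c_, 1, nc)))]
      ifelse(ok, v, 0)
    }
    val <- get(y0, x0) * (1 - fy) * (1 - fx) + get(y0, x0 + 1) * (1 - fy) * fx +
      get(y0 + 1, x0) * fy * (1 - fx) + get(y0 + 1, x0 + 1) * fy * fx
    out[ok] <- val[ok]
  }
  out
}

#' Rotate an image (and optionally its mask) about the center
#'
#' Right-angle rotations (multiples of 90 degrees) are exact index
#' permutations; other angles use bilinear resampling for the image and
#' nearest-neighbor for the mask, with out-of-frame fill 0. The shape is
#' preserved.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param angle_deg Rotation angle in degrees (counter-clockwise).
#' @param mask Optional binary matrix transformed identically (nearest).
#' @return The rotated image, or a list `(image, mask)` when a mask is given.
#' @export
rotate_image <- function(image, angle_deg, mask = NULL) {
  img <- as_gray(image)
  rot <- rotate_matrix(as_pixel_matrix(img), angle_deg, "bilinear")
  out <- gray_image(rot, attr(img, "value_range"), "rotate")
  if (is.null(mask)) return(out)
  msk <- rotate_matrix(mask, angle_deg, "nearest")
  storage.mode(msk) <- "integer"
  list(image = out, mask = msk)
}

#' Flip an image
#'
#' Exact, lossless reflections: `"vertical"` reverses rows (upside-down),
#' `"horizontal"` reverses columns, `"both"` applies both reversals and
#' equals a 180-degree rotation. Each mode is an involution.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param mode One of `"vertical"`, `"horizontal"`, `"both"`.
#' @return The flipped object, same type as the input.
#' @export
flip_image <- function(image, mode = c("vertical", "horizontal", "both")) {
  mode <- match.arg(mode)
  m <- if (inherits(image, "gray_image")) as_pixel_matrix(image) else image
  out <- switch(mode,
                vertical = m[rev(seq_len(nrow(m))), , drop = FALSE],
                horizontal = m[, rev(seq_len(ncol(m))), drop = FALSE],
                both = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
  if (inherits(image, "gray_image")) gray_image(out, attr(image, "value_range"), "flip") else out
}

#' Erase one random square patch of an image
#'
#' Replaces exactly one axis-aligned square, whose side is a random fraction
#' of the image side drawn from `erase_fraction_range` and which lies fully
#' inside the frame, with the configured fill (zero, the image mean, or
#' uniform noise over the declared value range). All other pixels are
#' unchanged.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param spec An [augment_spec()].
#' @return The erased image (same type as input).
#' @export
random_erase <- function(image, spec) {
  img <- as_gray(image)
  m <- as_pixel_matrix(img)
  n <- min(dim(m))
  frac <- runif(1, spec$erase_fraction_range[1], spec$erase_fraction_range[2])
  s <- max(1L, as.integer(round(frac * n)))
  s <- min(s, nrow(m), ncol(m))
  r0 <- sample.int(nrow(m) - s + 1L, 1)
  c0 <- sample.int(ncol(m) - s + 1L, 1)
  fill <- switch(spec$erase_fill,
                 zero = 0,
                 mean = mean(m),
                 random = {
                   vr <- attr(img, "value_range")
                   matrix(runif(s * s, vr[1], vr[2]), s, s)
                 })
  m[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- fill
  gray_image(m, attr(img, "value_range"), "erase")
}

#' Expand a dataset with augmented copies
#'
#' Each input sample yields itself plus `copies_per_image` augmented
#' variants; for every copy one enabled operator family (rotation, erasing,
#' flipping) is chosen uniformly at random. Masks follow geometric operators
#' and are untouched by erasing; labels are preserved. Fully seeded.
#'
#' @param samples Tibble from [generate_phantoms()] (or the same shape).
#' @param spec An [augment_spec()].
#' @return A tibble of `nrow(samples) * (1 + copies_per_image)` rows with an
#'   added `augmented` column naming the operator (`"none"` for originals).
#' @export
augment_dataset <- function(samples, spec) {
  check_that(inherits(spec, "augment_spec"), "spec", "must be an augment_spec")
  if (spec$copies_per_image == 0) {
    out <- dplyr::mutate(samples, augmented = "none")
    return(out)
  }
  with_seed(spec$seed, {
    rows <- purrr::map(seq_len(nrow(samples)), function(i) {
      base <- samples[i, ]
      base$augmented <- "none"
      copies <- purrr::map(seq_len(spec$copies_per_image), function(k) {
        op <- sample(c("rotate", "erase", "flip"), 1)
        img <- samples$image[[i]]; msk <- samples$mask[[i]]
        if (op == "rotate") {
          ang <- if (length(spec$rotation_angles) == 1) spec$rotation_angles else
            sample(spec$rotation_angles, 1)
          rr <- rotate_image(img, ang, msk)
          img <- rr$image; msk <- rr$mask
          op <- sprintf("rotate_%g", ang)
        } else if (op == "erase") {
          img <- random_erase(img, spec)
        } else {
          mode <- if (length(spec$flips) == 1) spec$flips else sample(spec$flips, 1)
          img <- flip_image(img, mode)
          msk <- flip_image(msk, mode)
          storage.mode(msk) <- "integer"
          op <- paste0("flip_", mode)
        }
        tibble::tibble(id = paste0(samples$id[i], "_a", k), label = samples$label[i],
                       image = list(img), mask = list(msk), augmented = op)
      })
      dplyr::bind_rows(tibble::as_tibble(base), copies)
    })
    dplyr::bind_rows(rows)
  })
}
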