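#' Read a grayscale image from PNG or TIFF
#'
#' RGB(A) inputs are converted to luminance (0.2126 R + 0.7152 G + 0.0722 B);
#' 8-bit files are returned on a declared 0-255 range, 16-bit PNG on 0-65535.
#' JPEG is not supported.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) abort(paste("cannot read image, no such file:", path),
                                class = "bcdnet_io_error")
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           jpg = ,
           jpeg = abort(paste("JPEG input is not supported; convert to PNG or TIFF:", path),
                        class = "bcdnet_io_error"),
           abort(paste("unsupported image format:", path), class = "bcdnet_io_error")),
    error = function(e) {
      if (inherits(e, "bcdnet_io_error")) stop(e)
      abort(paste0("failed to read image '", path, "': ", conditionMessage(e)),
            class = "bcdnet_io_error")
    })
  # readPNG/readTIFF return values in [0,1]; detect bit depth from file for PNG
  bits <- 8L
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 25)
    if (length(hdr) >= 25) bits <- as.integer(hdr[25])
    if (!bits %in% c(1L, 2L, 4L, 8L, 16L)) bits <- 8L
  }
  scale <- 2^max(bits, 8L) - 1
  m <- if (length(dim(arr)) == 3) {
    0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  } else arr
  gray_image(m * scale, c(0, scale), paste0("file:", basename(path)))
}

#' Write a grayscale image to PNG (8- or 16-bit) or TIFF
#'
#' Intensities are mapped from the image's declared value range to the file
#' scale and quantized on write; in-memory pixels always stay floating point.
#'
#' @param image A `gray_image` or numeric matrix.
#' @param path Output path; format from the extension (`.png`, `.tif`).
#' @param bits 8 or 16 (PNG only).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, bits = 8) {
  img <- as_gray(image)
  vr <- attr(img, "value_range")
  norm <- clamp((as_pixel_matrix(img) - vr[1]) / (vr[2] - vr[1]), 0, 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    # quantize to the target depth so a write/read round-trip is exact
    levels <- 2^bits - 1
    png::writePNG(round(norm * levels) / levels, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = as.integer(bits))
  } else {
    abort(paste("unsupported output format:", path), class = "bcdnet_io_error")
  }
  invisible(path)
}

#' Write a phantom dataset to disk (images, masks, manifest)
#'
#' @param samples Tibble from [generate_phantoms()].
#' @param dir Output directory (created if missing).
#' @return Path of the written manifest CSV (columns `filename`,
#'   `mask_filename`, `label`), invisibly.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    fn <- paste0(samples$id[i], ".png")
    mfn <- paste0(samples$id[i], "_mask.png")
    write_gray_image(samples$image[[i]], file.path(dir, fn))
    write_gray_image(gray_image(samples$mask[[i]] + 0, c(0, 1), "mask"), file.path(dir, mfn))
    tibble::tibble(filename = fn, mask_filename = mfn, label = samples$label[i])
  })
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Load a dataset from a manifest CSV
#'
#' @param manifest_path CSV with columns `filename`, `mask_filename`
#'   (optional, may be empty strings), `label`.
#' @return A tibble with columns `id`, `label`, `image`, `mask` (mask `NULL`
#'   entries where no mask file is listed).
#' @export
read_samples <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste("manifest not found:", manifest_path), class = "bcdnet_io_error")
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  check_that(all(c("filename", "label") %in% names(man)), "manifest",
             "must have columns filename and label")
  base <- dirname(manifest_path)
  rows <- purrr::map(seq_len(nrow(man)), function(i) {
    ip <- file.path(base, man$filename[i])
    if (!file.exists(ip)) {
      abort(sprintf("manifest row %d: missing image file '%s'", i, man$filename[i]),
            class = "bcdnet_io_error")
    }
    img <- read_gray_image(ip)
    msk <- NULL
    if (!is.null(man$mask_filename) && !is.na(man$mask_filename[i]) &&
        nzchar(man$mask_filename[i])) {
      mp <- file.path(base, man$mask_filename[i])
      if (!file.exists(mp)) {
        abort(sprintf("manifest row %d: missing mask file '%s'", i, man$mask_filename[i]),
              class = "bcdnet_io_error")
      }
      mm <- as_pixel_matrix(read_gray_image(mp))
      msk <- matrix(as.integer(mm > max(mm) / 2 & mm > 0), nrow(mm), ncol(mm))
    }
    tibble::tibble(id = tools::file_path_sans_ext(man$filename[i]),
                   label = as.integer(man$label[i]),
                   image = list(img), mask = list(msk))
  })
  dplyr::bind_rows(rows)
}
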