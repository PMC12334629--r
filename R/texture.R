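# Neighbor offsets (drow, dcol) starting East, counter-clockwise, for the
# 8-bit local codes. Row axis points down, so "North" is drow = -1.
.nbr8 <- cbind(drow = c(0, -1, -1, -1, 0, 1, 1, 1),
               dcol = c(1, 1, 0, -1, -1, -1, 0, 1))

# Shift a matrix by (drow, dcol), padding with NA. shift(m, 1, 0) moves
# content down, so out[y, x] = m[y - drow, x - dcol].
shift_matrix <- function(m, drow, dcol) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + drow):min(nr, nr + drow)
  cs <- max(1, 1 + dcol):min(nc, nc + dcol)
  out[rs, cs] <- m[rs - drow, cs - dcol, drop = FALSE]
  out
}

# Value of each pixel's neighbor at offset (drow, dcol): nb[y, x] = m[y+drow, x+dcol].
neighbor_at <- function(m, drow, dcol) shift_matrix(m, -drow, -dcol)

#' Local binary pattern map
#'
#' For each interior pixel the 8 neighbors (starting East, counter-clockwise)
#' are compared against the center: bit r is set when
#' `neighbor - center >= 0` (ties count as 1), and the code is
#' `sum(bit_r * 2^r)`. Border pixels get code 0. Codes are invariant to
#' adding a constant to the image.
#'
#' @param image A `gray_image` or numeric matrix.
#' @return An integer matrix of codes in `[0, 255]`, same shape.
#' @export
lbp_map <- function(image) {
  m <- if (inherits(image, "gray_image")) as_pixel_matrix(image) else image
  code <- matrix(0, nrow(m), ncol(m))
  for (r in 0:7) {
    nb <- neighbor_at(m, .nbr8[r + 1, 1], .nbr8[r + 1, 2])
    bit <- (nb - m) >= 0
    bit[is.na(bit)] <- FALSE
    code <- code + bit * 2^r
  }
  interior <- matrix(FALSE, nrow(m), ncol(m))
  interior[2:(nrow(m) - 1), 2:(ncol(m) - 1)] <- TRUE
  code[!interior] <- 0
  storage.mode(code) <- "integer"
  code
}

#' Local vector pattern maps at four directions
#'
#' For each direction `h` in `{0, 45, 90, 135}` degrees, first-order
#' directional derivatives `I'_h(p) = I(p + u_h) - I(p)` are formed (with
#' `u_h` the unit pixel step along `h`), together with the derivative at
#' `h + 45` degrees. Each pixel is encoded by comparing, at each of its 8
#' neighbors k, the transformed value
#' `I'_{h+45}(k) - (I'_{h+45}(p) / I'_h(p)) * I'_h(k)` against 0 (bit = 1
#' when >= 0; the ratio slope is treated as 0 when `I'_h(p) = 0`). This is
#' the comparative-space transform of the first-order local vector pattern
#' with radius 1 and 8 neighbors. Pixels within 2 of the border get code 0.
#'
#' @param image A `gray_image` or numeric matrix.
#' @return Named list of four integer code maps (`lvp_0`, `lvp_45`,
#'   `lvp_90`, `lvp_135`), values in `[0, 255]`.
#' @export
lvp_maps <- function(image) {
  m <- if (inherits(image, "gray_image")) as_pixel_matrix(image) else image
  nr <- nrow(m); nc <- ncol(m)
  # unit steps for 0,45,90,135,180 degrees (x right, y up => drow = -sin)
  steps <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                `135` = c(-1, -1), `180` = c(0, -1))
  deriv <- lapply(steps, function(u) neighbor_at(m, u[1], u[2]) - m)
  dirs <- c(0, 45, 90, 135)
  out <- list()
  for (d in dirs) {
    Ia <- deriv[[as.character(d)]]          # I'_h
    Ib <- deriv[[as.character(d + 45)]]     # I'_{h+45}
    slope <- Ib / Ia
    slope[!is.finite(slope)] <- 0
    code <- matrix(0, nr, nc)
    for (r in 0:7) {
      Ia_k <- neighbor_at(Ia, .nbr8[r + 1, 1], .nbr8[r + 1, 2])
      Ib_k <- neighbor_at(Ib, .nbr8[r + 1, 1], .nbr8[r + 1, 2])
      val <- Ib_k - slope * Ia_k
      bit <- val >= 0
      bit[is.na(bit)] <- FALSE
      code <- code + bit * 2^r
    }
    interior <- matrix(FALSE, nr, nc)
    if (nr > 4 && nc > 4) interior[3:(nr - 2), 3:(nc - 2)] <- TRUE
    code[!interior] <- 0
    storage.mode(code) <- "integer"
    out[[paste0("lvp_", d)]] <- code
  }
  out
}
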