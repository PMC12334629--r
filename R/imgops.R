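# Internal low-level image operations shared by several stages: reflect
# padding, FFT correlation, Gaussian blur, bilinear resampling, pooling and
# the im2col convolution used by the small networks. All of these operate on
# plain numeric matrices (rows = y, cols = x, origin top-left).

pad_reflect <- function(m, top, bottom = top, left = top, right = left) {
  # symmetric (edge-repeating) reflection; indices clamp so pads wider than
  # the image stay valid on tiny inputs
  nr <- nrow(m); nc <- ncol(m)
  ridx <- c(rev(pmin(seq_len(top), nr)), seq_len(nr), nr + 1 - pmin(seq_len(bottom), nr))
  cidx <- c(rev(pmin(seq_len(left), nc)), seq_len(nc), nc + 1 - pmin(seq_len(right), nc))
  m[ridx, cidx, drop = FALSE]
}

# Cross-correlation of `m` with (possibly complex) kernel `k` (odd dims),
# reflect ("symmetric") boundary, output the size of `m`. FFT-based:
# correlation with k equals circular convolution with the index-reversed
# kernel; the padded plane is exactly large enough that no wraparound
# reaches the extracted window.
xcorr2_reflect <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  mp <- pad_reflect(m, top = pr, bottom = pr, left = pc, right = pc)
  nr <- nrow(mp); nc <- ncol(mp)
  kfull <- matrix(0 + 0i, nr, nc)
  kfull[1:kr, 1:kc] <- k[kr:1, kc:1, drop = FALSE]
  res <- fft(fft(mp) * fft(kfull), inverse = TRUE) / (nr * nc)
  res[kr:(kr + nrow(m) - 1), kc:(kc + ncol(m) - 1), drop = FALSE]
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur, symmetric boundary.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  half <- (length(k) - 1) %/% 2
  mp <- pad_reflect(m, top = half, bottom = half, left = half, right = half)
  # blur columns then rows via stats::filter-style matrix products
  kr <- matrix(0, nrow(mp), nrow(mp) - 2 * half)
  for (i in seq_len(ncol(kr))) kr[i:(i + 2 * half), i] <- k
  kc <- matrix(0, ncol(mp), ncol(mp) - 2 * half)
  for (i in seq_len(ncol(kc))) kc[i:(i + 2 * half), i] <- k
  t(kr) %*% mp %*% kc
}

# Bilinear resize to out_dim = c(rows, cols). Pixel centers are mapped with
# the half-pixel convention; constant inputs stay constant. The index/weight
# plan depends only on the shapes, so it is memoized (the segmenter calls
# this thousands of times with the same geometry).
.resize_plans <- new.env(parent = emptyenv())

resize_plan <- function(nr, nc, or, oc) {
  key <- paste(nr, nc, or, oc, sep = "x")
  plan <- .resize_plans[[key]]
  if (is.null(plan)) {
    ys <- clamp(((seq_len(or) - 0.5) * nr / or) - 0.5, 0, nr - 1)
    xs <- clamp(((seq_len(oc) - 0.5) * nc / oc) - 0.5, 0, nc - 1)
    y0 <- pmin(floor(ys), nr - 1); x0 <- pmin(floor(xs), nc - 1)
    y1 <- pmin(y0 + 1, nr - 1);    x1 <- pmin(x0 + 1, nc - 1)
    wy <- matrix(ys - y0, or, oc); wx <- matrix(xs - x0, or, oc, byrow = TRUE)
    plan <- list(y0 = y0 + 1, y1 = y1 + 1, x0 = x0 + 1, x1 = x1 + 1,
                 wy = wy, wx = wx)
    .resize_plans[[key]] <- plan
  }
  plan
}

bilinear_resize <- function(m, out_dim) {
  nr <- nrow(m); nc <- ncol(m)
  or <- out_dim[1]; oc <- out_dim[2]
  if (or == nr && oc == nc) return(m)
  if (nr == 1 && nc == 1) return(matrix(m[1, 1], or, oc))
  p <- resize_plan(nr, nc, or, oc)
  a <- m[p$y0, p$x0, drop = FALSE]; b <- m[p$y0, p$x1, drop = FALSE]
  c_ <- m[p$y1, p$x0, drop = FALSE]; d <- m[p$y1, p$x1, drop = FALSE]
  a * (1 - p$wy) * (1 - p$wx) + b * (1 - p$wy) * p$wx +
    c_ * p$wy * (1 - p$wx) + d * p$wy * p$wx
}

# Adaptive average pooling to s x s bins (floor/ceil bin edges, every input
# pixel covered exactly once when s divides the size).
adaptive_avg_pool <- function(m, s) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, s, s)
  for (i in seq_len(s)) {
    r0 <- floor((i - 1) * nr / s) + 1; r1 <- ceiling(i * nr / s)
    for (j in seq_len(s)) {
      c0 <- floor((j - 1) * nc / s) + 1; c1 <- ceiling(j * nc / s)
      out[i, j] <- mean(m[r0:r1, c0:c1])
    }
  }
  out
}

# Non-overlapping 2x2 average pooling (even dims assumed).
avg_pool2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr %% 2 == 0, nc %% 2 == 0)
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
   m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

# im2col for 3x3 same-size convolution with zero padding: returns an
# (nr*nc) x (9*n_ch) matrix of patches (channels = list of matrices).
im2col3 <- function(channels) {
  nr <- nrow(channels[[1]]); nc <- ncol(channels[[1]])
  n <- nr * nc
  cols <- vector("list", 9L * length(channels))
  idx <- 1L
  for (ch in channels) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- ch
    for (dx in 0:2) for (dy in 0:2) {
      cols[[idx]] <- as.vector(p[(1 + dy):(nr + dy), (1 + dx):(nc + dx)])
      idx <- idx + 1L
    }
  }
  matrix(unlist(cols, use.names = FALSE), nrow = n)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Min-max rescale of a matrix/vector to [lo, hi]; constant input maps to lo.
rescale_range <- function(x, lo, hi) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0 + lo)
  (x - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}
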