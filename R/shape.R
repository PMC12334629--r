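# Largest 4-connected foreground component of a binary matrix. Internal
# iterative flood fill (no recursion, queue of linear indices).
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(mask > 0)
  for (start in fg) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      c_ <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c_ + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] > 0 && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  if (cur == 0L) return(matrix(0L, nr, nc))
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  best <- which.max(sizes)
  out <- matrix(0L, nr, nc)
  out[lab == best] <- 1L
  out
}

# Crack (inter-pixel) perimeter: number of unit edges between a foreground
# pixel and background or the image border. A filled 10x10 square gives 40.
crack_perimeter <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  sum(core & !pad[1:nr, 2:(nc + 1)]) +        # exposed top edges
    sum(core & !pad[3:(nr + 2), 2:(nc + 1)]) + # bottom
    sum(core & !pad[2:(nr + 1), 1:nc]) +       # left
    sum(core & !pad[2:(nr + 1), 3:(nc + 2)])   # right
}

# Major/minor axis lengths of the second-central-moment ellipse of the
# region (regionprops convention: axis = 4 * sqrt(eigenvalue) of the
# coordinate covariance). The +1/12 terms treat each pixel as a unit square
# rather than a point mass, so a filled w x h rectangle has an exact axis
# ratio of w/h and a single pixel is non-degenerate.
moment_axes <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  n <- length(y)
  cyy <- sum((y - mean(y))^2) / n + 1 / 12
  cxx <- sum((x - mean(x))^2) / n + 1 / 12
  cxy <- sum((x - mean(x)) * (y - mean(y))) / n
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  c(major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 0)))
}

# Pixel area of the convex hull: hull of the region's pixel centers, then
# the count of pixel centers inside the hull polygon (half-plane test,
# boundary inclusive) — the "convex image" convention, under which a filled
# convex region is its own hull.
convex_area <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pts <- idx
  hull <- grDevices::chull(pts[, 2], pts[, 1])  # x = col, y = row
  hx <- pts[hull, 2]; hy <- pts[hull, 1]        # chull returns clockwise order
  nh <- length(hull)
  if (nh < 3) return(sum(mask > 0))
  rr <- range(idx[, 1]); cr <- range(idx[, 2])
  cand <- expand.grid(row = rr[1]:rr[2], col = cr[1]:cr[2])
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    cross <- ex * (cand$row - hy[i]) - ey * (cand$col - hx[i])
    # chull order is clockwise in (x, y); points inside have cross <= 0
    inside <- inside & (cross <= 1e-9)
  }
  sum(inside)
}

#' Region shape features from a binary mask
#'
#' Computed on the largest connected component. The formulas follow the
#' field-specific definitions used throughout this pipeline, even where they
#' differ from textbook conventions (documented here so downstream users are
#' not surprised):
#' \itemize{
#'   \item compactness `H1 = P / A`: crack (inter-pixel) perimeter over pixel
#'     area — the plain ratio, not the dimensionless `P^2 / A`;
#'   \item eccentricity `H2 = major / minor`: the axis-length ratio of the
#'     second-central-moment ellipse (1 for a disk or square);
#'   \item rectangularity `H3 = A / H2`: area over eccentricity;
#'   \item solidity `H4 = A / convex_area`, in `(0, 1]`.
#' }
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return A named numeric vector `c(compactness, eccentricity,
#'   rectangularity, solidity)`.
#' @examples
#' sq <- matrix(0L, 16, 16); sq[4:13, 4:13] <- 1L
#' shape_features(sq)  # compactness 0.4, eccentricity 1, rect 100, solidity 1
#' @export
shape_features <- function(mask) {
  check_that(is.matrix(mask), "mask", "must be a matrix")
  if (sum(mask > 0) == 0) abort("no region: mask has no foreground pixels",
                                class = "bcdnet_state_error")
  comp <- largest_component(mask)
  a <- sum(comp)
  p <- crack_perimeter(comp)
  ax <- moment_axes(comp)
  h2 <- unname(ax["major"] / ax["minor"])
  c(compactness = p / a,
    eccentricity = h2,
    rectangularity = a / h2,
    solidity = a / convex_area(comp))
}
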