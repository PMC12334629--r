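# Shared fixtures: tiny deterministic images and datasets built in code.

fixture_phantoms <- local({
  cache <- new.env(parent = emptyenv())
  function(image_size = 32, n_per_class = 4, seed = 1, ...) {
    key <- paste(image_size, n_per_class, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_phantoms(
        phantom_spec(image_size = image_size, seed = seed, ...), n_per_class)
    }
    cache[[key]]
  }
})

# A 3x3 neighborhood with known LBP code 85 under the East-start
# counter-clockwise order: alternating 6/4 ring around a 5.
fixture_lbp85 <- function() {
  m <- matrix(0, 3, 3)
  m[2, 2] <- 5
  m[2, 3] <- 6; m[1, 3] <- 4; m[1, 2] <- 6; m[1, 1] <- 4
  m[2, 1] <- 6; m[3, 1] <- 4; m[3, 2] <- 6; m[3, 3] <- 4
  m
}

# Separable 2-D toy features for classifier sanity checks.
fixture_toy_features <- function(n = 40, gap = 2, seed = 2) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n, -gap), rnorm(n)), cbind(rnorm(n, gap), rnorm(n)))
  tibble::tibble(id = as.character(seq_len(2 * n)), label = rep(0:1, each = n),
                 f1 = X[, 1], f2 = X[, 2])
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  testthat::expect_true(is.matrix(a) && is.matrix(b))
  testthat::expect_equal(dim(a), dim(b))
  testthat::expect_lt(max(abs(a - b)), tol)
}
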