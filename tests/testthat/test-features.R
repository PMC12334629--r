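test_that("gabor kernel matches its closed form at the origin and under rotation", {
  p <- gabor_params(0.2, 1, 1, 0)
  k <- gabor_kernel(p, 15)
  expect_equal(Im(k[8, 8]), 0)
  expect_equal(Re(k[8, 8]), 0.2^2 / pi)
  expect_error(gabor_kernel(p, 14), "odd")
  # isotropic envelope: rotating theta by 90 degrees transposes the kernel
  k90 <- gabor_kernel(gabor_params(0.2, 1, 1, pi / 2), 15)
  expect_lt(max(Mod(k90 - t(k))), 1e-9)
})

test_that("gabor magnitude of a constant image equals |kernel sum| times the constant", {
  # independent direct-convolution oracle on a small image
  p <- gabor_params(0.25, 1, 1, pi / 6)
  bank <- gabor_bank(matrix(3, 9, 9), frequencies = 0.25, orientations = 30)
  expect_equal(length(bank), 1)
  expected <- Mod(sum(gabor_kernel(p))) * 3
  expect_lt(max(abs(bank[[1]] - expected)), 1e-9)
})

test_that("the gabor bank is shaped and oriented as configured", {
  img <- matrix(rnorm(32 * 32), 32, 32)
  bank <- gabor_bank(img)
  expect_equal(length(bank), 16)
  expect_true(all(vapply(bank, function(m) all(m >= 0), logical(1))))
  expect_true(all(vapply(bank, function(m) all(dim(m) == c(32, 32)), logical(1))))
  # stripes aligned with one bank orientation respond most at that orientation
  xx <- matrix(seq_len(48), 48, 48, byrow = TRUE)
  stripes <- sin(2 * pi * 0.2 * xx) * 100  # vertical stripes, variation along x
  resp <- gabor_bank(stripes, frequencies = 0.2, orientations = c(0, 45, 90, 135))
  means <- vapply(resp, mean, numeric(1))
  expect_equal(names(which.max(means)), "gabor_f0.2_t0")
})

test_that("LBP codes follow the East-start counter-clockwise convention", {
  expect_equal(lbp_map(fixture_lbp85())[2, 2], 85L)
  flat <- lbp_map(matrix(7, 5, 5))
  expect_true(all(flat[2:4, 2:4] == 255L))
  expect_true(all(flat[1, ] == 0L))
  # offset invariance
  m <- matrix(runif(49, 0, 255), 7, 7)
  expect_identical(lbp_map(m), lbp_map(m + 17.3))
  expect_true(all(lbp_map(m) >= 0 & lbp_map(m) <= 255))
})

test_that("LVP maps are uniform on constant and linear-ramp images", {
  lv <- lvp_maps(matrix(7, 9, 9))
  expect_equal(length(lv), 4)
  expect_true(all(lv$lvp_0[4:6, 4:6] == 255L))
  ramp <- matrix(rep(1:9, times = 9), 9, 9, byrow = TRUE)
  lvr <- lvp_maps(ramp)
  expect_equal(length(unique(as.vector(lvr$lvp_0[4:6, 4:6]))), 1)
  m <- matrix(runif(81, 0, 255), 9, 9)
  lvm <- lvp_maps(m)
  expect_true(all(vapply(lvm, function(x) all(x >= 0 & x <= 255), logical(1))))
  # offset invariance
  expect_identical(lvp_maps(m), lvp_maps(m + 31))
})

test_that("shape features reproduce hand-computed square, disk and rectangle values", {
  sq <- matrix(0L, 16, 16); sq[4:13, 4:13] <- 1L
  h <- shape_features(sq)
  expect_equal(h[["compactness"]], 0.4)       # crack perimeter 40 / area 100
  expect_equal(h[["eccentricity"]], 1)
  expect_equal(h[["rectangularity"]], 100)
  expect_equal(h[["solidity"]], 1)

  n <- 40; r <- 15
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  disk <- matrix(as.integer((yy - 20.5)^2 + (xx - 20.5)^2 <= r^2), n, n)
  hd <- shape_features(disk)
  expect_gte(hd[["eccentricity"]], 0.98); expect_lte(hd[["eccentricity"]], 1.02)
  expect_gte(hd[["solidity"]], 0.98)

  rect <- matrix(0L, 30, 30); rect[6:10, 6:25] <- 1L  # 5 x 20
  hr <- shape_features(rect)
  expect_lt(abs(hr[["eccentricity"]] - 4) / 4, 0.05)

  expect_error(shape_features(matrix(0L, 5, 5)), "no region")
})

test_that("doubling a region's linear size halves its compactness", {
  sq1 <- matrix(0L, 30, 30); sq1[5:14, 5:14] <- 1L       # 10 x 10
  sq2 <- matrix(0L, 40, 40); sq2[5:24, 5:24] <- 1L       # 20 x 20
  expect_equal(shape_features(sq2)[["compactness"]],
               shape_features(sq1)[["compactness"]] / 2)
})

test_that("only the largest connected component is measured", {
  m <- matrix(0L, 20, 20)
  m[3:10, 3:10] <- 1L   # 64 px
  m[15:16, 15:16] <- 1L # 4 px satellite
  h <- shape_features(m)
  expect_equal(h[["rectangularity"]], 64)  # area of the big square, H2 = 1
})

test_that("histogram statistics match the stated formulas and a brute-force oracle", {
  y <- statistical_features(matrix(c(0, 1), 4, 4), levels = 2)
  expect_equal(unname(y), c(0.5, 0.25, 0.5, 0, 1))
  yc <- statistical_features(matrix(37, 5, 5))
  expect_equal(unname(yc), c(37, 0, 0, 0, 0))
  set.seed(8)
  m <- matrix(runif(400, 0, 255), 20, 20)
  got <- statistical_features(m, 256)
  # independent oracle: explicit loop over all 256 bins
  bins <- round(as.vector(m)); E <- 256
  A <- vapply(0:(E - 1), function(v) sum(bins == v), numeric(1)) / length(bins)
  mu <- 0; for (v in 0:(E - 1)) mu <- mu + v * A[v + 1]
  va <- 0; sk <- 0; ku <- 0
  for (v in 0:(E - 1)) {
    va <- va + (v - mu)^2 * A[v + 1]
    sk <- sk + (v - mu)^3 * A[v + 1]
    ku <- ku + (v - mu)^4 * A[v + 1]
  }
  expect_lt(abs(got[["mean"]] - mu), 1e-9)
  expect_lt(abs(got[["variance"]] - va), 1e-9)
  expect_lt(abs(got[["sd"]] - sqrt(va)), 1e-9)
  expect_lt(abs(got[["skewness"]] - sk / mu^3), 1e-9)
  expect_lt(abs(got[["kurtosis"]] - ku / mu^4), 1e-9)
  expect_lt(abs(got[["sd"]]^2 - got[["variance"]]), 1e-9)
})

test_that("assembled vectors have the documented length, order and stability", {
  ds <- fixture_phantoms(image_size = 32, n_per_class = 1, seed = 2)
  maps <- texture_maps(ds$image[[2]])
  asm <- assemble_features(maps, ds$mask[[2]], ds$image[[2]])
  expect_length(asm$vector, 5 * (16 + 1 + 4) + 4)
  expect_false(any(is.na(asm$vector)))
  nms <- names(asm$vector)
  expect_equal(nms[1], "gabor_f0.1_t0_mean")
  expect_equal(nms[81], "lbp_mean")
  expect_equal(nms[86], "lvp_0_mean")
  expect_equal(tail(nms, 4),
               c("shape_compactness", "shape_eccentricity",
                 "shape_rectangularity", "shape_solidity"))
  # repeated calls byte-identical
  asm2 <- assemble_features(texture_maps(ds$image[[2]]), ds$mask[[2]], ds$image[[2]])
  expect_identical(asm$vector, asm2$vector)
  # feature-image stack: intensity + lbp + 4 lvp + mean gabor
  expect_length(asm$stack, 7)
})

test_that("at least one feature separates the phantom classes strongly", {
  ds <- fixture_phantoms(image_size = 32, n_per_class = 25, seed = 12)
  ft <- extract_features(ds)
  vals <- as.matrix(ft[, setdiff(names(ft), c("id", "label"))])
  d <- apply(vals, 2, function(v) {
    g0 <- v[ft$label == 0]; g1 <- v[ft$label == 1]
    pooled <- sqrt((var(g0) + var(g1)) / 2)
    if (pooled < 1e-12) 0 else abs(mean(g1) - mean(g0)) / pooled
  })
  expect_gte(max(d), 0.8)
})
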