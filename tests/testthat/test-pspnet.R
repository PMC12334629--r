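test_that("parameter counting and unpacking are consistent", {
  arch <- seg_architecture(encoder_channels = c(8, 16), pyramid_scales = c(1, 2, 3, 6),
                           reduction_channels = 4, input_size = 64)
  # concatenated channels before the head: encoder tail + scales * reduction
  expect_equal(16 + 4 * 4, 32)
  expect_equal(seg_param_count(arch),
               (9 * 1 * 8 + 3 * 8) + (9 * 8 * 16 + 3 * 16) +
                 4 * (16 * 4 + 4) + 32 + 1)
  w <- bcdnet:::seg_unpack(seq_len(seg_param_count(arch)), arch)
  expect_length(w$stages, 2)
  expect_equal(dim(w$stages[[2]]$W), c(72, 16))
  expect_length(w$head_w, 32)
  expect_error(seg_forward(matrix(0.5, 64, 64), rep(0, 10), arch), "expected")
})

test_that("architecture validation rejects impossible layouts", {
  expect_error(seg_architecture(pyramid_scales = c(2, 1)), "pyramid_scales")
  expect_error(seg_architecture(encoder_channels = c(4, 4, 4), input_size = 30),
               "input_size")
  expect_error(seg_architecture(pyramid_scales = c(1, 64), input_size = 64),
               "pyramid_scales")
})

test_that("the zero-parameter network outputs exactly one half everywhere", {
  arch <- seg_architecture(preset = "tiny")
  img <- gray_image(matrix(runif(32 * 32, 0, 255), 32, 32))
  out <- seg_forward(img, rep(0, seg_param_count(arch)), arch)
  expect_equal(dim(out), c(32, 32))
  expect_true(all(out == 0.5))
})

test_that("forward is deterministic and outputs probabilities in (0, 1)", {
  arch <- seg_architecture(preset = "tiny")
  set.seed(4)
  theta <- runif(seg_param_count(arch), -2, 2)
  img <- fixture_phantoms(image_size = 32, n_per_class = 1, seed = 5)$image[[2]]
  o1 <- seg_forward(img, theta, arch)
  o2 <- seg_forward(img, theta, arch)
  expect_identical(o1, o2)
  expect_true(all(o1 > 0 & o1 < 1))
})

test_that("adaptive pooling of a constant map returns the constant", {
  expect_equal(bcdnet:::adaptive_avg_pool(matrix(7, 4, 4), 2), matrix(7, 2, 2))
  # uneven bins cover every pixel
  m <- matrix(1:25, 5, 5)
  expect_equal(bcdnet:::adaptive_avg_pool(m, 1)[1, 1], mean(m))
})

test_that("fitness is the mean per-pixel squared error with zero at perfection", {
  arch <- seg_architecture(preset = "tiny")
  ds <- fixture_phantoms(image_size = 32, n_per_class = 2, seed = 5)
  # toy two-pixel arithmetic
  expect_equal(mean((c(1, 0) - c(0, 0))^2), 0.5)
  # constant-0.5 prediction on any mask gives exactly 0.25
  f0 <- seg_fitness(rep(0, seg_param_count(arch)), arch, ds)
  expect_equal(f0, 0.25)
  expect_gte(f0, 0)
})

test_that("binarize applies the >= threshold convention", {
  m <- matrix(0.5, 3, 3)
  expect_true(all(binarize(m, 0.5) == 1L))
  expect_true(all(binarize(m, 1.1) == 0L))
  gt <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(binarize(gt, 0.5), matrix(as.integer(gt), 2, 2))
})

test_that("dice coefficient handles overlap, disjoint and empty masks", {
  a <- matrix(c(1, 1, 0, 0), 2, 2); b <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice_coef(a, b), 0.5)
  expect_equal(dice_coef(a, a), 1)
  expect_equal(dice_coef(a, 1 - a), 0)
  expect_equal(dice_coef(a * 0, a * 0), 1)
})

test_that("the parameter cap refuses oversized architectures", {
  arch <- seg_architecture(encoder_channels = c(32, 64), pyramid_scales = c(1, 2, 3, 6),
                           reduction_channels = 16, input_size = 64)
  ds <- fixture_phantoms(image_size = 32, n_per_class = 1, seed = 1)
  expect_error(train_segmenter(ds, arch, jso_config(population = 2, iterations = 1)),
               "smaller architecture")
})

test_that("a short training run returns the best evaluated parameters", {
  arch <- seg_architecture(preset = "tiny")
  ds <- fixture_phantoms(image_size = 32, n_per_class = 2, seed = 5)
  mal <- ds[ds$label == 1, ]
  seg <- train_segmenter(mal, arch, jso_config(population = 5, iterations = 2, seed = 2))
  expect_length(seg$theta, seg_param_count(arch))
  expect_equal(seg$result$best_fitness, seg_fitness(seg$theta, arch, mal))
  # best is no worse than the constant-0.5 network
  expect_lte(seg$result$best_fitness, seg_fitness(rep(0, seg_param_count(arch)), arch, mal))
  expect_s3_class(tidy(seg), "tbl_df")
})
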