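test_that("softmax is stable, normalized and uniform at equal logits", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  big <- softmax(c(1000, 0))
  expect_true(all(is.finite(big)))
  expect_gt(big[1], 1 - 1e-12)
  set.seed(3)
  for (i in 1:20) {
    t <- softmax(rnorm(sample(2:6, 1), sd = 5))
    expect_lt(abs(sum(t) - 1), 1e-12)
  }
})

test_that("the error-similarity loss vanishes exactly for confident-correct samples", {
  expect_equal(ces_loss(c(1, 0), 1), 0)
  expect_equal(ces_loss(c(0.6, 0.4), 1), 0)  # correct but not one-hot: weight 0
  expect_equal(ces_loss(c(0.7, 0.3), 2), -0.4 * log(0.3))
  expect_true(all(ces_gradient(c(1, 0), 1) == 0))
  expect_true(all(ces_gradient(c(0.6, 0.4), 1) == 0))
})

test_that("for fixed true class the loss increases with the probability gap", {
  # harder samples (larger t_max - t_eps) weigh more at the same t_eps
  teps <- 0.2
  gaps <- seq(0.05, 0.6, by = 0.05)
  losses <- vapply(gaps, function(g) -(g) * log(teps), numeric(1))
  expect_true(all(diff(losses) > 0))
  expect_equal(ces_loss(c(teps, teps + 0.3, 1 - 2 * teps - 0.3), 1), -0.3 * log(teps))
})

test_that("both printed gradient forms agree and match finite differences", {
  set.seed(11)
  for (k in c(2, 3, 5)) {
    for (rep in 1:34) {
      a <- rnorm(k, sd = 2)
      t <- softmax(a)
      eps <- sample.int(k, 1)
      g <- ces_gradient(t, eps)
      w <- max(t) - t[eps]  # frozen weight
      h <- 1e-6
      num <- vapply(seq_len(k), function(u) {
        ap <- a; am <- a
        ap[u] <- a[u] + h; am[u] <- a[u] - h
        (-w * log(softmax(ap)[eps]) + w * log(softmax(am)[eps])) / (2 * h)
      }, numeric(1))
      expect_lt(max(abs(g - num)), 1e-5)
    }
  }
  # the worked two-class example
  expect_equal(ces_gradient(c(0.7, 0.3), 2), 0.4 * (c(0.7, 0.3) - c(0, 1)))
})

test_that("the CAViaR update blends lags by error-similarity ratios", {
  cfg <- classifier_config(hidden = 2, learning_rate = 0.1, phi0 = 0, seed = 1)
  G <- matrix(1, 2, 3)
  st <- list(config = cfg, output_weights = G, lag_weights = NULL,
             lag_gradient = NULL, errors = c(NA_real_, NA_real_))
  grad <- matrix(0.5, 2, 3)
  # no history: one plain gradient step
  st1 <- caviar_update(st, grad, error = 1)
  expect_equal(st1$output_weights, G - 0.1 * grad)
  expect_equal(st1$errors, c(1, NA_real_))
  # second call still degenerate (only one recorded error)
  st2 <- caviar_update(st1, grad, error = 1)
  expect_equal(st2$output_weights, st1$output_weights - 0.1 * grad)
  # equal errors: phi ratios normalize to one half each
  st3 <- caviar_update(st2, grad, error = 1)
  expected <- 0.5 * st2$output_weights + 0.5 * st1$output_weights -
    0.1 * (0.5 * grad + 0.5 * grad)
  expect_equal(st3$output_weights, expected)
  # identical lagged weights and gradients reduce to the plain step
  stx <- st2
  stx$lag_weights <- st2$output_weights
  stx$lag_gradient <- grad
  stx$errors <- c(2, 0.5)
  st4 <- caviar_update(stx, grad, error = 0.7)
  expect_equal(st4$output_weights, st2$output_weights - 0.1 * grad)
})

test_that("zero lagged errors give the clamped maximal ratio instead of NaN", {
  cfg <- classifier_config(hidden = 2, learning_rate = 0.1, phi_max = 10, seed = 1)
  G1 <- matrix(1, 2, 3); G2 <- matrix(-1, 2, 3)
  F1 <- matrix(0.2, 2, 3); F2 <- matrix(-0.2, 2, 3)
  st <- list(config = cfg, output_weights = G1, lag_weights = G2,
             lag_gradient = F2, errors = c(0, 4))
  out <- caviar_update(st, F1, error = 1)
  # phi1 = phi_max = 10, phi2 = 0.25; normalized 40/41 and 1/41
  p1 <- 10 / 10.25; p2 <- 0.25 / 10.25
  expect_equal(out$output_weights,
               p1 * G1 + p2 * G2 - 0.1 * (p1 * F1 + p2 * F2))
})

test_that("training separates a linearly separable toy and the loss descends", {
  ft <- fixture_toy_features()
  accs <- vapply(1:5, function(s) {
    m <- train_classifier(ft, classifier_config(hidden = 8, epochs = 60,
                                                learning_rate = 2, batch_size = 4,
                                                seed = s))
    expect_lte(tail(m$loss_history, 1), m$loss_history[1])
    mean(predict(m, ft)$.pred_label == ft$label)
  }, numeric(1))
  # the self-weighted loss drives zero-margin separators; boundary jitter
  # keeps a few samples at probability ~0.5, so the plateau sits just
  # below 1 (see the methods vignette)
  expect_gte(median(accs), 0.9)
})

test_that("the adaptive recursion is non-destructive relative to plain SGD", {
  ft <- fixture_toy_features()
  cfg <- function(adaptive) classifier_config(hidden = 8, epochs = 60,
                                              learning_rate = 2, batch_size = 4,
                                              adaptive = adaptive, seed = 3)
  acc <- vapply(c(TRUE, FALSE), function(a) {
    m <- train_classifier(ft, cfg(a))
    mean(predict(m, ft)$.pred_label == ft$label)
  }, numeric(1))
  expect_gte(acc[1], 0.85)
  expect_gte(acc[2], 0.85)
})

test_that("the convolutional branch trains on stacked feature images", {
  ds <- fixture_phantoms(image_size = 32, n_per_class = 6, seed = 21)
  ft <- extract_features(ds, keep_stack = TRUE)
  cfg <- classifier_config(use_dense = TRUE, use_conv = TRUE, hidden = 4,
                           conv_channels = c(2, 3), epochs = 8,
                           learning_rate = 0.5, batch_size = 4, seed = 2)
  m <- train_classifier(ft, cfg)
  pred <- predict(m, ft)
  expect_true(all(abs(pred$.prob_0 + pred$.prob_1 - 1) < 1e-9))
  expect_gte(mean(pred$.pred_label == ft$label), 0.5)
  expect_error(train_classifier(dplyr::select(ft, -stack), cfg), "keep_stack")
})

test_that("prediction breaks ties toward the lower class index", {
  ft <- fixture_toy_features(n = 10)
  m <- train_classifier(ft, classifier_config(hidden = 2, epochs = 1, seed = 1))
  # force equal logits by zeroing the output weights
  m$output_weights[] <- 0
  pred <- predict(m, ft)
  expect_true(all(pred$.pred_label == 0L))
  expect_true(all(pred$.prob_0 == 0.5))
})

test_that("training is seed-deterministic", {
  ft <- fixture_toy_features(n = 15)
  m1 <- train_classifier(ft, classifier_config(hidden = 4, epochs = 5, seed = 9))
  m2 <- train_classifier(ft, classifier_config(hidden = 4, epochs = 5, seed = 9))
  expect_identical(m1$output_weights, m2$output_weights)
  expect_identical(m1$loss_history, m2$loss_history)
})
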