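test_that("logistic map steps and chaotic initialization stay in bounds", {
  expect_equal(logistic_step(0.2), 0.64)
  expect_equal(logistic_step(0.5), 1)
  set.seed(1)
  pos <- logistic_init(10, jso_config(population = 30), lower = -5, upper = 5)
  expect_equal(dim(pos), c(30, 10))
  expect_true(all(pos >= -5 & pos <= 5))
})

test_that("time control decays to zero at the final iteration", {
  expect_equal(time_control(100, 100, r = 0.123), 0)
  expect_equal(time_control(50, 100, r = 1), 0.5)
  set.seed(2)
  draws <- replicate(10000, time_control(1, 100))
  expect_true(all(draws >= 0 & draws <= 0.99))
  # E|2r-1| = 1/2, so the mean is 0.99 * 0.5 = 0.495
  expect_lt(abs(mean(draws) - 0.495), 3 * sd(draws) / sqrt(10000))
})

test_that("the three move operators obey their degenerate identities", {
  cfg <- jso_config()
  p <- c(1, 2); best <- c(0, 0); mean_pos <- c(0.5, 0.5)
  expect_equal(ocean_current_move(p, best, mean_pos, cfg, -5, 5, r1 = 0.3, r2 = 0),
               p)
  expect_equal(ocean_current_move(p, c(3, 3), rep(0, 2), cfg, -5, 5, r1 = 0.7, r2 = 1),
               p + c(3, 3))
  expect_equal(ocean_current_move(c(0, 0), c(0, 0), c(0, 0), cfg, -5, 5, r1 = 1, r2 = 1),
               c(0, 0))
  expect_equal(passive_move(p, cfg, -5, 5, r = 0), p)
  expect_equal(passive_move(5, jso_config(chi = 0.1), 0, 10, r = 1), 6)
  cfg0 <- jso_config(chi = 0)
  expect_equal(passive_move(p, cfg0, -5, 5, r = 0.9), p)
  # active motion: worse jellyfish moves toward the better one
  to_q <- active_move(c(0, 0), c(1, 0), fitness_pos = 2, fitness_other = 1,
                      -5, 5, r = 0.5)
  expect_equal(to_q, c(0.5, 0))
  expect_equal(active_move(p, p, 1, 2, -5, 5, r = 0.8), p)
  away <- active_move(c(1, 1), c(2, 2), fitness_pos = 1, fitness_other = 2,
                      -5, 5, r = 1)
  expect_equal(away, c(0, 0))
})

test_that("optimization is deterministic, feasible and monotone in the incumbent", {
  sphere <- function(x) sum(x^2)
  cfg <- jso_config(population = 10, iterations = 40, seed = 5)
  trace_pos <- new.env(); trace_pos$all <- list()
  wrapped <- function(x) { trace_pos$all[[length(trace_pos$all) + 1L]] <- x; sphere(x) }
  r1 <- jso_optimize(wrapped, 3, -5, 5, cfg)
  r2 <- jso_optimize(sphere, 3, -5, 5, cfg)
  expect_equal(r1$history, r2$history)
  expect_equal(r1$best_position, r2$best_position)
  # every evaluated position within bounds
  expect_true(all(vapply(trace_pos$all, function(p) all(p >= -5 & p <= 5), logical(1))))
  # incumbent non-increasing; final best equals min over all evaluations
  expect_true(all(diff(r1$history$best_fitness) <= 0))
  expect_equal(r1$best_fitness, min(vapply(trace_pos$all, sphere, numeric(1))))
})

test_that("a single iteration still reports the best of everything evaluated", {
  r <- jso_optimize(function(x) sum(x^2), 2, -5, 5,
                    jso_config(population = 2, iterations = 1, seed = 3))
  expect_equal(nrow(r$history), 1)
  expect_equal(r$best_fitness, r$history$best_fitness[1])
  expect_equal(r$best_fitness, sum(r$best_position^2))
})

test_that("non-finite fitness aborts with the offending vector", {
  expect_error(
    jso_optimize(function(x) if (x[1] > 0) NaN else sum(x^2), 2, -5, 5,
                 jso_config(population = 5, iterations = 5, seed = 1)),
    "non-finite")
})

test_that("sphere-5D converges and beats random search at equal budget", {
  best <- vapply(1:10, function(s)
    jso_optimize(function(x) sum(x^2), 5, -5, 5, jso_config(seed = s))$best_fitness,
    numeric(1))
  expect_gte(sum(best < 1e-2), 9)
  budget <- 30 + 30 * 500
  rs <- vapply(1:10, function(s) {
    set.seed(s + 1000)
    min(colSums(matrix(runif(5 * budget, -5, 5), nrow = 5)^2))
  }, numeric(1))
  expect_gte(sum(best < rs), 9)
})

test_that("the 1-D quadratic is located to within 0.1", {
  r <- jso_optimize(function(x) (x - 3)^2, 1, 0, 5,
                    jso_config(iterations = 200, seed = 1))
  expect_lt(abs(r$best_position - 3), 0.1)
})

test_that("tidy and glance summarize a run", {
  r <- jso_optimize(function(x) sum(x^2), 2, -5, 5,
                    jso_config(population = 5, iterations = 10, seed = 1))
  expect_equal(nrow(tidy(r)), 10)
  expect_named(glance(r), c("best_fitness", "evaluations", "iterations", "dim"))
})
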