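#' Jellyfish search optimizer configuration
#'
#' Tunables of the jellyfish search metaheuristic: a population of candidate
#' vectors alternates between ocean-current moves toward the incumbent best
#' and passive/active swarm moves, scheduled by a decaying stochastic
#' time-control function. Minimization convention throughout.
#'
#' @param population Number of jellyfish c (>= 2).
#' @param iterations Iteration budget N (>= 1).
#' @param beta Logistic-map parameter for chaotic initialization (fixed at 4
#'   in the canonical method).
#' @param eta Distribution coefficient of the ocean current (default 3).
#' @param chi Passive-motion coefficient (default 0.1).
#' @param x0 Time-control threshold separating current-following from swarm
#'   moves (default 0.5).
#' @param seed Integer seed; identical configs give identical runs.
#' @return A `jso_config` list.
#' @export
jso_config <- function(population = 30, iterations = 500, beta = 4,
                       eta = 3, chi = 0.1, x0 = 0.5, seed = 1L) {
  check_that(is_count(population) && population >= 2, "population", "must be an integer >= 2")
  check_that(is_count(iterations) && iterations >= 1, "iterations", "must be an integer >= 1")
  check_that(is_num1(beta) && beta > 0, "beta", "must be > 0")
  check_that(is_num1(eta), "eta", "must be a number")
  check_that(is_num1(chi) && chi >= 0, "chi", "must be >= 0")
  check_that(is_num1(x0) && x0 >= 0 && x0 <= 1, "x0", "must be in [0, 1]")
  check_that(is_count(seed), "seed", "must be an integer")
  structure(list(population = as.integer(population), iterations = as.integer(iterations),
                 beta = beta, eta = eta, chi = chi, x0 = x0, seed = as.integer(seed)),
            class = "jso_config")
}

#' Chaotic (logistic-map) population initialization
#'
#' Each dimension of each jellyfish is produced by iterating the logistic map
#' `x <- beta * x * (1 - x)` from a seeded start in (0,1) excluding the
#' degenerate points `{0, 0.25, 0.5, 0.75, 1}` (those collapse the map), then
#' mapped affinely onto the box `[lower, upper]`.
#'
#' @param dim Search-space dimension.
#' @param config A [jso_config()].
#' @param lower,upper Numeric bounds, recycled to `dim`.
#' @return A `population x dim` matrix of in-bound positions.
#' @export
logistic_init <- function(dim, config, lower, upper) {
  check_that(is_count(dim) && dim >= 1, "dim", "must be an integer >= 1")
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  c_ <- config$population
  x <- runif(dim)
  bad <- function(v) abs(v) < 1e-9 | abs(v - 0.25) < 1e-9 | abs(v - 0.5) < 1e-9 |
    abs(v - 0.75) < 1e-9 | abs(v - 1) < 1e-9
  while (any(bad(x))) x[bad(x)] <- runif(sum(bad(x)))
  pos <- matrix(0, c_, dim)
  for (s in seq_len(c_)) {
    x <- config$beta * x * (1 - x)
    pos[s, ] <- x
  }
  sweep(sweep(pos, 2, upper - lower, `*`), 2, lower, `+`)
}

#' One step of the logistic chaotic map
#' @param x Value in [0, 1].
#' @param beta Map parameter (default 4).
#' @return `beta * x * (1 - x)`.
#' @export
logistic_step <- function(x, beta = 4) beta * x * (1 - x)

#' Time-control function
#'
#' `|(1 - iter/total) * (2 r - 1)|` with `r ~ U(0,1)`: a random value in
#' `[0, 1)` whose envelope decays linearly to zero at the final iteration,
#' scheduling the switch from current-following to swarm moves.
#'
#' @param iteration Current iteration (1..total).
#' @param total Total iterations.
#' @param r Optional uniform draw (drawn internally when `NULL`).
#' @return Scalar in `[0, 1)`.
#' @export
time_control <- function(iteration, total, r = NULL) {
  if (is.null(r)) r <- runif(1)
  abs((1 - iteration / total) * (2 * r - 1))
}

#' Ocean-current move
#'
#' Drifts a jellyfish toward the incumbent best: the current direction is
#' `best - eta * r1 * mean_position` and the step is a second uniform draw
#' times that direction, clipped to the box.
#'
#' @param position,best,mean_position Numeric vectors of equal length.
#' @param config A [jso_config()].
#' @param lower,upper Bounds.
#' @param r1,r2 Optional uniform draws (drawn internally when `NULL`).
#' @return The new in-bound position.
#' @export
ocean_current_move <- function(position, best, mean_position, config, lower, upper,
                               r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- runif(1)
  if (is.null(r2)) r2 <- runif(1)
  trend <- best - config$eta * r1 * mean_position
  clamp(position + r2 * trend, lower, upper)
}

#' Passive swarm move
#'
#' A small random exploration around the jellyfish's own position scaled by
#' the box extent: `position + chi * r * (upper - lower)`, clipped.
#'
#' @inheritParams ocean_current_move
#' @param r Optional uniform draw.
#' @return The new in-bound position.
#' @export
passive_move <- function(position, config, lower, upper, r = NULL) {
  if (is.null(r)) r <- runif(1)
  clamp(position + config$chi * r * (upper - lower), lower, upper)
}

#' Active swarm move
#'
#' Moves toward a randomly chosen better neighbor and away from a worse one:
#' the direction is `other - position` when the neighbor's fitness is no
#' worse (minimization), else `position - other`; the step is a uniform draw
#' times the direction, clipped.
#'
#' @param position,other Numeric vectors.
#' @param fitness_pos,fitness_other Their fitness values.
#' @param lower,upper Bounds.
#' @param r Optional uniform draw.
#' @return The new in-bound position.
#' @export
active_move <- function(position, other, fitness_pos, fitness_other, lower, upper, r = NULL) {
  if (is.null(r)) r <- runif(1)
  dir <- if (fitness_pos >= fitness_other) other - position else position - other
  clamp(position + r * dir, lower, upper)
}

#' Minimize a function with jellyfish search
#'
#' Runs the full metaheuristic: chaotic initialization, then per iteration
#' and per jellyfish a time-control draw decides between the ocean-current
#' move (`xi >= x0`) and a swarm move (passive when a fresh uniform draw
#' exceeds `1 - iter/N`, active otherwise). Positions always move; the
#' incumbent best is tracked separately so the best-so-far fitness is
#' non-increasing and equals the minimum over every evaluation.
#'
#' @param fitness Function mapping a numeric vector to a finite scalar.
#' @param dim Search-space dimension.
#' @param lower,upper Bounds (recycled to `dim`).
#' @param config A [jso_config()].
#' @return A `jso_result` list: `best_position`, `best_fitness`, `history`
#'   (tibble of iteration and best fitness), `evaluations`.
#' @examples
#' res <- jso_optimize(function(x) sum(x^2), dim = 2, lower = -5, upper = 5,
#'                     config = jso_config(population = 10, iterations = 50, seed = 42))
#' res$best_fitness
#' @export
jso_optimize <- function(fitness, dim, lower, upper, config = jso_config()) {
  check_that(is.function(fitness), "fitness", "must be a function")
  lower <- rep_len(as.numeric(lower), dim); upper <- rep_len(as.numeric(upper), dim)
  check_that(all(lower < upper), "bounds", "lower must be < upper elementwise")
  c_ <- config$population; N <- config$iterations

  eval_fit <- function(x) {
    f <- fitness(x)
    if (!is_num1(f)) {
      abort("fitness returned a non-finite value", class = "bcdnet_fitness_error",
            body = paste("at position:", paste(signif(x, 4), collapse = ", ")))
    }
    f
  }

  with_seed(config$seed, {
    pos <- logistic_init(dim, config, lower, upper)
    fit <- apply(pos, 1, eval_fit)
    n_eval <- c_
    best_idx <- which.min(fit)
    best_pos <- pos[best_idx, ]; best_fit <- fit[best_idx]
    hist_fit <- numeric(N)

    for (iter in seq_len(N)) {
      mean_pos <- colMeans(pos)
      for (s in seq_len(c_)) {
        xi <- time_control(iter, N)
        newp <- if (xi >= config$x0) {
          ocean_current_move(pos[s, ], best_pos, mean_pos, config, lower, upper)
        } else if (runif(1) > (1 - xi)) {
          # swarm branch: passive probability equals the decaying time-control
          # value, so exploration fades into neighbor-directed exploitation
          passive_move(pos[s, ], config, lower, upper)
        } else {
          q <- sample(setdiff(seq_len(c_), s), 1)
          active_move(pos[s, ], pos[q, ], fit[s], fit[q], lower, upper)
        }
        newf <- eval_fit(newp)
        n_eval <- n_eval + 1L
        if (newf < fit[s]) { pos[s, ] <- newp; fit[s] <- newf }  # greedy acceptance
        if (newf < best_fit) { best_fit <- newf; best_pos <- newp }
      }
      hist_fit[iter] <- best_fit
    }

    structure(list(best_position = best_pos, best_fitness = best_fit,
                   history = tibble::tibble(iteration = seq_len(N), best_fitness = hist_fit),
                   evaluations = n_eval, config = config, dim = dim),
              class = "jso_result")
  })
}

#' @export
print.jso_result <- function(x, ...) {
  cat(sprintf("<jso_result> dim %d, %d evaluations, best fitness %.6g\n",
              x$dim, x$evaluations, x$best_fitness))
  invisible(x)
}

#' @export
#' @rdname jso_optimize
#' @param x A `jso_result`.
#' @param ... Unused.
glance.jso_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness, evaluations = x$evaluations,
                 iterations = nrow(x$history), dim = x$dim)
}

#' @export
#' @rdname jso_optimize
tidy.jso_result <- function(x, ...) x$history

#' Plot a jellyfish-search convergence curve
#' @param object A `jso_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.jso_result <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$iteration, .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "best fitness (log scale)")
}
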