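#' Two-timescale perspective-taking decision model
#'
#' Constructs the full model object: a fast "potentiation" process and a
#' slow "simulation" process, each descending a tilted double-well potential
#' \eqn{V(x) = kx - x^2/2 + x^4/4} at its own rate, coupled by mutual pull
#' terms and perturbed by Gaussian noise. A decision trial starts at the
#' saddle and ends when the running sum of either coordinate first reaches
#' \code{threshold} in absolute value; the crossing process is the winner
#' and the sign of its sum names the outcome (negative = egocentric,
#' positive = other-centric).
#'
#' This is the central object of the package: [simulate()] runs seeded
#' batches of trials, [plot()] draws the noise-free vector field,
#' [fixed_points()] enumerates and classifies equilibria, and [coef()]
#' extracts the parameter vector.
#'
#' @param k_fast,u_fast Tilt and descent rate of the fast process (x_P).
#' @param k_slow,u_slow Tilt and descent rate of the slow process (x_S).
#' @param alpha Coupling pulling the fast process toward the slow one.
#' @param beta Coupling pulling the slow process toward the fast one.
#' @param sigma Per-step Gaussian noise standard deviation.
#' @param threshold Accumulator bound (> 0); the canonical value is 30.
#' @param max_steps Per-trial step cap; trials that never cross are recorded
#'   as non-decisions.
#' @param init Initial state, length-2 numeric; the canonical start is the
#'   saddle \code{c(0, 0)}.
#' @return An object of class \code{"perspective_model"}.
#' @examples
#' m <- perspective_model(k_fast = 0.2, u_fast = 0.2, u_slow = 0.1)
#' b <- simulate(m, nsim = 50, seed = 1)
#' summary(b)
#' @export
perspective_model <- function(k_fast = 0, u_fast = 0.2,
                              k_slow = 0, u_slow = 0.2,
                              alpha = 0, beta = 0, sigma = 0.01,
                              threshold = 30, max_steps = 50000L,
                              init = c(0, 0)) {
  dynamics <- two_process_config(
    fast = process_params(k = k_fast, u = u_fast),
    slow = process_params(k = k_slow, u = u_slow),
    alpha = alpha, beta = beta, sigma = sigma
  )
  new_perspective_model(dynamics, threshold, max_steps, init)
}

new_perspective_model <- function(dynamics, threshold = 30,
                                  max_steps = 50000L, init = c(0, 0),
                                  preset = NULL) {
  stopifnot(inherits(dynamics, "two_process_config"))
  check_finite(threshold, "threshold")
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (!is.numeric(max_steps) || max_steps < 1)
    stop("`max_steps` must be >= 1", call. = FALSE)
  check_finite(init, "init")
  if (length(init) != 2L) stop("`init` must have length 2", call. = FALSE)
  structure(list(dynamics = dynamics, threshold = threshold,
                 max_steps = as.integer(max_steps),
                 init = as.numeric(init), preset = preset),
            class = "perspective_model")
}

as_perspective_model <- function(x) {
  if (inherits(x, "perspective_model")) return(x)
  if (inherits(x, "two_process_config")) return(new_perspective_model(x))
  stop("expected a perspective_model or two_process_config", call. = FALSE)
}

#' @export
print.perspective_model <- function(x, ...) {
  cat("perspective-taking decision model",
      if (!is.null(x$preset)) sprintf("(preset '%s')", x$preset), "\n")
  print(x$dynamics)
  cat(sprintf("  threshold = %g, max_steps = %d, init = (%g, %g)\n",
              x$threshold, x$max_steps, x$init[1L], x$init[2L]))
  invisible(x)
}

#' @export
coef.perspective_model <- function(object, ...) {
  d <- object$dynamics
  c(k_fast = d$fast$k, u_fast = d$fast$u,
    k_slow = d$slow$k, u_slow = d$slow$u,
    alpha = d$alpha, beta = d$beta, sigma = d$sigma,
    threshold = object$threshold)
}

#' Summary of a perspective model: parameters and landscape structure
#'
#' Reports the parameter vector together with the noise-free landscape
#' analysis: the marginal 1-D equilibria of each process and the fixed
#' points of the coupled 2-D map with their stability classes.
#'
#' @param object A \code{perspective_model}.
#' @param ... Unused.
#' @export
summary.perspective_model <- function(object, ...) {
  structure(list(model = object,
                 coef = coef(object),
                 fp_fast = fixed_points_1d(object$dynamics$fast$k),
                 fp_slow = fixed_points_1d(object$dynamics$slow$k),
                 fp_2d = fixed_points(object)),
            class = "summary.perspective_model")
}

#' @export
print.summary.perspective_model <- function(x, ...) {
  print(x$model)
  cat("\nmarginal 1-D equilibria (fast process):\n")
  print(x$fp_fast, row.names = FALSE)
  cat("marginal 1-D equilibria (slow process):\n")
  print(x$fp_slow, row.names = FALSE)
  cat("\ncoupled-map fixed points:\n")
  print(x$fp_2d, row.names = FALSE)
  invisible(x)
}

#' Simulate decision trials from a perspective model
#'
#' Runs a seeded batch of decision trials (see [run_batch()]); this is the
#' model's main entry point for generating data.
#'
#' @param object A \code{perspective_model}.
#' @param nsim Number of trials.
#' @param seed Integer batch seed (required for reproducibility; defaults
#'   to 1).
#' @param keep_states Keep per-trial trajectories?
#' @param ... Unused.
#' @return A \code{perspective_batch}.
#' @export
simulate.perspective_model <- function(object, nsim = 1, seed = 1L,
                                       keep_states = FALSE, ...) {
  run_batch(object, n_trials = nsim, seed = seed, keep_states = keep_states)
}

#' @export
summary.perspective_batch <- function(object, ...) object$summary

#' Vector-field plot of the noise-free map
#'
#' Draws the one-step displacement field of the deterministic map over a
#' grid of joint states (fast process on the horizontal axis), with located
#' fixed points overlaid: filled points are attractors, open squares
#' saddles, crosses repellers.
#'
#' @param x A \code{perspective_model}.
#' @param grid A [grid_spec()]; default covers \eqn{[-1.5, 1.5]^2}.
#' @param scale Arrow length multiplier.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.perspective_model <- function(x, grid = grid_spec(), scale = 1, ...) {
  vf <- vector_field(x, grid)
  df <- as.data.frame(vf)
  plot(df$x_fast, df$x_slow, type = "n",
       xlab = "x_fast (egocentric < 0 < other-centric)",
       ylab = "x_slow", ...)
  nz <- sqrt(df$dx_fast^2 + df$dx_slow^2) > 1e-12
  graphics::arrows(df$x_fast[nz], df$x_slow[nz],
                   df$x_fast[nz] + scale * df$dx_fast[nz],
                   df$x_slow[nz] + scale * df$dx_slow[nz],
                   length = 0.04, col = "grey40")
  fp <- fixed_points(x, grid = grid)
  if (nrow(fp)) {
    pch <- c(stable = 19, saddle = 22, unstable = 4)[fp$classification]
    graphics::points(fp$x_fast, fp$x_slow, pch = pch, cex = 1.4,
                     col = "firebrick", bg = "white")
  }
  invisible(x)
}
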