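#' One accumulation process: tilt and descent rate
#'
#' Bundles the two parameters that define a single accumulation process:
#' the landscape tilt \code{k} and the per-step gradient-descent rate
#' \code{u}. The fast "potentiation" process and the slow "simulation"
#' process are each a \code{process_params}; the slow process typically has
#' the smaller \code{u}.
#'
#' @param k Tilt; finite numeric, typically in \eqn{[-0.3, 0.3]}.
#' @param u Descent rate; \eqn{0 < u \le 1}.
#' @return An object of class \code{"process_params"} (a named list).
#' @export
process_params <- function(k = 0, u = 0.2) {
  check_finite(k, "k")
  check_finite(u, "u")
  if (length(k) != 1L || length(u) != 1L)
    stop("`k` and `u` must be scalars", call. = FALSE)
  if (u <= 0 || u > 1)
    stop("`u` must satisfy 0 < u <= 1 (u = 0 never descends)", call. = FALSE)
  structure(list(k = k, u = u), class = "process_params")
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("process: k = %g, u = %g\n", x$k, x$u))
  invisible(x)
}

#' Full two-process dynamics configuration
#'
#' The complete parameterisation of the coupled stochastic map: a fast and
#' a slow [process_params()], the couplings \code{alpha} (pull of the fast
#' process toward the slow one — top-down strategy) and \code{beta} (pull
#' of the slow process toward the fast one — bottom-up), and the shared
#' per-step Gaussian noise standard deviation \code{sigma}.
#'
#' @param fast,slow [process_params()] for the fast (x_P) and slow (x_S)
#'   process.
#' @param alpha,beta Coupling strengths, \eqn{\ge 0}.
#' @param sigma Per-step noise standard deviation, \eqn{\ge 0}.
#' @return An object of class \code{"two_process_config"}.
#' @export
two_process_config <- function(fast = process_params(),
                               slow = process_params(),
                               alpha = 0, beta = 0, sigma = 0.01) {
  stopifnot(inherits(fast, "process_params"), inherits(slow, "process_params"))
  check_finite(alpha, "alpha"); check_finite(beta, "beta")
  check_finite(sigma, "sigma")
  if (alpha < 0 || beta < 0) stop("couplings must be >= 0", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(fast = fast, slow = slow,
                 alpha = alpha, beta = beta, sigma = sigma),
            class = "two_process_config")
}

#' @export
print.two_process_config <- function(x, ...) {
  cat("two-process dynamics\n")
  cat(sprintf("  fast (x_P): k = %g, u = %g\n", x$fast$k, x$fast$u))
  cat(sprintf("  slow (x_S): k = %g, u = %g\n", x$slow$k, x$slow$u))
  cat(sprintf("  alpha = %g, beta = %g, sigma = %g\n",
              x$alpha, x$beta, x$sigma))
  invisible(x)
}

#' One-dimensional stochastic update
#'
#' The single-process map
#' \deqn{x_{t+1} = x_t + (-k + x_t - x_t^3) + \sigma\,\xi,}
#' a unit-rate noisy gradient descent on the tilted double-well potential.
#' The standard-normal variate \code{noise_draw} is supplied by the caller,
#' keeping the map deterministic given the draw. With \code{sigma = 0} the
#' map is pure gradient descent at unit rate; the descent rate \code{u}
#' only enters the two-process map [step_2d()].
#'
#' @param x Current state; finite numeric.
#' @param k Tilt.
#' @param sigma Noise standard deviation, \eqn{\ge 0}.
#' @param noise_draw Standard-normal variate(s); default 0.
#' @return Next state, same length as \code{x}.
#' @export
step_1d <- function(x, k, sigma = 0, noise_draw = 0) {
  check_finite(x, "x"); check_finite(k, "k"); check_finite(sigma, "sigma")
  x + (-k + x - x^3) + sigma * noise_draw
}

#' Two-process coupled stochastic update
#'
#' One synchronous step of the coupled map:
#' \deqn{x_{P,t+1} = x_{P,t} - u_P (k_P - x_{P,t} + x_{P,t}^3)
#'   + \alpha (x_{S,t} - x_{P,t}) + \sigma\,\xi_P}
#' \deqn{x_{S,t+1} = x_{S,t} - u_S (k_S - x_{S,t} + x_{S,t}^3)
#'   + \beta (x_{P,t} - x_{S,t}) + \sigma\,\xi_S.}
#' Both coordinates are updated from the time-\eqn{t} state; the two
#' standard-normal draws are independent and both scaled by the shared
#' \code{sigma}.
#'
#' @param state Numeric length-2 vector \code{c(x_fast, x_slow)}.
#' @param cfg A [two_process_config()].
#' @param draw_fast,draw_slow Standard-normal variates (default 0).
#' @return Numeric length-2 vector: the next state.
#' @export
step_2d <- function(state, cfg, draw_fast = 0, draw_slow = 0) {
  check_finite(state, "state")
  if (length(state) != 2L) stop("`state` must have length 2", call. = FALSE)
  xp <- state[[1L]]; xs <- state[[2L]]
  c(xp - cfg$fast$u * (cfg$fast$k - xp + xp^3) + cfg$alpha * (xs - xp) +
      cfg$sigma * draw_fast,
    xs - cfg$slow$u * (cfg$slow$k - xs + xs^3) + cfg$beta * (xp - xs) +
      cfg$sigma * draw_slow)
}

#' Jacobian of the noise-free two-process map
#'
#' Partial derivatives of the \eqn{\sigma = 0} [step_2d()] map with respect
#' to the state, used to classify the stability of its fixed points
#' (eigenvalue magnitudes relative to 1, as appropriate for a discrete map):
#' \deqn{J = \begin{pmatrix}
#'   1 - u_P(3x_P^2 - 1) - \alpha & \alpha \\
#'   \beta & 1 - u_S(3x_S^2 - 1) - \beta \end{pmatrix}.}
#'
#' @inheritParams step_2d
#' @return A 2x2 numeric matrix.
#' @export
map_jacobian <- function(state, cfg) {
  check_finite(state, "state")
  xp <- state[[1L]]; xs <- state[[2L]]
  matrix(c(1 - cfg$fast$u * (-1 + 3 * xp^2) - cfg$alpha, cfg$beta,
           cfg$alpha, 1 - cfg$slow$u * (-1 + 3 * xs^2) - cfg$beta),
         nrow = 2L)
}
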