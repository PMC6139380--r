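#' Tilted double-well potential
#'
#' The scalar landscape governing each accumulation process,
#' \deqn{V(x) = kx - x^2/2 + x^4/4.}
#' For \eqn{|k| < 2/(3\sqrt 3)} the landscape has two local minima (the
#' stable "egocentric" and "other-centric" perspectives, at negative and
#' positive \eqn{x} respectively) separated by a local maximum (the saddle).
#' The tilt \eqn{k} biases the landscape: positive \eqn{k} deepens the
#' negative (egocentric) well.
#'
#' @param x State coordinate(s); finite numeric.
#' @param k Tilt parameter; finite numeric scalar.
#' @return Potential value(s), same length as \code{x}.
#' @seealso [potential_gradient()], [fixed_points_1d()]
#' @examples
#' potential_value(c(-1, 0, 1), k = 0)   # -0.25  0.00 -0.25
#' @export
potential_value <- function(x, k) {
  check_finite(x, "x")
  check_finite(k, "k")
  k * x - x^2 / 2 + x^4 / 4
}

#' Gradient of the tilted double-well potential
#'
#' First derivative of [potential_value()] with respect to \code{x}:
#' \eqn{dV/dx = k - x + x^3}. The stochastic maps descend this gradient.
#'
#' @inheritParams potential_value
#' @return Gradient value(s), same length as \code{x}.
#' @export
potential_gradient <- function(x, k) {
  check_finite(x, "x")
  check_finite(k, "k")
  k - x + x^3
}

#' Fixed points of the one-dimensional noise-free map
#'
#' Finds all real roots of the drift \eqn{-k + x - x^3} (equivalently of
#' \eqn{x^3 - x + k = 0}) and classifies each as a stable or unstable
#' equilibrium of the deterministic update map. Stability is taken from the
#' drift's derivative: \eqn{1 - 3x^2 < 0} at a root means perturbations
#' decay, i.e. a potential minimum.
#'
#' For \eqn{|k| < 2/(3\sqrt 3) \approx 0.385} there are three roots
#' (stable, unstable, stable in ascending order); beyond that fold the
#' tilted landscape retains a single stable well.
#'
#' @param k Tilt parameter; finite numeric scalar.
#' @return A data frame with columns \code{location} (ascending) and
#'   \code{stability} (\code{"stable"} or \code{"unstable"}).
#' @examples
#' fixed_points_1d(0)    # -1 (stable), 0 (unstable), 1 (stable)
#' @export
fixed_points_1d <- function(k) {
  check_finite(k, "k")
  # roots of x^3 - x + k: coefficients in increasing degree for polyroot
  z <- polyroot(c(k, -1, 0, 1))
  # real-root filter; tolerance generous, roots polished by Newton below
  re <- Re(z)[abs(Im(z)) < 1e-7]
  for (i in seq_along(re)) {
    for (it in 1:50) {
      f <- re[i]^3 - re[i] + k
      fp <- 3 * re[i]^2 - 1
      if (abs(fp) < 1e-12 || abs(f) < 1e-14) break
      re[i] <- re[i] - f / fp
    }
  }
  re <- sort(re)
  # near the fold, polyroot can report a double root twice; dedup
  if (length(re) > 1) re <- re[c(TRUE, diff(re) > 1e-8)]
  stab <- ifelse(1 - 3 * re^2 < 0, "stable", "unstable")
  data.frame(location = re, stability = stab, stringsAsFactors = FALSE)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  }
  invisible(TRUE)
}
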