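#' Grid specification for landscape analysis
#'
#' @param x_min,x_max Bounds of the square state grid; defaults
#'   \eqn{[-1.5, 1.5]} cover all attractors for tilts \eqn{|k| \le 0.3}.
#' @param resolution Points per axis (>= 2); default 21.
#' @return An object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(x_min = -1.5, x_max = 1.5, resolution = 21L) {
  check_finite(x_min, "x_min"); check_finite(x_max, "x_max")
  if (x_min >= x_max) stop("`x_min` must be < `x_max`", call. = FALSE)
  if (resolution < 2L) stop("`resolution` must be >= 2", call. = FALSE)
  structure(list(x_min = x_min, x_max = x_max,
                 resolution = as.integer(resolution)),
            class = "grid_spec")
}

# sigma = 0 one-step displacement of the map, vectorised over states
displacement <- function(xp, xs, cfg) {
  list(dx_fast = -cfg$fast$u * (cfg$fast$k - xp + xp^3) +
         cfg$alpha * (xs - xp),
       dx_slow = -cfg$slow$u * (cfg$slow$k - xs + xs^3) +
         cfg$beta * (xp - xs))
}

#' Noise-free vector field of the coupled map
#'
#' Samples the one-step displacement of the deterministic
#' (\eqn{\sigma = 0}) map, \code{step_2d(node) - node}, at every node of a
#' state grid. This is the field whose arrows show which joint decisions a
#' parameter regime favours.
#'
#' @param model A [perspective_model()] (or a [two_process_config()]).
#' @param grid A [grid_spec()].
#' @return An object of class \code{"vector_field_grid"}: list with the
#'   axis coordinates \code{x} and matrices \code{dx_fast}, \code{dx_slow}
#'   (rows index the fast coordinate, columns the slow).
#' @export
vector_field <- function(model, grid = grid_spec()) {
  cfg <- as_perspective_model(model)$dynamics
  stopifnot(inherits(grid, "grid_spec"))
  x <- seq(grid$x_min, grid$x_max, length.out = grid$resolution)
  xp <- matrix(x, grid$resolution, grid$resolution)
  xs <- t(xp)
  d <- displacement(xp, xs, cfg)
  structure(list(x = x, dx_fast = d$dx_fast, dx_slow = d$dx_slow),
            class = "vector_field_grid")
}

#' Long-format table of a vector field
#'
#' @param x A \code{vector_field_grid}.
#' @param row.names,optional Unused; for the generic.
#' @param ... Unused.
#' @return Data frame with columns \code{x_fast}, \code{x_slow},
#'   \code{dx_fast}, \code{dx_slow}, one row per grid node.
#' @export
as.data.frame.vector_field_grid <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  n <- length(x$x)
  data.frame(x_fast = rep(x$x, times = n),
             x_slow = rep(x$x, each = n),
             dx_fast = as.vector(x$dx_fast),
             dx_slow = as.vector(x$dx_slow))
}

#' @export
print.vector_field_grid <- function(x, ...) {
  cat(sprintf("vector field on a %d x %d grid over [%g, %g]\n",
              length(x$x), length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Classify the stability of a fixed point of the coupled map
#'
#' Compares the eigenvalue magnitudes of [map_jacobian()] at the point to 1,
#' as appropriate for a discrete-time map: both moduli below 1 is an
#' attractor (\code{"stable"}), both above a repeller (\code{"unstable"}),
#' one on each side a \code{"saddle"}. A warning is issued when a modulus
#' lies within \code{1e-6} of 1 (marginal case).
#'
#' @param state Length-2 numeric, an (approximate) fixed point.
#' @param cfg A [two_process_config()].
#' @return List with \code{classification} and the sorted eigenvalue
#'   \code{moduli}.
#' @export
classify_stability <- function(state, cfg) {
  ev <- Mod(eigen(map_jacobian(state, cfg), only.values = TRUE)$values)
  if (any(abs(ev - 1) < 1e-6))
    warning("eigenvalue modulus within 1e-6 of 1: marginal stability",
            call. = FALSE)
  n_in <- sum(ev < 1)
  cls <- if (n_in == 2L) "stable" else if (n_in == 0L) "unstable" else "saddle"
  list(classification = cls, moduli = sort(ev, decreasing = TRUE))
}

#' Locate and classify fixed points of the coupled noise-free map
#'
#' Runs damped Newton iterations on the \eqn{\sigma = 0} displacement from
#' every node of the grid, discards non-converged starts, deduplicates
#' roots closer than \code{dedup_tol}, and classifies each survivor via
#' [classify_stability()]. With zero coupling the result is the Cartesian
#' product of each process's 1-D equilibria.
#'
#' @param model A [perspective_model()] (or [two_process_config()]).
#' @param grid A [grid_spec()] supplying the Newton seeds.
#' @param tol Convergence tolerance on the displacement magnitude.
#' @param dedup_tol Roots closer than this are merged.
#' @return Data frame sorted lexicographically by location, with columns
#'   \code{x_fast}, \code{x_slow}, \code{lambda1}, \code{lambda2}
#'   (eigenvalue moduli, descending) and \code{classification}.
#' @export
fixed_points <- function(model, grid = grid_spec(), tol = 1e-10,
                         dedup_tol = 1e-5) {
  cfg <- as_perspective_model(model)$dynamics
  stopifnot(inherits(grid, "grid_spec"))
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  ax <- seq(grid$x_min, grid$x_max, length.out = grid$resolution)
  seeds <- expand.grid(xp = ax, xs = ax)
  roots <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(seeds))) {
    p <- c(seeds$xp[i], seeds$xs[i])
    ok <- FALSE
    for (it in 1:100) {
      d <- displacement(p[1L], p[2L], cfg)
      f <- c(d$dx_fast, d$dx_slow)
      if (sqrt(sum(f^2)) < tol) { ok <- TRUE; break }
      # Jacobian of the displacement = map Jacobian - I
      J <- map_jacobian(p, cfg) - diag(2)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      # damp long steps to keep Newton inside the basin structure
      if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5 / sqrt(sum(step^2))
      p <- p - step
      if (any(abs(p) > 10)) break
    }
    if (ok) roots <- rbind(roots, p)
  }
  if (nrow(roots) == 0L) {
    return(data.frame(x_fast = numeric(0), x_slow = numeric(0),
                      lambda1 = numeric(0), lambda2 = numeric(0),
                      classification = character(0)))
  }
  # dedup: greedy cluster by distance
  keep <- matrix(roots[1L, ], ncol = 2L)
  for (i in seq_len(nrow(roots))[-1L]) {
    dmin <- min(sqrt((keep[, 1L] - roots[i, 1L])^2 +
                     (keep[, 2L] - roots[i, 2L])^2))
    if (dmin > dedup_tol) keep <- rbind(keep, roots[i, ])
  }
  ord <- order(keep[, 1L], keep[, 2L])
  keep <- keep[ord, , drop = FALSE]
  cls <- character(nrow(keep)); l1 <- numeric(nrow(keep)); l2 <- l1
  for (i in seq_len(nrow(keep))) {
    s <- classify_stability(keep[i, ], cfg)
    cls[i] <- s$classification
    l1[i] <- s$moduli[1L]; l2[i] <- s$moduli[2L]
  }
  data.frame(x_fast = keep[, 1L], x_slow = keep[, 2L],
             lambda1 = l1, lambda2 = l2, classification = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}
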