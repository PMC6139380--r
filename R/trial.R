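#' Accumulator stopping rule
#'
#' Pure decision predicate shared by the trial runners. A trial stops at the
#' first step where either running sum reaches the threshold in absolute
#' value; the accumulator that crossed is the winner and its sign gives the
#' outcome (negative = egocentric, positive = other-centric). If both cross
#' on the same step the larger absolute sum wins; on an exact tie the fast
#' process wins.
#'
#' @param accum_fast,accum_slow Current signed running sums of the fast and
#'   slow coordinate.
#' @param threshold Positive accumulator bound.
#' @return A list with elements \code{outcome} (\code{"egocentric"},
#'   \code{"other_centric"} or \code{"none"}) and \code{winner}
#'   (\code{"fast"}, \code{"slow"} or \code{"none"}).
#' @export
decide <- function(accum_fast, accum_slow, threshold) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  f <- abs(accum_fast) >= threshold
  s <- abs(accum_slow) >= threshold
  if (!f && !s) return(list(outcome = "none", winner = "none"))
  winner <- if (f && s) {
    if (abs(accum_slow) > abs(accum_fast)) "slow" else "fast"
  } else if (f) "fast" else "slow"
  val <- if (winner == "fast") accum_fast else accum_slow
  list(outcome = if (val < 0) "egocentric" else "other_centric",
       winner = winner)
}

#' Simulate one two-process decision trial
#'
#' Iterates the coupled map [step_2d()] from the initial state, maintaining
#' signed running sums of both coordinates (the initial state itself is not
#' summed), and stops at the first step where [decide()] fires. If
#' \code{max_steps} is reached without a crossing the trial is recorded as a
#' non-decision (\code{outcome = winner = "none"}).
#'
#' Randomness comes from the R session RNG; position it with
#' \code{set.seed()} before calling (the batch runner [run_batch()] does
#' this per trial).
#'
#' @param model A [perspective_model()].
#' @param keep_states Keep the full state trajectory and accumulator
#'   sequences? Set \code{FALSE} in large batches to save memory.
#' @return An object of class \code{"perspective_trial"}: a list with
#'   \code{outcome}, \code{winner}, \code{steps}, final accumulators
#'   \code{accum_fast_final}/\code{accum_slow_final}, and (if kept)
#'   \code{states} (a \code{(steps+1) x 2} matrix including the initial
#'   state) and \code{accum_fast}/\code{accum_slow} (length \code{steps}).
#' @export
run_trial_2d <- function(model, keep_states = TRUE) {
  model <- as_perspective_model(model)
  cfg <- model$dynamics
  thr <- model$threshold
  mx <- model$max_steps
  up <- cfg$fast$u; kp <- cfg$fast$k
  us <- cfg$slow$u; ks <- cfg$slow$k
  a <- cfg$alpha; b <- cfg$beta; sg <- cfg$sigma

  cap <- as.integer(min(mx, 2048L))
  xs <- numeric(cap + 1L); ys <- numeric(cap + 1L)
  af <- numeric(cap); as_ <- numeric(cap)
  x <- model$init[[1L]]; y <- model$init[[2L]]
  xs[1L] <- x; ys[1L] <- y
  sf <- 0; ss <- 0
  outcome <- "none"; winner <- "none"; steps <- mx

  for (t in seq_len(mx)) {
    if (t > cap) {
      cap2 <- as.integer(min(mx, cap * 2L))
      xs <- c(xs, numeric(cap2 - cap)); ys <- c(ys, numeric(cap2 - cap))
      af <- c(af, numeric(cap2 - cap)); as_ <- c(as_, numeric(cap2 - cap))
      cap <- cap2
    }
    z1 <- stats::rnorm(1L); z2 <- stats::rnorm(1L)
    xn <- x - up * (kp - x + x^3) + a * (y - x) + sg * z1
    yn <- y - us * (ks - y + y^3) + b * (x - y) + sg * z2
    x <- xn; y <- yn
    sf <- sf + x; ss <- ss + y
    xs[t + 1L] <- x; ys[t + 1L] <- y
    af[t] <- sf; as_[t] <- ss
    d <- decide(sf, ss, thr)
    if (d$winner != "none") {
      outcome <- d$outcome; winner <- d$winner; steps <- t
      break
    }
  }

  out <- list(outcome = outcome, winner = winner, steps = steps,
              accum_fast_final = sf, accum_slow_final = ss)
  if (keep_states) {
    idx <- seq_len(steps)
    out$states <- cbind(x_fast = xs[seq_len(steps + 1L)],
                        x_slow = ys[seq_len(steps + 1L)])
    out$accum_fast <- af[idx]
    out$accum_slow <- as_[idx]
  }
  structure(out, class = "perspective_trial")
}

#' Simulate one single-process decision trial
#'
#' One-dimensional variant: iterates [step_1d()] with a single signed
#' accumulator \eqn{\sum x}; the trial stops when \eqn{|\sum x|} first
#' reaches the threshold, the sign of the sum giving the outcome.
#'
#' @param k Tilt.
#' @param sigma Noise standard deviation.
#' @param threshold Positive accumulator bound (default 30).
#' @param max_steps Step cap (default 50000).
#' @param init Initial state (default 0, the saddle).
#' @param keep_states Keep trajectory and accumulator sequences?
#' @return A \code{"perspective_trial"} object (with \code{states} a
#'   \code{(steps+1)}-vector and a single \code{accum} sequence).
#' @export
run_trial_1d <- function(k, sigma, threshold = 30, max_steps = 50000L,
                         init = 0, keep_states = TRUE) {
  check_finite(k, "k"); check_finite(sigma, "sigma")
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (max_steps < 1L) stop("`max_steps` must be >= 1", call. = FALSE)
  cap <- as.integer(min(max_steps, 2048L))
  xs <- numeric(cap + 1L); ac <- numeric(cap)
  x <- init; xs[1L] <- x
  s <- 0
  outcome <- "none"; steps <- max_steps
  for (t in seq_len(max_steps)) {
    if (t > cap) {
      cap2 <- as.integer(min(max_steps, cap * 2L))
      xs <- c(xs, numeric(cap2 - cap)); ac <- c(ac, numeric(cap2 - cap))
      cap <- cap2
    }
    x <- x + (-k + x - x^3) + sigma * stats::rnorm(1L)
    s <- s + x
    xs[t + 1L] <- x; ac[t] <- s
    if (abs(s) >= threshold) {
      outcome <- if (s < 0) "egocentric" else "other_centric"
      steps <- t
      break
    }
  }
  out <- list(outcome = outcome,
              winner = if (outcome == "none") "none" else "fast",
              steps = steps, accum_final = s)
  if (keep_states) {
    out$states <- xs[seq_len(steps + 1L)]
    out$accum <- ac[seq_len(steps)]
  }
  structure(out, class = "perspective_trial")
}

#' @export
print.perspective_trial <- function(x, ...) {
  cat(sprintf("trial: outcome = %s, winner = %s, steps = %d\n",
              x$outcome, x$winner, x$steps))
  invisible(x)
}

#' Run a seeded batch of decision trials
#'
#' Trial \code{i} uses an RNG stream seeded deterministically from
#' \code{(seed, i)}, so batches are bitwise reproducible and independent of
#' execution order.
#'
#' @param model A [perspective_model()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer batch seed.
#' @param keep_states Keep per-trial trajectories? Default \code{FALSE}.
#' @return An object of class \code{"perspective_batch"}: list with
#'   \code{trials} (list of \code{perspective_trial}), \code{summary} (a
#'   [summarize_trials()] result), \code{model}, \code{n_trials},
#'   \code{seed}.
#' @export
run_batch <- function(model, n_trials, seed = 1L, keep_states = FALSE) {
  model <- as_perspective_model(model)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    set.seed(trial_seed(seed, i))
    trials[[i]] <- run_trial_2d(model, keep_states = keep_states)
  }
  structure(list(trials = trials, summary = summarize_trials(trials),
                 model = model, n_trials = as.integer(n_trials),
                 seed = as.integer(seed)),
            class = "perspective_batch")
}

# Deterministic per-trial substream seed from (batch seed, trial index).
# Lehmer-style mix kept below 2^31; exact in double arithmetic.
trial_seed <- function(seed, i) {
  ((abs(as.numeric(seed)) %% 2147483647) * 48271 + i) %% 2147483647
}

#' Summarise a list of trials
#'
#' Counts outcomes and winners, and computes decision-time statistics over
#' decided trials. \code{prop_other} is the fraction of \emph{decided}
#' trials with an other-centric outcome.
#'
#' @param trials Non-empty list of \code{perspective_trial} objects.
#' @return An object of class \code{"batch_summary"}.
#' @export
summarize_trials <- function(trials) {
  if (length(trials) == 0L) stop("`trials` must be non-empty", call. = FALSE)
  outcome <- vapply(trials, `[[`, "", "outcome")
  winner <- vapply(trials, `[[`, "", "winner")
  steps <- vapply(trials, function(t) as.numeric(t$steps), 0)
  counts <- table(outcome = factor(outcome, c("egocentric", "other_centric",
                                              "none")),
                  winner = factor(winner, c("fast", "slow", "none")))
  decided <- outcome != "none"
  n_dec <- sum(decided)
  structure(list(
    n_trials = length(trials),
    counts = counts,
    n_decided = n_dec,
    n_nondecision = sum(!decided),
    prop_other = if (n_dec > 0) mean(outcome[decided] == "other_centric")
                 else NA_real_,
    prop_fast_winner = if (n_dec > 0) mean(winner[decided] == "fast")
                       else NA_real_,
    mean_steps = if (n_dec > 0) mean(steps[decided]) else NA_real_,
    sd_steps = if (n_dec > 1) stats::sd(steps[decided]) else NA_real_
  ), class = "batch_summary")
}

#' @export
print.batch_summary <- function(x, digits = 3, ...) {
  cat(sprintf("batch of %d trials (%d decided, %d non-decisions)\n",
              x$n_trials, x$n_decided, x$n_nondecision))
  print(x$counts)
  if (x$n_decided > 0) {
    cat(sprintf("prop other-centric: %s   prop fast winner: %s\n",
                format(x$prop_other, digits = digits),
                format(x$prop_fast_winner, digits = digits)))
    cat(sprintf("steps to decision: mean %s, sd %s\n",
                format(x$mean_steps, digits = digits),
                format(x$sd_steps, digits = digits)))
  }
  invisible(x)
}

#' @export
print.perspective_batch <- function(x, ...) {
  cat(sprintf("perspective_batch (seed %d)\n", x$seed))
  print(x$summary)
  invisible(x)
}

#' Tabulate a batch as one row per trial
#'
#' @param x A \code{perspective_batch}.
#' @param row.names,optional Unused; for the generic.
#' @param ... Unused.
#' @return Data frame with columns \code{trial}, \code{trial_seed},
#'   \code{outcome}, \code{winner}, \code{steps}, \code{accum_fast_final},
#'   \code{accum_slow_final}.
#' @export
as.data.frame.perspective_batch <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(
    trial = seq_along(x$trials),
    trial_seed = vapply(seq_along(x$trials),
                        function(i) trial_seed(x$seed, i), 0),
    outcome = vapply(x$trials, `[[`, "", "outcome"),
    winner = vapply(x$trials, `[[`, "", "winner"),
    steps = vapply(x$trials, function(t) as.integer(t$steps), 0L),
    accum_fast_final = vapply(x$trials, `[[`, 0, "accum_fast_final"),
    accum_slow_final = vapply(x$trials, `[[`, 0, "accum_slow_final"),
    stringsAsFactors = FALSE
  )
}

#' Long-format trajectory table for a batch run with kept states
#'
#' @param x A \code{perspective_batch} run with \code{keep_states = TRUE}.
#' @return Data frame with columns \code{trial}, \code{step} (0 = initial
#'   state), \code{x_fast}, \code{x_slow}, \code{accum_fast},
#'   \code{accum_slow} (accumulators are \code{NA} at step 0).
#' @export
trajectories <- function(x) {
  stopifnot(inherits(x, "perspective_batch"))
  if (is.null(x$trials[[1L]]$states))
    stop("batch was run with keep_states = FALSE", call. = FALSE)
  do.call(rbind, lapply(seq_along(x$trials), function(i) {
    tr <- x$trials[[i]]
    n <- tr$steps
    data.frame(trial = i, step = 0:n,
               x_fast = tr$states[, "x_fast"],
               x_slow = tr$states[, "x_slow"],
               accum_fast = c(NA, tr$accum_fast),
               accum_slow = c(NA, tr$accum_slow))
  }))
}
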