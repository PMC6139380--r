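# Independent oracles: deliberately naive re-implementations used to
# cross-check the package. They share no code with R/.

# brute-force real-root scan of x^3 - x + k = 0 by bisection on sign changes
oracle_roots_1d <- function(k, lo = -3, hi = 3, n_grid = 6000) {
  xs <- seq(lo, hi, length.out = n_grid)
  f <- xs^3 - xs + k
  roots <- numeric(0)
  for (i in seq_len(n_grid - 1)) {
    if (f[i] == 0) roots <- c(roots, xs[i])
    if (f[i] * f[i + 1] < 0) {
      a <- xs[i]; b <- xs[i + 1]
      for (it in 1:80) {
        m <- (a + b) / 2
        if ((a^3 - a + k) * (m^3 - m + k) <= 0) b <- m else a <- m
      }
      roots <- c(roots, (a + b) / 2)
    }
  }
  sort(roots)
}

# straight-line re-iteration of the coupled map with a caller-supplied
# draw matrix (n_steps x 2); returns trajectory and accumulator sums
oracle_iterate_2d <- function(x0, y0, kp, up, ks, us, alpha, beta, sigma,
                              draws) {
  n <- nrow(draws)
  x <- x0; y <- y0; sf <- 0; ss <- 0
  xs <- numeric(n); ys <- numeric(n); af <- numeric(n); as2 <- numeric(n)
  for (t in seq_len(n)) {
    xn <- x - up * (kp - x + x^3) + alpha * (y - x) + sigma * draws[t, 1]
    yn <- y - us * (ks - y + y^3) + beta * (x - y) + sigma * draws[t, 2]
    x <- xn; y <- yn
    sf <- sf + x; ss <- ss + y
    xs[t] <- x; ys[t] <- y; af[t] <- sf; as2[t] <- ss
  }
  list(x = xs, y = ys, accum_fast = af, accum_slow = as2)
}

# independent tally of a trial list (second implementation of summarize)
oracle_tally <- function(trials) {
  n_other <- 0L; n_ego <- 0L; n_none <- 0L; n_fastwin <- 0L
  steps <- numeric(0)
  for (tr in trials) {
    if (tr$outcome == "none") n_none <- n_none + 1L
    else {
      if (tr$outcome == "other_centric") n_other <- n_other + 1L
      else n_ego <- n_ego + 1L
      if (tr$winner == "fast") n_fastwin <- n_fastwin + 1L
      steps <- c(steps, tr$steps)
    }
  }
  n_dec <- n_ego + n_other
  list(n_ego = n_ego, n_other = n_other, n_none = n_none,
       prop_other = if (n_dec > 0) n_other / n_dec else NA_real_,
       prop_fast_winner = if (n_dec > 0) n_fastwin / n_dec else NA_real_,
       mean_steps = if (n_dec > 0) mean(steps) else NA_real_)
}

# wrap a dynamics config in a model with trial settings (exported API only)
new_model_for_test <- function(cfg, threshold = 30, max_steps = 50000) {
  perspective_model(k_fast = cfg$fast$k, u_fast = cfg$fast$u,
                    k_slow = cfg$slow$k, u_slow = cfg$slow$u,
                    alpha = cfg$alpha, beta = cfg$beta, sigma = cfg$sigma,
                    threshold = threshold, max_steps = max_steps)
}

# random valid dynamics configuration (for property loops)
random_config <- function() {
  two_process_config(
    fast = process_params(k = runif(1, -0.3, 0.3), u = runif(1, 0.05, 0.5)),
    slow = process_params(k = runif(1, -0.3, 0.3), u = runif(1, 0.05, 0.5)),
    alpha = runif(1, 0, 0.3), beta = runif(1, 0, 0.3),
    sigma = runif(1, 0, 0.2))
}
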