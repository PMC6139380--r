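test_that("stopping predicate implements the documented rule", {
  expect_equal(decide(-30.2, 4.1, 30),
               list(outcome = "egocentric", winner = "fast"))
  expect_equal(decide(12, -12, 30), list(outcome = "none", winner = "none"))
  # same-step double crossing: larger absolute sum wins
  expect_equal(decide(31, -33, 30),
               list(outcome = "egocentric", winner = "slow"))
  # exact tie goes to the fast process
  expect_equal(decide(-31, 31, 30),
               list(outcome = "egocentric", winner = "fast"))
  expect_equal(decide(4, 30, 30),
               list(outcome = "other_centric", winner = "slow"))
  expect_error(decide(0, 0, 0), "threshold")
})

test_that("deterministic trial matches a brute-force re-simulation", {
  m <- perspective_model(k_fast = 0.2, u_fast = 0.2,
                         k_slow = 0, u_slow = 0.1, sigma = 0)
  tr <- run_trial_2d(m)
  # pinned against an independent straight-line iteration of the map
  expect_equal(tr$steps, 35L)
  expect_equal(tr$outcome, "egocentric")
  expect_equal(tr$winner, "fast")
  expect_equal(tr$accum_fast_final, -30.66828, tolerance = 1e-6)
  o <- oracle_iterate_2d(0, 0, 0.2, 0.2, 0, 0.1, 0, 0, 0,
                         matrix(0, 40, 2))
  expect_equal(tr$accum_fast, o$accum_fast[1:35])
  expect_equal(tr$states[-1, "x_fast"], o$x[1:35])
})

test_that("exact saddle with zero noise yields a non-decision", {
  m <- perspective_model(sigma = 0, max_steps = 200)
  tr <- run_trial_2d(m)
  expect_equal(tr$outcome, "none")
  expect_equal(tr$winner, "none")
  expect_equal(tr$steps, 200L)
  tr1 <- run_trial_1d(k = 0, sigma = 0, max_steps = 200)
  expect_equal(tr1$outcome, "none")
})

test_that("trials satisfy the first-crossing property and invariants", {
  set.seed(303)
  for (rep in 1:20) {
    cfg <- random_config()
    m <- new_model_for_test(cfg, threshold = 20, max_steps = 5000)
    tr <- run_trial_2d(m, keep_states = TRUE)
    if (tr$outcome == "none") {
      expect_equal(tr$winner, "none")
      expect_equal(tr$steps, 5000L)
      expect_true(all(abs(tr$accum_fast) < 20 & abs(tr$accum_slow) < 20))
    } else {
      n <- tr$steps
      # no prefix crosses before the recorded stopping step
      if (n > 1) {
        expect_true(all(abs(tr$accum_fast[-n]) < 20))
        expect_true(all(abs(tr$accum_slow[-n]) < 20))
      }
      crossed <- if (tr$winner == "fast") tr$accum_fast[n]
                 else tr$accum_slow[n]
      expect_gte(abs(crossed), 20)
      expect_equal(tr$outcome,
                   if (crossed < 0) "egocentric" else "other_centric")
      # trajectories stay bounded under default parameter ranges
      expect_true(all(abs(tr$states) < 2))
    }
  }
})

test_that("batches are reproducible and order-independent", {
  m <- preset("fig2")
  b1 <- run_batch(m, 20, seed = 77)
  b2 <- run_batch(m, 20, seed = 77)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  # trial 7 of the batch equals a lone trial on the (seed, 7) substream
  set.seed(perspectr:::trial_seed(77, 7))
  lone <- run_trial_2d(m, keep_states = FALSE)
  expect_identical(b1$trials[[7]]$accum_fast_final, lone$accum_fast_final)
  expect_identical(b1$trials[[7]]$steps, lone$steps)
  # different seed, different realisation
  b3 <- run_batch(m, 20, seed = 78)
  expect_false(identical(as.data.frame(b1)$accum_fast_final,
                         as.data.frame(b3)$accum_fast_final))
})

test_that("summaries agree with an independent recount", {
  set.seed(5150)
  trials <- list()
  for (rep in 1:5) {
    cfg <- random_config()
    m <- new_model_for_test(cfg, threshold = 15, max_steps = 3000)
    b <- run_batch(m, 20, seed = rep)
    trials <- c(trials, b$trials)
  }
  s <- summarize_trials(trials)
  o <- oracle_tally(trials)
  expect_equal(s$n_trials, 100L)
  expect_equal(s$n_nondecision, o$n_none)
  expect_equal(sum(s$counts), s$n_trials)
  expect_equal(unname(s$counts["egocentric", "fast"] +
                      s$counts["egocentric", "slow"]), o$n_ego)
  expect_equal(s$prop_other, o$prop_other)
  expect_equal(s$prop_fast_winner, o$prop_fast_winner)
  expect_equal(s$mean_steps, o$mean_steps)
  expect_error(summarize_trials(list()), "non-empty")
  # hand-built toy lists
  toy <- function(outcome, winner)
    structure(list(outcome = outcome, winner = winner, steps = 10L,
                   accum_fast_final = 0, accum_slow_final = 0),
              class = "perspective_trial")
  expect_equal(summarize_trials(replicate(3, toy("egocentric", "fast"),
                                          simplify = FALSE))$prop_other, 0)
  mixed <- c(replicate(2, toy("other_centric", "slow"), simplify = FALSE),
             replicate(2, toy("egocentric", "fast"), simplify = FALSE))
  expect_equal(summarize_trials(mixed)$prop_other, 0.5)
})

test_that("1-D trials behave per regime: split at k=0, unanimity at k=0.5", {
  outs <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    run_trial_1d(k = 0, sigma = 0.1, keep_states = FALSE)$outcome
  }, "")
  expect_true(sum(outs == "egocentric") > 0)
  expect_true(sum(outs == "other_centric") > 0)
  # strong tilt: egocentric for essentially every seed
  outs2 <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    run_trial_1d(k = 0.5, sigma = 0.01, keep_states = FALSE)$outcome
  }, "")
  expect_true(all(outs2 == "egocentric"))
})

test_that("mutual coupling speeds decisions relative to one-way coupling", {
  # at the fig5 tilts, adding the bottom-up pull beta shortens decisions
  one_way <- perspective_model(k_fast = 0.2, u_fast = 0.2,
                               k_slow = -0.025, u_slow = 0.1,
                               alpha = 0.2, beta = 0)
  s_mutual <- summary(simulate(preset("fig5"), nsim = 1000, seed = 4))
  s_oneway <- summary(simulate(one_way, nsim = 1000, seed = 4))
  expect_lt(s_mutual$mean_steps, s_oneway$mean_steps)
})

test_that("trajectory export has one row per step plus the initial state", {
  b <- run_batch(preset("fig3"), 3, seed = 9, keep_states = TRUE)
  tj <- trajectories(b)
  expect_equal(nrow(tj), sum(vapply(b$trials, `[[`, 0L, "steps")) + 3L)
  expect_true(all(is.na(tj$accum_fast[tj$step == 0])))
  expect_equal(tj$x_fast[tj$step == 0], rep(0, 3))
  b2 <- run_batch(preset("fig3"), 3, seed = 9, keep_states = FALSE)
  expect_error(trajectories(b2), "keep_states")
})
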