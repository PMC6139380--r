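test_that("vector field is the one-step displacement of the noise-free map", {
  m0 <- perspective_model(u_fast = 0.2, u_slow = 0.2)  # decoupled, k = 0
  vf <- vector_field(m0, grid_spec(-1.5, 1.5, 7))
  df <- as.data.frame(vf)
  expect_equal(nrow(df), 49L)
  at <- function(d, x, y) d[abs(d$x_fast - x) < 1e-9 &
                             abs(d$x_slow - y) < 1e-9, ]
  # saddle and attractor are stationary
  expect_equal(unlist(at(df, 0, 0)[, c("dx_fast", "dx_slow")]),
               c(dx_fast = 0, dx_slow = 0))
  expect_equal(unlist(at(df, 1, 1)[, c("dx_fast", "dx_slow")]),
               c(dx_fast = 0, dx_slow = 0))
  # nearby nodes point toward the attractor at (1, 1)
  nb <- at(df, 0.5, 0.5)
  expect_gt(nb$dx_fast, 0); expect_gt(nb$dx_slow, 0)
  nb2 <- at(df, 1.5, 1.5)
  expect_lt(nb2$dx_fast, 0); expect_lt(nb2$dx_slow, 0)
  # fig3 parameters: drift at the origin is the hand-computed (-0.04, 0)
  vf3 <- vector_field(preset("fig3"), grid_spec(-1, 1, 3))
  df3 <- as.data.frame(vf3)
  expect_equal(unlist(at(df3, 0, 0)[, c("dx_fast", "dx_slow")]),
               c(dx_fast = -0.04, dx_slow = 0))
  # field values agree with step_2d at sigma = 0 on every node
  cfg <- preset("fig4")$dynamics
  vf4 <- as.data.frame(vector_field(preset("fig4"), grid_spec(-1.5, 1.5, 5)))
  for (i in seq_len(nrow(vf4))) {
    s <- step_2d(c(vf4$x_fast[i], vf4$x_slow[i]), cfg)
    expect_equal(c(vf4$dx_fast[i], vf4$dx_slow[i]),
                 s - c(vf4$x_fast[i], vf4$x_slow[i]))
  }
})

test_that("decoupled fixed points are the product of the 1-D equilibria", {
  m0 <- perspective_model(u_fast = 0.2, u_slow = 0.2)
  fp <- fixed_points(m0)
  expect_equal(nrow(fp), 9L)
  expect_equal(sum(fp$classification == "stable"), 4L)
  expect_equal(sum(fp$classification == "saddle"), 4L)
  expect_equal(sum(fp$classification == "unstable"), 1L)
  grid_pts <- expand.grid(x_fast = c(-1, 0, 1), x_slow = c(-1, 0, 1))
  for (i in 1:9) {
    d <- sqrt((fp$x_fast - grid_pts$x_fast[i])^2 +
              (fp$x_slow - grid_pts$x_slow[i])^2)
    expect_lt(min(d), 1e-7)
  }
  # general decoupled config: Cartesian product with conjunct stability
  m <- perspective_model(k_fast = 0.15, u_fast = 0.3,
                         k_slow = -0.1, u_slow = 0.1)
  fp1f <- fixed_points_1d(0.15); fp1s <- fixed_points_1d(-0.1)
  fp2 <- fixed_points(m)
  expect_equal(nrow(fp2), nrow(fp1f) * nrow(fp1s))
  for (i in seq_len(nrow(fp1f))) {
    for (j in seq_len(nrow(fp1s))) {
      d <- sqrt((fp2$x_fast - fp1f$location[i])^2 +
                (fp2$x_slow - fp1s$location[j])^2)
      hit <- which.min(d)
      expect_lt(d[hit], 1e-7)
      both <- c(fp1f$stability[i], fp1s$stability[j])
      want <- if (all(both == "stable")) "stable"
              else if (all(both == "unstable")) "unstable" else "saddle"
      expect_equal(fp2$classification[hit], want)
    }
  }
  # single fast root beyond the fold: 1 x 3 product
  m1 <- perspective_model(k_fast = 1, u_fast = 0.2, u_slow = 0.2)
  expect_equal(nrow(fixed_points(m1)), 3L)
})

test_that("every located fixed point is stationary under the map", {
  for (id in c("fig2", "fig4", "fig5")) {
    m <- preset(id)
    fp <- fixed_points(m, grid_spec(-1.5, 1.5, 9))
    expect_gt(nrow(fp), 0)
    cfg <- m$dynamics
    cfg0 <- two_process_config(cfg$fast, cfg$slow, cfg$alpha, cfg$beta, 0)
    for (i in seq_len(nrow(fp))) {
      p <- c(fp$x_fast[i], fp$x_slow[i])
      expect_lt(sqrt(sum((step_2d(p, cfg0) - p)^2)), 1e-8)
    }
  }
})

test_that("stability classification follows the eigenvalue moduli", {
  cfg <- two_process_config(process_params(0, 0.2), process_params(0, 0.2))
  expect_equal(classify_stability(c(0, 0), cfg)$classification, "unstable")
  expect_equal(classify_stability(c(1, 1), cfg)$classification, "stable")
  s <- classify_stability(c(1, 0), cfg)
  expect_equal(s$classification, "saddle")
  expect_equal(s$moduli, c(1.2, 0.6))
  # marginal modulus warns
  cfg_m <- two_process_config(process_params(0, 1e-9), process_params(0, 0.2))
  expect_warning(classify_stability(c(0, 0), cfg_m), "marginal")
})

test_that("negating both tilts reflects the fixed-point set", {
  m <- perspective_model(k_fast = 0.2, u_fast = 0.2,
                         k_slow = -0.1, u_slow = 0.1,
                         alpha = 0.15, beta = 0.05)
  mneg <- perspective_model(k_fast = -0.2, u_fast = 0.2,
                            k_slow = 0.1, u_slow = 0.1,
                            alpha = 0.15, beta = 0.05)
  fp <- fixed_points(m)
  fpn <- fixed_points(mneg)
  expect_equal(nrow(fp), nrow(fpn))
  reflected <- fpn[order(-fpn$x_fast, -fpn$x_slow), ]
  expect_equal(fp$x_fast, -reflected$x_fast, tolerance = 1e-7)
  expect_equal(fp$x_slow, -reflected$x_slow, tolerance = 1e-7)
  expect_equal(fp$classification, reflected$classification)
})

test_that("grid specification rejects degenerate bounds", {
  expect_error(grid_spec(1, 1), "x_min")
  expect_error(grid_spec(0, 1, resolution = 1), "resolution")
})
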