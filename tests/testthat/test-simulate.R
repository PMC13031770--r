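test_that("a single observation moves the belief halfway to the blend", {
  # fresh agent, (healthy, tasty): tally (1,0,0,0), psi = 1, phi = 0 (warm-up)
  st <- agent_state(beta = 1, alpha = 0.5)
  st <- observe(st, "cafeteria", TRUE, TRUE)
  expect_equal(st$belief, 0.5)
  expect_identical(st$t, 1L)
  expect_identical(as.integer(st$tallies$cafeteria), c(1L, 0L, 0L, 0L))
})

test_that("step-wise observation matches the vectorised trajectory", {
  env <- calibration_environment("healthy", seed = 11)
  for (pars in list(c(1, 0.5), c(0.3, 0.25), c(0, 1))) {
    sim <- simulate_agent(env, beta = pars[1], alpha = pars[2])
    st <- agent_state(pars[1], pars[2])
    beliefs <- numeric(24)
    for (i in seq_len(24)) {
      o <- env$observations[i, ]
      st <- observe(st, o$context, o$healthy == 1, o$tasty == 1)
      beliefs[i] <- st$belief
    }
    expect_equal(sim$trajectory$belief, beliefs, tolerance = 1e-12)
    expect_equal(sim$final_belief, beliefs[24], tolerance = 1e-12)
  }
})

test_that("final beliefs are linear in bias strength for a fixed order", {
  env <- calibration_environment("unhealthy", seed = 5)
  f <- function(b) simulate_agent(env, b, 0.4)$final_belief
  b0 <- f(0); b1 <- f(1)
  for (b in c(0.2, 0.5, 0.77, 1.6, -0.5))
    expect_equal(f(b), (1 - b) * b0 + b * b1, tolerance = 1e-12)
})

test_that("alpha = 1 replaces the belief with the momentary blend", {
  sim <- simulate_agent(calibration_environment("healthy", seed = 2), 0.6, 1)
  expect_equal(sim$trajectory$belief, sim$trajectory$phi_hat)
})

test_that("trajectories stay within [-1, 1] for bias strengths in [0, 1]", {
  set.seed(31)
  for (i in 1:20) {
    env <- calibration_environment(sample(c("healthy", "unhealthy", "balanced"), 1),
                                   seed = sample.int(1e6, 1))
    sim <- simulate_agent(env, stats::runif(1), stats::runif(1, 0.05, 1))
    expect_true(all(abs(sim$trajectory$belief) <= 1 + 1e-12))
    expect_true(all(abs(sim$trajectory$phi_hat) <= 1 + 1e-12))
  }
})

test_that("populations are reproducible and spread grows with heterogeneity", {
  p1 <- simulate_population("balanced", 50, beta = 0, alpha = 0.5, seed = 4)
  p2 <- simulate_population("balanced", 50, beta = 0, alpha = 0.5, seed = 4)
  expect_identical(p1, p2)
  # contingency-only agents in the balanced environment end near zero
  expect_lt(max(abs(p1)), 0.25)
  expect_lt(stats::sd(p1), 0.08)
  pc <- simulate_population("healthy", 100, beta = 0.5, alpha = 0.5, seed = 4)
  ph <- simulate_population("healthy", 100, beta = bias_uniform(0, 1),
                            alpha = 0.5, seed = 4)
  expect_gte(stats::sd(ph), stats::sd(pc))
  expect_length(attr(ph, "beta"), 100L)
})

test_that("time to equilibrium follows the geometric decay of smoothing", {
  for (cs in list(list(alpha = 0.5, target = 0.8, tol = 1e-3),
                  list(alpha = 0.3, target = -0.6, tol = 2e-3))) {
    b <- pcbias:::smooth_series(rep(cs$target, 60), cs$alpha)
    k <- time_to_equilibrium(b, cs$tol)
    # oracle: explicit scan of the definition
    dev <- abs(b - b[60])
    expected <- if (any(dev > cs$tol)) max(which(dev > cs$tol)) else 0L
    expect_identical(k, expected)
    # first compliant step matches the closed-form geometric-decay count
    expect_identical(expected + 1L,
                     as.integer(ceiling(log(cs$tol / abs(cs$target)) /
                                          log(1 - cs$alpha))))
  }
  expect_identical(time_to_equilibrium(c(0.5, 0.1, 0.1), 10), 0L)
  # alpha = 1 jumps straight to a constant target: never leaves the band
  expect_identical(time_to_equilibrium(pcbias:::smooth_series(rep(0.5, 10), 1),
                                       1e-6), 0L)
})

test_that("the vector field vanishes at the fixed point and flags inference error", {
  env <- calibration_environment("healthy", seed = 1)
  vf0 <- vector_field(env, beta = 0, alpha = 0.5)
  expect_equal(unique(vf0$inference_error), 0)
  vf1 <- vector_field(env, beta = 1, alpha = 0.5, grid = c(-0.5, 0.25, 0.9))
  expect_equal(unique(vf1$inference_error), 7 / 12)
  expect_equal(vf1$displacement[2], 0) # the fixed point: the context psi
  expect_gt(vf1$displacement[1], 0)   # pulled up from below
  expect_lt(vf1$displacement[3], 0)   # pulled down from above
})

test_that("long-run beliefs are independent of the learning rate", {
  finals <- vapply(c(0.2, 0.9), function(a)
    simulate_agent(calibration_environment("healthy", seed = 3), 0.7, a,
                   cycles = 200)$final_belief, numeric(1))
  expect_equal(finals[1], finals[2], tolerance = 1e-3)
})
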