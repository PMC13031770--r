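test_that("calibration designs realise the printed contingencies and skews", {
  cases <- list(list(cond = "healthy", phi = -1 / 3, psi = 0.25),
                list(cond = "unhealthy", phi = 1 / 3, psi = -0.25),
                list(cond = "balanced", phi = 0, psi = 0))
  for (cs in cases) {
    env <- calibration_environment(cs$cond, seed = 7)
    expect_identical(env$n_meals, 24L)
    expect_length(env$contexts, 2L)
    for (tab in env$contexts) {
      expect_equal(phi_coef(tab), cs$phi, tolerance = 1e-12)
      expect_equal(pseudocontingency(skews(marginals(tab))), cs$psi)
    }
  }
  expect_error(calibration_environment("vegan"), "condition")
})

test_that("contexts mirror each other: pooled base rates are neutral", {
  for (cond in c("healthy", "unhealthy")) {
    env <- calibration_environment(cond, seed = 1)
    pooled <- Reduce(`+`, lapply(env$contexts, as.integer))
    expect_equal(unname(skews(marginals(pooled))), c(0, 0))
    for (tab in env$contexts)
      expect_equal(abs(unname(skews(marginals(tab)))), c(0.25, 0.25))
  }
})

test_that("shuffling never changes the tallied per-context tables", {
  for (s in c(1, 23, 999)) {
    for (inter in c(FALSE, TRUE)) {
      env <- calibration_environment("healthy", seed = s, interleave = inter)
      expect_identical(lapply(tally_observations(env), as.integer),
                       lapply(env$contexts, as.integer))
    }
  }
  # identical seed gives identical order; different seeds differ
  e1 <- calibration_environment("unhealthy", seed = 5)
  e2 <- calibration_environment("unhealthy", seed = 5)
  e3 <- calibration_environment("unhealthy", seed = 6)
  expect_identical(e1$observations, e2$observations)
  expect_false(identical(e1$observations, e3$observations))
})

test_that("validation designs have zero contingency with skewed base rates", {
  b <- validation_environment("balanced", seed = 2)
  expect_identical(as.integer(b$contexts$restaurant), rep(6L, 4L))
  for (cond in c("healthy", "unhealthy")) {
    env <- validation_environment(cond, seed = 2)
    tab <- env$contexts$restaurant
    expect_equal(phi_coef(tab), 0)
    m <- marginals(tab)
    expect_equal(unname(m["p_h"]), if (cond == "healthy") 0.75 else 0.25)
    expect_identical(sum(tab), 24L)
  }
  # base rates alone imply opposite-signed relationships across conditions
  psi_of <- function(cond)
    pseudocontingency(skews(marginals(
      validation_environment(cond, seed = 1)$contexts$restaurant)))
  expect_gt(psi_of("healthy"), 0)
  expect_lt(psi_of("unhealthy"), 0)
  expect_identical(psi_of("balanced"), 0)
  expect_error(validation_environment("balanced", n_meals = 22), "divisible")
  expect_error(validation_environment("healthy", n_meals = 20), "infeasible")
})

test_that("environment files round-trip and reject malformed input", {
  env <- calibration_environment("unhealthy", seed = 3)
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_environment(env, path)
  env2 <- read_environment(path)
  expect_identical(env2$condition, env$condition)
  expect_identical(lapply(env2$contexts, as.integer),
                   lapply(env$contexts, as.integer))
  expect_equal(env2$observations, env$observations)

  writeLines(c("condition=unhealthy", "[contexts]", "context,ht,hn,ut,un",
               "a,-1,2,2,2", "[observations]", "index,context,healthy,tasty",
               "1,a,1,1"), path)
  expect_error(read_environment(path), "negative")
  writeLines(c("condition=keto", "[contexts]", "context,ht,hn,ut,un",
               "a,1,0,0,0", "[observations]", "index,context,healthy,tasty",
               "1,a,1,1"), path)
  expect_error(read_environment(path), "unknown condition")
  writeLines(c("condition=balanced", "[contexts]", "context,ht,hn,ut,un",
               "a,1,0,0,0", "[observations]", "index,context,healthy,tasty",
               "1,b,1,1"), path)
  expect_error(read_environment(path), "undeclared context")
})
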