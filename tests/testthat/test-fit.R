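test_that("quantile-paired MAE measures distributional mismatch", {
  expect_equal(mae_quantile(c(0, 1), c(1, 0)), 0)
  expect_equal(mae_quantile(1:5, 5:1), 0)
  expect_equal(mae_quantile(0.2, 0.5), 0.3)
  expect_equal(mae_quantile(c(0, 1), c(0, 0, 1, 1)), 0)
  expect_gt(mae_quantile(c(0, 1), c(0.5, 0.5)), 0)
  expect_error(mae_quantile(numeric(0), 1), "empty")
})

test_that("the KS statistic matches enumeration and stats::ks.test", {
  expect_equal(ks_stat(c(0, 1), c(0.5, 1)), 0.5)
  expect_equal(ks_stat(1:4, 1:4), 0)
  expect_equal(ks_stat(c(0, 0.1), c(5, 6)), 1)
  expect_error(ks_stat(numeric(0), 1), "empty")
  set.seed(8)
  for (i in 1:20) {
    a <- stats::rnorm(17); b <- stats::rnorm(23, 0.3)
    expect_equal(ks_stat(a, b),
                 unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("the SD ratio is the plain ratio and flags constant simulations", {
  expect_equal(sd_ratio(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(sd_ratio(c(-0.19, 0.19), c(-0.05, 0.05)), 3.8)
  expect_warning(r <- sd_ratio(c(1, 2), c(1, 1)), "zero")
  expect_identical(r, Inf)
  expect_error(sd_ratio(1, c(1, 2)), "two elements")
})

test_that("the group fit recovers a constant generating bias on the grid", {
  cfg <- cohort_config(n_per_condition = 40, bias_sampler = bias_constant(0.8),
                       noise_sd = 0, seed = 11)
  coh <- generate_cohort(cfg)
  ctl <- fit_control(seed = 3, n_sim = 80)
  fit <- fit_bias(coh, "group", control = ctl, conditions = "healthy")
  expect_lte(abs(coef(fit)[["healthy"]] - 0.8), 0.01 + 1e-9)
  expect_lt(fit$fits$healthy$mae, 0.03)
  # a single-point grid returns that bias strength with its objectives
  ctl1 <- fit_control(beta_grid = 0.37, seed = 3, n_sim = 20)
  fit1 <- fit_bias(coh, "group", control = ctl1, conditions = "healthy")
  expect_identical(coef(fit1)[["healthy"]], 0.37)
  expect_true(is.finite(fit1$fits$healthy$objective))
})

test_that("the balanced condition only weakly identifies the bias strength", {
  # zero reports are matched almost equally well across the whole grid:
  # the design's phi and psi are both 0, so only warm-up fluctuations
  # separate candidate bias strengths
  coh <- data.frame(participant_id = sprintf("p%02d", 1:20),
                    condition = "balanced",
                    reported_belief = rep(0, 20))
  ctl <- fit_control(seed = 2, n_sim = 30)
  fit <- fit_bias(coh, "group", control = ctl)
  curve <- fit$fits$balanced$curve
  expect_lt(min(curve$mae), 0.01)
  expect_lt(max(curve$mae) - min(curve$mae), 0.1)
  expect_lt(fit$fits$balanced$mae, 0.05)
  # any beta fits zero reports in the balanced design: residual error is tiny
  fi <- fit_bias(coh, "individual", control = ctl)
  expect_lt(fi$fits$balanced$mae, 0.02)
})

test_that("self-fit of the exactly simulated population has zero objectives", {
  ctl <- fit_control(seed = 9, n_sim = 40)
  eps <- pcbias:::population_endpoints("healthy", calibration_environment, ctl,
                                       pcbias:::condition_seed(9, "healthy"))
  obs <- (1 - 0.6) * eps[, 1] + 0.6 * eps[, 2]
  coh <- data.frame(participant_id = paste0("p", seq_along(obs)),
                    condition = "healthy", reported_belief = obs)
  fit <- fit_bias(coh, "group", control = ctl, conditions = "healthy")
  expect_identical(coef(fit)[["healthy"]], 0.6)
  expect_equal(fit$fits$healthy$mae, 0, tolerance = 1e-12)
  expect_equal(fit$fits$healthy$ks, 0, tolerance = 1e-12)
})

test_that("individual fits invert reports constructed on the prediction curve", {
  ctl <- fit_control(seed = 4)
  oseeds <- pcbias:::child_seeds(pcbias:::condition_seed(4, "healthy", salt = 1L),
                                 ctl$n_orders)
  ep <- vapply(oseeds, function(s)
    pcbias:::env_endpoints(calibration_environment("healthy", seed = s),
                           ctl$alpha), numeric(2))
  m0 <- mean(ep[1, ]); m1 <- mean(ep[2, ])
  true_b <- c(0, 0.13, 0.6, 0.97, 1)
  coh <- data.frame(participant_id = paste0("p", 1:5), condition = "healthy",
                    reported_belief = (1 - true_b) * m0 + true_b * m1)
  fit <- fit_bias(coh, "individual", control = ctl)
  expect_true(all(abs(coef(fit)$healthy - true_b) <= 0.005 + 1e-12))

  # a report above the achievable range censors at the grid boundary ...
  coh2 <- data.frame(participant_id = "x", condition = "healthy",
                     reported_belief = 0.5)
  f2 <- fit_bias(coh2, "individual", control = ctl)
  expect_identical(unname(coef(f2)$healthy), 1)
  # ... but sits in the interior of the extended grid
  f3 <- fit_bias(coh2, "individual",
                 control = fit_control(seed = 4, extended = TRUE))
  expect_gt(unname(coef(f3)$healthy), 1)
  expect_lt(unname(coef(f3)$healthy), 2)
})

test_that("the bootstrap is reproducible with sane degenerate behaviour", {
  cohd <- data.frame(participant_id = sprintf("p%02d", 1:12),
                     condition = "healthy",
                     reported_belief = rep(0.1, 12))
  ctl <- fit_control(seed = 6, n_sim = 25, boot_b = 30L)
  fit <- fit_bias(cohd, "group", control = ctl, conditions = "healthy")
  bt <- bootstrap_bias(fit)
  # identical participants: every resample refits to the same point
  expect_identical(bt$results$healthy$ci_low, bt$results$healthy$ci_high)
  expect_identical(bt$results$healthy$median, coef(fit)[["healthy"]])
  bt2 <- bootstrap_bias(fit)
  expect_identical(bt$results$healthy$stats, bt2$results$healthy$stats)
  b1 <- bootstrap_bias(fit, B = 1L)
  expect_identical(b1$results$healthy$ci_low, b1$results$healthy$median)
  expect_identical(b1$results$healthy$ci_high, b1$results$healthy$median)
})

test_that("the fit object's methods are coherent", {
  coh <- generate_cohort(cohort_config(n_per_condition = 12, seed = 2))
  ctl <- fit_control(seed = 2, n_sim = 25, n_orders = 10, boot_b = 20L)
  fit <- fit_bias(coh, "individual", control = ctl)
  expect_output(print(fit), "individual")
  s <- summary(fit)
  expect_s3_class(s, "summary.bias_fit")
  expect_identical(nrow(s$table), 3L)
  expect_output(print(s), "sd_ratio")
  ci <- confint(fit)
  expect_true(all(ci[, 2] <= ci[, 1] & ci[, 1] <= ci[, 3]))
  pr <- predict(fit)
  expect_named(pr, c("healthy", "unhealthy", "balanced"))
  res <- residuals(fit)
  expect_equal(unname(res$healthy),
               fit$fits$healthy$observed - fit$fits$healthy$sim)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_identical(nrow(sims[[1]]), nrow(coh))
  grDevices::pdf(NULL); plot(fit); grDevices::dev.off()
  pv <- predict(fit, env_builder = validation_environment,
                mode = "sampled_individual")
  expect_length(pv$healthy, 12L)
  expect_true(all(abs(pv$healthy) <= 1))
})
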