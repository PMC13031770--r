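#' @title Bias-strength calibration
#' @description Estimate the bias strength at group level (one beta per
#'   condition, matching the distribution of reported beliefs) and at
#'   individual level (one beta per participant, matching each report) by
#'   grid search on mean-absolute-error and Kolmogorov-Smirnov objectives.
#' @name calibration
NULL

#' Quantile-paired mean absolute error between two samples
#'
#' Measures distributional mismatch: both samples are sorted, the simulated
#' sample's quantile function is resampled at the observed sample's plotting
#' positions, and the mean absolute difference is returned. For equal sample
#' sizes this reduces to the mean absolute difference of sorted values, so
#' two samples containing the same values in any order have error 0.
#'
#' @param observed,simulated Non-empty numeric vectors.
#' @return Non-negative scalar.
#' @examples
#' mae_quantile(c(0, 1), c(1, 0)) # 0
#' @export
mae_quantile <- function(observed, simulated) {
  n <- length(observed)
  if (n < 1L || length(simulated) < 1L) stop("empty input", call. = FALSE)
  probs <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  qs <- stats::quantile(simulated, probs, names = FALSE, type = 7)
  mean(abs(sort(observed) - qs))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the two empirical cumulative distribution
#' functions, evaluated exactly over the pooled support (ties allowed).
#'
#' @param a,b Non-empty numeric vectors.
#' @return Scalar in \[0, 1\].
#' @examples
#' ks_stat(c(0, 1), c(0.5, 1)) # 0.5
#' @export
ks_stat <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("empty input", call. = FALSE)
  a <- sort(a); b <- sort(b)
  z <- c(a, b)
  max(abs(findInterval(z, a) / length(a) - findInterval(z, b) / length(b)))
}

# ks_stat for pre-sorted inputs (bootstrap hot path).
ks_sorted <- function(a, b) {
  z <- c(a, b)
  max(abs(findInterval(z, a) / length(a) - findInterval(z, b) / length(b)))
}

#' Ratio of empirical to simulated standard deviation
#'
#' A value of 1 means the model reproduces the variability of the empirical
#' beliefs in full; large values mean the simulated distribution is too
#' narrow.
#'
#' @param empirical,simulated Numeric vectors with at least two elements.
#' @return `sd(empirical) / sd(simulated)`; `Inf` with a warning when the
#'   simulated sample is constant.
#' @examples
#' sd_ratio(c(-0.19, 0.19), c(-0.05, 0.05)) # 3.8
#' @export
sd_ratio <- function(empirical, simulated) {
  if (length(empirical) < 2L || length(simulated) < 2L)
    stop("both samples need at least two elements", call. = FALSE)
  s <- stats::sd(simulated)
  if (s == 0) {
    warning("simulated standard deviation is zero; ratio is infinite")
    return(Inf)
  }
  stats::sd(empirical) / s
}

#' Calibration settings
#'
#' @param beta_grid Ordered candidate bias strengths; defaults to
#'   `seq(0, 1, by = step)`, or `seq(-1, 2, by = step)` when
#'   `extended = TRUE` (sensitivity range allowing bias strengths below 0 or
#'   above 1).
#' @param extended Use the extended grid.
#' @param step Grid step, default 0.01.
#' @param alpha Learning rate used for fitting.
#' @param alpha_grid Learning rates for stability checks.
#' @param n_sim Simulated agents per group-level objective evaluation.
#' @param n_orders Presentation orders averaged into a participant's
#'   predicted belief (makes the individual objective deterministic and
#'   smooth).
#' @param boot_b Bootstrap resamples, default 1000.
#' @param ci_level Confidence level for percentile intervals.
#' @param seed Master seed for all fitting randomness.
#' @param lambda Pseudocontingency scaling constant.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(beta_grid = NULL, extended = FALSE, step = 0.01,
                        alpha = 0.5, alpha_grid = c(0.25, 0.5, 0.75, 1),
                        n_sim = 100L, n_orders = 25L, boot_b = 1000L,
                        ci_level = 0.95, seed = 1L, lambda = 4) {
  if (is.null(beta_grid))
    beta_grid <- if (extended) seq(-1, 2, by = step) else seq(0, 1, by = step)
  if (length(beta_grid) < 1L || is.unsorted(beta_grid))
    stop("beta_grid must be a non-empty sorted vector", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1, n_sim >= 1L, n_orders >= 1L, boot_b >= 1L,
            ci_level > 0, ci_level < 1)
  structure(list(beta_grid = beta_grid, alpha = alpha, alpha_grid = alpha_grid,
                 n_sim = as.integer(n_sim), n_orders = as.integer(n_orders),
                 boot_b = as.integer(boot_b), ci_level = ci_level,
                 seed = seed, lambda = lambda),
            class = "fit_control")
}

# Stable per-condition seed, independent of which conditions are being fit.
condition_seed <- function(seed, condition, salt = 0L) {
  if (is.null(seed)) return(NULL)
  idx <- match(condition, pc_conditions)
  if (is.na(idx)) idx <- 4L
  child_seeds(seed, 20L)[[idx + 3L * salt]]
}

# Per-agent (b0, b1) endpoint matrix for a simulated population.
population_endpoints <- function(condition, env_builder, control, seed) {
  seeds <- child_seeds(seed, control$n_sim)
  t(vapply(seq_len(control$n_sim), function(i) {
    env <- env_builder(condition, seed = seeds[[i]])
    env_endpoints(env, control$alpha, lambda = control$lambda)
  }, numeric(2L)))
}

# Group-level MAE/KS objective along the beta grid, given observed beliefs
# and the per-agent endpoints (final beliefs are linear in beta, so the same
# simulated population serves every grid point).
group_curve <- function(observed, endpoints, grid) {
  obs_sorted <- sort(observed)
  mae <- ks <- numeric(length(grid))
  for (g in seq_along(grid)) {
    sim <- sort((1 - grid[g]) * endpoints[, 1L] + grid[g] * endpoints[, 2L])
    probs <- if (length(observed) == 1L) 0.5
             else (seq_along(observed) - 1) / (length(observed) - 1)
    mae[g] <- mean(abs(obs_sorted - stats::quantile(sim, probs, names = FALSE,
                                                    type = 7)))
    ks[g] <- ks_sorted(obs_sorted, sim)
  }
  data.frame(beta = grid, mae = mae, ks = ks, objective = mae + ks)
}

#' Fit bias strengths to a cohort
#'
#' The central calibration routine. At `level = "group"` one bias strength
#' per condition is chosen on the grid to minimise the sum of the
#' quantile-paired mean absolute error and the Kolmogorov-Smirnov statistic
#' between the cohort's reported beliefs and a simulated population of
#' `n_sim` agents; ties go to the smallest bias strength (conservative
#' towards actual-contingency use). At `level = "individual"` each
#' participant gets the grid value minimising the absolute difference
#' between their report and the model prediction, where the prediction at a
#' given bias strength is the mean final belief over `n_orders` seeded
#' presentation orders.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]): columns `participant_id`, `condition`,
#'   `reported_belief`.
#' @param level `"group"` or `"individual"`.
#' @param env_builder Environment constructor for the condition being fit.
#' @param control A [fit_control()].
#' @param conditions Conditions to fit; default all present in the cohort.
#' @return An object of class `"bias_fit"` with methods `print`, `summary`,
#'   `coef`, `confint`, `predict`, `simulate`, `residuals` and `plot`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_condition = 10, seed = 1))
#' fit <- fit_bias(cohort, "group", control = fit_control(n_sim = 20))
#' coef(fit)
#' @export
fit_bias <- function(cohort, level = c("group", "individual"),
                     env_builder = calibration_environment,
                     control = fit_control(), conditions = NULL) {
  level <- match.arg(level)
  stopifnot(is.data.frame(cohort),
            all(c("participant_id", "condition", "reported_belief") %in%
                  names(cohort)))
  if (is.null(conditions)) {
    conditions <- intersect(pc_conditions, unique(cohort$condition))
    if (length(conditions) == 0L) conditions <- unique(cohort$condition)
  }
  grid <- control$beta_grid
  fits <- lapply(conditions, function(cond) {
    rows <- cohort$condition == cond
    r <- cohort$reported_belief[rows]
    ids <- cohort$participant_id[rows]
    if (length(r) < 1L) stop("no participants in condition ", cond, call. = FALSE)
    if (level == "group") {
      if (length(r) < 2L) stop("group-level fit needs >= 2 participants", call. = FALSE)
      eps <- population_endpoints(cond, env_builder, control,
                                  condition_seed(control$seed, cond))
      curve <- group_curve(r, eps, grid)
      best <- which.min(curve$objective) # first minimum = smallest beta
      beta_hat <- grid[best]
      sim <- (1 - beta_hat) * eps[, 1L] + beta_hat * eps[, 2L]
      list(condition = cond, n = length(r), observed = r, ids = ids,
           beta_hat = beta_hat, estimate = beta_hat,
           mae = curve$mae[best], ks = curve$ks[best],
           objective = curve$objective[best], curve = curve,
           endpoints = eps, sim = sim,
           sd_emp = stats::sd(r), sd_sim = stats::sd(sim))
    } else {
      oseeds <- child_seeds(condition_seed(control$seed, cond, salt = 1L),
                            control$n_orders)
      ep <- vapply(seq_len(control$n_orders), function(k) {
        env <- env_builder(cond, seed = oseeds[[k]])
        env_endpoints(env, control$alpha, lambda = control$lambda)
      }, numeric(2L))
      m0 <- mean(ep[1L, ]); m1 <- mean(ep[2L, ])
      pred_grid <- (1 - grid) * m0 + grid * m1
      err <- abs(outer(r, pred_grid, "-"))
      beta_i <- grid[apply(err, 1L, which.min)] # first minimum = smallest beta
      names(beta_i) <- ids
      pred_i <- (1 - beta_i) * m0 + beta_i * m1
      list(condition = cond, n = length(r), observed = r, ids = ids,
           beta_hat = beta_i, estimate = stats::median(beta_i),
           mae = mean(abs(pred_i - r)),
           ks = if (length(r) >= 1L) ks_stat(r, pred_i) else NA_real_,
           objective = NA_real_,
           pred_endpoints = c(m0 = m0, m1 = m1), sim = unname(pred_i),
           sd_emp = if (length(r) >= 2L) stats::sd(r) else NA_real_,
           sd_sim = if (length(r) >= 2L) stats::sd(pred_i) else NA_real_)
    }
  })
  names(fits) <- conditions
  structure(list(level = level, conditions = conditions, fits = fits,
                 control = control, env_builder = env_builder,
                 call = match.call()),
            class = "bias_fit")
}

#' Bootstrap medians and percentile confidence intervals
#'
#' Resamples participants with replacement within each condition and refits
#' the summary statistic per resample: the group-level bias strength (grid
#' argmin of MAE + KS against the fixed simulated population) or the median
#' of the individual bias strengths. Returns the median of the bootstrap
#' statistics and equal-tail percentile bounds.
#'
#' @param fit A `"bias_fit"`.
#' @param B Number of bootstrap resamples.
#' @param seed Seed for the resampling.
#' @param ci_level Confidence level.
#' @return An object of class `"bias_boot"`: per condition the bootstrap
#'   distribution, its median, and the confidence bounds.
#' @export
bootstrap_bias <- function(fit, B = fit$control$boot_b,
                           seed = fit$control$seed,
                           ci_level = fit$control$ci_level) {
  stopifnot(inherits(fit, "bias_fit"), B >= 1L)
  grid <- fit$control$beta_grid
  pl <- (1 - ci_level) / 2
  out <- lapply(fit$fits, function(f) {
    n <- f$n
    stats_b <- if (fit$level == "group") {
      eps <- f$endpoints
      sim_sorted <- lapply(grid, function(b) sort((1 - b) * eps[, 1L] + b * eps[, 2L]))
      probs <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
      qmat <- vapply(sim_sorted, function(s)
        stats::quantile(s, probs, names = FALSE, type = 7), numeric(n))
      with_seed(condition_seed(seed, f$condition, salt = 2L), {
        vapply(seq_len(B), function(b) {
          rs <- sort(f$observed[sample.int(n, n, replace = TRUE)])
          mae <- colMeans(abs(rs - qmat))
          ks <- vapply(sim_sorted, function(s) ks_sorted(rs, s), numeric(1L))
          grid[which.min(mae + ks)]
        }, numeric(1L))
      })
    } else {
      with_seed(condition_seed(seed, f$condition, salt = 2L), {
        vapply(seq_len(B), function(b)
          stats::median(f$beta_hat[sample.int(n, n, replace = TRUE)]),
          numeric(1L))
      })
    }
    qs <- stats::quantile(stats_b, c(pl, 1 - pl), names = FALSE, type = 7)
    list(condition = f$condition, stats = stats_b,
         median = stats::median(stats_b), ci_low = qs[1L], ci_high = qs[2L])
  })
  structure(list(level = fit$level, results = out, B = B,
                 ci_level = ci_level, seed = seed),
            class = "bias_boot")
}

#' @export
print.bias_boot <- function(x, ...) {
  cat("Bootstrap of ", x$level, "-level bias strength (B = ", x$B, ", ",
      round(100 * x$ci_level), "% percentile CI)\n", sep = "")
  for (res in x$results)
    cat(sprintf("  %-10s median %.2f, CI [%.2f, %.2f]\n", res$condition,
                res$median, res$ci_low, res$ci_high))
  invisible(x)
}
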