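#' @export
print.bias_fit <- function(x, digits = 3, ...) {
  cat("Pseudocontingency bias-strength fit (", x$level, " level)\n", sep = "")
  for (f in x$fits) {
    est <- if (x$level == "group") sprintf("beta = %.*f", digits, f$beta_hat)
           else sprintf("median beta_i = %.*f (n = %d)", digits, f$estimate, f$n)
    cat(sprintf("  %-10s %s   MAE = %.*f  KS = %.*f\n", f$condition, est,
                digits, f$mae, digits, f$ks))
  }
  invisible(x)
}

#' @export
summary.bias_fit <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f) {
    data.frame(condition = f$condition, level = object$level, n = f$n,
               estimate = f$estimate, mae = f$mae, ks = f$ks,
               sd_emp = f$sd_emp, sd_sim = f$sd_sim,
               sd_ratio = if (!is.na(f$sd_sim) && f$sd_sim > 0)
                 f$sd_emp / f$sd_sim else Inf,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, level = object$level,
                 grid_range = range(object$control$beta_grid)),
            class = "summary.bias_fit")
}

#' @export
print.summary.bias_fit <- function(x, digits = 3, ...) {
  cat("Bias-strength calibration, ", x$level, " level (grid ",
      x$grid_range[1L], "..", x$grid_range[2L], ")\n", sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bias_fit <- function(object, ...) {
  if (object$level == "group") {
    vapply(object$fits, function(f) f$beta_hat, numeric(1L))
  } else {
    lapply(object$fits, function(f) f$beta_hat)
  }
}

#' Bootstrap percentile confidence intervals for fitted bias strengths
#'
#' Runs [bootstrap_bias()] and returns one row per condition with the
#' bootstrap median and the equal-tail percentile bounds.
#'
#' @param object A `"bias_fit"`.
#' @param parm Conditions to include (default all).
#' @param level Confidence level.
#' @param B Bootstrap resamples.
#' @param seed Resampling seed.
#' @param ... Unused.
#' @return A matrix with columns `median`, lower and upper bounds; the full
#'   `"bias_boot"` object is attached as attribute `"boot"`.
#' @export
confint.bias_fit <- function(object, parm = NULL, level = 0.95,
                             B = object$control$boot_b,
                             seed = object$control$seed, ...) {
  boot <- bootstrap_bias(object, B = B, seed = seed, ci_level = level)
  res <- boot$results
  if (!is.null(parm)) res <- res[intersect(parm, names(res))]
  out <- t(vapply(res, function(r) c(r$median, r$ci_low, r$ci_high),
                  numeric(3L)))
  colnames(out) <- c("median", sprintf("%.1f %%", 100 * (1 - level) / 2),
                     sprintf("%.1f %%", 100 * (1 - (1 - level) / 2)))
  attr(out, "boot") <- boot
  out
}

#' Model-predicted belief distributions from a fit
#'
#' With the default `env_builder = NULL` the in-sample simulated beliefs are
#' returned (group level: the simulated population at the fitted bias
#' strength; individual level: each participant's predicted belief at their
#' fitted bias strength). Supplying an environment builder simulates the
#' fitted parameters in a new environment — the cross-experiment validation
#' use — either with the group estimate for all agents, or with bias
#' strengths resampled with replacement from the fitted individual pool
#' (`mode = "sampled_individual"`, only for individual-level fits).
#'
#' @param object A `"bias_fit"`.
#' @param env_builder Optional environment constructor for out-of-sample
#'   prediction, e.g. [validation_environment].
#' @param mode `"group"` or `"sampled_individual"` (out-of-sample only).
#' @param n_agents Agents per condition for out-of-sample simulation.
#' @param seed Seed for out-of-sample simulation.
#' @param ... Unused.
#' @return Named list (per condition) of numeric belief vectors.
#' @export
predict.bias_fit <- function(object, env_builder = NULL,
                             mode = c("group", "sampled_individual"),
                             n_agents = NULL, seed = object$control$seed, ...) {
  if (is.null(env_builder))
    return(lapply(object$fits, function(f) f$sim))
  mode <- match.arg(mode)
  if (mode == "sampled_individual" && object$level != "individual")
    stop("sampled_individual prediction requires an individual-level fit",
         call. = FALSE)
  out <- lapply(object$fits, function(f) {
    n <- if (is.null(n_agents)) f$n else n_agents
    s <- condition_seed(seed, f$condition, salt = 2L)
    beta <- if (mode == "group") {
      if (object$level == "group") f$beta_hat else f$estimate
    } else {
      with_seed(s, sample(f$beta_hat, n, replace = TRUE))
    }
    as.numeric(simulate_population(f$condition, n, beta = beta,
                                   alpha = object$control$alpha, seed = s,
                                   env_builder = env_builder,
                                   lambda = object$control$lambda))
  })
  out
}

#' Simulate cohorts from a fitted model
#'
#' Draws `nsim` synthetic cohorts at the fitted bias strengths (the model
#' has no fitted noise term, so reports equal model beliefs).
#'
#' @param object A `"bias_fit"`.
#' @param nsim Number of cohorts.
#' @param seed Master seed.
#' @param ... Unused.
#' @return List of `nsim` data frames (`participant_id`, `condition`,
#'   `reported_belief`).
#' @export
simulate.bias_fit <- function(object, nsim = 1, seed = object$control$seed, ...) {
  seeds <- child_seeds(seed, nsim)
  lapply(seq_len(nsim), function(s) {
    parts <- lapply(object$fits, function(f) {
      beta <- if (object$level == "group") f$beta_hat else unname(f$beta_hat)
      beliefs <- simulate_population(f$condition, f$n, beta = beta,
                                     alpha = object$control$alpha,
                                     seed = seeds[[s]],
                                     env_builder = object$env_builder,
                                     lambda = object$control$lambda)
      data.frame(participant_id = sprintf("%s_%03d", f$condition, seq_len(f$n)),
                 condition = f$condition,
                 reported_belief = as.numeric(beliefs),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' @export
residuals.bias_fit <- function(object, ...) {
  lapply(object$fits, function(f) {
    if (object$level == "individual") {
      stats::setNames(f$observed - f$sim, f$ids)
    } else {
      # quantile residuals: sorted observations minus matched sim quantiles
      n <- f$n
      probs <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
      sort(f$observed) - stats::quantile(f$sim, probs, names = FALSE, type = 7)
    }
  })
}

#' Plot empirical against simulated belief distributions
#'
#' One panel per condition: histogram of reported beliefs with the
#' model-simulated beliefs overlaid, annotated with both standard
#' deviations.
#'
#' @param x A `"bias_fit"`.
#' @param breaks Histogram breaks over \[-1, 1\].
#' @param ... Passed to [graphics::hist()].
#' @export
plot.bias_fit <- function(x, breaks = seq(-1, 1, by = 0.1), ...) {
  old <- graphics::par(mfrow = c(1, length(x$fits)))
  on.exit(graphics::par(old))
  for (f in x$fits) {
    graphics::hist(f$observed, breaks = breaks, col = "#4477aa80",
                   border = NA, freq = FALSE, xlab = "reported belief",
                   main = sprintf("%s (SD emp %.2f / sim %.2f)", f$condition,
                                  f$sd_emp, f$sd_sim), ...)
    graphics::hist(f$sim, breaks = breaks, col = "#cc333380", border = NA,
                   freq = FALSE, add = TRUE)
  }
  invisible(x)
}
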