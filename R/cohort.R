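#' @title Synthetic cohorts
#' @description Generate participants with known ground-truth bias strengths
#'   and reporting noise, emulating the statistical structure of the
#'   calibration and validation studies, so the whole calibration pipeline is
#'   testable without the deposited experimental data.
#' @name synthetic-cohort
NULL

#' Bias-strength samplers
#'
#' Named families for the distribution of ground-truth bias strengths across
#' a cohort. The default cohort family, `bias_mixture()`, is concentrated
#' near 1 (a Beta spike with mode 0.95) with a long lower tail (a uniform
#' component over \[0, 1\]), matching the empirically reported shape of
#' fitted individual bias strengths: a majority clustered near 0.9-1 plus
#' substantial spread below.
#'
#' @param spike_shape1,spike_shape2 Beta parameters of the spike component
#'   (defaults give mode 0.95).
#' @param spike_weight Mixture weight of the spike component.
#' @return A sampler `function(n)` returning `n` draws in \[0, 1\].
#' @examples
#' set.seed(1); summary(bias_mixture()(1000))
#' @export
bias_mixture <- function(spike_shape1 = 10.5, spike_shape2 = 1.5,
                         spike_weight = 0.5) {
  stopifnot(spike_shape1 > 0, spike_shape2 > 0,
            spike_weight >= 0, spike_weight <= 1)
  function(n) {
    spike <- stats::runif(n) < spike_weight
    ifelse(spike, stats::rbeta(n, spike_shape1, spike_shape2), stats::runif(n))
  }
}

#' @rdname bias_mixture
#' @param beta Fixed bias strength for a homogeneous cohort.
#' @export
bias_constant <- function(beta) {
  force(beta)
  function(n) rep(beta, n)
}

#' @rdname bias_mixture
#' @param min,max Range of the uniform stress-test family.
#' @export
bias_uniform <- function(min = 0, max = 1) {
  function(n) stats::runif(n, min, max)
}

#' Configuration of a synthetic cohort
#'
#' Defaults reproduce the calibration study's scale: 52 participants per
#' condition (156 over three conditions), one pass through a 24-meal
#' two-context environment each, heterogeneous bias strengths from
#' [bias_mixture()], and additive Gaussian reporting noise on the belief
#' scale, clipped to \[-1, 1\]. The default `noise_sd = 0.09` is set so the
#' simulated healthy-condition cohort's belief standard deviation matches the
#' empirically reported 0.19.
#'
#' @param n_per_condition Participants per condition.
#' @param conditions Condition labels to generate.
#' @param bias_sampler `function(n)` drawing ground-truth bias strengths.
#' @param noise_sd Reporting-noise standard deviation (>= 0) on the \[-1, 1\]
#'   belief scale.
#' @param alpha Learning rate shared by all agents.
#' @param seed Master seed.
#' @param env_builder Environment constructor, `calibration_environment` by
#'   default.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_condition = 52L,
                          conditions = c("healthy", "unhealthy", "balanced"),
                          bias_sampler = bias_mixture(),
                          noise_sd = 0.09,
                          alpha = 0.5,
                          seed = 1L,
                          env_builder = calibration_environment) {
  stopifnot(n_per_condition >= 1L, noise_sd >= 0, is.function(bias_sampler),
            alpha > 0, alpha <= 1)
  structure(list(n_per_condition = as.integer(n_per_condition),
                 conditions = conditions, bias_sampler = bias_sampler,
                 noise_sd = noise_sd, alpha = alpha, seed = seed,
                 env_builder = env_builder),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' For each participant: draw a ground-truth bias strength, simulate one pass
#' through that participant's own shuffled environment, add independent
#' zero-mean Gaussian reporting noise, and clip the report to \[-1, 1\].
#'
#' @param config A [cohort_config()].
#' @return A data frame of class `"pc_cohort"` with columns
#'   `participant_id`, `condition`, `reported_belief`, `true_beta`, and the
#'   generating config in attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_condition = 5, seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cond_seeds <- child_seeds(config$seed, length(config$conditions))
  out <- lapply(seq_along(config$conditions), function(ci) {
    cond <- config$conditions[ci]
    n <- config$n_per_condition
    seeds <- child_seeds(cond_seeds[[ci]], 2L)
    beliefs <- simulate_population(cond, n, beta = config$bias_sampler,
                                   alpha = config$alpha, seed = seeds[[1L]],
                                   env_builder = config$env_builder)
    noise <- with_seed(seeds[[2L]], stats::rnorm(n, 0, config$noise_sd))
    data.frame(participant_id = sprintf("%s_%03d", cond, seq_len(n)),
               condition = cond,
               reported_belief = clip1(as.numeric(beliefs) + noise),
               true_beta = attr(beliefs, "beta"),
               stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  attr(cohort, "config") <- config
  class(cohort) <- c("pc_cohort", "data.frame")
  cohort
}

#' Write / read a cohort file
#'
#' Delimited text with `# key=value` header comments recording the reporting
#' scale and generator settings, then CSV columns
#' `participant_id,condition,reported_belief[,true_beta]`. Beliefs are on the
#' \[-1, 1\] scale; empirical exports, which lack a ground truth, load with
#' `true_beta` absent (`NA`).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   validated cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  cfg <- attr(cohort, "config")
  header <- c("# scale=belief in [-1,1] (identity mapping)",
              if (!is.null(cfg)) c(
                paste0("# n_per_condition=", cfg$n_per_condition),
                paste0("# noise_sd=", cfg$noise_sd),
                paste0("# alpha=", cfg$alpha),
                paste0("# seed=", cfg$seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "reported_belief")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort file '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(df$condition %in% pc_conditions))
    stop("cohort file '", path, "' has unknown condition label(s): ",
         paste(unique(setdiff(df$condition, pc_conditions)), collapse = ", "),
         call. = FALSE)
  if (anyNA(df$reported_belief) || any(abs(df$reported_belief) > 1))
    stop("reported_belief must lie in [-1, 1]", call. = FALSE)
  if (is.null(df$true_beta)) df$true_beta <- NA_real_
  class(df) <- c("pc_cohort", "data.frame")
  df
}
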