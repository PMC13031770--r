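#' @title Agent simulation
#' @description Run agents through food environments: sequential per-context
#'   tallying, bias-weighted blending of actual and pseudo contingency, and
#'   exponential smoothing of the running belief.
#' @name simulation
NULL

# Step-wise phi/psi targets for an observation stream. Tallies are scoped per
# context (the within-context design wording), so each step's targets come
# from the cumulative table of that step's own context. During warm-up (any
# margin of the context tally still zero) phi is 0 by convention while psi is
# computed as usual. Vectorised via per-context cumulative sums.
target_series <- function(obs, lambda = 4) {
  n <- nrow(obs)
  phi <- psi <- numeric(n)
  warm <- logical(n)
  for (idx in split(seq_len(n), obs$context)) {
    h <- obs$healthy[idx]; t <- obs$tasty[idx]
    # doubles: cell products in the phi denominator overflow integers on
    # long cycled streams
    cht <- cumsum(as.numeric(h & t)); chn <- cumsum(as.numeric(h & !t))
    cut <- cumsum(as.numeric(!h & t)); cun <- cumsum(as.numeric(!h & !t))
    m <- seq_along(idx)
    psi[idx] <- lambda * ((cht + chn) / m - 0.5) * ((cht + cut) / m - 0.5)
    denom2 <- (cht + chn) * (cut + cun) * (cht + cut) * (chn + cun)
    ok <- denom2 > 0
    phi[idx][ok] <- ((cht * cun - chn * cut)[ok]) / sqrt(denom2[ok])
    warm[idx] <- !ok
  }
  list(phi = phi, psi = psi, warm = warm)
}

# Exponential smoothing of a target series from a zero initial belief:
# b_t = (1 - alpha) b_{t-1} + alpha x_t.
smooth_series <- function(x, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive"))
}

cycle_obs <- function(env, cycles) {
  obs <- env$observations
  if (cycles > 1L) obs <- obs[rep(seq_len(nrow(obs)), cycles), , drop = FALSE]
  obs
}

# Final smoothed beliefs at beta = 0 and beta = 1 for one environment pass.
# Because the momentary blend is linear in beta and smoothing is linear, the
# final belief at any beta is (1 - beta) * b0 + beta * b1 for a fixed
# observation order; fitting routines exploit this identity.
env_endpoints <- function(env, alpha, cycles = 1L, lambda = 4) {
  obs <- cycle_obs(env, cycles)
  ts <- target_series(obs, lambda)
  n <- nrow(obs)
  c(b0 = smooth_series(ts$phi, alpha)[n], b1 = smooth_series(ts$psi, alpha)[n])
}

#' Simulate one agent through an environment
#'
#' Processes the environment's observation stream in order. After each food
#' the agent updates the current context's tally, computes the actual
#' contingency (phi) and the pseudocontingency effect (psi) from that tally,
#' blends them with bias strength `beta`, and folds the blend into the
#' running belief by exponential smoothing (initial belief 0).
#'
#' @param env A `"pc_env"` environment.
#' @param beta Bias strength (weight on the pseudocontingency).
#' @param alpha Learning rate in (0, 1].
#' @param cycles Number of times the stream is repeated; 1 (single pass)
#'   emulates the experiments, larger values expose the long-run dynamics.
#' @param lambda Pseudocontingency scaling constant, default 4.
#' @return A list with `trajectory` (data frame: `t`, `context`, `phi`,
#'   `psi`, `phi_hat`, `belief`, `warm`) and `final_belief`.
#' @examples
#' sim <- simulate_agent(calibration_environment("healthy", seed = 1),
#'                       beta = 1, alpha = 0.5)
#' sim$final_belief
#' @export
simulate_agent <- function(env, beta, alpha, cycles = 1L, lambda = 4) {
  stopifnot(inherits(env, "pc_env"), nrow(env$observations) >= 1L)
  obs <- cycle_obs(env, cycles)
  ts <- target_series(obs, lambda)
  phi_hat <- blend_belief(ts$phi, ts$psi, beta)
  belief <- smooth_series(phi_hat, alpha)
  traj <- data.frame(t = seq_len(nrow(obs)), context = obs$context,
                     phi = ts$phi, psi = ts$psi, phi_hat = phi_hat,
                     belief = belief, warm = ts$warm,
                     stringsAsFactors = FALSE)
  class(traj) <- c("belief_trajectory", "data.frame")
  list(trajectory = traj, final_belief = belief[length(belief)])
}

#' Create a fresh agent and feed it single observations
#'
#' Step-wise counterpart of [simulate_agent()] for incremental use: an agent
#' carries its bias strength, learning rate, per-context tallies, and the
#' current smoothed belief.
#'
#' @param beta Bias strength.
#' @param alpha Learning rate in (0, 1].
#' @param lambda Pseudocontingency scaling constant.
#' @return An `"agent_state"` object.
#' @export
agent_state <- function(beta, alpha, lambda = 4) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(beta = beta, alpha = alpha, lambda = lambda,
                 tallies = list(), belief = 0, t = 0L),
            class = "agent_state")
}

#' @rdname agent_state
#' @param state An `"agent_state"`.
#' @param context Context identifier of the observed food.
#' @param healthy,tasty Logical/0-1 attributes of the observed food.
#' @return `observe()` returns the updated `"agent_state"`.
#' @export
observe <- function(state, context, healthy, tasty) {
  stopifnot(inherits(state, "agent_state"))
  tab <- state$tallies[[context]]
  if (is.null(tab)) tab <- contingency_table(0, 0, 0, 0)
  cell <- if (healthy) { if (tasty) "ht" else "hn" } else { if (tasty) "ut" else "un" }
  tab[cell] <- tab[cell] + 1L
  state$tallies[[context]] <- tab
  psi <- pseudocontingency(skews(marginals(tab)), state$lambda)
  phi <- phi_coef(tab)
  state$belief <- smooth_update(state$belief,
                                blend_belief(phi, psi, state$beta),
                                state$alpha)
  state$t <- state$t + 1L
  state
}

#' Simulate a population of agents
#'
#' Each agent receives its own presentation order (a child seed derived from
#' `seed` by a fixed counter scheme) and one value of the bias strength.
#'
#' @param condition Condition label passed to `env_builder`.
#' @param n_agents Number of agents.
#' @param beta A single bias strength, a vector of length `n_agents`, or a
#'   sampler `function(n)` drawing bias strengths.
#' @param alpha Learning rate.
#' @param seed Master seed; per-agent environment seeds and the `beta`
#'   sampler draw are derived from it.
#' @param env_builder Environment constructor, called as
#'   `env_builder(condition, seed = <child seed>)`.
#' @param cycles Stream repetitions per agent.
#' @param lambda Pseudocontingency scaling constant.
#' @return Numeric vector of final beliefs, with the realised bias strengths
#'   in attribute `"beta"`.
#' @examples
#' simulate_population("balanced", 5, beta = 0, alpha = 0.5, seed = 1)
#' @export
simulate_population <- function(condition, n_agents, beta, alpha = 0.5,
                                seed = NULL,
                                env_builder = calibration_environment,
                                cycles = 1L, lambda = 4) {
  stopifnot(n_agents >= 1L)
  seeds <- child_seeds(seed, n_agents + 1L)
  betas <- if (is.function(beta)) with_seed(seeds[[n_agents + 1L]], beta(n_agents))
           else if (length(beta) == 1L) rep(as.numeric(beta), n_agents)
           else as.numeric(beta)
  if (length(betas) != n_agents)
    stop("beta must be length 1, length n_agents, or a sampler function", call. = FALSE)
  beliefs <- vapply(seq_len(n_agents), function(i) {
    env <- env_builder(condition, seed = seeds[[i]])
    ep <- env_endpoints(env, alpha, cycles, lambda)
    (1 - betas[i]) * ep[["b0"]] + betas[i] * ep[["b1"]]
  }, numeric(1L))
  attr(beliefs, "beta") <- betas
  beliefs
}

#' Steps until a trajectory settles at its final belief
#'
#' Returns the number of steps after which the belief stays within `tol` of
#' its final value for the rest of the trajectory (0 if it never leaves that
#' band).
#'
#' @param traj A trajectory from [simulate_agent()], or a numeric belief
#'   series.
#' @param tol Positive tolerance.
#' @return Integer step count.
#' @export
time_to_equilibrium <- function(traj, tol) {
  stopifnot(tol > 0)
  b <- if (is.data.frame(traj)) traj$belief else as.numeric(traj)
  dev <- abs(b - b[length(b)])
  viol <- which(dev > tol)
  if (length(viol) == 0L) 0L else max(viol)
}

#' One-step belief dynamics over a grid (phase-space vector field)
#'
#' For each belief value `b` on the grid, the one-step displacement towards
#' the environment's asymptotic momentary belief `phi_hat_star` is
#' `alpha * (phi_hat_star - b)`; `phi_hat_star` is the bias-weighted blend
#' evaluated on the complete per-context design tables (averaged over
#' contexts). The constant column `inference_error` is
#' `|phi_hat_star - phi|`, the distance of the fixed point from perfect
#' inference; it is 0 when `beta = 0`.
#'
#' @param env A `"pc_env"` environment.
#' @param beta Bias strength.
#' @param alpha Learning rate.
#' @param grid Belief values in \[-1, 1\].
#' @param lambda Pseudocontingency scaling constant.
#' @return Data frame with `belief`, `displacement`, `inference_error`.
#' @examples
#' vf <- vector_field(calibration_environment("healthy", seed = 1),
#'                    beta = 1, alpha = 0.5)
#' unique(vf$inference_error) # 7/12
#' @export
vector_field <- function(env, beta, alpha, grid = seq(-1, 1, by = 0.1),
                         lambda = 4) {
  stopifnot(inherits(env, "pc_env"), all(abs(grid) <= 1))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  phis <- vapply(env$contexts, phi_coef, numeric(1L))
  psis <- vapply(env$contexts, function(tab)
    pseudocontingency(skews(marginals(tab)), lambda), numeric(1L))
  phi_star <- mean(blend_belief(phis, psis, beta))
  phi_env <- mean(phis)
  data.frame(belief = grid,
             displacement = alpha * (phi_star - grid),
             inference_error = abs(phi_star - phi_env))
}
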