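#' @title Cell-weighting integration model
#' @description Alternative account of contingency judgment in which the
#'   belief integrates evidence from all four cells of the contingency table
#'   with subjective weights: concordant cells (healthy-tasty,
#'   unhealthy-not-tasty) count positively, discordant cells negatively, and
#'   the weighted difference is normalised by the weighted total. Weights are
#'   normalised to sum 1 for identifiability (the belief is invariant to
#'   positive rescaling of the weights).
#' @name integration-model
NULL

normalize_weights <- function(w) {
  w <- as.numeric(w)
  if (length(w) != 4L || anyNA(w) || any(w < 0))
    stop("weights must be four non-negative values (w_ht, w_hn, w_ut, w_un)",
         call. = FALSE)
  if (sum(w) == 0) stop("weights must not all be zero", call. = FALSE)
  stats::setNames(w / sum(w), c("w_ht", "w_hn", "w_ut", "w_un"))
}

#' Cell-weighted integration belief
#'
#' `(w_ht*ht + w_un*un - w_hn*hn - w_ut*ut) / (w_ht*ht + w_hn*hn + w_ut*ut +
#' w_un*un)`, in \[-1, 1\]; 0 by convention when all weighted counts are
#' zero. With equal weights this is the symmetric concordant-minus-discordant
#' evidence balance, which is 0 on any table with `ht + un = hn + ut` — and
#' therefore differs from the phi coefficient (e.g. it is 0 on the
#' healthy-context design table where phi = -1/3).
#'
#' @param table A [contingency_table()] or length-4 count vector.
#' @param w Four non-negative cell weights (normalised internally).
#' @return Scalar belief in \[-1, 1\].
#' @examples
#' integration_belief(contingency_table(6, 3, 3, 0), rep(1, 4)) # 0
#' @export
integration_belief <- function(table, w = rep(1, 4)) {
  cells <- as_table_cells(table)
  if (sum(cells) < 1) stop("empty contingency table: at least one observation required", call. = FALSE)
  w <- normalize_weights(w)
  den <- sum(w * cells)
  if (den == 0) return(0)
  sum(w * cells * c(1, -1, -1, 1)) / den
}

# Per-step cumulative cell counts of the current context's tally, aligned to
# the global observation order (n x 4 matrix, columns ht, hn, ut, un).
cum_cells <- function(obs) {
  n <- nrow(obs)
  out <- matrix(0, n, 4L)
  for (idx in split(seq_len(n), obs$context)) {
    h <- obs$healthy[idx]; t <- obs$tasty[idx]
    out[idx, ] <- cbind(cumsum(as.numeric(h & t)), cumsum(as.numeric(h & !t)),
                        cumsum(as.numeric(!h & t)), cumsum(as.numeric(!h & !t)))
  }
  out
}

#' Simulate one agent under the integration model
#'
#' Same sequential dynamics as [simulate_agent()] — per-context tallies and
#' exponential smoothing from a zero initial belief — but with the
#' cell-weighted integration belief as the momentary target instead of the
#' bias-weighted phi/psi blend.
#'
#' @param env A `"pc_env"` environment.
#' @param w Four cell weights.
#' @param alpha Learning rate in (0, 1].
#' @param cycles Stream repetitions.
#' @return A list with `trajectory` (`t`, `context`, `target`, `belief`) and
#'   `final_belief`.
#' @export
integration_trajectory <- function(env, w = rep(1, 4), alpha = 0.5,
                                   cycles = 1L) {
  stopifnot(inherits(env, "pc_env"))
  w <- normalize_weights(w)
  obs <- cycle_obs(env, cycles)
  cc <- cum_cells(obs)
  den <- as.numeric(cc %*% w)
  num <- as.numeric(cc %*% (w * c(1, -1, -1, 1)))
  target <- ifelse(den > 0, num / den, 0)
  belief <- smooth_series(target, alpha)
  traj <- data.frame(t = seq_len(nrow(obs)), context = obs$context,
                     target = target, belief = belief,
                     stringsAsFactors = FALSE)
  list(trajectory = traj, final_belief = belief[length(belief)])
}

# All weight vectors with components on a simplex lattice of the given step
# (enumerated lexicographically; grid-search ties go to the first candidate).
weights_grid <- function(step = 0.1) {
  s <- round(1 / step)
  g <- expand.grid(i = 0:s, j = 0:s, k = 0:s)
  g$l <- s - g$i - g$j - g$k
  g <- g[g$l >= 0, , drop = FALSE]
  m <- as.matrix(g)[, c("i", "j", "k", "l"), drop = FALSE] / s
  colnames(m) <- c("w_ht", "w_hn", "w_ut", "w_un")
  m
}

#' Fit the integration model to a cohort
#'
#' Grid search over normalised cell weights minimising the same MAE + KS
#' group objective as [fit_bias()], with the same smoothing dynamics. The
#' result is intended for side-by-side comparison with the one-parameter
#' pseudocontingency fit: the integration model spends four parameters
#' (three free after normalisation) where the bias strength spends one.
#'
#' @param cohort A cohort data frame.
#' @param env_builder Environment constructor.
#' @param control A [fit_control()] (supplies `alpha`, `n_sim`, `seed`).
#' @param weight_step Lattice step of the weight grid (0.1 gives 286
#'   candidate weight vectors).
#' @param candidates Optional matrix of candidate weight rows overriding the
#'   lattice.
#' @param conditions Conditions to fit; default all present.
#' @return An object of class `"integration_fit"`: per condition the best
#'   weights, MAE, KS and combined objective.
#' @export
fit_integration <- function(cohort, env_builder = calibration_environment,
                            control = fit_control(), weight_step = 0.1,
                            candidates = NULL, conditions = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(conditions)) {
    conditions <- intersect(pc_conditions, unique(cohort$condition))
    if (length(conditions) == 0L) conditions <- unique(cohort$condition)
  }
  if (is.null(candidates)) candidates <- weights_grid(weight_step)
  candidates <- t(apply(candidates, 1L, normalize_weights))
  sign_vec <- c(1, -1, -1, 1)
  fits <- lapply(conditions, function(cond) {
    r <- cohort$reported_belief[cohort$condition == cond]
    if (length(r) < 2L) stop("integration fit needs >= 2 participants", call. = FALSE)
    seeds <- child_seeds(condition_seed(control$seed, cond), control$n_sim)
    # cumulative cell matrices are weight-independent: precompute per agent
    ccs <- lapply(seq_len(control$n_sim), function(i)
      cum_cells(env_builder(cond, seed = seeds[[i]])$observations))
    obs_sorted <- sort(r)
    probs <- if (length(r) == 1L) 0.5 else (seq_along(r) - 1) / (length(r) - 1)
    evals <- apply(candidates, 1L, function(w) {
      sim <- vapply(ccs, function(cc) {
        den <- as.numeric(cc %*% w)
        num <- as.numeric(cc %*% (w * sign_vec))
        target <- ifelse(den > 0, num / den, 0)
        b <- smooth_series(target, control$alpha)
        b[length(b)]
      }, numeric(1L))
      sim <- sort(sim)
      mae <- mean(abs(obs_sorted - stats::quantile(sim, probs, names = FALSE,
                                                   type = 7)))
      c(mae = mae, ks = ks_sorted(obs_sorted, sim))
    })
    obj <- evals["mae", ] + evals["ks", ]
    best <- which.min(obj)
    list(condition = cond, n = length(r),
         weights = stats::setNames(candidates[best, ],
                                   c("w_ht", "w_hn", "w_ut", "w_un")),
         mae = unname(evals["mae", best]), ks = unname(evals["ks", best]),
         objective = unname(obj[best]), n_candidates = nrow(candidates))
  })
  names(fits) <- conditions
  structure(list(fits = fits, control = control, weight_step = weight_step),
            class = "integration_fit")
}

#' @export
print.integration_fit <- function(x, digits = 3, ...) {
  cat("Integration-model fit (cell weights, grid step ", x$weight_step,
      ")\n", sep = "")
  for (f in x$fits) {
    cat(sprintf("  %-10s MAE = %.*f  KS = %.*f  weights (ht,hn,ut,un) = %s\n",
                f$condition, digits, f$mae, digits, f$ks,
                paste(format(round(f$weights, 2)), collapse = ", ")))
  }
  invisible(x)
}
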