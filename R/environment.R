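#' @title Food environments
#' @description Observation streams that emulate the two experimental designs:
#'   a two-context calibration environment in which within-context base rates
#'   imply a relationship opposite to the actual contingency, and a
#'   single-context validation environment with zero actual contingency but
#'   skewed base rates.
#' @name environments
NULL

pc_conditions <- c("healthy", "unhealthy", "balanced")

# Minimal integer tables consistent with the printed design constraints:
# 24 meals over 2 contexts, per-context phi = -1/3 (healthy) / +1/3
# (unhealthy) / 0 (balanced), with opposing base-rate skews of +/-0.25 per
# context so pooled base rates are neutral. Config-overridable.
default_calibration_tables <- function(condition) {
  switch(condition,
    healthy = list(cafeteria  = contingency_table(6, 3, 3, 0),
                   restaurant = contingency_table(0, 3, 3, 6)),
    unhealthy = list(cafeteria  = contingency_table(3, 6, 0, 3),
                     restaurant = contingency_table(3, 0, 6, 3)),
    balanced = list(cafeteria  = contingency_table(3, 3, 3, 3),
                    restaurant = contingency_table(3, 3, 3, 3)),
    stop("unknown condition: ", condition, call. = FALSE))
}

match_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% pc_conditions)
    stop("condition must be one of ", paste(pc_conditions, collapse = ", "), call. = FALSE)
  condition
}

# One row per observed food, in cell order (shuffling happens later).
expand_table <- function(table, context) {
  cells <- as_table_cells(table)
  data.frame(
    context = context,
    healthy = rep(c(1L, 1L, 0L, 0L), cells),
    tasty   = rep(c(1L, 0L, 1L, 0L), cells),
    stringsAsFactors = FALSE)
}

new_environment <- function(condition, contexts, observations) {
  structure(list(condition = condition,
                 contexts = contexts,
                 observations = observations,
                 n_meals = nrow(observations)),
            class = "pc_env")
}

#' Build a two-context calibration environment
#'
#' Constructs the 24-meal, two-context observation stream of the calibration
#' design. In the `healthy` condition one context holds mostly healthy (and
#' mostly tasty) foods and the other mostly unhealthy (and mostly not-tasty)
#' foods, so within each context the base rates imply a positive health-taste
#' relationship (psi = +0.25) while the actual contingency is negative
#' (phi = -1/3). The `unhealthy` condition mirrors this (psi = -0.25,
#' phi = +1/3); the `balanced` condition has neutral base rates and zero
#' contingency in both contexts.
#'
#' Meals are presented context-blocked: all meals of one context, then the
#' other. The block order and the order within each block are shuffled under
#' `seed`; `interleave = TRUE` instead shuffles the full stream across
#' contexts (sensitivity switch).
#'
#' @param condition One of `"healthy"`, `"unhealthy"`, `"balanced"`.
#' @param seed Integer seed for the presentation-order shuffle, or `NULL` for
#'   the current RNG state.
#' @param tables Optional named list of per-context [contingency_table()]s
#'   overriding the default design.
#' @param interleave Logical; shuffle across contexts instead of blocking.
#' @return A `"pc_env"` object: condition, per-context design tables, and the
#'   ordered observation data frame (`context`, `healthy`, `tasty`).
#' @examples
#' env <- calibration_environment("healthy", seed = 1)
#' sapply(env$contexts, phi_coef)
#' @export
calibration_environment <- function(condition, seed = NULL, tables = NULL,
                                    interleave = FALSE) {
  condition <- match_condition(condition)
  if (is.null(tables)) tables <- default_calibration_tables(condition)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("context tables must be named", call. = FALSE)
  blocks <- lapply(names(tables), function(ctx) expand_table(tables[[ctx]], ctx))
  obs <- with_seed(seed, {
    if (interleave) {
      pooled <- do.call(rbind, blocks)
      pooled[sample.int(nrow(pooled)), , drop = FALSE]
    } else {
      blocks <- blocks[sample.int(length(blocks))]
      do.call(rbind, lapply(blocks, function(b) b[sample.int(nrow(b)), , drop = FALSE]))
    }
  })
  rownames(obs) <- NULL
  new_environment(condition, tables, obs)
}

#' Build a single-context validation environment
#'
#' The validation design has zero actual contingency in every condition
#' (row-proportional tables, so phi = 0 exactly) but skewed base rates in the
#' `healthy` (mostly healthy) and `unhealthy` (mostly unhealthy) conditions.
#' Taste base rates are mildly tasty-skewed in both skewed conditions
#' (`p_tasty = 2/3` by default), so base rates alone imply a positive
#' health-taste relationship in the healthy condition and a negative one in
#' the unhealthy condition, while the true relationship is absent.
#'
#' @param condition One of `"healthy"`, `"unhealthy"`, `"balanced"`.
#' @param n_meals Number of meals; must admit an exact integer
#'   row-proportional table for the requested base rates (and be divisible by
#'   4 in the balanced condition).
#' @param skew_h Health base-rate skew `|p_h - 0.5|` in the skewed
#'   conditions, default 0.25.
#' @param p_tasty Taste base rate; default 2/3 in skewed conditions, 1/2 in
#'   the balanced condition.
#' @param seed Integer seed for the presentation-order shuffle.
#' @return A `"pc_env"` object with a single `"restaurant"` context.
#' @examples
#' env <- validation_environment("healthy", seed = 1)
#' phi_coef(env$contexts$restaurant) # 0
#' @export
validation_environment <- function(condition, n_meals = 24, skew_h = 0.25,
                                   p_tasty = NULL, seed = NULL) {
  condition <- match_condition(condition)
  if (n_meals < 4) stop("n_meals must be at least 4", call. = FALSE)
  p_h <- switch(condition, healthy = 0.5 + skew_h, unhealthy = 0.5 - skew_h,
                balanced = 0.5)
  if (is.null(p_tasty)) p_tasty <- if (condition == "balanced") 0.5 else 2 / 3
  if (condition == "balanced" && n_meals %% 4 != 0)
    stop("n_meals must be divisible by 4 in the balanced condition", call. = FALSE)
  rows <- c(h = n_meals * p_h, u = n_meals * (1 - p_h))
  cells <- c(rows[["h"]] * p_tasty, rows[["h"]] * (1 - p_tasty),
             rows[["u"]] * p_tasty, rows[["u"]] * (1 - p_tasty))
  if (any(abs(cells - round(cells)) > 1e-9))
    stop("infeasible design: n_meals = ", n_meals, " does not yield integer ",
         "cell counts for p_h = ", signif(p_h, 4), ", p_tasty = ",
         signif(p_tasty, 4), call. = FALSE)
  table <- contingency_table(round(cells)[1L], round(cells)[2L],
                             round(cells)[3L], round(cells)[4L])
  obs <- expand_table(table, "restaurant")
  obs <- with_seed(seed, obs[sample.int(nrow(obs)), , drop = FALSE])
  rownames(obs) <- NULL
  new_environment(condition, list(restaurant = table), obs)
}

#' Recover per-context tallies from an observation stream
#'
#' Tallies the full observation stream of an environment back into one
#' contingency table per context; shuffling never changes these tables.
#'
#' @param env A `"pc_env"` object.
#' @return Named list of [contingency_table()]s.
#' @export
tally_observations <- function(env) {
  stopifnot(inherits(env, "pc_env"))
  obs <- env$observations
  out <- lapply(split(obs, obs$context), function(d) {
    contingency_table(sum(d$healthy == 1 & d$tasty == 1),
                      sum(d$healthy == 1 & d$tasty == 0),
                      sum(d$healthy == 0 & d$tasty == 1),
                      sum(d$healthy == 0 & d$tasty == 0))
  })
  out[names(env$contexts)]
}

#' @export
print.pc_env <- function(x, ...) {
  cat("Food environment (", x$condition, " condition): ", x$n_meals,
      " meals, ", length(x$contexts), " context(s)\n", sep = "")
  for (ctx in names(x$contexts)) {
    tab <- x$contexts[[ctx]]
    cat(sprintf("  %-12s phi = %+.3f  psi = %+.3f  (ht=%d hn=%d ut=%d un=%d)\n",
                ctx, phi_coef(tab), pseudocontingency(skews(marginals(tab))),
                tab[1L], tab[2L], tab[3L], tab[4L]))
  }
  invisible(x)
}

#' Write / read an environment specification
#'
#' Plain-text round trip of condition, per-context design tables, and the
#' observation order. The format is line-oriented: a `condition=<label>`
#' header, a `[contexts]` section with CSV rows `context,ht,hn,ut,un`, and an
#' `[observations]` section with CSV rows `index,context,healthy,tasty`
#' (0/1 coding).
#'
#' @param env A `"pc_env"` object.
#' @param path File path.
#' @return `write_environment()` returns `path` invisibly;
#'   `read_environment()` returns the reconstructed `"pc_env"`.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "pc_env"))
  lines <- c(paste0("condition=", env$condition), "[contexts]",
             "context,ht,hn,ut,un")
  for (ctx in names(env$contexts)) {
    tab <- env$contexts[[ctx]]
    lines <- c(lines, paste(ctx, tab[1L], tab[2L], tab[3L], tab[4L], sep = ","))
  }
  obs <- env$observations
  lines <- c(lines, "[observations]", "index,context,healthy,tasty",
             paste(seq_len(nrow(obs)), obs$context, obs$healthy, obs$tasty,
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  lines <- readLines(path)
  fail <- function(i, msg) stop("parse error at line ", i, " of '", path,
                                "': ", msg, call. = FALSE)
  if (length(lines) < 1L || !grepl("^condition=", lines[1L]))
    fail(1L, "expected 'condition=<label>' header")
  condition <- sub("^condition=", "", lines[1L])
  if (!condition %in% pc_conditions)
    fail(1L, paste0("unknown condition label '", condition, "'"))
  ctx_start <- which(lines == "[contexts]")
  obs_start <- which(lines == "[observations]")
  if (length(ctx_start) != 1L || length(obs_start) != 1L ||
      obs_start < ctx_start + 3L || obs_start + 2L > length(lines))
    fail(1L, "expected one [contexts] section followed by one [observations] section")
  contexts <- list()
  for (i in seq(ctx_start + 2L, obs_start - 1L)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) != 5L) fail(i, "expected 'context,ht,hn,ut,un'")
    counts <- suppressWarnings(as.numeric(parts[2:5]))
    if (anyNA(counts)) fail(i, "non-numeric cell count")
    if (any(counts < 0)) fail(i, "negative cell count")
    if (any(counts != round(counts))) fail(i, "non-integer cell count")
    contexts[[parts[1L]]] <- contingency_table(counts[1L], counts[2L],
                                               counts[3L], counts[4L])
  }
  obs_lines <- lines[seq(obs_start + 2L, length(lines))]
  parts <- strsplit(obs_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) fail(obs_start + 1L + bad[1L], "expected 'index,context,healthy,tasty'")
  m <- do.call(rbind, parts)
  hv <- suppressWarnings(as.integer(m[, 3L]))
  tv <- suppressWarnings(as.integer(m[, 4L]))
  bad <- which(is.na(hv) | is.na(tv) | !(hv %in% 0:1) | !(tv %in% 0:1))
  if (length(bad)) fail(obs_start + 1L + bad[1L], "healthy/tasty must be 0 or 1")
  bad <- which(!m[, 2L] %in% names(contexts))
  if (length(bad)) fail(obs_start + 1L + bad[1L],
                        paste0("undeclared context '", m[bad[1L], 2L], "'"))
  obs <- data.frame(context = m[, 2L], healthy = hv, tasty = tv,
                    stringsAsFactors = FALSE)
  env <- new_environment(condition, contexts, obs)
  tallied <- tally_observations(env)
  for (ctx in names(contexts)) {
    if (!identical(unclass(tallied[[ctx]]), unclass(contexts[[ctx]])))
      fail(obs_start, paste0("observations do not match the declared table for ",
                             "context '", ctx, "'"))
  }
  env
}
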