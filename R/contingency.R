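#' Build a 2x2 health-by-taste contingency table
#'
#' The four cells count co-occurrences of two binary food attributes:
#' healthy/unhealthy and tasty/not-tasty. Rows are health, columns are taste,
#' so `ht` counts healthy-and-tasty foods, `un` unhealthy-and-not-tasty.
#'
#' @param ht,hn,ut,un Non-negative integer cell counts: healthy-tasty,
#'   healthy-not-tasty, unhealthy-tasty, unhealthy-not-tasty.
#' @return An integer vector of class `"contingency_table"` with elements
#'   `ht`, `hn`, `ut`, `un`.
#' @examples
#' contingency_table(6, 3, 3, 0)
#' @export
contingency_table <- function(ht = 0L, hn = 0L, ut = 0L, un = 0L) {
  cells <- c(ht = ht, hn = hn, ut = ut, un = un)
  if (length(cells) != 4L || anyNA(cells))
    stop("all four cell counts must be given and non-missing", call. = FALSE)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("contingency table cells must be non-negative integers", call. = FALSE)
  structure(as.integer(round(cells)),
            names = c("ht", "hn", "ut", "un"),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("healthy", "unhealthy"), c("tasty", "not tasty")))
  print(m)
  invisible(x)
}

as_table_cells <- function(table) {
  if (inherits(table, "contingency_table")) return(as.numeric(table))
  cells <- as.numeric(table)
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0))
    stop("expected four non-negative cell counts (ht, hn, ut, un)", call. = FALSE)
  cells
}

#' Marginal probabilities of healthiness and tastiness
#'
#' The base rates: the proportion of observed foods that are healthy and the
#' proportion that are tasty, irrespective of the other attribute.
#'
#' @param table A [contingency_table()] (or a length-4 count vector
#'   `c(ht, hn, ut, un)`) with at least one observation.
#' @return Named numeric vector `c(p_h = , p_t = )`, both in \[0, 1\].
#' @examples
#' marginals(contingency_table(6, 3, 3, 0))
#' @export
marginals <- function(table) {
  cells <- as_table_cells(table)
  n <- sum(cells)
  if (n < 1) stop("empty contingency table: at least one observation required", call. = FALSE)
  c(p_h = (cells[1L] + cells[2L]) / n,
    p_t = (cells[1L] + cells[3L]) / n)
}

#' Marginal skews from neutral base rates
#'
#' Deviation of each base rate from 0.5, the neutral environment in which
#' healthy and unhealthy (or tasty and not-tasty) foods are equally likely.
#'
#' @param m Marginals as returned by [marginals()] (named or unnamed
#'   length-2 probability vector).
#' @return Named numeric vector `c(d_h = , d_t = )`, both in \[-0.5, 0.5\].
#' @examples
#' skews(c(0.75, 0.75))
#' @export
skews <- function(m) {
  m <- as.numeric(m)
  if (length(m) != 2L || anyNA(m) || any(m < 0) || any(m > 1))
    stop("marginals must be two probabilities in [0, 1]", call. = FALSE)
  c(d_h = m[1L] - 0.5, d_t = m[2L] - 0.5)
}

#' Pseudocontingency effect from marginal skews
#'
#' The relationship implied by skewed base rates alone: the product of the two
#' marginal skews, scaled by `lambda` so that the effect spans \[-1, +1\] and
#' is directly comparable to the phi coefficient. Without scaling the product
#' of two skews in \[-0.5, 0.5\] could only reach +/-0.25; the default
#' `lambda = 4` expands that to +/-1.
#'
#' @param s Skews as returned by [skews()] (length-2 numeric).
#' @param lambda Scaling constant, default 4.
#' @return The pseudocontingency effect, in \[-1, +1\] for the default scaling.
#' @examples
#' pseudocontingency(c(0.25, 0.25)) # 0.25
#' @export
pseudocontingency <- function(s, lambda = 4) {
  s <- as.numeric(s)
  if (length(s) != 2L || anyNA(s) || any(abs(s) > 0.5 + 1e-12))
    stop("skews must be two values in [-0.5, 0.5]", call. = FALSE)
  lambda * s[1L] * s[2L]
}

#' Phi coefficient of a 2x2 contingency table
#'
#' The actual contingency between the two binary attributes: the
#' cross-product difference over the geometric mean of the margins,
#' identical to the Pearson correlation of the two attributes coded 0/1.
#' When any margin is zero one attribute shows no variation and no
#' association is estimable; by convention the function returns 0 so that
#' belief trajectories stay defined during the first observations.
#'
#' @param table A [contingency_table()] or length-4 count vector.
#' @return The phi coefficient, in \[-1, +1\].
#' @examples
#' phi_coef(contingency_table(6, 3, 3, 0)) # -1/3
#' @export
phi_coef <- function(table) {
  cells <- as_table_cells(table)
  if (sum(cells) < 1) stop("empty contingency table: at least one observation required", call. = FALSE)
  ht <- cells[1L]; hn <- cells[2L]; ut <- cells[3L]; un <- cells[4L]
  denom2 <- (ht + hn) * (ut + un) * (ht + ut) * (hn + un)
  if (denom2 <= 0) return(0)
  (ht * un - hn * ut) / sqrt(denom2)
}

#' Momentary belief as a bias-weighted blend
#'
#' The momentary belief about the health-taste relationship is a weighted
#' combination of the actual contingency `phi` and the pseudocontingency
#' effect `psi`, with the bias strength `beta` giving the weight on the
#' pseudocontingency: `(1 - beta) * phi + beta * psi`. `beta = 0` is pure
#' contingency use, `beta = 1` pure reliance on base rates. Values of `beta`
#' outside \[0, 1\] are permitted (extended-range calibration) and may push
#' the blend outside \[-1, 1\]; clipping, if any, happens at the reporting
#' layer only.
#'
#' @param phi Actual contingency in \[-1, 1\] (vectorised).
#' @param psi Pseudocontingency effect in \[-1, 1\] (vectorised).
#' @param beta Bias strength (vectorised).
#' @return Numeric blend, a convex combination for `beta` in \[0, 1\].
#' @examples
#' blend_belief(-1/3, 0.25, 0.5)
#' @export
blend_belief <- function(phi, psi, beta) {
  (1 - beta) * phi + beta * psi
}

#' Exponential-smoothing belief update
#'
#' Integrates a new momentary belief into the running belief:
#' `(1 - alpha) * prev + alpha * target`, where the learning rate `alpha`
#' controls the weight given to new information.
#'
#' @param prev Current smoothed belief (vectorised).
#' @param target New momentary belief (vectorised).
#' @param alpha Learning rate in (0, 1].
#' @return Updated belief.
#' @examples
#' smooth_update(0, 0.2, 0.5)
#' @export
smooth_update <- function(prev, target, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  (1 - alpha) * prev + alpha * target
}
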