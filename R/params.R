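#' Model parameters
#'
#' Bundle the five scalar parameters of the fast/slow-cell resource model and
#' the aggregation rule. All rates are in the model's nondimensional time
#' units (resource-consumer encounter rate scaled to 1); the payoff
#' coefficients are dimensionless reproductive efficiencies.
#'
#' @param r resource maximum growth rate (> 0).
#' @param K resource carrying capacity (> 0).
#' @param d consumer (cell) death rate (> 0).
#' @param lambda_F payoff coefficient of fast cells feeding in isolation
#'   (> 0).
#' @param lambda_S payoff coefficient of slow cells exploiting collective
#'   transport inside groups (> 0); the evolvable trait.
#' @param aggregation_rule an [aggregation_rule()] object; defaults to the
#'   linear rule in which the probability of remaining solitary is `R/K`.
#'
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 16)
#' @export
model_params <- function(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 16,
                         aggregation_rule = ecoevocycle::aggregation_rule()) {
  for (nm in c("r", "K", "d", "lambda_F", "lambda_S")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  stopifnot(inherits(aggregation_rule, "aggregation_rule"))
  structure(
    list(r = r, K = K, d = d, lambda_F = lambda_F, lambda_S = lambda_S,
         aggregation_rule = aggregation_rule),
    class = "model_params")
}

#' Aggregation rule: probability of remaining solitary
#'
#' The partition of the population between solitary and grouped cells is
#' driven by resource availability: cells stay alone when food is abundant
#' and aggregate when it is depleted. The `linear` rule sets the probability
#' of being solitary to `R/K` (all cells solitary at carrying capacity, all
#' grouped at zero resource). The `bounded` variant multiplies this by a
#' factor `alone_scale` in (0, 1], so that a fraction of the population
#' remains grouped even at carrying capacity.
#'
#' @param kind `"linear"` or `"bounded"`.
#' @param alone_scale proportionality factor in (0, 1]; ignored (fixed at 1)
#'   for the linear rule.
#' @return An object of class `"aggregation_rule"`.
#' @export
aggregation_rule <- function(kind = c("linear", "bounded"), alone_scale = 1) {
  kind <- match.arg(kind)
  if (kind == "linear") alone_scale <- 1
  if (!is.numeric(alone_scale) || length(alone_scale) != 1L ||
      alone_scale <= 0 || alone_scale > 1)
    stop("'alone_scale' must be in (0, 1]")
  structure(list(kind = kind, alone_scale = alone_scale),
            class = "aggregation_rule")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (fast/slow cells + shared resource)\n")
  cat(sprintf("  r = %g, K = %g, d = %g, lambda_F = %g, lambda_S = %g\n",
              x$r, x$K, x$d, x$lambda_F, x$lambda_S))
  cat(sprintf("  aggregation rule: %s (alone_scale = %g)\n",
              x$aggregation_rule$kind, x$aggregation_rule$alone_scale))
  invisible(x)
}

#' Probability that a cell is solitary at resource density R
#'
#' @param R resource density (vectorised, each element >= 0). Transient
#'   numerical overshoot above `K` is tolerated: the probability is clipped
#'   to 1 so payoffs stay non-negative.
#' @param params a [model_params()] object.
#' @return probabilities in `[0, 1]`, same length as `R`.
#' @export
probability_alone <- function(R, params) {
  if (any(R < 0)) stop("resource density R must be non-negative")
  a <- params$aggregation_rule$alone_scale
  pmin(a * R / params$K, 1)
}

#' Type payoffs and population mean payoff
#'
#' Fast cells earn `probability_alone(R) * lambda_F` by feeding in isolation
#' and nothing inside groups, where they fuel collective transport. Slow
#' cells earn nothing alone; inside groups they exploit the fast cells'
#' propulsion, with payoff `x * (1 - probability_alone(R)) * lambda_S`
#' increasing with the fast-cell fraction x. The mean payoff is the
#' frequency-weighted average.
#'
#' @param x frequency of fast cells in `[0, 1]` (vectorised).
#' @param R resource density (vectorised, recycled with `x`).
#' @param params a [model_params()] object.
#' @return a list with components `p_F`, `p_S`, `p_bar`.
#' @export
payoffs <- function(x, R, params) {
  if (any(x < 0 | x > 1)) stop("fast-cell frequency x must lie in [0, 1]")
  q <- probability_alone(R, params)
  p_F <- q * params$lambda_F
  p_S <- x * (1 - q) * params$lambda_S
  list(p_F = p_F, p_S = p_S, p_bar = x * p_F + (1 - x) * p_S)
}
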