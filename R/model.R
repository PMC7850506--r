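#' Right-hand side of the eco-evolutionary system
#'
#' Time derivatives of the coupled resource-demography-replicator dynamics:
#' \deqn{dR/dt = R [ r (1 - R/K) - N ]}
#' \deqn{dN/dt = N [ \bar p(x, R) R - d ]}
#' \deqn{dx/dt = x (1 - x) R [ p_F(x, R) - p_S(x, R) ]}
#' where R is the resource density, N the total cell population size and x
#' the frequency of fast-moving cells.
#'
#' @param state numeric vector `c(R, N, x)`.
#' @param params a [model_params()] object.
#' @return numeric vector of derivatives `c(dR, dN, dx)`.
#' @export
eco_evo_rhs <- function(state, params) {
  R <- state[[1]]; N <- state[[2]]; x <- state[[3]]
  p <- payoffs(x, R, params)
  c(R * (params$r * (1 - R / params$K) - N),
    N * (p$p_bar * R - params$d),
    x * (1 - x) * R * (p$p_F - p$p_S))
}

#' Right-hand side of the neutral (purely ecological) submodel
#'
#' When both motility types have equal payoffs the fast-cell frequency is
#' constant and the demography decouples: the resource and population-size
#' equations are integrated with the mean payoff evaluated at a fixed
#' frequency `x_fixed`.
#'
#' @param R resource density.
#' @param N population size.
#' @param x_fixed frozen fast-cell frequency in `[0, 1]`.
#' @param params a [model_params()] object.
#' @return numeric vector `c(dR, dN)`.
#' @export
neutral_rhs <- function(R, N, x_fixed, params) {
  if (x_fixed < 0 || x_fixed > 1) stop("x_fixed must lie in [0, 1]")
  p <- payoffs(x_fixed, R, params)
  c(R * (params$r * (1 - R / params$K) - N),
    N * (p$p_bar * R - params$d))
}

#' Right-hand side of the resident-mutant three-strategy system
#'
#' Extends the model to fast cells, resident slow cells (trait `lambda_S`
#' from `params`) and mutant slow cells (trait `lambda_S_mut`). Both slow
#' types exploit the same fast fraction; each frequency follows a replicator
#' term `x_i R (p_i - p_bar)`, which conserves the frequency simplex exactly
#' in continuous time.
#'
#' @param state numeric vector `c(R, N, x_F, x_Sr, x_Sm)`; the three
#'   frequencies must sum to 1 within `sum_tol`.
#' @param params a [model_params()] object (resident trait in
#'   `params$lambda_S`).
#' @param lambda_S_mut mutant exploitation trait (> 0).
#' @param sum_tol tolerated drift of the frequency sum from 1.
#' @return numeric vector of the five derivatives.
#' @export
three_strategy_rhs <- function(state, params, lambda_S_mut, sum_tol = 1e-6) {
  R <- state[[1]]; N <- state[[2]]
  x_F <- state[[3]]; x_Sr <- state[[4]]; x_Sm <- state[[5]]
  if (lambda_S_mut <= 0) stop("lambda_S_mut must be positive")
  s <- x_F + x_Sr + x_Sm
  if (abs(s - 1) > sum_tol)
    stop(sprintf("frequency sum %.3g deviates from 1 beyond tolerance", s))
  q <- probability_alone(R, params)
  p_F <- q * params$lambda_F
  p_Sr <- x_F * (1 - q) * params$lambda_S
  p_Sm <- x_F * (1 - q) * lambda_S_mut
  p_bar <- x_F * p_F + x_Sr * p_Sr + x_Sm * p_Sm
  c(R * (params$r * (1 - R / params$K) - N),
    N * (p_bar * R - params$d),
    x_F * R * (p_F - p_bar),
    x_Sr * R * (p_Sr - p_bar),
    x_Sm * R * (p_Sm - p_bar))
}

#' Integrate the resident-mutant three-strategy system
#'
#' @param params a [model_params()] object (resident trait in
#'   `params$lambda_S`).
#' @param lambda_S_mut mutant exploitation trait.
#' @param init numeric `c(R, N, x_F, x_Sr, x_Sm)`.
#' @param t_span final time or vector of output times.
#' @param rtol,atol integration tolerances.
#' @param dt output step when `t_span` is scalar.
#' @return a data.frame with columns `t, R, N, x_F, x_Sr, x_Sm`. The
#'   frequency columns are renormalised to sum to one wherever numerical
#'   drift exceeds 1e-9 (the replicator structure conserves the sum
#'   exactly in continuous time, so drift beyond integration error is a
#'   solver diagnostic, reported via warning above 1e-6).
#' @export
simulate_three_strategy <- function(params, lambda_S_mut, init, t_span,
                                    rtol = 1e-10, atol = 1e-12, dt = 0.05) {
  stopifnot(length(init) == 5)
  times <- if (length(t_span) == 1L) seq(0, t_span, by = dt) else t_span
  out <- deSolve::ode(y = unname(init), times = times,
                      func = three_strategy_rhs_desolve,
                      parms = list(params = params,
                                   lambda_S_mut = lambda_S_mut,
                                   sum_tol = 1e-6),
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 1e6)
  df <- as.data.frame(out)
  names(df) <- c("t", "R", "N", "x_F", "x_Sr", "x_Sm")
  s <- df$x_F + df$x_Sr + df$x_Sm
  if (max(abs(s - 1)) > 1e-6)
    warning(sprintf("frequency-sum drift reached %.3g", max(abs(s - 1))))
  fix <- abs(s - 1) > 1e-9
  if (any(fix)) {
    df$x_F[fix] <- df$x_F[fix] / s[fix]
    df$x_Sr[fix] <- df$x_Sr[fix] / s[fix]
    df$x_Sm[fix] <- df$x_Sm[fix] / s[fix]
  }
  attr(df, "max_drift") <- max(abs(s - 1))
  df
}

# deSolve-facing wrappers ----------------------------------------------------

rhs_desolve <- function(t, y, parms) {
  list(eco_evo_rhs(y, parms))
}

neutral_rhs_desolve <- function(t, y, parms) {
  list(neutral_rhs(y[[1]], y[[2]], parms$x_fixed, parms$params))
}

three_strategy_rhs_desolve <- function(t, y, parms) {
  list(three_strategy_rhs(y, parms$params, parms$lambda_S_mut,
                          sum_tol = parms$sum_tol))
}
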