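#' @keywords internal
invasion_result <- function(lambda_S_res, lambda_S_mut, S, method, regime) {
  structure(list(lambda_S_resident = lambda_S_res,
                 lambda_S_mutant = lambda_S_mut,
                 fitness = S, method = method, regime = regime),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf(
    "Invasion fitness S = %.6g (mutant %.4g vs resident %.4g; %s, %s)\n",
    x$fitness, x$lambda_S_mutant, x$lambda_S_resident, x$method, x$regime))
  invisible(x)
}

#' Analytic invasion fitness at the coexistence equilibrium
#'
#' Growth rate of a rare mutant slow type with exploitation trait
#' `lambda_S_mut` in a resident population equilibrated at
#' `lambda_S_res`: `S = d (lambda_S_mut - lambda_S_res) / lambda_S_res`.
#' The sign of S equals the sign of the trait difference, so more
#' exploitative mutants always invade at equilibrium.
#'
#' @param lambda_S_mut mutant trait (> 0).
#' @param lambda_S_res resident trait (> 0).
#' @param params a [model_params()] object; `params$lambda_S` is ignored in
#'   favour of `lambda_S_res`.
#' @return an `invasion_result` with `method = "analytic_eq"`.
#' @export
invasion_fitness_equilibrium <- function(lambda_S_mut, lambda_S_res,
                                         params) {
  p <- params
  p$lambda_S <- lambda_S_res
  eq <- coexistence_equilibrium(p)
  if (!eq$exists)
    stop("resident coexistence equilibrium does not exist")
  regime <- if (eq$stability == "unstable") "LC" else "SC"
  S <- params$d * (lambda_S_mut - lambda_S_res) / lambda_S_res
  invasion_result(lambda_S_res, lambda_S_mut, S, "analytic_eq", regime)
}

simpson <- function(t, y) {
  n <- length(t)
  if (n %% 2 == 0) { # drop one point; grids here are dense
    n <- n - 1
    t <- t[1:n]; y <- y[1:n]
  }
  h <- (t[n] - t[1]) / (n - 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
             2 * sum(y[seq(3, n - 2, by = 2)]))
}

#' Cycle-averaged (transverse) invasion fitness
#'
#' On the resident limit cycle the mutant's rare-frequency growth rate is
#' the transverse Floquet-type exponent
#' `S = (1/T) \int_0^T R(t) [p_mut(t) - p_bar(t)] dt`, with
#' `p_mut = x(t) (1 - probability_alone(R)) lambda_S_mut` evaluated along
#' the resident cycle. The integral is taken by composite Simpson quadrature
#' on the dense one-period sample.
#'
#' @param lambda_S_mut mutant trait.
#' @param lambda_S_res resident trait.
#' @param params base [model_params()].
#' @param resident_cycle optionally a precomputed converged
#'   [find_limit_cycle()] summary for the resident (saves the search when
#'   scanning many mutants against one resident).
#' @param ... passed to [find_limit_cycle()] when the cycle is not supplied.
#' @return an `invasion_result` with `method = "cycle_average"`.
#' @export
invasion_fitness_cycle <- function(lambda_S_mut, lambda_S_res, params,
                                   resident_cycle = NULL, ...) {
  p <- params
  p$lambda_S <- lambda_S_res
  lc <- if (is.null(resident_cycle)) find_limit_cycle(p, ...)
        else resident_cycle
  if (!inherits(lc, "limit_cycle_summary") || !lc$converged)
    stop("resident limit cycle not converged")
  cy <- lc$cycle
  # p_S along the cycle is x (1-q) lambda_S_res, so the mutant payoff is a
  # rescaling of it
  p_mut <- cy$p_S * lambda_S_mut / lambda_S_res
  S <- simpson(cy$t, cy$R * (p_mut - cy$p_bar)) / lc$period
  invasion_result(lambda_S_res, lambda_S_mut, S, "cycle_average", "LC")
}

#' Invasion fitness from direct resident-mutant simulation
#'
#' Integrates the five-variable resident-mutant system with the mutant
#' introduced at a small share `x0_mut` of the slow subpopulation, and fits
#' the slope of the log mutant frequency while the mutant stays rare. In
#' the stable-equilibrium regime the resident sits at its coexistence
#' equilibrium; in the cyclic regime the resident is first relaxed onto its
#' limit cycle and the slope is fitted across samples taken at integer
#' multiples of the resident period (which removes the periodic modulation
#' of the mutant frequency).
#'
#' @param lambda_S_mut mutant trait.
#' @param lambda_S_res resident trait.
#' @param params base [model_params()].
#' @param x0_mut initial mutant share of the slow subpopulation.
#' @param n_periods number of resident periods (LC) spanned by the fit.
#' @param t_fit fitting horizon in the SC regime (time units).
#' @param rarity_factor fit uses only samples with mutant frequency below
#'   `rarity_factor` times its initial value.
#' @param resident_cycle optional precomputed converged resident
#'   [find_limit_cycle()] summary (LC regime only).
#' @param rtol,atol integration tolerances.
#' @return an `invasion_result` with `method = "direct_sim"`.
#' @export
invasion_fitness_direct <- function(lambda_S_mut, lambda_S_res, params,
                                    x0_mut = 1e-6, n_periods = 8,
                                    t_fit = 60, rarity_factor = 100,
                                    resident_cycle = NULL,
                                    rtol = 1e-10, atol = 1e-12) {
  p <- params
  p$lambda_S <- lambda_S_res
  eq <- coexistence_equilibrium(p)
  if (!eq$exists) stop("resident coexistence equilibrium does not exist")
  regime <- if (eq$stability == "unstable") "LC" else "SC"
  if (regime == "SC") {
    base <- eq$location
    times <- seq(0, t_fit, length.out = 161)
  } else {
    lc <- if (is.null(resident_cycle))
      find_limit_cycle(p, rtol = rtol, atol = atol) else resident_cycle
    if (!lc$converged) stop("resident limit cycle not converged")
    base <- c(R = lc$cycle$R[1], N = lc$cycle$N[1], x = lc$cycle$x[1])
    times <- seq(0, n_periods, by = 1) * lc$period
  }
  slow <- 1 - base[["x"]]
  y0 <- c(base[["R"]], base[["N"]], base[["x"]],
          slow * (1 - x0_mut), slow * x0_mut)
  df <- simulate_three_strategy(p, lambda_S_mut, y0, times,
                                rtol = rtol, atol = atol)
  xm <- df$x_Sm
  keep <- xm > 0 & xm < rarity_factor * xm[1]
  if (sum(keep) < 4)
    stop("mutant left the rare regime too quickly for a slope fit")
  fit <- stats::lm(log(xm[keep]) ~ df$t[keep])
  invasion_result(lambda_S_res, lambda_S_mut,
                  unname(stats::coef(fit)[2]), "direct_sim", regime)
}

#' Trait substitution sequence for the exploitation level
#'
#' Adaptive-dynamics walk of the slow-cell exploitation trait: at each step
#' a mutant with trait `lambda_S* + delta` challenges the resident; if its
#' invasion fitness is positive the mutant substitutes the resident. The
#' fitness is the analytic equilibrium expression while the resident sits
#' at a stable coexistence equilibrium and the cycle-averaged transverse
#' growth rate once the resident population oscillates, so the walk records
#' the crossing from the SC into the LC regime.
#'
#' @param params base [model_params()].
#' @param lambda_S_start initial resident trait.
#' @param delta mutational increment (> 0).
#' @param n_steps number of substitution attempts.
#' @return an object of class `"evolution_trace"`: a data.frame with one
#'   row per attempted step (`step, lambda_S_res, lambda_S_mut, S, method,
#'   regime, accepted`), with `delta` stored as an attribute.
#' @export
trait_substitution <- function(params, lambda_S_start, delta = 0.1,
                               n_steps = 50) {
  stopifnot(delta > 0, n_steps >= 1)
  lam <- lambda_S_start
  rows <- vector("list", n_steps)
  warm_cycle <- NULL
  for (k in seq_len(n_steps)) {
    p <- params
    p$lambda_S <- lam
    eq <- coexistence_equilibrium(p)
    if (!eq$exists) stop(sprintf(
      "resident equilibrium ceased to exist at lambda_S = %g", lam))
    regime <- if (eq$stability == "unstable") "LC" else "SC"
    if (regime == "SC") {
      res <- invasion_fitness_equilibrium(lam + delta, lam, p)
      warm_cycle <- NULL
    } else {
      init <- if (is.null(warm_cycle)) NULL
              else unlist(warm_cycle[1, c("R", "N", "x")])
      lc <- find_limit_cycle(p, init = init)
      res <- invasion_fitness_cycle(lam + delta, lam, p,
                                    resident_cycle = lc)
      warm_cycle <- lc$cycle
    }
    accepted <- res$fitness > 0
    rows[[k]] <- data.frame(step = k, lambda_S_res = lam,
                            lambda_S_mut = lam + delta, S = res$fitness,
                            method = res$method, regime = regime,
                            accepted = accepted)
    if (!accepted) {
      rows <- rows[seq_len(k)]
      break
    }
    lam <- lam + delta
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  class(out) <- c("evolution_trace", class(out))
  out
}

#' Reciprocal scaling of invasion fitness along a trace
#'
#' At fixed mutational increment the equilibrium fitness is
#' `d * delta / lambda_S*`, i.e. it scales as the reciprocal of the
#' resident trait; the same scaling holds empirically on the cycle. Fits
#' the log-log slope of fitness against resident trait over the accepted
#' steps of a substitution trace.
#'
#' @param trace an `"evolution_trace"` from [trait_substitution()] with at
#'   least 10 accepted steps.
#' @return a list: `slope`, `intercept`, `residual_sd`.
#' @export
reciprocal_scaling_check <- function(trace) {
  acc <- trace[trace$accepted & trace$S > 0, ]
  if (nrow(acc) < 10)
    stop("need at least 10 accepted steps for the scaling fit")
  fit <- stats::lm(log(S) ~ log(lambda_S_res), data = acc)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = stats::sd(stats::residuals(fit)))
}
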