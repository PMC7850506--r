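#' Integrate the eco-evolutionary system
#'
#' Wraps a stiff-capable integrator (`deSolve::ode`, `lsoda`) with tight
#' default error control; amplitude and period estimates near the Hopf curve
#' are sensitive to integration error, hence the conservative tolerances.
#'
#' @param params a [model_params()] object.
#' @param init numeric `c(R, N, x)` initial state.
#' @param t_span either a final time or a vector of output times.
#' @param rtol,atol relative / absolute local error tolerances.
#' @param dt output step when `t_span` is a scalar final time.
#' @param method deSolve method tag.
#' @param domain_tol tolerated excursion outside the admissible domain
#'   (`R >= 0`, `N >= 0`, `0 <= x <= 1`) before an error is raised.
#' @return an object of class `"eco_trajectory"`: a list with `times`,
#'   `states` (data.frame `t, R, N, x`), `params` and `solver_meta`.
#' @examples
#' tr <- simulate_model(model_params(), c(0.5, 0.5, 0.5), t_span = 20)
#' tail(tr$states)
#' @export
simulate_model <- function(params, init, t_span,
                           rtol = 1e-10, atol = 1e-12, dt = 0.05,
                           method = "lsoda", domain_tol = 1e-6) {
  stopifnot(length(init) == 3, all(is.finite(init)))
  if (init[[1]] < 0 || init[[2]] < 0 || init[[3]] < 0 || init[[3]] > 1)
    stop("initial state outside admissible domain")
  times <- if (length(t_span) == 1L) seq(0, t_span, by = dt) else t_span
  out <- deSolve::ode(y = unname(init), times = times, func = rhs_desolve,
                      parms = params, method = method, rtol = rtol,
                      atol = atol, maxsteps = 1e6)
  st <- as.data.frame(out)
  names(st) <- c("t", "R", "N", "x")
  if (min(st$R) < -domain_tol || min(st$N) < -domain_tol ||
      min(st$x) < -domain_tol || max(st$x) > 1 + domain_tol)
    stop(sprintf(paste("trajectory left the admissible domain:",
                       "min R = %.3g, min N = %.3g, x range [%.3g, %.3g]"),
                 min(st$R), min(st$N), min(st$x), max(st$x)))
  structure(list(times = st$t, states = st, params = params,
                 solver_meta = list(method = method, rtol = rtol,
                                    atol = atol)),
            class = "eco_trajectory")
}

#' Default perturbed initial condition
#'
#' The coexistence equilibrium displaced by a 1% multiplicative perturbation
#' along a fixed, seed-reproducible direction. Used as the standard starting
#' point for limit-cycle searches.
#'
#' @param params a [model_params()] object.
#' @param rel relative perturbation size.
#' @param seed seed for the perturbation direction.
#' @return numeric `c(R, N, x)`.
#' @export
perturbed_init <- function(params, rel = 0.01, seed = 1L) {
  eq <- coexistence_equilibrium(params)
  if (!eq$exists) stop("no interior equilibrium to perturb")
  u <- withr_seed(seed, stats::runif(3, -1, 1))
  init <- eq$location * (1 + rel * u)
  init[3] <- min(max(init[3], 0), 1)
  unname(init)
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-time-point observables of a trajectory
#'
#' Augments a trajectory with the quantities the model narrates: type
#' payoffs, mean payoff, per-capita birth rate `p_bar * R`, the grouped
#' fraction `1 - probability_alone(R)`, and the partition of the population
#' into fast/slow x solitary/grouped cell counts (groups draw cells at
#' random, so counts factorise over frequency and aggregation probability).
#'
#' @param traj an `"eco_trajectory"` from [simulate_model()], or a
#'   data.frame with columns `t, R, N, x` plus a `params` argument.
#' @param params required when `traj` is a bare data.frame.
#' @return a data.frame with columns `t, R, N, x, p_F, p_S, p_bar,
#'   birth_rate, frac_grouped, n_fast_alone, n_fast_grouped, n_slow_alone,
#'   n_slow_grouped`.
#' @export
derive_observables <- function(traj, params = NULL) {
  if (inherits(traj, "eco_trajectory")) {
    st <- traj$states
    params <- traj$params
  } else {
    st <- traj
    if (is.null(params)) stop("'params' required for a bare data.frame")
  }
  q <- probability_alone(st$R, params)
  p <- payoffs(st$x, st$R, params)
  data.frame(
    t = st$t, R = st$R, N = st$N, x = st$x,
    p_F = p$p_F, p_S = p$p_S, p_bar = p$p_bar,
    birth_rate = p$p_bar * st$R,
    frac_grouped = 1 - q,
    n_fast_alone = st$N * st$x * q,
    n_fast_grouped = st$N * st$x * (1 - q),
    n_slow_alone = st$N * (1 - st$x) * q,
    n_slow_grouped = st$N * (1 - st$x) * (1 - q))
}

# cubic-Hermite refinement of an upward level crossing of x between two
# output points, using exact derivatives from the vector field
refine_crossing <- function(t0, t1, s0, s1, level, params) {
  h <- t1 - t0
  f0 <- eco_evo_rhs(s0, params); f1 <- eco_evo_rhs(s1, params)
  hermite <- function(tau, y0, y1, d0, d1) {
    u <- tau / h
    (2 * u^3 - 3 * u^2 + 1) * y0 + (u^3 - 2 * u^2 + u) * h * d0 +
      (-2 * u^3 + 3 * u^2) * y1 + (u^3 - u^2) * h * d1
  }
  g <- function(tau) hermite(tau, s0[3], s1[3], f0[3], f1[3]) - level
  tau <- tryCatch(stats::uniroot(g, c(0, h), tol = 1e-13)$root,
                  error = function(e) h * (level - s0[3]) / (s1[3] - s0[3]))
  state <- vapply(1:3, function(i)
    hermite(tau, s0[i], s1[i], f0[i], f1[i]), numeric(1))
  list(t = t0 + tau, state = state)
}

#' Locate the limit cycle by direct simulation
#'
#' Integrates past transients and detects periodicity on a Poincare section:
#' upward crossings of the fast-cell frequency `x` through its mean level
#' over an initial probe window (`x` has a single maximum per cycle in this
#' system). Crossing times are refined by cubic-Hermite interpolation using
#' exact derivative values, giving period estimates well below the
#' convergence tolerance. The search stops when three successive periods
#' agree to `period_tol` relative (or `max_cycles` is reached); optionally
#' the cycle amplitude is also iterated to convergence, which matters close
#' to the Hopf point where transients decay slowly.
#'
#' Convergence to the equilibrium instead of a cycle is reported as
#' `converged = FALSE` with near-zero amplitudes, not as an error.
#'
#' @param params a [model_params()] object.
#' @param init initial state; defaults to [perturbed_init()].
#' @param burn_in transient time discarded before the section search.
#' @param period_tol relative agreement required of 3 successive periods.
#' @param max_cycles cap on the number of section returns examined.
#' @param amp_rel_tol if non-`NULL`, additionally iterate (in blocks of 10
#'   periods) until the one-period amplitude of `R` changes by less than
#'   this relative amount; `NULL` skips the amplitude polish.
#' @param amp_tol absolute oscillation amplitude in `x` and `R` below which
#'   the trajectory is declared equilibrium-bound.
#' @param rtol,atol integration tolerances.
#' @param n_period_samples output points on the final one-period sample.
#' @return an object of class `"limit_cycle_summary"`: `period`, `extrema`
#'   (per-variable min/max/amplitude), `means` (cycle averages of R, N, x,
#'   p_bar and birth rate), `converged`, `n_transient_cycles`,
#'   `net_growth_integral` (the per-period integral of `p_bar R - d`, zero
#'   on a true cycle), and `cycle`, the dense one-period observable table.
#' @examples
#' \donttest{
#' lc <- find_limit_cycle(model_params())
#' lc$period
#' }
#' @export
find_limit_cycle <- function(params, init = NULL, burn_in = 150,
                             period_tol = 1e-6, max_cycles = 500,
                             amp_rel_tol = NULL, amp_tol = 1e-6,
                             rtol = 1e-10, atol = 1e-12,
                             n_period_samples = 2001) {
  if (is.null(init)) init <- perturbed_init(params)
  eq <- coexistence_equilibrium(params)
  # initial period guess from the linearisation, if it rotates
  im <- max(abs(Im(eq$eigenvalues)))
  T_est <- if (is.finite(im) && im > 1e-8) 2 * pi / im else 6
  dt <- T_est / 200

  run <- function(y0, t_end) simulate_model(params, y0, t_span = t_end,
                                            rtol = rtol, atol = atol,
                                            dt = dt)
  tr <- run(init, max(burn_in, 2 * T_est))
  y <- last_state(tr)

  probe <- run(y, max(6 * T_est, 30))
  amp_probe <- c(R = diff(range(probe$states$R)),
                 x = diff(range(probe$states$x)))
  if (all(amp_probe < amp_tol))
    return(cycle_summary_equilibrium(params, probe, n_period_samples))
  level <- mean(probe$states$x)
  y <- last_state(probe)

  periods <- numeric(0)
  last_cross <- NULL
  converged <- FALSE
  n_cycles <- 0
  t_base <- 0
  amp_prev <- NULL
  while (n_cycles < max_cycles && !converged) {
    chunk <- run(y, 12 * T_est)
    st <- chunk$states
    amp_now <- diff(range(st$R))
    if (is.null(amp_prev)) {
      half <- st$t <= max(st$t) / 2
      amp_prev <- diff(range(st$R[half]))
      amp_now <- diff(range(st$R[!half]))
    }
    if (amp_now < amp_tol && diff(range(st$x)) < amp_tol)
      return(cycle_summary_equilibrium(params, chunk, n_period_samples))
    # a trajectory spiralling into a stable focus can show stable return
    # times long before its amplitude dies; require the oscillation
    # amplitude to have stopped contracting before accepting a cycle
    contracting <- amp_now < 0.99 * amp_prev
    xs <- st$x
    up <- which(xs[-length(xs)] < level & xs[-1] >= level)
    for (i in up) {
      cr <- refine_crossing(st$t[i], st$t[i + 1],
                            unlist(st[i, c("R", "N", "x")]),
                            unlist(st[i + 1, c("R", "N", "x")]),
                            level, params)
      t_abs <- t_base + cr$t
      if (!is.null(last_cross)) {
        periods <- c(periods, t_abs - last_cross$t)
        n_cycles <- n_cycles + 1
      }
      last_cross <- list(t = t_abs, state = cr$state)
      k <- length(periods)
      if (k >= 3 && !contracting) {
        p3 <- periods[(k - 2):k]
        if (diff(range(p3)) / mean(p3) < period_tol) { converged <- TRUE
                                                       break }
      }
      if (n_cycles >= max_cycles) break
    }
    t_base <- t_base + max(st$t)
    y <- last_state(chunk)
    amp_prev <- amp_now
  }
  if (length(periods) == 0)
    return(cycle_summary_equilibrium(params, probe, n_period_samples))
  T_cyc <- mean(utils::tail(periods, 3))

  y_start <- last_cross$state
  if (!is.null(amp_rel_tol)) {
    amp_prev <- -Inf
    for (it in seq_len(150)) {
      one <- run(y_start, T_cyc)
      amp <- diff(range(one$states$R))
      if (abs(amp - amp_prev) <= amp_rel_tol * max(amp, 1e-14)) break
      amp_prev <- amp
      drift <- run(y_start, 10 * T_cyc)
      y_start <- last_state(drift)
    }
  }

  one <- simulate_model(params, y_start,
                        t_span = seq(0, T_cyc, length.out = n_period_samples),
                        rtol = rtol, atol = atol)
  obs <- derive_observables(one)
  structure(list(
    period = T_cyc,
    extrema = cycle_extrema(obs),
    means = c(R = trapz_mean(obs$t, obs$R), N = trapz_mean(obs$t, obs$N),
              x = trapz_mean(obs$t, obs$x),
              p_bar = trapz_mean(obs$t, obs$p_bar),
              birth_rate = trapz_mean(obs$t, obs$birth_rate)),
    converged = converged,
    n_transient_cycles = length(periods),
    net_growth_integral = trapz(obs$t, obs$birth_rate - params$d),
    section_level = level,
    cycle = obs,
    params = params),
    class = "limit_cycle_summary")
}

last_state <- function(tr) {
  st <- tr$states[nrow(tr$states), ]
  c(st$R, st$N, st$x)
}

cycle_extrema <- function(obs) {
  vars <- c("R", "N", "x")
  data.frame(
    variable = vars,
    min = vapply(vars, function(v) min(obs[[v]]), numeric(1)),
    max = vapply(vars, function(v) max(obs[[v]]), numeric(1)),
    amplitude = vapply(vars, function(v) diff(range(obs[[v]])), numeric(1)),
    row.names = NULL)
}

cycle_summary_equilibrium <- function(params, probe, n_period_samples) {
  obs <- derive_observables(probe)
  structure(list(
    period = NA_real_,
    extrema = cycle_extrema(obs),
    means = c(R = mean(obs$R), N = mean(obs$N), x = mean(obs$x),
              p_bar = mean(obs$p_bar), birth_rate = mean(obs$birth_rate)),
    converged = FALSE,
    n_transient_cycles = 0L,
    net_growth_integral = NA_real_,
    section_level = NA_real_,
    cycle = obs,
    params = params),
    class = "limit_cycle_summary")
}

#' @export
print.limit_cycle_summary <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Limit cycle: period %.6g (%d transient cycles)\n",
                x$period, x$n_transient_cycles))
  } else {
    cat("No converged limit cycle (equilibrium-bound or cap reached)\n")
  }
  print(x$extrema)
  invisible(x)
}

trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) +
                                         utils::tail(y, -1)) / 2)
trapz_mean <- function(t, y) trapz(t, y) / (max(t) - min(t))

#' Cycle-period to generation-time ratios
#'
#' Compares the timescale of the emergent aggregation cycle with the
#' timescale of cell reproduction. The per-capita net growth rate
#' `p_bar R - d` integrates to exactly zero over a period, so generation
#' time is measured from the per-capita birth rate `b(t) = p_bar R`:
#' `ratio_vs_max_rate = T * max b` (the fastest demographic timescale along
#' the cycle) and `ratio_vs_mean_rate = T * mean b`. Per-type birth-rate
#' ratios (`p_F R` for fast, `p_S R` for slow) are reported alongside.
#'
#' @param summary a converged [find_limit_cycle()] result.
#' @return a list with `ratio_vs_max_rate`, `ratio_vs_mean_rate`, and
#'   per-type analogues `ratio_fast_max`, `ratio_fast_mean`,
#'   `ratio_slow_max`, `ratio_slow_mean`.
#' @export
generation_ratio <- function(summary) {
  if (!inherits(summary, "limit_cycle_summary") || !summary$converged)
    stop("generation_ratio() needs a converged limit-cycle summary")
  cy <- summary$cycle
  T_cyc <- summary$period
  b <- cy$birth_rate
  bF <- cy$p_F * cy$R
  bS <- cy$p_S * cy$R
  list(ratio_vs_max_rate = T_cyc * max(b),
       ratio_vs_mean_rate = T_cyc * trapz_mean(cy$t, b),
       ratio_fast_max = T_cyc * max(bF),
       ratio_fast_mean = T_cyc * trapz_mean(cy$t, bF),
       ratio_slow_max = T_cyc * max(bS),
       ratio_slow_mean = T_cyc * trapz_mean(cy$t, bS))
}

#' Phase lag between two cyclic series
#'
#' Time by which the peak of series `b` trails the peak of series `a`
#' within one period, reported circularly in `[0, T)`. Peaks are refined by
#' quadratic interpolation through the three samples around the maximum.
#'
#' @param summary a converged [find_limit_cycle()] result.
#' @param series_a,series_b column names of the cycle table (e.g. `"R"`,
#'   `"N"`, `"x"`, `"frac_grouped"`).
#' @return lag in time units, in `[0, T)`.
#' @export
phase_lag <- function(summary, series_a, series_b) {
  if (!inherits(summary, "limit_cycle_summary") || !summary$converged)
    stop("phase_lag() needs a converged limit-cycle summary")
  cy <- summary$cycle
  T_cyc <- summary$period
  peak_time <- function(v) {
    y <- cy[[v]]
    n <- length(y)
    i <- which.max(y[-n])  # drop duplicated endpoint of the period
    if (i == 1 || i >= n - 1) return(cy$t[i])
    h <- cy$t[i + 1] - cy$t[i]
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    off <- if (abs(denom) < 1e-300) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
    cy$t[i] + off * h
  }
  lag <- peak_time(series_b) - peak_time(series_a)
  lag %% T_cyc
}
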