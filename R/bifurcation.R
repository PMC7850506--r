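#' One-parameter bifurcation scan
#'
#' Walks a sorted grid of one model parameter, reporting at each value the
#' interior equilibrium (location + stability) and, where the equilibrium is
#' unstable, the limit-cycle extrema and period. Each cycle search is
#' warm-started from the previous grid point's attractor, which keeps the
#' scan cheap and the cycle branch continuous.
#'
#' @param params base [model_params()]; the scanned entry is overridden.
#' @param param_name one of `"lambda_S"`, `"lambda_F"`, `"r"`, `"K"`, `"d"`.
#' @param grid sorted numeric vector of parameter values.
#' @param cycle_opts list of extra arguments passed to [find_limit_cycle()].
#' @return a data.frame with one row per grid value: the scanned value,
#'   `exists`, `stability`, the equilibrium `eq_R, eq_N, eq_x`,
#'   `leading_real_part`, cycle `min`/`max` columns for R, N, x, and
#'   `period` (`NA` where the equilibrium is stable: the cycle branch is
#'   absent, not zero-period).
#' @export
scan_1d <- function(params, param_name = "lambda_S", grid,
                    cycle_opts = list()) {
  stopifnot(param_name %in% c("lambda_S", "lambda_F", "r", "K", "d"))
  if (is.unsorted(grid)) stop("'grid' must be sorted")
  rows <- vector("list", length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    p <- params
    p[[param_name]] <- grid[i]
    eq <- coexistence_equilibrium(p)
    row <- data.frame(value = grid[i], exists = eq$exists,
                      stability = eq$stability,
                      eq_R = eq$location[["R"]], eq_N = eq$location[["N"]],
                      eq_x = eq$location[["x"]],
                      leading_real_part = eq$leading_real_part,
                      cyc_min_R = NA_real_, cyc_max_R = NA_real_,
                      cyc_min_N = NA_real_, cyc_max_N = NA_real_,
                      cyc_min_x = NA_real_, cyc_max_x = NA_real_,
                      period = NA_real_)
    if (eq$exists && eq$stability == "unstable") {
      init <- if (is.null(warm)) perturbed_init(p) else warm
      lc <- do.call(find_limit_cycle,
                    c(list(params = p, init = init), cycle_opts))
      if (lc$converged) {
        ex <- lc$extrema
        row$cyc_min_R <- ex$min[ex$variable == "R"]
        row$cyc_max_R <- ex$max[ex$variable == "R"]
        row$cyc_min_N <- ex$min[ex$variable == "N"]
        row$cyc_max_N <- ex$max[ex$variable == "N"]
        row$cyc_min_x <- ex$min[ex$variable == "x"]
        row$cyc_max_x <- ex$max[ex$variable == "x"]
        row$period <- lc$period
        warm <- unlist(lc$cycle[1, c("R", "N", "x")])
      }
    } else {
      warm <- NULL
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- param_name
  rownames(out) <- NULL
  out
}

#' Hopf point along one parameter
#'
#' Bisects the leading real part of the interior equilibrium's eigenvalues
#' to locate where the equilibrium changes stability, and verifies that the
#' eigenvalue pair crossing the axis rotates (nonzero imaginary part), the
#' Hopf signature.
#'
#' @param params base [model_params()].
#' @param param_name scanned parameter, default the exploitation trait.
#' @param bracket length-2 numeric with opposite stability at the ends.
#' @param tol bisection stops when the bracket width falls below `tol`.
#' @return a list: `critical_value`, `leading_real_part` (residual at the
#'   root), `omega` (imaginary part, the linear oscillation frequency),
#'   `period_linear` (`2*pi/omega`).
#' @export
hopf_point <- function(params, param_name = "lambda_S", bracket,
                       tol = 1e-10) {
  lead_or_na <- function(v) {
    p <- params
    p[[param_name]] <- v
    eq <- coexistence_equilibrium(p)
    if (!eq$exists) NA_real_ else eq$leading_real_part
  }
  lead <- function(v) {
    l <- lead_or_na(v)
    if (is.na(l)) stop(sprintf(
      "no interior equilibrium at %s = %g inside bracket", param_name, v))
    l
  }
  lo <- bracket[1]; hi <- bracket[2]
  # clip the bracket to the sub-interval where the interior equilibrium
  # exists (the existence boundary can cut into a user-supplied bracket)
  f_lo <- lead_or_na(lo); f_hi <- lead_or_na(hi)
  if (is.na(f_lo) || is.na(f_hi)) {
    g <- seq(lo, hi, length.out = 101)
    vals <- vapply(g, lead_or_na, numeric(1))
    ok <- which(!is.na(vals))
    if (length(ok) < 2)
      stop("no interior equilibrium anywhere in the bracket")
    lo <- g[min(ok)]; hi <- g[max(ok)]
    f_lo <- vals[min(ok)]; f_hi <- vals[max(ok)]
  }
  if (sign(f_lo) == sign(f_hi))
    stop("stability does not differ at the bracket endpoints")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(lead(mid)) == sign(f_lo)) { lo <- mid } else { hi <- mid }
  }
  crit <- (lo + hi) / 2
  p <- params
  p[[param_name]] <- crit
  eq <- coexistence_equilibrium(p)
  omega <- max(abs(Im(eq$eigenvalues)))
  if (omega <= 1e-8)
    stop("leading eigenvalue at the root is real: not a Hopf point")
  list(critical_value = crit, leading_real_part = eq$leading_real_part,
       omega = omega, period_linear = 2 * pi / omega)
}

#' Hopf curve in the (lambda_S, lambda_F) plane
#'
#' For each solitary-feeding payoff `lambda_F` on a grid, locates the
#' critical exploitation level `lambda_S_c` where the coexistence
#' equilibrium changes stability. Successive points warm-start the bisection
#' bracket by continuation. Grid values for which no valid bracket exists
#' (no interior equilibrium, or no stability change in range) are skipped
#' with a message.
#'
#' @param lambda_F_grid sorted grid of `lambda_F` values.
#' @param base_params base [model_params()].
#' @param lambda_S_range outer search range for the critical `lambda_S`.
#' @param tol bisection tolerance on `lambda_S`.
#' @return a data.frame `lambda_F, lambda_S_critical, omega`.
#' @export
hopf_curve <- function(lambda_F_grid, base_params = model_params(),
                       lambda_S_range = c(1.2, 200), tol = 1e-8) {
  rows <- vector("list", length(lambda_F_grid))
  prev <- NULL
  for (i in seq_along(lambda_F_grid)) {
    p <- base_params
    p$lambda_F <- lambda_F_grid[i]
    br <- find_hopf_bracket(p, lambda_S_range, prev)
    if (is.null(br)) {
      message(sprintf("hopf_curve: no bracket at lambda_F = %g; skipped",
                      lambda_F_grid[i]))
      next
    }
    hp <- hopf_point(p, "lambda_S", br, tol = tol)
    prev <- hp$critical_value
    rows[[i]] <- data.frame(lambda_F = lambda_F_grid[i],
                            lambda_S_critical = hp$critical_value,
                            omega = hp$omega)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# scan lambda_S for a sign change of the leading real part, preferring a
# window around a continuation guess
find_hopf_bracket <- function(params, lambda_S_range, guess = NULL) {
  lead_or_na <- function(v) {
    p <- params
    p$lambda_S <- v
    eq <- coexistence_equilibrium(p)
    if (!eq$exists) NA_real_ else eq$leading_real_part
  }
  grids <- list()
  if (!is.null(guess))
    grids <- c(grids, list(guess * c(0.7, 0.85, 1, 1.2, 1.4)))
  grids <- c(grids, list(exp(seq(log(lambda_S_range[1]),
                                 log(lambda_S_range[2]), length.out = 40))))
  for (g in grids) {
    g <- g[g >= lambda_S_range[1] & g <= lambda_S_range[2]]
    vals <- vapply(g, lead_or_na, numeric(1))
    ok <- which(!is.na(vals))
    if (length(ok) < 2) next
    g <- g[ok]; vals <- vals[ok]
    sw <- which(vals[-1] * vals[-length(vals)] < 0)
    if (length(sw) > 0) return(c(g[sw[1]], g[sw[1] + 1]))
  }
  NULL
}

#' Two-parameter regime sweep
#'
#' Classifies each cell of a `(lambda_S, lambda_F)` grid as stable
#' coexistence (SC) or limit cycle (LC) from the equilibrium eigenvalues,
#' and in LC cells measures the cycle: per-variable amplitudes, period and
#' generation-time ratios. Cycle searches are warm-started along each
#' `lambda_S` row. SC cells carry amplitude 0 and an undefined (`NA`)
#' period.
#'
#' @param lambda_S_grid,lambda_F_grid sorted grids.
#' @param base_params base [model_params()].
#' @param cycle_opts list of extra arguments for [find_limit_cycle()].
#' @return a long-format data.frame with columns `lambda_S, lambda_F,
#'   regime, amplitude_R, amplitude_N, amplitude_x, period, ratio_max,
#'   ratio_mean`.
#' @export
sweep_2d <- function(lambda_S_grid, lambda_F_grid,
                     base_params = model_params(), cycle_opts = list()) {
  rows <- list()
  for (lF in lambda_F_grid) {
    warm <- NULL
    for (lS in lambda_S_grid) {
      p <- base_params
      p$lambda_F <- lF
      p$lambda_S <- lS
      eq <- coexistence_equilibrium(p)
      row <- data.frame(lambda_S = lS, lambda_F = lF, regime = "none",
                        amplitude_R = NA_real_, amplitude_N = NA_real_,
                        amplitude_x = NA_real_, period = NA_real_,
                        ratio_max = NA_real_, ratio_mean = NA_real_)
      if (eq$exists) {
        if (eq$stability == "unstable") {
          row$regime <- "LC"
          init <- if (is.null(warm)) perturbed_init(p) else warm
          lc <- tryCatch(
            do.call(find_limit_cycle,
                    c(list(params = p, init = init), cycle_opts)),
            error = function(e) NULL)
          if (!is.null(lc) && lc$converged) {
            ex <- lc$extrema
            row$amplitude_R <- ex$amplitude[ex$variable == "R"]
            row$amplitude_N <- ex$amplitude[ex$variable == "N"]
            row$amplitude_x <- ex$amplitude[ex$variable == "x"]
            row$period <- lc$period
            gr <- generation_ratio(lc)
            row$ratio_max <- gr$ratio_vs_max_rate
            row$ratio_mean <- gr$ratio_vs_mean_rate
            warm <- unlist(lc$cycle[1, c("R", "N", "x")])
          } else {
            message(sprintf(
              "sweep_2d: cycle search failed at (lS=%g, lF=%g)", lS, lF))
          }
        } else {
          row$regime <- "SC"
          row$amplitude_R <- 0
          row$amplitude_N <- 0
          row$amplitude_x <- 0
          warm <- NULL
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
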