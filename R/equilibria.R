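#' Analytic Jacobian of the eco-evolutionary system
#'
#' Partial derivatives of [eco_evo_rhs()] with respect to `(R, N, x)`,
#' evaluated at an arbitrary state. The aggregation probability is treated
#' as piecewise linear: its slope is zero where it is clipped at 1.
#'
#' @param state numeric vector `c(R, N, x)`.
#' @param params a [model_params()] object.
#' @return a 3x3 numeric matrix.
#' @export
model_jacobian <- function(state, params) {
  R <- state[[1]]; N <- state[[2]]; x <- state[[3]]
  r <- params$r; K <- params$K; d <- params$d
  lF <- params$lambda_F; lS <- params$lambda_S
  a <- params$aggregation_rule$alone_scale
  q <- min(a * R / K, 1)
  qp <- if (a * R / K < 1) a / K else 0
  p_F <- q * lF
  p_S <- x * (1 - q) * lS
  p_bar <- x * p_F + (1 - x) * p_S
  dpF_R <- lF * qp
  dpS_R <- -x * lS * qp
  dpS_x <- (1 - q) * lS
  dpb_R <- x * dpF_R + (1 - x) * dpS_R
  dpb_x <- p_F - p_S + (1 - x) * dpS_x
  matrix(c(
    r * (1 - 2 * R / K) - N,            -R,             0,
    N * (dpb_R * R + p_bar),            p_bar * R - d,  N * R * dpb_x,
    x * (1 - x) * ((p_F - p_S) + R * (dpF_R - dpS_R)), 0,
    (1 - 2 * x) * R * (p_F - p_S) - x * (1 - x) * R * dpS_x
  ), nrow = 3, ncol = 3, byrow = TRUE)
}

classify_stability <- function(leading_real_part, marginal_tol = 1e-8) {
  if (abs(leading_real_part) < marginal_tol) "marginal"
  else if (leading_real_part < 0) "stable"
  else "unstable"
}

equilibrium_report <- function(label, location, params, exists = TRUE,
                               marginal_tol = 1e-8) {
  ev <- eigen(model_jacobian(location, params), only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  lead <- Re(ev[1])
  structure(
    list(label = label,
         location = c(R = unname(location[[1]]), N = unname(location[[2]]),
                      x = unname(location[[3]])),
         eigenvalues = ev,
         stability = classify_stability(lead, marginal_tol),
         leading_real_part = lead,
         exists = exists,
         residual = sqrt(sum(eco_evo_rhs(location, params)^2))),
    class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("%s equilibrium (exists: %s, %s)\n", x$label, x$exists,
              x$stability))
  cat(sprintf("  R = %.8g, N = %.8g, x = %.8g   |rhs| = %.2g\n",
              x$location[["R"]], x$location[["N"]], x$location[["x"]],
              x$residual))
  cat("  eigenvalues:",
      paste(sprintf("%.6g%+.6gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  invisible(x)
}

# Closed-form interior candidate: p_F = p_S and p_bar * R = d give
# q(R) R lambda_F = d (with q = a R / K), hence R = sqrt(d K / (a lambda_F)),
# x = q lambda_F / ((1 - q) lambda_S), N = r (1 - R / K).
coexistence_candidate <- function(params) {
  a <- params$aggregation_rule$alone_scale
  Rhat <- sqrt(params$d * params$K / (a * params$lambda_F))
  q <- a * Rhat / params$K
  xhat <- if (q < 1) q * params$lambda_F / ((1 - q) * params$lambda_S) else Inf
  c(R = Rhat, N = params$r * (1 - Rhat / params$K), x = xhat)
}

#' Interior (coexistence) equilibrium
#'
#' Solves `eco_evo_rhs = 0` for the interior fixed point where resource,
#' population size and fast-cell frequency are all constant and both cell
#' types are present. The closed-form candidate (from equating the two type
#' payoffs and balancing births against deaths) seeds a Newton iteration on
#' the full right-hand side; the polished root is reported together with its
#' Jacobian eigenvalues and linear stability class.
#'
#' @param params a [model_params()] object.
#' @param tol residual norm at which Newton polishing stops.
#' @param marginal_tol half-width of the leading-eigenvalue band classified
#'   as `"marginal"`.
#' @return an `equilibrium_report` with fields `label`, `location`,
#'   `eigenvalues`, `stability`, `leading_real_part`, `exists`, `residual`.
#'   `exists` is `FALSE` (with the unpolished candidate reported) when the
#'   candidate leaves the interior: this is a valid report, not an error.
#' @examples
#' eq <- coexistence_equilibrium(model_params())
#' eq$location
#' @export
coexistence_equilibrium <- function(params, tol = 1e-12,
                                    marginal_tol = 1e-8) {
  cand <- coexistence_candidate(params)
  exists <- is.finite(cand[["x"]]) && cand[["x"]] > 0 && cand[["x"]] < 1 &&
    cand[["R"]] > 0 && cand[["R"]] < params$K
  if (!exists) {
    cand["x"] <- min(max(cand[["x"]], 0), 1)
    return(equilibrium_report("coexistence", cand, params, exists = FALSE,
                              marginal_tol = marginal_tol))
  }
  y <- cand
  for (i in seq_len(50)) {
    f <- eco_evo_rhs(y, params)
    if (sqrt(sum(f^2)) < tol) break
    y <- y - solve(model_jacobian(y, params), f)
  }
  equilibrium_report("coexistence", y, params, exists = TRUE,
                     marginal_tol = marginal_tol)
}

#' Boundary equilibria
#'
#' Fixed points on the faces of the state space: the extinction states
#' `(R = K, N = 0)` -- where the fast-cell frequency is dynamically
#' arbitrary, reported at the representatives `x = 0` and `x = 1` -- and the
#' fast-only state `x = 1` with the `(R, N)` pair of the single-type
#' consumer-resource subsystem (present when fast cells can sustain
#' themselves, i.e. the subsystem root lies inside `(0, K)`).
#'
#' @param params a [model_params()] object.
#' @param marginal_tol marginal-stability band as in
#'   [coexistence_equilibrium()].
#' @return a list of `equilibrium_report` objects.
#' @export
boundary_equilibria <- function(params, marginal_tol = 1e-8) {
  reps <- list(
    equilibrium_report("extinction", c(params$K, 0, 0), params,
                       marginal_tol = marginal_tol),
    equilibrium_report("extinction", c(params$K, 0, 1), params,
                       marginal_tol = marginal_tol))
  # fast-only subsystem: p_F(R) R = d, N = r (1 - R/K)
  a <- params$aggregation_rule$alone_scale
  Rhat <- sqrt(params$d * params$K / (a * params$lambda_F))
  if (Rhat > 0 && Rhat < params$K) {
    loc <- c(Rhat, params$r * (1 - Rhat / params$K), 1)
    reps <- c(reps, list(
      equilibrium_report("fast_only", loc, params,
                         marginal_tol = marginal_tol)))
  }
  reps
}

#' Coexistence-existence condition, two ways
#'
#' Evaluates (i) the compact printed inequality
#' `lambda_F K / d > 1 + lambda_F / lambda_S` and (ii) the direct check that
#' the closed-form interior candidate actually lies inside the state space
#' (`x` in (0,1), `R` in (0,K)), and reports whether the two agree. The two
#' tests are kept separate deliberately: the direct substitution yields a
#' square-root form that is not algebraically identical to the printed one,
#' and disagreements are flagged rather than hidden.
#'
#' @param params a [model_params()] object.
#' @return a list with logical fields `printed_condition`, `direct_check`,
#'   `agree`.
#' @export
existence_condition <- function(params) {
  printed <- params$lambda_F * params$K / params$d >
    1 + params$lambda_F / params$lambda_S
  cand <- coexistence_candidate(params)
  direct <- is.finite(cand[["x"]]) && cand[["x"]] > 0 && cand[["x"]] < 1 &&
    cand[["R"]] > 0 && cand[["R"]] < params$K
  list(printed_condition = printed, direct_check = direct,
       agree = printed == direct)
}

# Neutral (fixed-x) two-variable submodel ------------------------------------

#' Interior equilibrium of the neutral submodel
#'
#' For a frozen fast-cell frequency the demography reduces to two ODEs. The
#' interior equilibrium solves `p_bar(x_fixed, R) R = d` for the smallest
#' root in `(0, K)` with `N = r (1 - R/K) > 0`, and is classified by the
#' eigenvalues of the 2x2 Jacobian.
#'
#' @param x_fixed frozen fast-cell frequency in `(0, 1]`.
#' @param params a [model_params()] object.
#' @return a list with `location` (`c(R, N)`), `eigenvalues`, `stability`,
#'   `leading_real_part`, `exists`.
#' @export
neutral_equilibrium <- function(x_fixed, params) {
  g <- function(R) {
    p <- payoffs(x_fixed, R, params)
    p$p_bar * R - params$d
  }
  Rs <- seq(1e-9 * params$K, params$K * (1 - 1e-9), length.out = 2048)
  gv <- vapply(Rs, g, numeric(1))
  idx <- which(gv[-1] * gv[-length(gv)] <= 0)
  if (length(idx) == 0)
    return(list(location = c(R = NA_real_, N = NA_real_),
                eigenvalues = complex(0), stability = NA_character_,
                leading_real_part = NA_real_, exists = FALSE))
  root <- stats::uniroot(g, c(Rs[idx[1]], Rs[idx[1] + 1]), tol = 1e-14)$root
  N <- params$r * (1 - root / params$K)
  J <- neutral_jacobian(root, N, x_fixed, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  list(location = c(R = root, N = N), eigenvalues = ev,
       stability = classify_stability(Re(ev[1])),
       leading_real_part = Re(ev[1]), exists = N > 0)
}

neutral_jacobian <- function(R, N, x_fixed, params) {
  a <- params$aggregation_rule$alone_scale
  qp <- if (a * R / params$K < 1) a / params$K else 0
  p <- payoffs(x_fixed, R, params)
  dpb_R <- x_fixed * params$lambda_F * qp -
    (1 - x_fixed) * x_fixed * params$lambda_S * qp
  matrix(c(
    params$r * (1 - 2 * R / params$K) - N, -R,
    N * (dpb_R * R + p$p_bar),             p$p_bar * R - params$d
  ), 2, 2, byrow = TRUE)
}
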