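#' Canonical study scenarios
#'
#' Deterministic parameter/initial-condition bundles covering the regimes
#' the analyses visit. `fig2_lc` is the canonical oscillatory set
#' `(r, K, d, lambda_F, lambda_S) = (1, 1, 1, 28, 16)`; `sc_low_exploit`
#' keeps the same ecology with exploitation lowered to the stable
#' coexistence regime (its stability is asserted at construction);
#' `near_hopf` sits just above the oscillation onset at the same
#' `lambda_F`; `neutral_fixed_x` freezes the fast-cell frequency at the
#' canonical equilibrium value for the purely ecological submodel.
#'
#' @return a named list of `"scenario"` objects, each with fields `name`,
#'   `params`, `init`, `horizon`, `seed`, and (for the neutral scenario)
#'   `x_fixed`.
#' @export
canonical_scenarios <- function() {
  base <- model_params(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 16)
  mk <- function(name, params, horizon, seed = 1L, x_fixed = NULL) {
    sc <- list(name = name, params = params,
               init = perturbed_init(params, seed = seed),
               horizon = horizon, seed = seed)
    if (!is.null(x_fixed)) sc$x_fixed <- x_fixed
    structure(sc, class = "scenario")
  }
  low <- model_params(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 8)
  stopifnot(coexistence_equilibrium(low)$stability == "stable")
  near <- model_params(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 14.2)
  stopifnot(coexistence_equilibrium(near)$stability == "unstable")
  xhat <- coexistence_equilibrium(base)$location[["x"]]
  list(
    fig2_lc = mk("fig2_lc", base, horizon = 300),
    sc_low_exploit = mk("sc_low_exploit", low, horizon = 150),
    near_hopf = mk("near_hopf", near, horizon = 600),
    neutral_fixed_x = mk("neutral_fixed_x", base, horizon = 150,
                         x_fixed = xhat))
}

#' Seeded parameter draws from a dynamical regime
#'
#' Rejection-samples model parameter sets whose interior equilibrium exists
#' and falls in the requested regime: `"SC"` (stable coexistence) or
#' `"LC"` (unstable equilibrium, oscillatory). Draws are log-uniform over
#' ecologically plausible ranges (`r, K, d` in [0.5, 2]; `lambda_F` in
#' [4, 60]; `lambda_S` in [1.5, 40]) and fully reproducible from the seed.
#'
#' @param region `"SC"` or `"LC"`.
#' @param n number of parameter sets.
#' @param seed RNG seed.
#' @param max_rejections rejection budget before erroring.
#' @return a list of `n` [model_params()] objects.
#' @export
sample_params <- function(region = c("SC", "LC"), n, seed = 1L,
                          max_rejections = 1000 * n) {
  region <- match.arg(region)
  stopifnot(n >= 1)
  withr_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    tries <- 0L
    lunif <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
    while (got < n) {
      tries <- tries + 1L
      if (tries > max_rejections)
        stop(sprintf("could not find %d '%s' parameter sets in %d draws",
                     n, region, max_rejections))
      p <- model_params(r = lunif(0.5, 2), K = lunif(0.5, 2),
                        d = lunif(0.5, 2), lambda_F = lunif(4, 60),
                        lambda_S = lunif(1.5, 40))
      eq <- coexistence_equilibrium(p)
      if (!eq$exists || eq$stability == "marginal") next
      if ((region == "SC") != (eq$stability == "stable")) next
      got <- got + 1L
      out[[got]] <- p
    }
    out
  })
}
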