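# canonical oscillatory parameter set used throughout
fig2_params <- function() {
  model_params(r = 1, K = 1, d = 1, lambda_F = 28, lambda_S = 16)
}

# the canonical limit cycle is expensive enough to share across test files
.fixture_cache <- new.env(parent = emptyenv())

fig2_cycle <- function() {
  if (is.null(.fixture_cache$lc))
    .fixture_cache$lc <- find_limit_cycle(fig2_params())
  .fixture_cache$lc
}

fig2_hopf <- function() {
  if (is.null(.fixture_cache$hp))
    .fixture_cache$hp <- hopf_point(fig2_params(), "lambda_S", c(2, 16),
                                    tol = 1e-10)
  .fixture_cache$hp
}

# independent central-finite-difference Jacobian oracle
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    J[, j] <- (eco_evo_rhs(state + e, params) -
                 eco_evo_rhs(state - e, params)) / (2 * h)
  }
  J
}
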