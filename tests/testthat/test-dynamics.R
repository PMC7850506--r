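test_that("the equilibrium is a fixed point of the integrator", {
  p <- fig2_params()
  eq <- coexistence_equilibrium(p)
  tr <- simulate_model(p, unname(eq$location), t_span = 30)
  dev <- max(abs(t(as.matrix(tr$states[, c("R", "N", "x")])) -
                   unname(eq$location)))
  expect_lt(dev, 1e-7)
})

test_that("canonical parameters sustain oscillations that straddle the equilibrium", {
  lc <- fig2_cycle()
  expect_true(lc$converged)
  expect_gt(lc$period, 1)
  eq <- coexistence_equilibrium(fig2_params())
  ex <- lc$extrema
  for (v in c("R", "N", "x")) {
    expect_lt(ex$min[ex$variable == v], eq$location[[v]])
    expect_gt(ex$max[ex$variable == v], eq$location[[v]])
  }
  # period-detection self-check: per-capita net growth integrates to zero
  # over one period (log N returns to itself)
  expect_lt(abs(lc$net_growth_integral), 1e-4)
})

test_that("below the bifurcation the trajectory settles on the equilibrium", {
  lc <- find_limit_cycle(model_params(lambda_S = 8))
  expect_false(lc$converged)
  expect_lt(max(lc$extrema$amplitude), 1e-6)
})

test_that("the cycle is the same attractor from different starting points", {
  p <- fig2_params()
  lc1 <- fig2_cycle()
  lc2 <- find_limit_cycle(p, init = c(0.5, 0.3, 0.6))
  expect_true(lc2$converged)
  expect_equal(lc2$period, lc1$period, tolerance = 1e-4)
})

test_that("period and amplitude are robust to halving integration tolerances", {
  lc1 <- fig2_cycle()
  lc2 <- find_limit_cycle(fig2_params(), rtol = 5e-11, atol = 5e-13)
  expect_equal(lc2$period, lc1$period, tolerance = 1e-4)
  expect_equal(lc2$extrema$amplitude, lc1$extrema$amplitude,
               tolerance = 1e-4)
})

test_that("observables partition the population and track the resource", {
  lc <- fig2_cycle()
  obs <- lc$cycle
  # the four cell-count compartments always sum to the population size
  total <- obs$n_fast_alone + obs$n_fast_grouped + obs$n_slow_alone +
    obs$n_slow_grouped
  expect_equal(total, obs$N, tolerance = 1e-12)
  # at carrying capacity every cell is solitary
  p <- fig2_params()
  at_K <- derive_observables(data.frame(t = 0, R = p$K, N = 0.7, x = 0.3),
                             params = p)
  expect_equal(at_K$n_fast_grouped, 0)
  expect_equal(at_K$n_slow_grouped, 0)
  # grouping is anti-phase with the resource: grouped fraction peaks at the
  # resource minimum
  expect_equal(which.max(obs$frac_grouped), which.min(obs$R))
})

test_that("cycle phases follow the aggregation narrative", {
  lc <- fig2_cycle()
  obs <- lc$cycle
  n <- nrow(obs) - 1  # drop duplicated endpoint
  i_Rmin <- which.min(obs$R[1:n])
  after <- function(i, frac) 1 + ((i - 1 + round(frac * n)) %% n)
  # just after the resource minimum (max aggregation) cheaters rise: the
  # fast-cell fraction declines
  i1 <- after(i_Rmin, 0.1)
  expect_lt(obs$x[after(i_Rmin, 0.15)], obs$x[i1])
  # and the resource recovers
  expect_gt(obs$R[after(i_Rmin, 0.25)], obs$R[i_Rmin])
})

test_that("the life-like cycle is slower than a cell generation", {
  lc <- fig2_cycle()
  gr <- generation_ratio(lc)
  expect_gt(gr$ratio_vs_mean_rate, 1)
  expect_gt(gr$ratio_vs_max_rate, 1)
  expect_gte(gr$ratio_vs_max_rate, gr$ratio_vs_mean_rate)
  # quadrature refinement: doubling the sampling density moves the ratios
  # by well under 1%
  lc2 <- find_limit_cycle(fig2_params(), n_period_samples = 4001)
  gr2 <- generation_ratio(lc2)
  expect_equal(gr2$ratio_vs_max_rate, gr$ratio_vs_max_rate,
               tolerance = 0.01)
  expect_equal(gr2$ratio_vs_mean_rate, gr$ratio_vs_mean_rate,
               tolerance = 0.01)
  expect_error(generation_ratio(find_limit_cycle(model_params(lambda_S = 8))),
               "converged")
})

test_that("phase lags: population trails resource; peak-matching agrees with cross-correlation", {
  lc <- fig2_cycle()
  expect_equal(phase_lag(lc, "R", "R"), 0, tolerance = 1e-9)
  lag_RN <- phase_lag(lc, "R", "N")
  expect_gt(lag_RN, 0)
  expect_lt(lag_RN, lc$period)
  # oracle: both peak-matching and circular cross-correlation must recover
  # a known lag imposed by circularly shifting the same waveform
  obs <- lc$cycle
  n <- nrow(obs) - 1
  dt <- obs$t[2] - obs$t[1]
  k_true <- round(0.23 * n)
  lc_shift <- lc
  lc_shift$cycle$shifted <- obs$R[1 + ((seq_len(nrow(obs)) - 1 - k_true) %% n)]
  lag_peak <- phase_lag(lc_shift, "R", "shifted")
  expect_equal(lag_peak, k_true * dt, tolerance = 2 * dt / (k_true * dt))
  a <- obs$R[1:n] - mean(obs$R[1:n])
  b <- lc_shift$cycle$shifted[1:n] - mean(lc_shift$cycle$shifted[1:n])
  cc <- vapply(0:(n - 1), function(k)
    sum(a * b[1 + ((seq_len(n) - 1 + k) %% n)]), numeric(1))
  lag_cc <- (which.max(cc) - 1) %% n * dt
  expect_equal(lag_cc, k_true * dt, tolerance = 2 * dt / (k_true * dt))
  expect_lt(min(abs(lag_peak - lag_cc),
                lc$period - abs(lag_peak - lag_cc)), dt + 1e-9)
})
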