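test_that("equilibrium invasion fitness: neutrality, sign, scale", {
  p <- fig2_params()
  expect_equal(invasion_fitness_equilibrium(16, 16, p)$fitness, 0)
  # hand substitution d (mut - res) / res
  expect_equal(invasion_fitness_equilibrium(16.1, 16, p)$fitness, 0.00625)
  set.seed(3)
  for (i in 1:20) {
    res <- runif(1, 7, 20)
    mut <- res + runif(1, -1, 1)
    S <- invasion_fitness_equilibrium(mut, res, p)$fitness
    expect_identical(sign(S), sign(mut - res))
  }
  # linear in the increment, reciprocal in the resident trait
  S1 <- invasion_fitness_equilibrium(10.1, 10, p)$fitness
  S2 <- invasion_fitness_equilibrium(10.2, 10, p)$fitness
  expect_equal(S2, 2 * S1)
  expect_gt(S1, invasion_fitness_equilibrium(12.1, 12, p)$fitness)
})

test_that("cycle-averaged fitness: resident is neutral against itself and mutants gain", {
  p <- fig2_params()
  lc <- fig2_cycle()
  self <- invasion_fitness_cycle(16, 16, p, resident_cycle = lc)
  # bounded by how exactly the sampled orbit closes, not by quadrature
  expect_lt(abs(self$fitness), 1e-6)
  up <- invasion_fitness_cycle(16.1, 16, p, resident_cycle = lc)
  expect_gt(up$fitness, 0)
  down <- invasion_fitness_cycle(15.9, 16, p, resident_cycle = lc)
  expect_lt(down$fitness, 0)
})

test_that("cycle-averaged fitness approaches the equilibrium expression near onset", {
  hp <- fig2_hopf()
  lam <- hp$critical_value + 0.05   # small-amplitude cycle
  p <- model_params(lambda_S = lam)
  S_an <- p$d * 0.1 / lam
  S_cy <- invasion_fitness_cycle(lam + 0.1, lam, p)$fitness
  expect_equal(S_cy, S_an, tolerance = 1e-3)
})

test_that("direct simulation cross-validates both other estimators", {
  p <- fig2_params()
  lc <- fig2_cycle()
  S_cy <- invasion_fitness_cycle(16.1, 16, p, resident_cycle = lc)$fitness
  S_di <- invasion_fitness_direct(16.1, 16, p, resident_cycle = lc)$fitness
  expect_equal(S_di, S_cy, tolerance = 0.05)
  # analytic oracle in the stable regime, and decay of a milder mutant
  p8 <- model_params(lambda_S = 8)
  S_an <- invasion_fitness_equilibrium(8.1, 8, p8)$fitness
  S_d8 <- invasion_fitness_direct(8.1, 8, p8)$fitness
  expect_equal(S_d8, S_an, tolerance = 0.01)
  S_down <- invasion_fitness_direct(7.9, 8, p8)$fitness
  expect_lt(S_down, 0)
})

test_that("trait substitution walks exploitation up and into the cyclic regime", {
  tr <- trait_substitution(fig2_params(), lambda_S_start = 13, delta = 0.1,
                           n_steps = 15)
  expect_true(all(tr$accepted))
  expect_true(all(tr$S > 0))
  expect_true(all(diff(tr$lambda_S_res) > 0))
  # exactly one SC -> LC transition along the walk
  flips <- sum(tr$regime[-1] != tr$regime[-nrow(tr)])
  expect_identical(tr$regime[1], "SC")
  expect_identical(tr$regime[nrow(tr)], "LC")
  expect_identical(flips, 1L)
  expect_identical(unique(tr$method[tr$regime == "SC"]), "analytic_eq")
  expect_identical(unique(tr$method[tr$regime == "LC"]), "cycle_average")
  # in the stable regime the fitness is exactly d delta / lambda_S*, a
  # strictly decreasing sequence
  sc <- tr[tr$regime == "SC", ]
  expect_equal(sc$S, 1 * 0.1 / sc$lambda_S_res, tolerance = 1e-12)
})

test_that("invasion fitness scales as the reciprocal of the resident trait", {
  tr_sc <- trait_substitution(fig2_params(), lambda_S_start = 7,
                              delta = 0.1, n_steps = 12)
  expect_identical(unique(tr_sc$regime), "SC")
  fit_sc <- reciprocal_scaling_check(tr_sc)
  expect_equal(fit_sc$slope, -1, tolerance = 1e-6)
  tr_lc <- trait_substitution(fig2_params(), lambda_S_start = 15,
                              delta = 0.1, n_steps = 12)
  expect_identical(unique(tr_lc$regime), "LC")
  fit_lc <- reciprocal_scaling_check(tr_lc)
  expect_gt(fit_lc$slope, -1.2)
  expect_lt(fit_lc$slope, -0.8)
  expect_error(reciprocal_scaling_check(tr_lc[1:5, ]), "at least 10")
})

test_that("mutant and resident never coexist: fixation or loss", {
  p <- fig2_params()
  lc <- fig2_cycle()
  base <- unlist(lc$cycle[1, c("R", "N", "x")])
  slow <- 1 - base[["x"]]
  # advantageous mutant sweeps to fixation within the slow type
  up <- simulate_three_strategy(p, 17, c(base[[1]], base[[2]], base[[3]],
                                         slow * 0.99, slow * 0.01),
                                t_span = 1500, dt = 0.5)
  share_up <- up$x_Sm / (up$x_Sr + up$x_Sm)
  expect_gt(share_up[nrow(up)], 0.999)
  # disadvantageous mutant is lost
  dn <- simulate_three_strategy(p, 15, c(base[[1]], base[[2]], base[[3]],
                                         slow * 0.99, slow * 0.01),
                                t_span = 1500, dt = 0.5)
  share_dn <- dn$x_Sm / (dn$x_Sr + dn$x_Sm)
  expect_lt(share_dn[nrow(dn)], 1e-5)
})
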