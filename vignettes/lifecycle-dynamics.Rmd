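---
title: "Life-like cycles in aggregative multicellularity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-like cycles in aggregative multicellularity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevocycle)
```

## The model

Aggregative multicellular microbes (the *Dictyostelium* life style) alternate
between free-living cells and facultative multicellular aggregates. This
package studies a minimal dynamical model of how that alternation can emerge
as a collective *timescale* from the coupling of ecology and evolution,
without any externally imposed clock.

A population of $N$ cells feeds on a shared resource of density $R$ that
grows logistically (rate $r$, carrying capacity $K$) and is consumed at unit
encounter rate. Cells carry one of two heritable motility strategies: a
fraction $x$ is fast-moving, a fraction $1-x$ slow-moving. The state
$(R, N, x)$ evolves as

$$
\begin{aligned}
\dot R &= R\left[r\left(1-\tfrac{R}{K}\right) - N\right],\\
\dot N &= N\left[\bar p(x,R)\,R - d\right],\\
\dot x &= x(1-x)\,R\,[p_F(x,R) - p_S(x,R)],
\end{aligned}
$$

a resource–consumer pair coupled to a replicator equation through the
payoffs. All rates are nondimensional (the resource–cell encounter rate is
scaled to 1), so one time unit is the encounter timescale and all payoffs
are dimensionless reproductive efficiencies.

The payoffs encode a public-goods conflict inside aggregates:

* the probability that a cell is solitary tracks resource availability,
  $q(R) = R/K$ — everyone forages alone at carrying capacity, everyone
  aggregates at depletion (`probability_alone()`);
* solitary fast cells feed efficiently: $p_F = q(R)\,\lambda_F$; inside a
  group they fuel collective transport and gain nothing;
* slow cells gain nothing alone, but inside a group exploit the transport
  provided by fast cells: $p_S = x\,(1-q(R))\,\lambda_S$, increasing in the
  fast-cell fraction;
* $\bar p = x\,p_F + (1-x)\,p_S$ is the mean payoff and
  $\bar p R$ the per-capita birth rate.

This is the extreme version of the trade-off (each type reproduces in only
one social context); it makes the conflict as hard as possible and keeps the
equilibrium algebra closed-form.

### Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `r` | resource maximum growth rate | 1 | 1/time |
| `K` | resource carrying capacity | 1 | resource density |
| `d` | cell death rate | 1 | 1/time |
| `lambda_F` | fast-cell solitary feeding efficiency | 28 | dimensionless |
| `lambda_S` | slow-cell exploitation efficiency (the evolvable trait) | 16 | dimensionless |

The defaults are the canonical oscillatory operating point used throughout
the analyses; `canonical_scenarios()` also fixes a stable low-exploitation
counterpart (`lambda_S = 8`), a near-onset set (`lambda_S = 14.2`) and a
frozen-frequency neutral set.

### The bounded aggregation variant

The linear rule $q = R/K$ is the simplest choice consistent with "solitary
when resource is plentiful, grouped when depleted". As a robustness family
we expose a bounded variant $q = a R/K$ with $a \in (0,1]$ (clipped to
$[0,1]$): a fraction $1-a$ of the population remains aggregated even at
carrying capacity. This is our interpretation of a proportionality factor
different from one; only the linear rule is used in the headline analyses.

## Equilibria and linear stability

Setting the vector field to zero by hand gives the interior (coexistence)
candidate

$$
\hat R = \sqrt{dK/\lambda_F},\qquad
\hat N = r(1-\hat R/K),\qquad
\hat x = \frac{\lambda_F \hat R}{\lambda_S (K-\hat R)},
$$

which `coexistence_equilibrium()` polishes by Newton iteration on the full
right-hand side (residual tolerance $10^{-12}$); the polished root, not the
formula, is the source of truth. Stability comes from the analytic Jacobian
(`model_jacobian()`, verified against central finite differences in the test
suite). Eigenvalue real parts within $10^{-8}$ of zero are classified
*marginal* — the band the Hopf bisection needs.

Two remarks the implementation surfaces deliberately:

* The compact existence inequality $\lambda_F K/d > 1 + \lambda_F/\lambda_S$
  is **not** equivalent to direct substitution, which yields a square-root
  form. At the default ecology the direct interior check requires
  $\lambda_S \gtrsim 6.5$ while the inequality only asks
  $\lambda_S > 28/27$. `existence_condition()` reports both and an `agree`
  flag; the disagreements (always printed-true/direct-false) are recorded by
  `analysis/02_equilibria_stability.R` rather than hidden.
* On the extinction manifold $N = 0$ the frequency $x$ is dynamically
  arbitrary; `boundary_equilibria()` reports the $x \in \{0, 1\}$
  representatives by convention.

With the frequency frozen (`neutral_equilibrium()`), the two-dimensional
demographic submodel always has a stable interior equilibrium (its Jacobian
trace is $-r\hat R/K < 0$ at the smallest interior root): sustained
oscillation requires the eco-evolutionary coupling, which is the scientific
point of the neutral control.

## Cycle detection and observables

`find_limit_cycle()` is simulation-based (shooting/collocation solvers are
overkill in three dimensions):

* **Integrator.** `deSolve::lsoda` with `rtol = 1e-10`, `atol = 1e-12`.
  Amplitudes near the Hopf curve scale like the square root of the parameter
  excess, so loose tolerances visibly bias the scaling exponent.
* **Poincaré section.** Upward crossings of $x$ through its mean over a probe
  window; $x$ has a single maximum per cycle here. Crossing times are refined
  by cubic Hermite interpolation using exact derivative values from the
  vector field, so period estimates are limited by the integrator, not the
  output grid.
* **Transient rule.** Periods are accepted when three successive returns
  agree to $10^{-6}$ relative, capped at 500 cycles.
* **Spiral guard.** A trajectory spiralling into a stable focus shows stable
  return times long before it dies; a cycle is only accepted once the
  chunk-to-chunk oscillation amplitude has stopped contracting (ratio
  $\ge 0.99$). Decay to equilibrium is reported as `converged = FALSE` with
  near-zero amplitude, never as an exception.
* **Amplitude polish.** Close to onset the Floquet contraction is weak and
  the amplitude converges much more slowly than the period;
  `amp_rel_tol` optionally iterates in ten-period blocks until the
  one-period amplitude is stationary. The Hopf-scaling analyses use
  `1e-5`.
* **Default start.** The equilibrium displaced by a 1% multiplicative
  perturbation along a seeded direction (`perturbed_init()`), for exact
  reproducibility.

A strong self-check ties period detection to demography: along a true cycle
$\oint (\bar p R - d)\,dt = 0$ (log $N$ returns to itself); the summary
stores this integral and the tests bound it.

### Generation-time ratios

The net per-capita growth rate $\bar p R - d$ averages to exactly zero over a
period, so it cannot define a "mean demographic timescale". We therefore use
the per-capita **birth** rate $b(t) = \bar p R$ for both ratios:
$T \cdot \max_t b$ (fastest generation timescale) and $T \cdot \bar b$
(mean timescale, which equals $d\,T$ by the integral identity above).
Per-type birth-rate ratios ($p_F R$, $p_S R$) are reported alongside, since
either reading of "growth rate of the two cell types" is defensible. Both
headline ratios exceed one across the cycle region: the emergent
aggregation–dispersal cycle is slower than a cell generation, which is what
makes it a *life-cycle-like* timescale rather than a demographic ripple.

### Phase structure

`phase_lag()` reports peak-to-peak delays circularly in $[0, T)$, with
quadratic peak refinement. Peak-matching and circular cross-correlation are
*different* lag measures for non-sinusoidal waveforms (they differ by ~6% of
a period for $R$ vs $N$ at the canonical parameters); the test suite
validates both against a known imposed shift instead of against each other.
The cycle's event order — resource minimum, aggregation maximum, decline of
the fast fraction as exploiters rise, resource recovery — is asserted as a
sequence, not as numeric lags.

## Bifurcation analyses

`hopf_point()` bisects the leading eigenvalue real part (tolerance
$10^{-10}$ on the parameter; user brackets are clipped to the
existence region first) and verifies rotation at the root. We chose
eigenvalue bisection over reconstructing the critical cubic analytically:
the polished equilibrium makes eigenvalues cheap and exact to solver
precision, and the bisection generalises to every parameter. The onset
period then extrapolates to $2\pi/\omega$ from the imaginary part, and the
supercritical signature is checked empirically: the fitted log–log slope of
amplitude versus $\lambda_S - \lambda_{S,c}$ over the decade
$[0.08, 0.8]$ is $0.49$, within the $0.5 \pm 0.05$ band expected from the
normal form.

Scans (`scan_1d()`, `sweep_2d()`, `hopf_curve()`) warm-start each cycle
search from the previous attractor. The analysis scripts run the
two-parameter sweep at reduced resolution (9 × 5 cells,
`analysis/03_bifurcation.R`) — the regime partition and the
ratios-above-one claim are resolution-independent, and the function takes
arbitrary grids when a denser map is wanted. On the scanned range the period
grows monotonically with exploitation and stays bounded: increasing conflict
slows the cycle without destroying it. (Amplitude also grows with
$\lambda_S$; a statement that the period shrinks as amplitude grows holds
along other parameter directions, so the sweep records both rather than
presuming either reading.)

## Invasion fitness three ways

The evolving trait is $\lambda_S$. A rare mutant's fate is computed by three
independent routes:

1. **Analytic at equilibrium** — $S = d(\lambda_S - \lambda_S^*)/\lambda_S^*$
   (`invasion_fitness_equilibrium()`).
2. **Cycle-averaged transverse rate** —
   $S = \tfrac1T \oint R\,(p_{\mathrm{mut}} - \bar p)\,dt$ along the resident
   cycle, by Simpson quadrature on the dense period sample
   (`invasion_fitness_cycle()`); variance-free compared with long direct
   simulation.
3. **Direct five-ODE simulation** — resident and mutant slow types compete
   explicitly (`simulate_three_strategy()`); the slope of the log mutant
   frequency is fitted over an integer number of resident periods while the
   mutant stays below 100× its initial $10^{-6}$ share
   (`invasion_fitness_direct()`). The rarity threshold and the
   multi-period fitting window are estimator-stability choices.

A useful identity falls out of the cycle averages: over one period both
$\oint R\,\bar p\,dt$ and $\oint R\,p_S\,dt$ equal $d\,T$ (population size
and slow-cell count each return to themselves), so the transverse average
*equals* the equilibrium expression on the cycle as well. The three
estimators therefore cross-check integration, quadrature and slope-fitting
against algebra — and they agree to ~$10^{-4}$ relative in practice — rather
than representing three different biological answers. Fitness is positive
for every resident exploitation level in both regimes, declines as
$1/\lambda_S^*$ (log–log slope $-1$), and `trait_substitution()`
(deterministic accept-if-positive steps of $\Delta\lambda_S = 0.1$; no
mutation-limited waiting times) walks the population from stable coexistence
through the Hopf point into the oscillatory regime: evolution of exploitation
itself generates the life-like cycle. Mutant–resident coexistence never
occurs in the direct simulations — invasion implies substitution.
`analysis/04_adaptive_dynamics.R` scans residents over $[7, 20]$, from just
above the interior-existence threshold to well past onset; the range is this
package's choice.

## The scenario generator

`sample_params()` draws log-uniform parameter sets ($r, K, d \in [0.5, 2]$,
$\lambda_F \in [4, 60]$, $\lambda_S \in [1.5, 40]$) and rejection-filters
them into a requested regime via the equilibrium eigenvalues. It emulates
parameter *uncertainty* around the canonical operating point — it does not
emulate measurement noise, demographic stochasticity, spatial structure or
group-formation mechanics, so property tests passing on these draws speak to
the deterministic ODE model only, not to finite-population or spatial
robustness.

## Numerical choices, sizes and limitations

* Test-suite and acceptance problem sizes: 200 neutral-model draws, 10
  SC-oracle draws, 16 fitness-grid evaluations, 7 amplitude-scaling points,
  2001-point period samples — sizes at which every reported digit is stable
  under refinement (doubling the period sampling moves generation ratios by
  well under 1%).
* Degenerate inputs: $q$ is clipped at 1 for transient resource overshoot;
  monomorphic ($x \in \{0,1\}$) and extinct ($N = 0$) faces are invariant;
  the three-strategy simplex is conserved by construction and renormalised
  only past $10^{-9}$ drift (drift beyond $10^{-6}$ is a solver warning).
* The model has no group-size structure, no assortment, no space, no
  stochasticity, and payoffs are the all-or-nothing extreme; results are
  statements about this minimal caricature. Global stability and
  basin geometry are out of scope — stability claims are linear, plus
  direct-simulation corroboration on the scanned grids.
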