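# bridgemc

Monte Carlo machinery for optimal control problems in stochastic
thermodynamics: pointwise integration of Fokker–Planck equations driven by
time-dependent mechanical potentials, Bismut–Elworthy–Li (BEL) estimation of
Hamilton–Jacobi–Bellman value-function gradients, and the Schrödinger-bridge
constructions that couple the two.

## The problem

Nanoscale machines — molecular motors, driven colloids, biomolecular
assemblies — operate in strongly fluctuating environments, so their state is
a diffusion process rather than a deterministic trajectory. Steering such a
system between two assigned probability distributions in finite time, at
minimal cost, is a stochastic optimal control problem: a Fokker–Planck
equation transports the state density under a mechanical force
`-∇U_t(q)`, while a Hamilton–Jacobi–Bellman (HJB) equation determines the
value function `V_t` whose spatial gradient fixes the optimal force through
the stationarity relation `∇V = (β/2) ∇U`. Grid-based PDE solvers struggle
with the terminal-density boundary conditions and with dimension; this
package instead evaluates both equations *pointwise* by averaging over
sampled trajectories, with no spatial discretization.

Three Monte Carlo primitives are implemented for both overdamped
(Langevin–Smoluchowski) and underdamped (Langevin–Kramers) dynamics:

* **Girsanov-reweighted density solver.** The density `p_t(q)` of
  `dq = -μ∇U_t(q) dt + √(2μ/β) dw` is the average of the initial density
  over *driftless* backward paths anchored at `(t, q)`, weighted by the
  exponential change-of-measure factor
  `exp(-∫ √(βμ/2)⟨dw, ∇U⟩ - (βμ/4)∫‖∇U‖² ds)`. The phase-space version
  reweights a friction-free backward flow by the analogous momentum factor.
* **BEL value gradients.** `∇V_t` for
  `V_t(x) = E[φ(x_tf) + ∫ F_s(x_s) ds | x_t = x]` is a path average of
  `φ` and `F` multiplied by stochastic integrals of the tangent-flow cocycle
  against the path's own Brownian increments — no differentiation of `φ`,
  `F`, or the density. For the hypoelliptic underdamped system (noise only
  in the momentum) the volatility cannot be inverted, and the weight is
  built from an explicitly constructed variational field `(ℓ, g, h)`.
* **Bridge solvers.** `half_bridge_solve()` computes the Föllmer drift of
  the overdamped Schrödinger bridge (minimal Kullback–Leibler divergence
  from a free diffusion, both marginals pinned) by the classical `φ/φ̂`
  half-bridge sweep; `train_protocol()` learns a parametrized drift by
  coupling the two Monte Carlo primitives through a Lagrange-multiplier
  ascent on the terminal marginal.

## Worked example

Solve a two-well steering problem — initial marginal
`∝ exp(-β(q-1)⁴/4)`, final marginal `∝ exp(-β(q²-1)²/4)`, horizon 0.2 —
then verify the optimal force against the value gradient:

```r
library(bridgemc)

bounds <- boundary_conditions(function(q) (q - 1)^4 / 4,
                              function(q) (q^2 - 1)^2 / 4)
model  <- overdamped_model(fixture_potential("zero"))   # mu = beta = 1
grid   <- time_grid(0, 0.2, dt = 0.005)

bridge <- half_bridge_solve(bounds, model, grid,
                            points = seq(-3, 3, length.out = 300),
                            iterations = 10, M = 4000,
                            rng = rng_stream(1), tol = 1e-4)
glance(bridge)
#> # A tibble: 1 × 5
#>   l1_initial l1_final iterations last_change floored
#>        <dbl>    <dbl>      <int>       <dbl>   <int>
#> 1      0.179    0.190         10      0.0142       0
```

`l1_initial` and `l1_final` are the caption-style weighted l1 distances of
the reconstructed endpoint densities from the two assigned marginals,
summed over the 300 grid points — about 0.18, i.e. a weighted-relative
error around one percent after ten sweeps. (This boundary pair is weakly
coupled over the short horizon, so the proportional-fitting map converges
slowly; forty sweeps drive the distance three orders of magnitude lower —
see the methods vignette.) Now close the loop:
the BEL gradient of the reconstructed value function must reproduce the
bridge drift through `∇U = (2/β)∇V`:

```r
dyn   <- overdamped_model(bridge_potential(bridge))
probe <- seq(-1.5, 1.5, length.out = 9)
Vtf   <- function(q) approx(bridge$points, bridge$V[nrow(bridge$V), ],
                            xout = q, rule = 2)$y
grad  <- bel_gradient_overdamped(probe, 0, dyn, grid, Vtf,
                                 running_cost = "bridge", M = 4000,
                                 rng = rng_stream(2))
resid <- stationarity_residual(
  tibble::tibble(q = probe,
                 dU = approx(bridge$points, bridge$dU[1, ], xout = probe)$y,
                 dV = grad$estimate), beta = 1)
glance(resid)
#> # A tibble: 1 × 3
#>   max_abs mean_abs     n
#>     <dbl>    <dbl> <int>
#> 1  0.0722   0.0359     9
```

The mean absolute residual (~0.04 against drift values of order 3) is at
the Monte Carlo noise level: two independent estimators — a density-free
half-bridge sweep and a pathwise gradient estimator — agree on the optimal
protocol. `autoplot(bridge)` draws the density evolution; `tidy(bridge)`
returns the full `(time, q, φ, φ̂, p, V, ∇U)` table.

A command-line wrapper is installed as `exec/bridgemc`
(`bridgemc fp-solve ...`, `bel-grad`, `bridge`, `validate`).

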