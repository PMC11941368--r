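---
title: "Monte Carlo integration of Fokker–Planck and HJB equations for stochastic optimal control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo integration of Fokker-Planck and HJB equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgemc)
```

## The model class

Two diffusion models describe the state of a thermally agitated nanosystem
driven by a mechanical potential $U_t(q)$:

* **Overdamped (Langevin–Smoluchowski):**
  $dq_t = -\mu\,\nabla U_t(q_t)\,dt + \sqrt{2\mu/\beta}\,dw_t$, with
  motility $\mu$ (time/mass) and inverse temperature $\beta$ (1/energy).
* **Underdamped (Langevin–Kramers):**
  $dq_t = (p_t/m)\,dt$,
  $dp_t = -(p_t/\tau + \nabla U_t(q_t))\,dt + \sqrt{2m/(\tau\beta)}\,dw_t$,
  with mass $m$ and Stokes friction time $\tau$; the derived motility is
  $\mu = \tau/m$. Noise enters only the momentum: the diffusion is
  degenerate (hypoelliptic).

All estimators integrate paths with the Euler–Maruyama scheme on an
explicit `time_grid()`. Noise is drawn as standard normals scaled by
$\sqrt{\delta t}$ inside the steppers — one convention throughout, so
stored draws can be replayed bit-exactly and reused by the weight and
gradient calculations, which must integrate against the *same* Brownian
increments that moved the path. Each trajectory consumes its own
L'Ecuyer-CMRG substream, so enlarging the sample size extends, rather than
reshuffles, the sample set — the property that makes variance-versus-M
diagnostics meaningful.

## Girsanov solution of the Fokker–Planck equation

The density of the overdamped diffusion admits the pointwise representation

$$p_t(q) \;=\; \mathbb{E}\Big[\,p_{t_\iota}(q_{t_\iota})\,
  e^{-g}\,\Big|\,q_t = q\Big],\qquad
  g = \int_{t_\iota}^{t}\sqrt{\tfrac{\beta\mu}{2}}\langle dw_s,
  \nabla U_s(q_s)\rangle + \tfrac{\beta\mu}{4}\|\nabla U_s(q_s)\|^2\,ds ,$$

where the expectation runs over *driftless* backward paths
$d q = \sqrt{2\mu/\beta}\,dw$ anchored at $(t, q)$. Each query point is an
independent conditional expectation: no spatial mesh, no boundary
conditions, dimension enters only through the path state. The phase-space
version anchors a friction-free backward flow and weighs by the momentum
factor $\exp(-\frac{\tau\beta}{4m}\int\|p\|^2 -
\sqrt{\tau\beta/2m}\int\langle dw, p\rangle)$.

Numerical choices that matter:

* **Log-space weights.** $e^{-g}$ spans many orders of magnitude for stiff
  potentials; weights accumulate as log-increments and reductions use
  log-sum-exp. Every density estimate reports an effective sample size.
* **Weight evaluation node.** The displayed integrals are pre-point (Itô)
  forms, so the integrand is evaluated at the state the backward step just
  generated. A subtlety worth recording: because that state is generated
  *from* the interval's own draw, the discrete exponential is not a
  martingale — for the free underdamped flow its mean is
  $e^{(t - t_\iota)d/\tau}$, the phase-space contraction factor that the
  continuum pre-point identity absorbs. The density estimator built on this
  convention is nevertheless the correct one (verified against heat-kernel,
  Ornstein–Uhlenbeck, and linear phase-space closed forms). The
  backward-adapted alternative, `log_weight_*(at = "anchor")`, evaluates at
  the interval's anchor-side node, is an exact discrete martingale
  ($\mathbb{E}e^{-g} = 1$ step by step), and is the convention used for
  normalization checks.
* **Common random numbers.** By default all query points share one set of
  draws, which makes the estimated curve smooth in $q$; disable
  (`share_noise = FALSE`) for independent-error diagnostics.
* **Raw estimates.** The estimator targets the density value itself;
  normalization over a query grid and box-filter smoothing are optional
  post-processing (`normalize`, `window`), mirroring how the figures of
  this literature are produced.
* **Discretization bias.** The weight carries an $O(\delta t)$ bias that
  shows up as a probability-mass deficit on coarse grids; the mass
  conservation test documents the step sizes at which the deficit stays
  under a few percent.

## Dynkin values and Bismut–Elworthy–Li gradients

The value function of the terminal-value problem
$(\partial_t + \langle b,\nabla\rangle + \langle AA^\top, \nabla\otimes
\nabla\rangle)V = -F$, $V_{t_f} = \varphi$, is the path expectation
$V_t(x) = \mathbb{E}[\varphi(x_{t_f}) + \int_t^{t_f} F_s(x_s)ds]$
(`dynkin_value()`, left-endpoint quadrature for the running cost). Its
spatial gradient is what optimal control actually needs, and the BEL
identity provides it without differentiating anything:

$$\langle e_i, \nabla V_t(x)\rangle =
 \mathbb{E}\Big[\tfrac{\varphi(x_{t_f})}{t_f-t}\int_t^{t_f}
 \langle dw_u, A^{-1}x_{*u,t}e_i\rangle
 + \int_t^{t_f}\!\!ds\,\tfrac{F_s(x_s)}{s-t}\int_t^{s}
 \langle dw_u, A^{-1}x_{*u,t}e_i\rangle\Big],$$

with $x_{*u,t}$ the tangent-flow cocycle (derivative of the stochastic flow
in its initial condition). Design decisions:

* The overdamped specialization uses the accumulated-exponent cocycle
  $\exp(-\mu\int \partial^2 U)$ and the prefactor $\sqrt{\beta/(2\mu)}$
  obtained by inserting $A = \sqrt{2\mu/\beta}\,I$ into the general
  identity; the quadratic-potential oracle
  ($\partial V = e^{-\mu k (t_f - t)}$) pins this normalization. The
  general-diffusion path propagates the Euler-product cocycle
  $\prod(I + \delta t\, b_*)$ instead; the two discretizations differ at
  $O(\delta t)$, so they coincide exactly only for potentials with vanishing
  Hessian and agree to $O(\delta t)$ otherwise.
* The running-cost term's $1/(s-t)$ weight starts at the first node strictly
  after $t$ (the $s = t$ node has an empty inner integral), avoiding 0/0.
* The general estimator assumes a state-independent (time-dependent)
  volatility matrix, which covers every diffusion treated here; its
  condition number is checked before inversion (default threshold `1e8`).
* Estimates over many query points share draws (common random numbers)
  unless asked otherwise, and the per-point estimator variance scales as
  $1/M$.

The module's master oracle is `fd_gradient_dynkin()`: a central finite
difference of the Dynkin value with the *same* noises at both displaced
starting points, so the comparison error is per-path pathwise rather than
two independent Monte Carlo errors.

### Degenerate (underdamped) gradients

With noise only in the momentum, $A$ is singular and the weight is built
instead from a variational field: a free function $\ell_u$ with
$\ell_t = v$, $\ell_{t_f} = 0$ generates
$g_u = \tfrac{1}{m}\int_t^u \ell$, and the weight field is
$h_u = -\dot\ell_u - \ell_u/\tau - \nabla\otimes\nabla U_u(q_u)\,g_u$,
where the Hessian term rides along each sampled path (pre-point
evaluation). The closure condition $g_{t_f} = 0$ fixes the cubic family
$\ell_u = v\,(t_f-u)(t_f+2t-3u)/(t_f-t)^2$; a piecewise-linear tent field
satisfying the same constraints is provided because the estimator's *value*
must not depend on the choice of admissible field — only its variance does
— and the two-field agreement is one of the deeper consistency checks. The
sign grouping of $h_u$ is re-derived from the defining differential system
rather than transcribed, because the free-potential specialization
($h = -\dot\ell - \ell/\tau$, which reproduces
$\partial_p V = e^{-(t_f-t)/\tau}$ analytically) is the ground truth.
Inside the running-cost term the field is rebuilt on each sub-horizon
$[t, s]$, since the gradient identity holds horizon by horizon. A
position-direction field (`type = "qbump"`, $\ell_t = \ell_{t_f} = 0$,
$g_{t_f} = -v$) is exposed as an experimental option validated only against
the finite-difference oracle. The $\eta$-regularized linear system (extra
position noise of strength $\eta$) connects the degenerate and
non-degenerate routes: its momentum gradient is $\eta$-independent, and the
non-degenerate estimates at $\eta \in \{0.5, 0.1, 0.02\}$ bracket the
degenerate one.

## The Schrödinger bridge and the half-bridge sweep

Steering $P_\iota$ into $P_f$ while minimizing the KL divergence from a
free diffusion couples the Fokker–Planck equation to an HJB equation
through the stationarity relation $\nabla V = (\beta/2)\nabla U$. The
product decomposition $p_t = \varphi_t\hat\varphi_t$,
$V_t = -\log\varphi_t$ turns the pair into two *linear* heat-type
equations, each solved by the Gaussian smoothing identity
$\mathrm{value}(q) \leftarrow \mathbb{E}[\mathrm{value}(q +
\sqrt{2\mu\delta t/\beta}\,\xi)]$ — evaluated per step either by Monte
Carlo (shared draws across the point grid) or Gauss–Hermite quadrature.
`half_bridge_solve()` alternates boundary divisions with propagations from
the flat initial guess $\varphi \equiv 1$ (standard proportional-fitting
initialization). Numerical notes:

* $\varphi, \hat\varphi$ live in log space on one shared point grid;
  off-grid evaluation is linear in the log with linear tail extrapolation
  (quartic boundary potentials would be overweighted by constant
  extrapolation), and half-bridge divisions are clamped at $e^{\pm 700}$
  with a counter.
* The convergence metric is the relative l1 drift of the *pre-reset*
  reconstruction $\varphi_{t_f}\hat\varphi_{t_f}$ between sweeps — after
  the boundary reset the product equals $P_f$ identically and carries no
  information. For the same reason the summary (`glance()`) reports the
  final-marginal distance from the pre-reset candidate.
* The bridge drift follows from the stationarity relation as
  $-\tfrac{2}{\beta}\partial_q\log\varphi$ by central differences on the
  point grid, packaged by `bridge_potential()` as a drift/Hessian
  interpolant directly usable by the density and gradient estimators —
  which is how the package closes the loop: the BEL gradient of the
  reconstructed value function reproduces the bridge's own drift within
  Monte Carlo error.

A limitation worth knowing: the half-bridge map is a proportional-fitting
(Sinkhorn-type) iteration, and its geometric convergence rate degrades when
the heat kernel over the horizon barely connects the two marginals. For the
two-well pair on horizon 0.2 (kernel width $\sqrt{0.4} \approx 0.63$
against a well separation of $\approx 2$) the rate is about $0.65$ per
sweep, so ten sweeps still leave a percent-level relative error in the
endpoint marginals — visually converged, but three orders of magnitude
above the fixed point, which forty sweeps do reach (the convergence test
pins both facts with noise-free quadrature propagation). The kernel average
uses antithetic pairs, which cancel the odd component of the sampling error
and lower the Monte Carlo convergence floor substantially at no cost.

The factor in the stationarity relation deserves a note: substituting
$V = -\log\varphi$ into the HJB equation completes the square as
$\tfrac{\mu}{\beta}\|\nabla V - \tfrac{\beta}{2}\nabla U\|^2$, so
$\nabla U = (2/\beta)\nabla V$. The drift-update rule used by the trainer
follows this consistent reading (a literal transcription of the update with
a $\beta/2$ factor converges to one quarter of the optimal force; the
bridge/BEL closure experiment decides the question empirically).

## Learning a control protocol

`train_protocol()` implements the coupled learning loop: draw a uniform
batch on the training box; estimate the final density under the current
drift with the Girsanov solver; take a multiplier ascent step
$\lambda \leftarrow \lambda + \gamma_1\log(\hat p_{t_f}/P_f)$ (fitted as a
degree-6 polynomial by least squares — the log-ratio form preserves the
integrability of the value function, and matched densities are an exact
fixed point); set $V_{t_f} = \lambda$; estimate $\nabla V$ at every
interior grid node by BEL with the current drift; and fit the drift model
to the stationarity targets $(2/\beta)\nabla V$ by full-batch first-order
updates (SGD or Adam). Two drift models are provided: the reference
feed-forward network $(t,q)\to 4 \to 10 \to 1$ with swish activations and
Glorot initialization (analytic backpropagation, and an analytic spatial
derivative so the learned force can serve as the Hessian-bearing potential
of the other estimators), and a tensor-polynomial drift.

Choices made where the design was genuinely open:

* **Terminal-node targets are excluded from the fit.** The gradient
  estimator's horizon is empty at $t_f$, and the raw $\lambda'$ that would
  stand in is the only target not mollified by the heat flow — its tail
  values dominate the least squares and destabilize the loop.
* **Report metric.** The per-iteration final-marginal distance is evaluated
  on a fixed grid with common random numbers across iterations, so
  first-to-last comparisons are paired and reflect the drift rather than
  the batch draw (the raw per-batch value has sampling noise of the same
  size as several iterations of progress and is reported separately as
  `l1_batch`). The estimated density is box-smoothed and normalized before
  the multiplier update and the report when `smooth_window`/`normalize`
  are set.
* **Reduced study conditions.** The full reference schedule (four phases of
  20 iterations, 512 points, 100/10 trajectories, step 0.005) is the
  `trainer_config()` default. The reduced five-iteration run exercised by
  the tests uses 128 points, 1000 density trajectories, 50 gradient
  trajectories per node, step 0.02, 2000 Adam updates at
  $\gamma_2 = 10^{-3}$, $\gamma_1 = 0.1$, and the cubic polynomial drift.
  The polynomial is used there deliberately: at five iterations the
  multiplier signal vanishes pointwise exactly in the transport corridor,
  and the network learns a spurious dip there that a low-degree polynomial
  cannot express. Descent at this scale is small (a few percent of the
  initial distance) and is detectable only because of the paired
  evaluation.

## What the synthetic conditions do and do not show

All tests run on analytic fixture potentials (free, quadratic, quartic
well, double well, and the $\partial_q U = 2q^3$ stiff example), in one
spatial dimension (two phase-space dimensions), with Gaussian or Gibbs
boundary data on short horizons. Passing them shows that the estimators are
correctly wired to their continuum identities — closed-form transition
densities, the discrete martingale structure, cocycle algebra,
field-independence of the degenerate gradients, and the cross-estimator
closure of the bridge system. They do not probe high-dimensional behavior,
potentials with unbounded curvature along sampled paths, long horizons
(where the importance weights degenerate — watch the reported effective
sample size), or the full 80-iteration training schedule. The
$1/M$ variance scaling and the ESS diagnostics are the practical guide
to extrapolating sample sizes beyond the desk scale used here.

## Problem sizes

The test and acceptance runs use, by deliberate choice: $M = 10^4$
trajectories and $\delta t = 10^{-3}$ for the closed-form density checks
(21 query points); $M = 10^4$, $\delta t \le 10^{-2}$ for the gradient
oracles; a 500-point grid, $10^4$ kernel samples, ten sweeps for the
two-well bridge; and the reduced trainer conditions above over ten seeds.
These sizes put each Monte Carlo standard error well below the effect
being measured while keeping any single check in the minutes range on one
core.
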