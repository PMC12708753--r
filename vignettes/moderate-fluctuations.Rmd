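---
title: "Moderately interacting particles: models, numerics, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderately interacting particles: models, numerics, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modfluct)
```

## The model

`modfluct` simulates a system of $N$ diffusing particles on a periodic box
whose pairwise interaction derives from a mollified Riesz potential of
sub-Coulomb type,

$$\mathrm{d}X_i = \frac{\kappa}{N}\sum_{j=1}^{N}\nabla V^\eta(X_i - X_j)\,
\mathrm{d}t + \sqrt{2\sigma}\,\mathrm{d}W_i,\qquad
V^\eta = \chi^\eta * \Phi,\quad \Phi(x)=|x|^{-\lambda},$$

in dimension $d\ge 3$ with $0<\lambda<d-2$, $\kappa=+1$ (aggregation, the
chemotaxis-like regime) or $\kappa=-1$ (repulsion, nonlocal population
pressure), and diffusion $\sigma>0$. The mollifier $\chi^\eta=\xi^\eta*\xi^\eta$
is built from the canonical radial bump
$\xi(x)\propto\exp(-1/(1-|x|^2))$ scaled to radius $\eta$ and unit mass. In
the *moderate regime* the mollification radius shrinks with the population,
$\eta=N^{-\beta}$, so the interaction localizes as $N$ grows.

Three companion objects organize everything the package measures:

* the **intermediate equation** for the density $\bar u^\eta$ at fixed
  $\eta$,
  $\partial_t\bar u^\eta=\sigma\Delta\bar u^\eta-\kappa\,\mathrm{div}(\bar u^\eta\,
  \nabla V^\eta*\bar u^\eta)$, and the **limit equation** for $u$, with
  $V^\eta$ replaced by $\Phi$;
* the **intermediate particle system**: independent particles driven by the
  precomputed field $\kappa(\nabla V^\eta*\bar u^\eta)$, whose common law is
  $\bar u^\eta$ — the natural coupling partner for the interacting system;
* the **fluctuation field** $\mathcal F^\eta(t)=\sqrt N(\mu^\eta(t)-\bar
  u^\eta(t))$, where $\mu^\eta$ is the empirical measure.

The two quantitative phenomena the package is built to exhibit are:

1. **Mean-square convergence of smoothed empirical measures.** With
   $Z^\eta=\xi^\eta*\Psi$, where $\Psi(x)=c_{d,\lambda}|x|^{-(\lambda+d)/2}$
   is the convolution square root of $\Phi$ ($\Psi*\Psi=\Phi$), the smoothed
   measures $f^\eta=Z^\eta*\mu^\eta$ and $g^\eta=Z^\eta*\bar u^\eta$ satisfy
   $\mathbb E\sup_t\|f^\eta-g^\eta\|_{L^2}^2\lesssim N^{-1/2-\varepsilon}$
   for admissible $\beta<1/(8\lambda+12)$. The package estimates the decay
   exponent by Monte-Carlo over a ladder of $N$ (`estimate_rate`).
2. **Asymptotic Gaussianity of the fluctuations.** Pairings
   $\langle\mathcal F^\eta(t),\phi\rangle$ become Gaussian with variance
   $$\langle u_0,(T^t_\phi(0))^2\rangle-\langle u_0,T^t_\phi(0)\rangle^2
   +2\sigma\int_0^t\langle u(s),|\nabla T^t_\phi(s)|^2\rangle\,\mathrm ds,$$
   where $T^t_\phi$ solves the dual backward linearized equation
   $-\partial_s v-\sigma\Delta v=\kappa(\nabla\Phi*u)\cdot\nabla v-
   \kappa\nabla\Phi*(u\nabla v)$, $v(t)=\phi$. The package solves this flow
   pseudo-spectrally and tests replicate pairings against the predicted
   normal (`fluctuation_experiment`, `clt_test`).

Two supporting diagnostics mirror the probabilistic scaffolding: the
synchronous-coupling statistic $\max_i|X_i-\bar X_i|$ thresholded at
$N^{-\alpha}$ (`coupling_probability`), and the law-of-large-numbers
deviation $\max_i|\frac1N\sum_j\psi(\bar X_i-\bar X_j)-(\psi*\bar u^\eta)
(\bar X_i)|$ with $\psi=\nabla V^\eta$ thresholded at $N^{-\theta}$
(`lln_probability`). Both probabilities must decay in $N$ for admissible
exponents; the package checks monotone decay, not the non-constructive
constants.

## Discretization choices

**Torus truncation.** The model lives on $\mathbb R^d$; the package works on
the periodic box $[-L/2,L/2)^d$ with every kernel defined by its continuum
Fourier symbol on the wavenumber lattice, zero mode set to 0. Two facts make
this faithful: all statistics pair kernels against mean-zero signals
($\mu^\eta-\bar u^\eta$), for which the zero-mode convention is immaterial,
and the initial density is chosen to have negligible boundary mass. The
price is a *gauge*: real-space values of the periodized kernels differ from
their free-space counterparts by an additive constant plus smooth image
sums, because $\Phi$ and $\Psi$ are not integrable at infinity. All
comparisons against free-space formulas are therefore made either on
gradients and differences (gauge-free), or on the free-space radial profile
computed independently by Hankel quadrature of the continuum symbol
(`free_kernel_profile`). The kernel growth norms
$\|D^kV^\eta\|_\infty\sim N^{\beta(\lambda+k)}$ are measured on that
profile, where the scaling $\eta^{-(\lambda+k)}$ is exact by a change of
variables; the torus tables would add an $\eta$-independent gauge offset
that corrupts log-log slopes at any resolution.

**Factorization constant.** $c_{d,\lambda}$ is fixed analytically by
matching the Gamma-function Fourier symbols of $|x|^{-s}$, taking the
positive root so $\Psi\ge 0$. It is validated by an independent oracle that
integrates the convolution $(\Psi*\Psi)(|x|{=}1)$ directly in bipolar
coordinates (agreement to $10^{-6}$; the check scales as $c^2$ and is
sharp). A torus FFT cross-check compares $\Psi*\Psi$ with $\Phi$ on the
annulus $0.2L\le|x|\le0.4L$ after removing the smooth periodization
background; the residual is below 1%.

**Particle forces.** Pairwise forces use a radial table of $V^\eta$ and its
derivative extracted from the torus symbol along a lattice axis (resolution
4 points per grid cell, linear interpolation), with minimum-image
displacements — the standard particle-mesh compromise that keeps the
$O(N^2)$ inner loop cheap and compiled. The gradient table is exactly zero
at $r=0$ (anti-symmetry; the self-term contributes nothing) and at $r=L/2$
(where the cosine series has zero slope); beyond $L/2$ forces are clamped to
zero rather than mirror-extended, so diagonal separations see a smooth,
monotone tail. Forces are accumulated pairwise, making Newton's third law
— and hence the zero total drift — exact to rounding.

**Deposition and smoothing.** The empirical measure is deposited by
cloud-in-cell (CIC) weights; when the deposit is subsequently smoothed by
$Z^\eta$ (whose symbol decays well before the Nyquist scale), the CIC
transfer function $\prod_j\mathrm{sinc}^2(k_jh/2)$ is divided out in
Fourier space. Without this compensation the smoothed-measure statistics
are biased low by several percent — more than the Monte-Carlo error of the
i.i.d. oracle $\mathbb E\|Z^\eta*(\mu-u)\|^2=\frac1N(\|Z^\eta\|^2-
\|Z^\eta*u\|^2)$, which the deconvolved pipeline reproduces within
statistical error across $N=10^2\dots10^4$.

**PDE scheme.** The forward, dual backward and linearized solvers share one
scheme: exact integrating factor $e^{-\sigma|k|^2\Delta t}$ for diffusion,
explicit Heun (second order) for the quadratic transport term, 2/3-rule
dealiasing. The transport term is a divergence, so its zero mode vanishes
and mass is conserved to rounding — with $\kappa=0$ the heat flow is exact
in time, which the closed-form Gaussian oracles exploit. Positivity is not
enforced (spectral schemes are not positivity-preserving); the solver
records the minimum value per snapshot, and a sup-norm ceiling flags
blow-up-like growth loudly instead of failing silently. Measured
convergence order of the transport scheme is $\ge 1.9$.

**Duality.** The dual backward flow is the adjoint of the *linearized*
forward evolution: $\langle w(s),T^t_\phi(s)\rangle$ is conserved when $w$
solves the linearized equation along the background $u$. This is the
defining property and is what the tests verify (drift $<10^{-4}$ over the
horizon). Along the *nonlinear* solution $u$ itself the pairing is not
conserved — the residual $-\kappa\langle u(\nabla\Phi*u),\nabla
T\rangle$ is a genuine term, about 1.5% over $t=0.3$ at the default
parameters — so no test asserts the nonlinear pairing.

**Time stepping of particles.** Plain Euler–Maruyama with fixed
$\Delta t$; for fixed $\eta$ the drift is smooth and bounded, and the
statistics tested are weak-sense functionals for which first-order weak
accuracy suffices. Defaults keep $\|\text{drift}\|\Delta t$ far below one
grid cell. Brownian increments are drawn once per step in particle-major
order, which is what makes the synchronous coupling (shared increments for
$X$ and $\bar X$) well defined and the runs bit-exact under a fixed seed.
Replica streams derive from the base seed by a fixed integer recurrence
kept below $2^{31}$.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $d$, $\lambda$ | dimension, Riesz exponent | 3, 0.5 | smallest admissible $d$; $\lambda$ mid-window in $(0,1)$ |
| $\kappa$ | interaction sign | $+1$ | aggregation is the delicate case |
| $\sigma$ | diffusion | 1 | strong enough that the attractive runs stay smooth on a $32^3$ grid |
| $\beta$ | moderate exponent | 0.05 | inside the admissible window $\beta<1/(8\lambda+12)=1/16$ |
| $L$, $n$ | box, grid | 10, 32 | $u_0$ tail mass $\sim10^{-6}$ outside the box; $\eta\ge 2h$ keeps the mollifier resolved |
| $s_0$ | initial Gaussian width | 1 | box units; $\|u_0\|_{L^{p^*}}$ is logged, the abstract smallness constant is not checkable |
| $\Delta t$ | particle/PDE step | 0.005 (0.0025 for CLT runs) | weak bias $\sqrt N\,O(\Delta t)$ must stay below the fluctuation scale |
| $\alpha,\theta$ | coupling/LLN exponents | 0.3, 0.25 | inside $(\beta(\lambda+3),\,1/2-\beta(\lambda+1))=(0.175,0.425)$ |

The test functions are periodized Gaussians of width $\ge 4$ grid cells.
Periodization (summing lattice images) replaces the Schwartz decay
condition: at $L=10$ a width-1.5 Gaussian still has $\sim10^{-3}$ boundary
tail, but because the identical evaluator is used for grid quadrature and
for particle sums, the pairing $\langle\mathcal F^\eta,\phi\rangle$ sees no
consistency error.

One stated tolerance had to move: the initial-sampling tail guard. At the
default $s_0=1$, $L=10$ the unwrapped Gaussian carries $\approx 2\times
10^{-6}$ mass outside the box, so the guard defaults to $10^{-5}$
(configurable) rather than an unattainable $10^{-8}$.

## What the experiments are, at which sizes

* **Rate experiment** (`estimate_rate`): $N\in\{64,128,256,512\}$, 8
  replicas each, $T=0.5$, grid $32^3$, $\beta=0.05$. The statistic is
  $\sup_t\|f^\eta-g^\eta\|^2_{L^2}$ over snapshots every 10 steps (the
  continuous-time supremum is unobservable; the stride is recorded).
  Weighted log-log least squares gives the exponent; at these sizes the
  measured slope is close to the i.i.d. benchmark $1-\beta\lambda\approx
  0.97$, comfortably above the $1/2$ the theory guarantees. The $\varepsilon$
  in $N^{-1/2-\varepsilon}$ is not quantified by the theory, so only the
  bound $r \ge 1/2$ is asserted.
* **CLT experiment** (`fluctuation_experiment`): $N=500$, 100 replicates,
  $T=0.3$, $\Delta t=0.0025$. The variance prediction uses $u$ from the
  limit equation and the dual flow with the bare Riesz symbol, as the
  asymptotic statement does; at finite $\eta\approx0.73$ the empirical
  variance carries $O(\eta)$ corrections, so agreement is asserted
  statistically (3 bootstrap standard errors of the sample variance, KS at
  level 0.01) — the unconditional form of the statement, with fresh i.i.d.
  initial data per replicate, is the one tested; the conditional
  (filtration-pinned) form is not separately exercised.
* **Coupling / LLN decays**: $N\in\{128,256,512\}$, $T=0.25$, 12–16
  replicas, $\alpha=0.3$, $\theta=0.25$; only monotone decay of the
  empirical probabilities is asserted, since the theory's constants
  $C(\gamma,T)$, $C(m)$ are non-constructive.

## What the synthetic runs do and do not show

The generator produces exactly the study conditions above: wrapped-Gaussian
initial data, one interaction kernel family (Riesz-with-bump-mollifier; no
Coulomb cut-off variants), moderate coupling $\eta=N^{-\beta}$, one box
size. Passing tests show that the implemented dynamics, solvers and
statistics are mutually consistent at desk scale and reproduce the
predicted scalings and limit distributions there. They do not probe real
data, other kernel families, the Coulomb endpoint $\lambda=d-2$, vanishing
diffusion, dimensions above the grid budget, or the sharp admissibility
boundaries of $(\alpha,\beta,\theta)$ — near-boundary behavior involves
unknown constants and is out of scope by design.

## Known limitations

* Radial force tables are an axis profile of a not-exactly-radial
  periodized kernel; the anisotropy error is far below the sampling noise
  at the sizes used but would matter for much larger $N$ at fixed box.
* The spectral solvers do not preserve positivity; strongly attractive,
  weakly diffusive configurations under-resolve on $32^3$ and are flagged
  by the sup-norm ceiling rather than continued adaptively.
* The CLT test at finite $\eta$ inherits $O(\eta)$ model error in its
  variance prediction ($\eta\approx0.73$ at $N=500$); the sample-to-predicted
  variance ratio is asserted only within the 3-bootstrap-SE band of 1, not
  asymptotically sharply.
* Memory: PDE snapshots are stored densely; at $n=32$, $d=3$ this is a few
  MB per solve, but $d\cdot\log_2 n$ is capped in `torus_grid`.
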