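# modfluct

Simulation and verification toolkit for **moderately interacting particle
systems** with mollified attractive or repulsive **Riesz potentials of
sub-Coulomb type**, and for the statistics that connect them to their
mean-field limit: the decay of smoothed empirical-measure errors in the
particle number, and the asymptotic Gaussianity of the fluctuation field
with the variance given by a dual backward linearized flow. The intended
users are researchers in stochastic interacting particle systems and
aggregation–diffusion PDE (Keller–Segel-type chemotaxis, nonlocal
population models) who want desk-scale numerical evidence for, or
counter-examples to, mean-field and fluctuation scalings.

## The model

N particles on a periodic box follow

    dX_i = (kappa/N) * sum_j grad V^eta(X_i - X_j) dt + sqrt(2 sigma) dW_i,

with `V^eta = chi^eta * Phi`, `Phi(x) = |x|^-lambda`, `0 < lambda < d - 2`
(sub-Coulomb), `kappa = +1` aggregation / `-1` repulsion, and a smooth
compactly supported mollifier `chi^eta = xi^eta * xi^eta` of radius
`eta = N^-beta` (the *moderate regime*). The companion PDEs are the
intermediate equation for `ubar^eta` (kernel `V^eta`) and the limit
equation for `u` (kernel `Phi`):

    du/dt = sigma Lap u - kappa div(u grad Phi * u).

Writing `Psi * Psi = Phi` with `Psi(x) = c * |x|^-(lambda+d)/2` and
`Z^eta = xi^eta * Psi`, the smoothed measures `f^eta = Z^eta * mu^eta`
(empirical) and `g^eta = Z^eta * ubar^eta` satisfy a mean-square bound
`E sup_t ||f^eta - g^eta||_L2^2 <= C N^(-1/2 - eps)`, and pairings of the
fluctuation field `F^eta = sqrt(N) (mu^eta - ubar^eta)` with a test
function `phi` become Gaussian with variance

    <u0, T(0)^2> - <u0, T(0)>^2 + 2 sigma Int_0^t <u(s), |grad T(s)|^2> ds,

where `T = T^t_phi` solves the dual backward linearized equation with
terminal condition `phi`. The package implements all of these objects —
kernels as Fourier symbols and radial force tables, Euler–Maruyama particle
ensembles (with shared-noise coupling), pseudo-spectral PDE solvers, and
the Monte-Carlo statistics — and verifies them against closed-form and
quadrature oracles. See the vignette
(`vignettes/moderate-fluctuations.Rmd`) for the numerical choices.

## Worked example

```r
library(modfluct)

spec   <- riesz_spec(d = 3, lambda = 0.5)
grid   <- torus_grid(n = 32, d = 3, L = 10)
tables <- build_kernel_tables(spec, mollifier_spec(eta = 0.73, beta = 0.05), grid)

cfg  <- sim_config(N = 256, kappa = 1, sigma = 1, beta = 0.05,
                   dt = 0.005, T = 0.5, seed = 1)
u0   <- gaussian_field(grid, s0 = 1)
ubar <- solve_forward(u0, tables$V_eta_symbol, sigma = 1, kappa = 1,
                      dt = 0.005, T = 0.5)
paths <- simulate_interacting(cfg, tables)
err   <- smoothed_error(paths, ubar, tables)
fit   <- estimate_rate(cfg, N_list = c(64, 128, 256, 512), replicas = 4)
print(fit)
```

Output (exact under this seed):

```
sup_t ||f - g||^2 = 0.004289   (time-integrated gradient term 0.01065)
Mean-square convergence of smoothed empirical measures
  E sup_t ||f^eta - g^eta||_L2^2 over N in {64, 128, 256, 512}, 4 replicas
   N =    64 : 0.01536 (se 0.0013)
   N =   128 : 0.006511 (se 0.00037)
   N =   256 : 0.003676 (se 0.00035)
   N =   512 : 0.001804 (se 0.00015)
  fitted decay exponent r = 0.994 (se 0.067)
```

The per-N numbers are the Monte-Carlo means of the sup-in-time squared L2
error between the smoothed empirical measure and the smoothed intermediate
density; the fitted exponent `r` is the observed decay rate in `N` — here
close to the i.i.d. sampling benchmark `1 - beta*lambda = 0.975`, and well
above the theoretical guarantee `1/2`.

Other entry points: `fluctuation_experiment()` (dynamic CLT with the
dual-equation variance), `coupling_probability()` / `lln_probability()`
(convergence-in-probability diagnostics), `kernel_scaling_report()` (kernel
sup-norm growth under the moderate scaling), and `run_experiment()` /
`inst/cli/modfluct.R` for config-driven runs that write CSV/JSON bundles.

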