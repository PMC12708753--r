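# Riesz potentials, bump mollifiers and mollified interaction kernels.
#
# All kernels are handled in two representations that the rest of the package
# shares:
#   * Fourier symbols on the wavenumber lattice of a periodic box, used for
#     spectral convolution against smooth fields (zero mode set to 0);
#   * radial tables along a lattice axis, used for fast pairwise force
#     evaluation with minimum-image displacements.
# Free-space radial profiles (Hankel quadrature of the continuum symbols) are
# kept separately: the torus symbols carry a zero-mode gauge constant, so any
# comparison with the free-space Riesz potential must be made on gradients,
# on differences, or on the free-space profile itself.

#' Fourier-transform constant of a Riesz kernel
#'
#' Coefficient `A(s)` in the classical identity
#' `FT(|x|^{-s})(k) = A(s) |k|^{-(d-s)}` for `0 < s < d`, with the
#' non-unitary convention `FT(f)(k) = integral f(x) exp(-i k.x) dx`.
#'
#' @param d spatial dimension.
#' @param s kernel exponent, in `(0, d)`.
#' @return the positive constant `pi^{d/2} 2^{d-s} Gamma((d-s)/2) / Gamma(s/2)`.
#' @keywords internal
riesz_ft_constant <- function(d, s) {
  stopifnot(s > 0, s < d)
  pi^(d / 2) * 2^(d - s) * gamma((d - s) / 2) / gamma(s / 2)
}

#' Specification of a sub-Coulomb Riesz interaction
#'
#' Bundles the spatial dimension `d >= 3`, the Riesz exponent
#' `0 < lambda < d - 2` of the potential `Phi(x) = |x|^{-lambda}`, and the
#' factorization constant `c_half` of the convolution square root
#' `Psi(x) = c_half |x|^{-(lambda+d)/2}` with `Psi * Psi = Phi`.
#'
#' @param d spatial dimension (integer, at least 3).
#' @param lambda Riesz exponent; must satisfy `0 < lambda < d - 2`
#'   (sub-Coulomb condition).
#' @return an object of class `"riesz_spec"` with fields `d`, `lambda`,
#'   `c_half`.
#' @examples
#' sp <- riesz_spec(3, 0.5)
#' sp$c_half
#' @export
riesz_spec <- function(d = 3, lambda = 0.5) {
  if (d < 3 || d != round(d)) stop("dimension d must be an integer >= 3")
  if (!(lambda > 0 && lambda < d - 2)) {
    stop("sub-Coulomb condition violated: need 0 < lambda < d - 2, got lambda = ",
         lambda, " with d = ", d)
  }
  out <- list(d = as.integer(d), lambda = lambda,
              c_half = half_kernel_constant(d, lambda))
  class(out) <- "riesz_spec"
  out
}

#' @export
print.riesz_spec <- function(x, ...) {
  cat(sprintf("Riesz interaction: Phi(x) = |x|^-%g in d = %d (sub-Coulomb)\n",
              x$lambda, x$d))
  cat(sprintf("  convolution-square factor Psi(x) = %.8g * |x|^-%g\n",
              x$c_half, (x$lambda + x$d) / 2))
  invisible(x)
}

#' Convolution-square-root constant of the Riesz potential
#'
#' The unique positive constant `c` such that `Psi * Psi = Phi` for
#' `Psi(x) = c |x|^{-(lambda+d)/2}` and `Phi(x) = |x|^{-lambda}`, obtained by
#' matching Fourier symbols: `(c A((d+lambda)/2))^2 = A(lambda)` with `A` the
#' Gamma-formula transform constant. The positive root is taken so that
#' `Psi >= 0`.
#'
#' @param d spatial dimension.
#' @param lambda Riesz exponent in `(0, d - 2)`.
#' @return the constant `c_{d,lambda} > 0`.
#' @examples
#' half_kernel_constant(3, 1)   # equals pi^(-3/2)
#' @export
half_kernel_constant <- function(d, lambda) {
  if (!(lambda > 0 && lambda < d - 2)) {
    stop("need 0 < lambda < d - 2 for the sub-Coulomb factorization")
  }
  sqrt(riesz_ft_constant(d, lambda)) / riesz_ft_constant(d, (d + lambda) / 2)
}

#' Evaluate the Riesz potential
#'
#' `Phi(x) = |x|^{-lambda}`, radial and positive; singular at the origin.
#'
#' @param x a numeric vector (one point) or a matrix with one point per row.
#' @param spec a [riesz_spec()].
#' @return potential value(s).
#' @export
riesz_phi <- function(x, spec) {
  if (is.matrix(x)) r <- sqrt(rowSums(x^2)) else r <- sqrt(sum(x^2))
  if (any(r == 0)) stop("riesz_phi is singular at x = 0")
  r^(-spec$lambda)
}

# --- mollifier -------------------------------------------------------------

#' Mollifier specification
#'
#' The mollifier family `xi^eta(x) = eta^{-d} xi(x/eta)` built from the
#' canonical radial bump `xi(x) = c_xi exp(-1/(1-|x|^2))` on the unit ball,
#' normalized to unit mass. In the moderate regime the radius is coupled to
#' the particle number as `eta = N^{-beta}`.
#'
#' @param eta mollification radius (box length units), positive.
#' @param beta moderate-scaling exponent used to derive `eta` from a particle
#'   count; stored for bookkeeping, may be `NA`.
#' @return an object of class `"mollifier_spec"` with fields `eta`, `beta`.
#' @export
mollifier_spec <- function(eta, beta = NA_real_) {
  stopifnot(is.numeric(eta), length(eta) == 1, eta > 0)
  structure(list(eta = eta, beta = beta), class = "mollifier_spec")
}

#' @export
print.mollifier_spec <- function(x, ...) {
  cat(sprintf("bump mollifier, radius eta = %g", x$eta))
  if (is.finite(x$beta)) cat(sprintf("  (eta = N^-beta, beta = %g)", x$beta))
  cat("\n")
  invisible(x)
}

# unnormalized bump profile on [0, 1)
bump_profile <- function(r) {
  out <- numeric(length(r))
  inside <- r < 1
  out[inside] <- exp(-1 / (1 - r[inside]^2))
  out
}

# package-level cache for per-dimension mollifier data
.kernel_cache <- new.env(parent = emptyenv())

# normalization constant and radial Fourier transform table of the unit bump,
# cached per dimension.  xi_hat(q) is tabulated by Simpson quadrature of the
# radial (Hankel) transform and interpolated by a natural spline; it decays
# below 1e-6 well before the table end.
mollifier_profile <- function(d) {
  key <- paste0("d", d)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  Sd <- 2 * pi^(d / 2) / gamma(d / 2)
  c_xi <- 1 / (Sd * stats::integrate(function(r) bump_profile(r) * r^(d - 1),
                                     0, 1, rel.tol = 1e-12)$value)
  nu <- d / 2 - 1
  rr <- seq(1e-9, 1, length.out = 4001)
  w <- rep(c(4, 2), length.out = length(rr) - 2)
  simp <- function(y) (y[1] + y[length(y)] + sum(w * y[2:(length(y) - 1)])) *
    (rr[2] - rr[1]) / 3
  qmax <- 60
  qs <- seq(0, qmax, by = 0.02)
  vals <- vapply(qs, function(qi) {
    if (qi < 1e-8) return(1.0)
    simp(c_xi * bump_profile(rr) * rr^(d / 2) * besselJ(qi * rr, nu)) *
      (2 * pi)^(d / 2) * qi^(1 - d / 2)
  }, numeric(1))
  sf <- stats::splinefun(qs, vals, method = "natural")
  xi_hat <- function(q) {
    y <- sf(pmin(q, qmax))
    y[q >= qmax] <- 0
    y
  }
  res <- list(c_xi = c_xi, xi_hat = xi_hat, qmax = qmax)
  .kernel_cache[[key]] <- res
  res
}

#' Evaluate the scaled mollifier
#'
#' `xi^eta(x) = eta^{-d} xi(x / eta)` with the canonical unit-mass radial
#' bump `xi`. Nonnegative, smooth, supported in `|x| <= eta`.
#'
#' @param x a numeric vector (one point) or matrix of points (rows).
#' @param moll a [mollifier_spec()].
#' @param d spatial dimension.
#' @return density value(s).
#' @export
mollifier_xi <- function(x, moll, d = 3) {
  pr <- mollifier_profile(d)
  if (is.matrix(x)) r <- sqrt(rowSums(x^2)) else r <- sqrt(sum(x^2))
  moll$eta^(-d) * pr$c_xi * bump_profile(r / moll$eta)
}

#' Fourier transform of the scaled mollifier at radial wavenumber
#'
#' `xi_hat^eta(|k|) = xi_hat(eta |k|)`; equals 1 at `k = 0` (unit mass).
#'
#' @param k radial wavenumber(s), nonnegative.
#' @param moll a [mollifier_spec()].
#' @param d spatial dimension.
#' @return transform values.
#' @export
mollifier_xi_hat <- function(k, moll, d = 3) {
  mollifier_profile(d)$xi_hat(moll$eta * abs(k))
}

# --- symbols on a torus grid ----------------------------------------------

# Riesz symbol A(lambda) |k|^{lambda - d} on the grid lattice, zero mode 0.
riesz_symbol <- function(spec, grid) {
  A <- riesz_ft_constant(spec$d, spec$lambda)
  s <- A * ifelse(grid$kmag > 0, grid$kmag^(spec$lambda - spec$d), 0)
  s
}

# symbol of the half kernel Psi(x) = c_half |x|^{-(d+lambda)/2}
psi_symbol <- function(spec, grid) {
  s2 <- (spec$d + spec$lambda) / 2
  A2 <- riesz_ft_constant(spec$d, s2)
  spec$c_half * A2 * ifelse(grid$kmag > 0, grid$kmag^(-(spec$d - spec$lambda) / 2), 0)
}

#' Build kernel tables for a mollified Riesz interaction on a torus
#'
#' Assembles the spectral symbols `Phi_hat`, `Z_hat = xi_hat^eta * Psi_hat`,
#' `V_hat = (xi_hat^eta)^2 * Phi_hat` on the grid lattice (zero modes 0), and
#' radial tables of `V^eta` and its derivative extracted from the torus
#' symbol along a lattice axis, at a resolution of `oversample` points per
#' grid cell. The gradient table is forced to 0 at `r = 0` (anti-symmetry)
#' and ends with value 0 at `r = L/2`, beyond which forces are clamped to 0.
#' Sup norms of `V^eta`, its gradient and Hessian are measured on the
#' free-space radial profile (see [free_kernel_profile()]), which is free of
#' the torus zero-mode gauge.
#'
#' @param spec a [riesz_spec()].
#' @param moll a [mollifier_spec()]; the mollifier support must span at least
#'   four grid cells (`2 * eta >= 4 h`).
#' @param grid a [torus_grid()] with the same dimension as `spec`.
#' @param oversample radial table points per grid cell (default 4).
#' @return an object of class `"kernel_tables"` with fields `r_grid`,
#'   `V_eta`, `dV_eta`, `dr` (table spacing), `Phi_symbol`, `Z_eta_symbol`,
#'   `V_eta_symbol`, `xi_eta_symbol`, `sup_norms`, `spec`, `moll`, `grid`.
#' @export
build_kernel_tables <- function(spec, moll, grid, oversample = 4) {
  if (grid$d != spec$d) stop("grid and Riesz spec dimensions differ")
  if (2 * moll$eta < 4 * grid$h) {
    stop(sprintf(paste0("mollifier unresolved: support diameter 2*eta = %.4g",
                        " spans fewer than 4 grid cells (h = %.4g)"),
                 2 * moll$eta, grid$h))
  }
  xih <- mollifier_xi_hat(grid$kmag, moll, spec$d)
  Phi_hat <- riesz_symbol(spec, grid)
  Z_hat <- xih * psi_symbol(spec, grid)
  V_hat <- xih^2 * Phi_hat

  # collapse the symbol over the transverse wavenumbers: along a lattice
  # axis  V(r) = sum_k1 c(k1) cos(k1 r)  with  c(k1) = (1/L^d) sum_perp V_hat
  ck <- apply(array(V_hat, c(grid$n, grid$n^(spec$d - 1))), 1, sum) / grid$L^spec$d
  r_grid <- seq(0, grid$L / 2, by = grid$h / oversample)
  V_eta <- vapply(r_grid, function(r) sum(ck * cos(grid$kv * r)), numeric(1))
  dV_eta <- vapply(r_grid, function(r) -sum(ck * grid$kv * sin(grid$kv * r)),
                   numeric(1))
  dV_eta[1] <- 0                       # anti-symmetry of the gradient
  dV_eta[length(dV_eta)] <- 0          # exact by the cosine series; clamp

  prof <- free_kernel_profile(spec, moll$eta,
                              seq(0, 3 * moll$eta, length.out = 301))
  out <- list(r_grid = r_grid, V_eta = V_eta, dV_eta = dV_eta,
              dr = r_grid[2] - r_grid[1],
              Phi_symbol = Phi_hat, Z_eta_symbol = Z_hat, V_eta_symbol = V_hat,
              xi_eta_symbol = xih,
              sup_norms = prof$sup_norms,
              spec = spec, moll = moll, grid = grid)
  class(out) <- "kernel_tables"
  out
}

#' @export
print.kernel_tables <- function(x, ...) {
  cat(sprintf("mollified Riesz kernel tables: d = %d, lambda = %g, eta = %g\n",
              x$spec$d, x$spec$lambda, x$moll$eta))
  cat(sprintf("  torus %d^%d, L = %g; radial table %d points, dr = %.4g\n",
              x$grid$n, x$grid$d, x$grid$L, length(x$r_grid), x$dr))
  cat(sprintf("  free-space sup norms: |V| = %.4g, |DV| = %.4g, |D2V| = %.4g\n",
              x$sup_norms[1], x$sup_norms[2], x$sup_norms[3]))
  invisible(x)
}

#' Free-space radial profile of the mollified kernel
#'
#' Evaluates `V^eta(r)` on the whole space by quadrature of the continuum
#' symbol, `V^eta(r) = (2pi)^{-d/2} r^{1-d/2} int xihat(eta k)^2 A(lambda)
#' k^{lambda-d} k^{d/2} J_{d/2-1}(kr) dk`, with a power substitution
#' regularizing the integrable singularity at `k = 0`. Unlike the torus
#' tables this profile carries no zero-mode gauge: it converges to
#' `Phi(r) = r^{-lambda}` pointwise as `eta -> 0` and obeys the exact scaling
#' `V^eta(r) = eta^{-lambda} W(r/eta)`.
#'
#' @param spec a [riesz_spec()].
#' @param eta mollification radius.
#' @param r radial abscissae (nonnegative).
#' @param npts quadrature points.
#' @return a list with `r`, `V` (profile values) and `sup_norms`, the
#'   measured sup norms `(|V|, |V'|, |D^2 V|)` over `r <= 3 eta` (the
#'   profiles are monotone tails beyond the mollification core).
#' @export
free_kernel_profile <- function(spec, eta, r, npts = 4001) {
  d <- spec$d; lambda <- spec$lambda
  pr <- mollifier_profile(d)
  p <- max(2, ceiling(1.5 / lambda))      # k = q^p regularizes k^(lambda-1)
  kmax <- pr$qmax / eta
  qq <- seq(0, kmax^(1 / p), length.out = npts)
  kk <- qq^p
  jac <- p * qq^(p - 1)
  w <- rep(c(4, 2), length.out = npts - 2)
  simp <- function(y) (y[1] + y[npts] + sum(w * y[2:(npts - 1)])) *
    (qq[2] - qq[1]) / 3
  A <- riesz_ft_constant(d, lambda)
  Vh <- pr$xi_hat(eta * kk)^2 * A * c(0, kk[-1]^(lambda - d))
  Sd <- 2 * pi^(d / 2) / gamma(d / 2)
  V <- vapply(r, function(ri) {
    if (ri < 1e-9) {
      y <- Vh * kk^(d - 1) * jac
      (2 * pi)^(-d) * Sd * simp(y)
    } else {
      y <- Vh * kk^(d / 2) * besselJ(kk * ri, d / 2 - 1) * jac
      (2 * pi)^(-d / 2) * ri^(1 - d / 2) * simp(y)
    }
  }, numeric(1))
  rg <- seq(0, 3 * eta, length.out = 301)
  Vg <- if (isTRUE(all.equal(r, rg))) V else
    free_kernel_profile_core(spec, eta, rg, npts)
  sf <- stats::splinefun(rg, Vg)
  dV <- sf(rg, deriv = 1)
  d2V <- sf(rg, deriv = 2)
  hess <- pmax(abs(d2V), abs(c(d2V[1], (dV / rg)[-1])))
  list(r = r, V = V,
       sup_norms = c(V = max(abs(Vg)), dV = max(abs(dV)), d2V = max(hess)))
}

# core evaluation without the sup-norm recursion
free_kernel_profile_core <- function(spec, eta, r, npts = 4001) {
  d <- spec$d; lambda <- spec$lambda
  pr <- mollifier_profile(d)
  p <- max(2, ceiling(1.5 / lambda))
  kmax <- pr$qmax / eta
  qq <- seq(0, kmax^(1 / p), length.out = npts)
  kk <- qq^p
  jac <- p * qq^(p - 1)
  w <- rep(c(4, 2), length.out = npts - 2)
  simp <- function(y) (y[1] + y[npts] + sum(w * y[2:(npts - 1)])) *
    (qq[2] - qq[1]) / 3
  A <- riesz_ft_constant(d, lambda)
  Vh <- pr$xi_hat(eta * kk)^2 * A * c(0, kk[-1]^(lambda - d))
  Sd <- 2 * pi^(d / 2) / gamma(d / 2)
  vapply(r, function(ri) {
    if (ri < 1e-9) {
      (2 * pi)^(-d) * Sd * simp(Vh * kk^(d - 1) * jac)
    } else {
      (2 * pi)^(-d / 2) * ri^(1 - d / 2) *
        simp(Vh * kk^(d / 2) * besselJ(kk * ri, d / 2 - 1) * jac)
    }
  }, numeric(1))
}

#' Growth of kernel sup norms under the moderate scaling
#'
#' For `eta = N^{-beta}` the mollified kernel obeys
#' `sup |D^k V^eta| <= C N^{beta (lambda + k)}` for `k = 0, 1, 2`. This
#' report measures the sup norms on the free-space radial profile for each
#' `N` in `N_list` and fits the log-log slope against `N`, returning the
#' measured and predicted exponents.
#'
#' @param spec a [riesz_spec()].
#' @param beta moderate-scaling exponent (`beta = 0` keeps `eta` fixed at 1).
#' @param N_list at least three particle counts.
#' @return a data frame with columns `k`, `slope`, `target`, `rel_dev`.
#' @export
kernel_scaling_report <- function(spec, beta, N_list) {
  if (length(N_list) < 3) stop("need at least 3 values of N for a slope fit")
  sups <- vapply(N_list, function(N) {
    prof <- free_kernel_profile(spec, N^(-beta),
                                seq(0, 3 * N^(-beta), length.out = 301))
    prof$sup_norms
  }, numeric(3))
  if (any(!is.finite(sups))) stop("non-finite kernel table in scaling report")
  slopes <- vapply(1:3, function(i) {
    unname(stats::coef(stats::lm(log(sups[i, ]) ~ log(N_list)))[2])
  }, numeric(1))
  target <- beta * (spec$lambda + 0:2)
  data.frame(k = 0:2, slope = slopes, target = target,
             rel_dev = ifelse(target == 0, abs(slopes),
                              abs(slopes - target) / abs(target)))
}
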