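# Shared fixtures, memoized: kernel tables and PDE solves are reused across
# test files to keep the suite fast.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_grid <- function(n = 32) fx_memo(paste0("grid", n), torus_grid(n, 3, 10))

fx_spec <- function() fx_memo("spec", riesz_spec(3, 0.5))

fx_tables <- function(eta = 0.73, n = 32) {
  fx_memo(sprintf("tab_%g_%d", eta, n),
          build_kernel_tables(fx_spec(), mollifier_spec(eta, 0.05), fx_grid(n)))
}

fx_u0 <- function(n = 32) fx_memo(paste0("u0_", n), gaussian_field(fx_grid(n), 1))

# intermediate-equation solve at the default experiment parameters
fx_ubar <- function(T = 0.5) {
  fx_memo(paste0("ubar", T),
          solve_forward(fx_u0(), fx_tables()$V_eta_symbol, sigma = 1,
                        kappa = 1, dt = 0.005, T = T, save_stride = 10))
}

# direct bipolar-coordinate quadrature of (Psi * Psi)(|x| = 1) in d = 3:
# an oracle for the convolution-square factorization that is independent of
# the Gamma-function symbol matching.
psi_selfconv_at_one <- function(c_half, lambda) {
  s <- (3 + lambda) / 2
  q <- 1 - s / 2
  inner <- function(y) ((y + 1)^(2 * q) - abs(y - 1)^(2 * q)) / (2 * y * q)
  f <- function(y) c_half^2 * 2 * pi * y^(2 - s) * inner(y)
  I1 <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  I2 <- stats::integrate(f, 1, 50, rel.tol = 1e-10)$value
  tail <- 4 * pi * c_half^2 * 50^(3 - 2 * s) / (2 * s - 3)
  I1 + I2 + tail
}
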