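# Pseudo-spectral solvers on the torus.
#
# Forward (intermediate or limit) equation
#   du/dt = sigma Lap u - kappa div(u grad K * u),      K = V^eta or Phi,
# dual backward linearized equation (terminal condition phi at time t)
#   -dv/ds - sigma Lap v = kappa (grad Phi * u).grad v - kappa grad Phi*(u grad v),
# and the forward linearized equation used to verify duality.
#
# Scheme: integrating factor exp(-sigma |k|^2 dt) treats diffusion exactly;
# the transport term is advanced by explicit Heun (RK2) stages with 2/3-rule
# dealiasing of the quadratic products. The zero mode is untouched by the
# transport term (it is a divergence), so mass is conserved exactly.

#' Solve the forward nonlocal aggregation-diffusion equation
#'
#' Integrates `du/dt = sigma Lap u - kappa div(u grad K * u)` from a
#' nonnegative unit-mass initial field, where the kernel enters through its
#' Fourier symbol: pass the mollified symbol `V_eta_symbol` for the
#' intermediate equation or the bare Riesz symbol `Phi_symbol` for the limit
#' equation.
#'
#' @param u0 a [grid_field()], nonnegative with unit mass.
#' @param symbol kernel symbol array on the grid lattice.
#' @param sigma diffusion constant (nonnegative).
#' @param kappa interaction sign.
#' @param dt time step.
#' @param T horizon.
#' @param save_stride steps between saved snapshots (final step always
#'   saved).
#' @param blowup_ceiling sup-norm ceiling; exceeding it sets the `blowup`
#'   flag and stops the integration (expected for strongly attractive runs).
#' @param equation_tag label stored with the solution.
#' @return an object of class `"pde_solution"`: `snaps` (list of arrays),
#'   `times`, `mass_series`, `min_series`, `blowup`, `dt`, `grid`,
#'   `equation_tag`.
#' @export
solve_forward <- function(u0, symbol, sigma, kappa, dt, T, save_stride = 10,
                          blowup_ceiling = 1e6, equation_tag = "intermediate") {
  g <- u0$grid
  uh <- fft_fwd(u0$values, g)
  ef <- exp(-sigma * g$k2 * dt)
  rhs <- make_transport_rhs(g, symbol, kappa)
  nst <- round(T / dt)
  snaps <- list(u0$values)
  times <- 0
  mass <- field_mass(u0)
  minu <- min(u0$values)
  blowup <- FALSE
  for (s in seq_len(nst)) {
    k1 <- rhs(uh)
    u1 <- ef * (uh + dt * k1)
    k2 <- rhs(u1)
    uh <- ef * uh + (dt / 2) * (ef * k1 + k2)
    if (s %% save_stride == 0 || s == nst) {
      u <- fft_inv(uh, g)
      if (max(abs(u)) > blowup_ceiling || any(!is.finite(u))) {
        blowup <- TRUE
        warning(sprintf("solution exceeded the sup-norm ceiling at t = %g",
                        s * dt))
        break
      }
      snaps <- c(snaps, list(u))
      times <- c(times, s * dt)
      mass <- c(mass, sum(u) * g$h^g$d)
      minu <- c(minu, min(u))
    }
  }
  structure(list(snaps = snaps, times = times, mass_series = mass,
                 min_series = minu, blowup = blowup, dt = dt, grid = g,
                 sigma = sigma, kappa = kappa, symbol = symbol,
                 equation_tag = equation_tag),
            class = "pde_solution")
}

# transport right-hand side -kappa div(u grad K * u) in frequency space
make_transport_rhs <- function(g, symbol, kappa) {
  if (kappa == 0) {
    zero <- array(0 + 0i, rep(g$n, g$d))
    return(function(uh) zero)
  }
  msk <- g$dealias
  gradsym <- lapply(g$karr, function(kj) 1i * kj * symbol)
  function(uh) {
    uhm <- uh * msk
    u <- fft_inv(uhm, g)
    acc <- 0
    for (j in seq_len(g$d)) {
      wj <- fft_inv(gradsym[[j]] * uhm, g)
      acc <- acc + 1i * g$karr[[j]] * fft_fwd(u * wj, g)
    }
    -kappa * acc * msk
  }
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("pde solution (%s): %d snapshots on [0, %g], grid %d^%d\n",
              x$equation_tag, length(x$snaps), max(x$times), x$grid$n, x$grid$d))
  cat(sprintf("  mass drift %.3g, min value %.3g%s\n",
              diff(range(x$mass_series)), min(x$min_series),
              if (x$blowup) ", BLOWUP flagged" else ""))
  invisible(x)
}

# fetch the solution snapshot nearest to (or linearly interpolated at) time t
pde_at_time <- function(sol, t, interpolate = TRUE) {
  i <- findInterval(t, sol$times, all.inside = TRUE)
  if (!interpolate || abs(sol$times[i] - t) < 1e-12) return(sol$snaps[[i]])
  if (abs(sol$times[i + 1] - t) < 1e-12) return(sol$snaps[[i + 1]])
  w <- (t - sol$times[i]) / (sol$times[i + 1] - sol$times[i])
  (1 - w) * sol$snaps[[i]] + w * sol$snaps[[i + 1]]
}

#' Smooth test functions on the torus
#'
#' `gaussian_bump`: a periodized isotropic Gaussian
#' `amplitude * exp(-|x - center|^2 / (2 width^2))` (lattice images summed),
#' standing in for a Schwartz function. `coordinate_window`: the smooth
#' periodic window `amplitude * (1 + cos(2 pi (x_1 - center_1)/L)) / 2`.
#' `constant`: the constant function `amplitude`, for degenerate checks
#' (both measures have unit mass, so all fluctuation pairings vanish).
#'
#' @param kind `"gaussian_bump"`, `"coordinate_window"` or `"constant"`.
#' @param center center point (length `d`).
#' @param width Gaussian width (box units); keep at least 4 grid cells so
#'   quadrature error stays below statistical error.
#' @param amplitude scale factor.
#' @return an object of class `"test_function"` with an evaluator usable on
#'   position matrices.
#' @export
test_function <- function(kind = c("gaussian_bump", "coordinate_window",
                                   "constant"),
                          center = c(0, 0, 0), width = 1.5, amplitude = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, center = center, width = width,
                 amplitude = amplitude),
            class = "test_function")
}

#' Evaluate a test function at points
#'
#' @param tf a [test_function()].
#' @param X `N x d` matrix of points.
#' @param L box edge length (for periodization).
#' @return numeric vector of values.
#' @export
tf_eval <- function(tf, X, L) {
  d <- ncol(X)
  if (tf$kind == "constant") return(rep(tf$amplitude, nrow(X)))
  if (tf$kind == "coordinate_window") {
    return(tf$amplitude * (1 + cos(2 * pi * (X[, 1] - tf$center[1]) / L)) / 2)
  }
  # periodized gaussian: sum over the 3^d neighbor images
  shifts <- as.matrix(expand.grid(rep(list(c(-L, 0, L)), d)))
  v <- 0
  for (s in seq_len(nrow(shifts))) {
    r2 <- rowSums((sweep(X, 2, tf$center - shifts[s, ], `-`))^2)
    v <- v + exp(-r2 / (2 * tf$width^2))
  }
  tf$amplitude * v
}

#' Sample a test function on a grid
#'
#' @param tf a [test_function()].
#' @param grid a [torus_grid()].
#' @return a [grid_field()].
#' @export
tf_grid <- function(tf, grid) {
  pts <- as.matrix(expand.grid(rep(list(grid$x), grid$d)))
  grid_field(array(tf_eval(tf, pts, grid$L), rep(grid$n, grid$d)), grid)
}

#' Solve the dual backward linearized equation
#'
#' Integrates, backward from the terminal condition `v(t) = phi`,
#' `-dv/ds - sigma Lap v = kappa (grad Phi * u).grad v - kappa grad Phi*(u grad v)`
#' by substituting `tau = t - s` and marching forward with the same
#' integrating-factor Heun scheme; the coefficient fields are linearly
#' interpolated in time from the stored forward snapshots. The bare Riesz
#' symbol is used (pass `symbol = tables$Phi_symbol`), matching the
#' linearization of the limit equation.
#'
#' @param u_sol a [solve_forward()] solution covering `[0, t]`.
#' @param phi a [test_function()] or [grid_field()] terminal condition.
#' @param t terminal time.
#' @param symbol kernel symbol of the linearized operator (Riesz symbol).
#' @param save_stride steps between saved snapshots.
#' @return a `"pde_solution"` with `snaps` holding `T^t_phi(s)` at the saved
#'   times `s` (increasing, `T^t_phi(t) = phi`), tagged `dual_backward`.
#' @export
solve_dual_backward <- function(u_sol, phi, t, symbol, save_stride = 10) {
  g <- u_sol$grid
  if (max(u_sol$times) < t - 1e-12) stop("u snapshots do not span [0, t]")
  phi_f <- if (inherits(phi, "test_function")) tf_grid(phi, g) else phi
  dt <- u_sol$dt
  nst <- round(t / dt)
  vh <- fft_fwd(phi_f$values, g)
  ef <- exp(-u_sol$sigma * g$k2 * dt)
  kappa <- u_sol$kappa
  msk <- g$dealias
  rhs <- function(vh, uarr) {
    # kappa (grad Phi * u).grad v - kappa sum_j dPhi_j*(u dv_j), transformed
    uhm <- fft_fwd(uarr, g) * msk
    vhm <- vh * msk
    acc_t1 <- 0
    acc_t2 <- 0
    for (j in seq_len(g$d)) {
      bj <- fft_inv(1i * g$karr[[j]] * symbol * uhm, g)
      vj <- fft_inv(1i * g$karr[[j]] * vhm, g)
      acc_t1 <- acc_t1 + bj * vj
      acc_t2 <- acc_t2 + 1i * g$karr[[j]] * symbol * fft_fwd(fft_inv(uhm, g) * vj, g)
    }
    (fft_fwd(kappa * acc_t1, g) - kappa * acc_t2) * msk
  }
  snaps <- list(fft_inv(vh, g))     # value at s = t
  times <- t
  for (s in seq_len(nst)) {
    ua <- pde_at_time(u_sol, t - (s - 1) * dt)
    ub <- pde_at_time(u_sol, t - s * dt)
    k1 <- rhs(vh, ua)
    v1 <- ef * (vh + dt * k1)
    k2 <- rhs(v1, ub)
    vh <- ef * vh + (dt / 2) * (ef * k1 + k2)
    if (s %% save_stride == 0 || s == nst) {
      snaps <- c(snaps, list(fft_inv(vh, g)))
      times <- c(times, t - s * dt)
    }
  }
  ord <- order(times)
  structure(list(snaps = snaps[ord], times = times[ord],
                 mass_series = vapply(snaps[ord], function(v) sum(v) * g$h^g$d,
                                      numeric(1)),
                 min_series = vapply(snaps[ord], min, numeric(1)),
                 blowup = FALSE, dt = dt, grid = g, sigma = u_sol$sigma,
                 kappa = kappa, symbol = symbol,
                 equation_tag = "dual_backward"),
            class = "pde_solution")
}

#' Solve the forward linearized equation
#'
#' Integrates `dw/dt = sigma Lap w - kappa div(w (grad Phi * u) + u (grad Phi * w))`
#' along a stored background solution `u`. The dual backward flow is the
#' adjoint of this linear evolution: `<w(s), T^t_phi(s)>` is conserved in
#' `s`, which is the property the duality tests verify.
#'
#' @param w0 a [grid_field()] initial perturbation.
#' @param u_sol background [solve_forward()] solution covering `[0, T]`.
#' @param symbol kernel symbol of the linearization.
#' @param T horizon.
#' @param save_stride steps between saved snapshots.
#' @return a `"pde_solution"` tagged `linearized`.
#' @export
solve_forward_linearized <- function(w0, u_sol, symbol, T, save_stride = 10) {
  g <- u_sol$grid
  dt <- u_sol$dt
  nst <- round(T / dt)
  wh <- fft_fwd(w0$values, g)
  ef <- exp(-u_sol$sigma * g$k2 * dt)
  kappa <- u_sol$kappa
  msk <- g$dealias
  rhs <- function(wh, uarr) {
    uhm <- fft_fwd(uarr, g) * msk
    whm <- wh * msk
    u <- fft_inv(uhm, g)
    w <- fft_inv(whm, g)
    acc <- 0
    for (j in seq_len(g$d)) {
      bj <- fft_inv(1i * g$karr[[j]] * symbol * uhm, g)   # (grad Phi * u)_j
      cj <- fft_inv(1i * g$karr[[j]] * symbol * whm, g)   # (grad Phi * w)_j
      acc <- acc + 1i * g$karr[[j]] * fft_fwd(w * bj + u * cj, g)
    }
    -kappa * acc * msk
  }
  snaps <- list(w0$values)
  times <- 0
  for (s in seq_len(nst)) {
    ua <- pde_at_time(u_sol, (s - 1) * dt)
    ub <- pde_at_time(u_sol, s * dt)
    k1 <- rhs(wh, ua)
    w1 <- ef * (wh + dt * k1)
    k2 <- rhs(w1, ub)
    wh <- ef * wh + (dt / 2) * (ef * k1 + k2)
    if (s %% save_stride == 0 || s == nst) {
      snaps <- c(snaps, list(fft_inv(wh, g)))
      times <- c(times, s * dt)
    }
  }
  structure(list(snaps = snaps, times = times,
                 mass_series = vapply(snaps, function(v) sum(v) * g$h^g$d,
                                      numeric(1)),
                 min_series = vapply(snaps, min, numeric(1)),
                 blowup = FALSE, dt = dt, grid = g, sigma = u_sol$sigma,
                 kappa = kappa, symbol = symbol, equation_tag = "linearized"),
            class = "pde_solution")
}
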