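# Stochastic simulation of the interacting and intermediate particle systems.
#
# Interacting system:   dX_i = (kappa/N) sum_j grad V^eta(X_i - X_j) dt
#                              + sqrt(2 sigma) dW_i
# Intermediate system:  dXbar_i = kappa (grad V^eta * ubar^eta)(Xbar_i) dt
#                              + sqrt(2 sigma) dW_i
# Both are advanced by Euler-Maruyama with a fixed step, positions wrapped
# into the box. Brownian increments are drawn once per step in particle-major
# order, so driving both systems with the same draws yields the synchronous
# coupling used in the convergence-in-probability diagnostics.

#' Simulation configuration
#'
#' Collects the physical and numerical parameters of one run. The
#' mollification radius is coupled to the particle count as `eta = N^-beta`
#' unless `eta` is given explicitly.
#'
#' @param N particle count.
#' @param d spatial dimension (>= 3).
#' @param lambda Riesz exponent, in `(0, d-2)`.
#' @param kappa interaction sign: +1 aggregation, -1 repulsion, 0 free
#'   particles (test mode).
#' @param sigma diffusion constant, positive (0 allowed only in test mode).
#' @param beta moderate-scaling exponent.
#' @param dt time step.
#' @param T time horizon.
#' @param seed base random seed (mandatory; no wall-clock default).
#' @param L box edge length.
#' @param n grid points per dimension.
#' @param s0 width of the isotropic Gaussian initial density.
#' @param center center of the initial density.
#' @param snapshot_stride steps between saved snapshots.
#' @param eta mollification radius override (default `N^-beta`).
#' @param test_mode allow `sigma = 0` or `kappa = 0`, outside the diffusive
#'   interacting regime the asymptotic theory assumes.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(N, d = 3, lambda = 0.5, kappa = 1, sigma = 1,
                       beta = 0.05, dt = 0.005, T = 0.5, seed = 1L,
                       L = 10, n = 32, s0 = 1, center = rep(0, d),
                       snapshot_stride = 10, eta = NULL, test_mode = FALSE) {
  if (is.null(eta)) eta <- N^(-beta)
  cfg <- list(N = as.integer(N), d = as.integer(d), lambda = lambda,
              kappa = kappa, sigma = sigma, beta = beta, dt = dt, T = T,
              seed = as.integer(seed), L = L, n = as.integer(n), s0 = s0,
              center = center, snapshot_stride = as.integer(snapshot_stride),
              eta = eta, test_mode = isTRUE(test_mode))
  cfg$p_star <- d / (d - lambda)
  class(cfg) <- "sim_config"
  check_sim_config(cfg)
  cfg
}

check_sim_config <- function(cfg) {
  errs <- character()
  if (cfg$d < 3) errs <- c(errs, "dimension d must be >= 3")
  if (!(cfg$lambda > 0 && cfg$lambda < cfg$d - 2)) {
    errs <- c(errs, sprintf("lambda = %g violates 0 < lambda < d - 2", cfg$lambda))
  }
  if (!(cfg$kappa %in% c(-1, 0, 1))) errs <- c(errs, "kappa must be -1, 0 or +1")
  if (!cfg$test_mode) {
    if (cfg$sigma <= 0) errs <- c(errs, "sigma must be > 0 (or set test_mode)")
    if (cfg$kappa == 0) errs <- c(errs, "kappa = 0 requires test_mode")
  }
  if (cfg$sigma < 0) errs <- c(errs, "sigma must be nonnegative")
  if (cfg$dt <= 0 || cfg$T <= 0) errs <- c(errs, "dt and T must be positive")
  if (cfg$N < 1) errs <- c(errs, "N must be positive")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("particle run: N = %d, d = %d, lambda = %g, kappa = %+d,",
                     " sigma = %g\n"), x$N, x$d, x$lambda, x$kappa, x$sigma))
  cat(sprintf("  moderate scaling: beta = %g, eta = %.4g;  dt = %g, T = %g, seed = %d\n",
              x$beta, x$eta, x$dt, x$T, x$seed))
  cat(sprintf("  box L = %g, grid %d^%d, u0: Gaussian width %g;  L^p* norm logged with p* = %.3g\n",
              x$L, x$n, x$d, x$s0, x$p_star))
  invisible(x)
}

# seed for replica r derived from the base seed; kept below 2^31
replica_seed <- function(seed, replica) {
  ((as.double(seed) * 7919 + as.double(replica) * 104729) %% 2147483629) + 1
}

#' Draw the initial particle ensemble
#'
#' `N` i.i.d. draws from the isotropic Gaussian initial density, wrapped
#' into the box. The unwrapped tail mass outside the box is estimated and an
#' error is raised if it exceeds `tail_tol`.
#'
#' @param config a [sim_config()].
#' @param tail_tol tolerance on the unwrapped tail mass (default `1e-5`).
#' @return `N x d` matrix of positions in `[-L/2, L/2)^d`.
#' @export
sample_initial <- function(config, tail_tol = 1e-5) {
  half <- config$L / 2
  tail <- sum(vapply(seq_len(config$d), function(j) {
    stats::pnorm(-half, config$center[j] - 0, config$s0) +
      stats::pnorm(half, config$center[j], config$s0, lower.tail = FALSE)
  }, numeric(1)))
  if (tail > tail_tol) {
    stop(sprintf("initial density overflows the box: tail mass %.3g > %.3g",
                 tail, tail_tol))
  }
  set.seed(config$seed)
  X <- matrix(stats::rnorm(config$N * config$d, sd = config$s0),
              config$N, config$d, byrow = FALSE)
  X <- sweep(X, 2, config$center, `+`)
  wrap_box(X, config$L)
}

#' Pairwise interaction drift of the interacting system
#'
#' `(kappa/N) sum_j grad V^eta(X_i - X_j)` with minimum-image displacements
#' and the radial gradient table of the kernel; the `j = i` term contributes
#' exactly 0. Forces are accumulated pairwise so the total drift sums to zero
#' to rounding (Newton's third law).
#'
#' @param X `N x d` position matrix.
#' @param tables a [build_kernel_tables()] object.
#' @param kappa interaction sign.
#' @return `N x d` drift matrix.
#' @export
drift_interacting <- function(X, tables, kappa) {
  if (kappa == 0) return(matrix(0, nrow(X), ncol(X)))
  F <- pair_force_sum(X, tables$grid$L, tables$dV_eta, tables$dr)
  if (!all(is.finite(F))) stop("non-finite force table lookup")
  kappa * F
}

#' One Euler-Maruyama step
#'
#' `X <- wrap(X + drift dt + sqrt(2 sigma dt) G)` with `G` the supplied
#' standard-normal increments (drawn by the caller so that coupled systems
#' can share them).
#'
#' @param X `N x d` positions.
#' @param drift `N x d` drift.
#' @param sigma diffusion constant.
#' @param dt time step.
#' @param L box edge.
#' @param noise `N x d` standard normal matrix.
#' @return updated positions, wrapped.
#' @export
step_euler_maruyama <- function(X, drift, sigma, dt, L, noise) {
  wrap_box(X + drift * dt + sqrt(2 * sigma * dt) * noise, L)
}

#' Simulate the interacting particle system
#'
#' @param config a [sim_config()].
#' @param tables kernel tables built for the run's `eta`.
#' @param X0 initial positions (default [sample_initial()] under the config
#'   seed).
#' @param noise optional array `steps x N x d` of standard normal increments
#'   (for coupling or exchangeability experiments); drawn internally when
#'   `NULL`.
#' @return an object of class `"particle_paths"`: list with `snaps` (list of
#'   position matrices), `times`, `config`, and `X` (final positions).
#' @export
simulate_interacting <- function(config, tables, X0 = NULL, noise = NULL) {
  if (is.null(X0)) X0 <- sample_initial(config)
  nst <- round(config$T / config$dt)
  X <- X0
  snaps <- list(X)
  times <- 0
  for (s in seq_len(nst)) {
    G <- if (is.null(noise)) matrix(stats::rnorm(config$N * config$d),
                                    config$N, config$d)
         else matrix(noise[s, , ], config$N, config$d)
    dr <- drift_interacting(X, tables, config$kappa)
    X <- step_euler_maruyama(X, dr, config$sigma, config$dt, config$L, G)
    if (s %% config$snapshot_stride == 0 || s == nst) {
      snaps <- c(snaps, list(X))
      times <- c(times, s * config$dt)
    }
  }
  structure(list(snaps = snaps, times = times, config = config, X = X),
            class = "particle_paths")
}

#' @export
print.particle_paths <- function(x, ...) {
  cat(sprintf("particle paths: N = %d, d = %d, %d snapshots on [0, %g]\n",
              x$config$N, x$config$d, length(x$snaps), max(x$times)))
  invisible(x)
}

# precompute the drift fields kappa * (grad V^eta * ubar) at the saved
# snapshots of a pde_solution; returns list over snapshots of list over
# components (arrays)
intermediate_drift_fields <- function(ubar_sol, tables, kappa) {
  g <- tables$grid
  lapply(ubar_sol$snaps, function(u) {
    uh <- fft_fwd(u, g)
    lapply(seq_len(g$d), function(j) {
      fft_inv(1i * g$karr[[j]] * tables$V_eta_symbol * uh, g) * kappa
    })
  })
}

#' Simulate the intermediate (independent) particle system
#'
#' Particles driven by the precomputed mean-field force
#' `kappa (grad V^eta * ubar^eta)(t, x)`, interpolated linearly in time
#' between the stored PDE snapshots and multilinearly in space; no pairwise
#' interaction, so the particles are i.i.d. with common density `ubar^eta`.
#'
#' @param config a [sim_config()].
#' @param ubar_sol a [solve_forward()] solution of the intermediate equation
#'   whose snapshots cover `[0, T]`.
#' @param tables kernel tables (for the interaction symbol and grid).
#' @param X0,noise as in [simulate_interacting()].
#' @return a `"particle_paths"` object.
#' @export
simulate_intermediate <- function(config, ubar_sol, tables, X0 = NULL,
                                  noise = NULL) {
  if (max(ubar_sol$times) < config$T - 1e-12) {
    stop("ubar snapshots do not cover the simulation horizon")
  }
  if (is.null(X0)) X0 <- sample_initial(config)
  g <- tables$grid
  fields <- intermediate_drift_fields(ubar_sol, tables, config$kappa)
  ft <- ubar_sol$times
  nst <- round(config$T / config$dt)
  X <- X0
  snaps <- list(X)
  times <- 0
  for (s in seq_len(nst)) {
    G <- if (is.null(noise)) matrix(stats::rnorm(config$N * config$d),
                                    config$N, config$d)
         else matrix(noise[s, , ], config$N, config$d)
    tnow <- (s - 1) * config$dt
    dr <- eval_drift_field(fields, ft, tnow, X, g, config$kappa)
    X <- step_euler_maruyama(X, dr, config$sigma, config$dt, config$L, G)
    if (s %% config$snapshot_stride == 0 || s == nst) {
      snaps <- c(snaps, list(X))
      times <- c(times, s * config$dt)
    }
  }
  structure(list(snaps = snaps, times = times, config = config, X = X),
            class = "particle_paths")
}

# linear-in-time interpolation of the drift fields, gathered at positions
eval_drift_field <- function(fields, ftimes, tnow, X, grid, kappa) {
  if (kappa == 0) return(matrix(0, nrow(X), ncol(X)))
  i <- findInterval(tnow, ftimes, all.inside = TRUE)
  w <- (tnow - ftimes[i]) / (ftimes[i + 1] - ftimes[i])
  w <- min(max(w, 0), 1)
  dr <- matrix(0, nrow(X), grid$d)
  for (j in seq_len(grid$d)) {
    fj <- (1 - w) * fields[[i]][[j]] + w * fields[[i + 1]][[j]]
    dr[, j] <- cic_gather_cpp(as.vector(fj), X, grid$n, grid$L)
  }
  dr
}

#' Simulate the synchronously coupled pair of systems
#'
#' Runs the interacting and the intermediate system from the same initial
#' data with identical Brownian increments, recording the coupling statistic
#' `max_i |X_i - Xbar_i|` (minimum-image distance) at each saved snapshot.
#'
#' @param config a [sim_config()].
#' @param ubar_sol intermediate-equation solution covering `[0, T]`.
#' @param tables kernel tables for the run's `eta`.
#' @return a list of class `"coupled_paths"`: `X`, `Xbar` (final positions),
#'   `times`, `coupling` (the statistic per snapshot), `config`.
#' @export
simulate_coupled <- function(config, ubar_sol, tables) {
  if (max(ubar_sol$times) < config$T - 1e-12) {
    stop("ubar snapshots do not cover the simulation horizon")
  }
  g <- tables$grid
  fields <- intermediate_drift_fields(ubar_sol, tables, config$kappa)
  ft <- ubar_sol$times
  X0 <- sample_initial(config)
  X <- X0; Xb <- X0
  nst <- round(config$T / config$dt)
  coupling <- max_min_image_dist(X, Xb, config$L)
  times <- 0
  for (s in seq_len(nst)) {
    G <- matrix(stats::rnorm(config$N * config$d), config$N, config$d)
    tnow <- (s - 1) * config$dt
    drX <- drift_interacting(X, tables, config$kappa)
    drB <- eval_drift_field(fields, ft, tnow, Xb, g, config$kappa)
    X <- step_euler_maruyama(X, drX, config$sigma, config$dt, config$L, G)
    Xb <- step_euler_maruyama(Xb, drB, config$sigma, config$dt, config$L, G)
    if (s %% config$snapshot_stride == 0 || s == nst) {
      coupling <- c(coupling, max_min_image_dist(X, Xb, config$L))
      times <- c(times, s * config$dt)
    }
  }
  structure(list(X = X, Xbar = Xb, times = times, coupling = coupling,
                 config = config),
            class = "coupled_paths")
}

max_min_image_dist <- function(X, Y, L) {
  D <- wrap_box(X - Y, L)
  max(sqrt(rowSums(D^2)))
}

#' Coupling statistic of a coupled run
#'
#' @param coupled a `"coupled_paths"` object from [simulate_coupled()].
#' @return numeric vector: `max_i |X_i - Xbar_i|` at the saved snapshot
#'   times.
#' @export
coupling_statistic <- function(coupled) {
  if (!inherits(coupled, "coupled_paths")) {
    stop("coupling requires a shared-noise coupled run")
  }
  coupled$coupling
}

#' Interaction energy of a configuration
#'
#' `(1/N^2) sum_{i,j} V^eta(X_i - X_j)` from the radial table (diagonal
#' included); non-increasing along noiseless repulsive dynamics.
#'
#' @param X `N x d` positions.
#' @param tables kernel tables.
#' @return scalar energy.
#' @export
interaction_energy <- function(X, tables) {
  pair_energy(X, tables$grid$L, tables$V_eta, tables$dr)
}
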