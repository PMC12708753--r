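# The measurable statistics: smoothed empirical-measure error norms, the
# decay-rate fit in N, the fluctuation pairing and its CLT test, and the
# law-of-large-numbers / coupling diagnostics.

#' Smoothed empirical-measure error record
#'
#' Computes `f^eta = Z^eta * mu^eta` (empirical measure deposited by
#' deconvolved cloud-in-cell) and `g^eta = Z^eta * ubar^eta` at the shared
#' save times, and records `||f - g||_L2^2`, `||grad(f - g)||_L2^2`, their
#' sup over saved times and the trapezoidal time integral of the gradient
#' term. Both measures have unit mass, so `f - g` is mean-free to rounding.
#'
#' @param particles a `"particle_paths"` object.
#' @param ubar_sol intermediate-equation solution sharing the save times.
#' @param tables kernel tables providing `Z_eta_symbol`.
#' @return an object of class `"smoothed_error"` with fields `times`,
#'   `l2_sq`, `h1_sq`, `sup_l2_sq`, `dissipation`, `mean_abs` (the box mean
#'   of `f - g`, a zero check).
#' @export
smoothed_error <- function(particles, ubar_sol, tables) {
  g <- tables$grid
  tms <- particles$times
  if (length(tms) > length(ubar_sol$times) ||
      max(abs(tms - ubar_sol$times[seq_along(tms)])) > 1e-9) {
    stop("particle and PDE snapshots do not share save times")
  }
  hd <- g$h^g$d
  l2s <- h1s <- mns <- numeric(length(tms))
  for (i in seq_along(tms)) {
    mu <- deposit_particles(particles$snaps[[i]], g, "cic", deconvolve = TRUE)
    dh <- fft_fwd(mu$values - ubar_sol$snaps[[i]], g) * tables$Z_eta_symbol
    l2s[i] <- sum(Mod(dh)^2) / g$L^g$d
    h1s[i] <- sum(g$k2 * Mod(dh)^2) / g$L^g$d
    mns[i] <- Re(dh[1]) / g$L^g$d   # zero mode of the difference
  }
  structure(list(times = tms, l2_sq = l2s, h1_sq = h1s,
                 sup_l2_sq = max(l2s),
                 dissipation = trapz(tms, h1s),
                 mean_abs = max(abs(mns))),
            class = "smoothed_error")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Closed-form i.i.d. sampling identity
#'
#' For `N` i.i.d. samples from a density `u`,
#' `E ||Z^eta * (mu - u)||_L2^2 = (1/N)(||Z^eta||^2 - ||Z^eta * u||^2)`;
#' evaluated from the spectral symbols. Used as the static oracle for the
#' smoothed-error statistic.
#'
#' @param u_field a [grid_field()] density.
#' @param tables kernel tables.
#' @param N sample count.
#' @return the expected squared error.
#' @export
iid_smoothing_identity <- function(u_field, tables, N) {
  g <- tables$grid
  uh <- fft_fwd(u_field$values, g)
  Z2 <- sum(Mod(tables$Z_eta_symbol)^2) / g$L^g$d
  Zu2 <- sum(Mod(tables$Z_eta_symbol * uh)^2) / g$L^g$d
  (Z2 - Zu2) / N
}

#' Monte-Carlo estimate of the mean-square convergence rate
#'
#' For each `N` in `N_list` (with `eta = N^-beta`) the intermediate equation
#' is solved once and `replicas` interacting-particle runs are scored by
#' `sup_t ||f^eta - g^eta||_L2^2`; the decay exponent `r` in
#' `E sup_t ||f - g||^2 ~ N^-r` is fitted by weighted least squares of the
#' log means against `log N`.
#'
#' @param config_template a [sim_config()]; its `N` field is replaced per
#'   run, `eta` is re-derived as `N^-beta`.
#' @param N_list at least three particle counts.
#' @param replicas Monte-Carlo replicas per `N`.
#' @param seed base seed for the replica streams (defaults to the template
#'   seed).
#' @return an object of class `"rate_fit"` with `N_list`, `estimates`,
#'   `se`, `slope`, `slope_se`, `per_replica`.
#' @export
estimate_rate <- function(config_template, N_list, replicas = 8, seed = NULL) {
  if (length(N_list) < 3) stop("need at least 3 particle counts for a rate fit")
  if (is.null(seed)) seed <- config_template$seed
  cfg0 <- config_template
  if (cfg0$beta >= 1 / (8 * cfg0$lambda + 12)) {
    stop(sprintf("beta = %g outside the admissible range beta < 1/(8 lambda + 12) = %g",
                 cfg0$beta, 1 / (8 * cfg0$lambda + 12)))
  }
  grid <- torus_grid(cfg0$n, cfg0$d, cfg0$L)
  spec <- riesz_spec(cfg0$d, cfg0$lambda)
  u0 <- gaussian_field(grid, cfg0$s0, cfg0$center)
  per <- list()
  for (N in N_list) {
    cfg <- cfg0
    cfg$N <- as.integer(N)
    cfg$eta <- N^(-cfg$beta)
    tables <- build_kernel_tables(spec, mollifier_spec(cfg$eta, cfg$beta), grid)
    ubar <- solve_forward(u0, tables$V_eta_symbol, cfg$sigma, cfg$kappa,
                          cfg$dt, cfg$T, save_stride = cfg$snapshot_stride)
    vals <- vapply(seq_len(replicas), function(r) {
      cfg$seed <- replica_seed(seed, r + 1000 * match(N, N_list))
      paths <- simulate_interacting(cfg, tables)
      smoothed_error(paths, ubar, tables)$sup_l2_sq
    }, numeric(1))
    per[[as.character(N)]] <- vals
  }
  est <- vapply(per, mean, numeric(1))
  se <- vapply(per, function(v) stats::sd(v) / sqrt(length(v)), numeric(1))
  if (any(est <= 0)) stop("degenerate rate fit: nonpositive estimates")
  w <- (est / se)^2
  fit <- stats::lm(log(est) ~ log(N_list), weights = w)
  structure(list(N_list = N_list, estimates = est, se = se,
                 slope = -unname(stats::coef(fit)[2]),
                 slope_se = sqrt(stats::vcov(fit)[2, 2]),
                 per_replica = per, config = cfg0, replicas = replicas),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Mean-square convergence of smoothed empirical measures\n")
  cat(sprintf("  E sup_t ||f^eta - g^eta||_L2^2 over N in {%s}, %d replicas\n",
              paste(x$N_list, collapse = ", "), x$replicas))
  for (i in seq_along(x$N_list)) {
    cat(sprintf("   N = %5d : %.4g (se %.2g)\n", x$N_list[i], x$estimates[i],
                x$se[i]))
  }
  cat(sprintf("  fitted decay exponent r = %.3f (se %.3f)\n", x$slope,
              x$slope_se))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(slope = object$slope, slope_se = object$slope_se)
}

#' @export
plot.rate_fit <- function(x, ...) {
  graphics::plot(x$N_list, x$estimates, log = "xy", xlab = "N",
                 ylab = "E sup ||f - g||^2", pch = 19, ...)
  graphics::arrows(x$N_list, x$estimates - x$se, x$N_list, x$estimates + x$se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(stats::lm(log10(x$estimates) ~ log10(x$N_list)), lty = 2)
}

#' Fluctuation-field pairing
#'
#' `<F^eta(t), phi> = N^{-1/2} sum_i phi(X_i(t)) - sqrt(N) <ubar^eta(t), phi>`
#' with the bracket evaluated by grid quadrature.
#'
#' @param X `N x d` particle positions at time `t`.
#' @param ubar_t a [grid_field()] of the intermediate density at `t` (or a
#'   plain array on the same grid).
#' @param tf a [test_function()].
#' @param grid the [torus_grid()].
#' @return scalar pairing value.
#' @export
pair_fluctuation <- function(X, ubar_t, tf, grid) {
  N <- nrow(X)
  vals <- if (inherits(ubar_t, "grid_field")) ubar_t$values else ubar_t
  phig <- tf_grid(tf, grid)
  bracket <- sum(vals * phig$values) * grid$h^grid$d
  sum(tf_eval(tf, X, grid$L)) / sqrt(N) - sqrt(N) * bracket
}

#' Predicted asymptotic fluctuation variance
#'
#' The limit variance of `<F(t), phi>`:
#' `<u0, T^t_phi(0)^2> - <u0, T^t_phi(0)>^2
#'  + 2 sigma int_0^t <u(s), |grad T^t_phi(s)|^2> ds`,
#' with `u` the limit-equation solution and `T^t_phi` the dual backward
#' flow; quadrature on the grid and trapezoid in time over the dual's saved
#' snapshots.
#'
#' @param u_sol limit-equation [solve_forward()] solution covering `[0, t]`.
#' @param dual_sol matching [solve_dual_backward()] solution.
#' @param u0 a [grid_field()] initial density.
#' @param sigma diffusion constant.
#' @param t terminal time.
#' @return list with `total`, `initial`, `dynamic` variance components.
#' @export
predicted_variance <- function(u_sol, dual_sol, u0, sigma, t) {
  g <- u_sol$grid
  if (abs(dual_sol$times[1]) > 1e-9 ||
      abs(dual_sol$times[length(dual_sol$times)] - t) > 1e-9) {
    stop("dual solution does not cover [0, t]")
  }
  hd <- g$h^g$d
  T0 <- dual_sol$snaps[[1]]
  init <- sum(u0$values * T0^2) * hd - (sum(u0$values * T0) * hd)^2
  gr2 <- vapply(seq_along(dual_sol$times), function(i) {
    vh <- fft_fwd(dual_sol$snaps[[i]], g)
    acc <- 0
    for (j in seq_len(g$d)) acc <- acc + fft_inv(1i * g$karr[[j]] * vh, g)^2
    us <- pde_at_time(u_sol, dual_sol$times[i])
    sum(us * acc) * hd
  }, numeric(1))
  dyn <- 2 * sigma * trapz(dual_sol$times, gr2)
  list(total = init + dyn, initial = init, dynamic = dyn)
}

#' Distributional test of fluctuation replicates
#'
#' Compares Monte-Carlo replicates of `<F^eta(t), phi>` with the zero-mean
#' normal of the predicted variance: variance ratio with a bootstrap
#' standard error, and a Kolmogorov-Smirnov test. When the predicted
#' variance vanishes the test degenerates to requiring all samples to be
#' numerically zero.
#'
#' @param samples numeric vector of replicate pairings (at least 30 for the
#'   distributional branch).
#' @param predicted predicted variance (scalar or the list returned by
#'   [predicted_variance()]).
#' @param boot bootstrap resamples for the variance standard error.
#' @return an object of class `"clt_test"`: `variance_ratio`,
#'   `ks_statistic`, `ks_pvalue`, `var_boot_se`, `sample_var`, `predicted`,
#'   `degenerate`, `n`.
#' @export
clt_test <- function(samples, predicted, boot = 2000) {
  if (is.list(predicted)) predicted <- predicted$total
  n <- length(samples)
  if (predicted < 1e-14) {
    return(structure(list(variance_ratio = NA_real_, ks_statistic = NA_real_,
                          ks_pvalue = NA_real_, var_boot_se = NA_real_,
                          sample_var = stats::var(samples),
                          predicted = predicted,
                          degenerate = TRUE,
                          all_zero = all(abs(samples) < 1e-8), n = n),
                     class = "clt_test"))
  }
  if (n < 30) stop("need at least 30 replicates for a distributional test")
  sv <- stats::var(samples)
  bse <- stats::sd(vapply(seq_len(boot), function(b) {
    stats::var(sample(samples, replace = TRUE))
  }, numeric(1)))
  ks <- stats::ks.test(samples, "pnorm", mean = 0, sd = sqrt(predicted))
  structure(list(variance_ratio = sv / predicted,
                 ks_statistic = unname(ks$statistic),
                 ks_pvalue = ks$p.value, var_boot_se = bse,
                 sample_var = sv, predicted = predicted,
                 degenerate = FALSE, all_zero = NA, n = n),
            class = "clt_test")
}

#' @export
print.clt_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("degenerate CLT test (predicted variance 0): all samples zero = %s\n",
                x$all_zero))
    return(invisible(x))
  }
  cat(sprintf("fluctuation CLT test on %d replicates\n", x$n))
  cat(sprintf("  sample variance %.4g vs predicted %.4g  (ratio %.3f, boot se %.2g)\n",
              x$sample_var, x$predicted, x$variance_ratio, x$var_boot_se))
  cat(sprintf("  KS statistic %.3f, p = %.3g\n", x$ks_statistic, x$ks_pvalue))
  invisible(x)
}

#' Full dynamic central-limit-theorem experiment
#'
#' Solves the intermediate equation (mollified kernel) and the limit
#' equation (bare Riesz kernel), the dual backward flow with terminal
#' condition `phi`, forms the predicted variance, then simulates
#' `replicas` independent interacting-particle runs with fresh i.i.d.
#' initial data and evaluates `<F^eta(T), phi>` for each; returns the
#' [clt_test()] augmented with the samples and the variance components.
#'
#' @param config a [sim_config()]; the experiment horizon is `config$T`.
#' @param tf a [test_function()].
#' @param replicas number of Monte-Carlo replicates (>= 30).
#' @param pde_stride save stride of the PDE solves.
#' @return a `"clt_test"` object with extra fields `samples`, `components`,
#'   `config`.
#' @export
fluctuation_experiment <- function(config, tf, replicas = 100, pde_stride = 5) {
  grid <- torus_grid(config$n, config$d, config$L)
  spec <- riesz_spec(config$d, config$lambda)
  tables <- build_kernel_tables(spec, mollifier_spec(config$eta, config$beta),
                                grid)
  u0 <- gaussian_field(grid, config$s0, config$center)
  ubar <- solve_forward(u0, tables$V_eta_symbol, config$sigma, config$kappa,
                        config$dt, config$T, save_stride = pde_stride)
  ulim <- solve_forward(u0, tables$Phi_symbol, config$sigma, config$kappa,
                        config$dt, config$T, save_stride = pde_stride)
  dual <- solve_dual_backward(ulim, tf, config$T, tables$Phi_symbol,
                              save_stride = pde_stride)
  pv <- predicted_variance(ulim, dual, u0, config$sigma, config$T)
  ubar_T <- grid_field(pde_at_time(ubar, config$T), grid, config$T)
  cfg <- config
  samples <- vapply(seq_len(replicas), function(r) {
    cfg$seed <- replica_seed(config$seed, r)
    paths <- simulate_interacting(cfg, tables)
    pair_fluctuation(paths$X, ubar_T, tf, grid)
  }, numeric(1))
  out <- clt_test(samples, pv)
  out$samples <- samples
  out$components <- pv
  out$config <- config
  out
}

#' Empirical law-of-large-numbers set probability
#'
#' For the intermediate (i.i.d.) system and the vector kernel
#' `psi = grad V^eta`, estimates the probability of the event that
#' `max_i |(1/N) sum_j psi(Xbar_i - Xbar_j) - (psi * ubar^eta)(Xbar_i)|`
#' exceeds `N^-theta` at any saved time, by Monte-Carlo over replicas.
#'
#' @param config a [sim_config()].
#' @param theta threshold exponent (>= 0).
#' @param replicas Monte-Carlo replicas (>= 20 recommended).
#' @return a list with `prob` (fraction of replicas in the set at any saved
#'   time), `prob_final` (at the final time), `threshold`, `max_dev` (per
#'   replica sup deviation).
#' @export
lln_probability <- function(config, theta, replicas = 20) {
  grid <- torus_grid(config$n, config$d, config$L)
  spec <- riesz_spec(config$d, config$lambda)
  tables <- build_kernel_tables(spec, mollifier_spec(config$eta, config$beta),
                                grid)
  u0 <- gaussian_field(grid, config$s0, config$center)
  ubar <- solve_forward(u0, tables$V_eta_symbol, config$sigma, config$kappa,
                        config$dt, config$T, save_stride = config$snapshot_stride)
  # grad V^eta * ubar fields at the saved times
  gfields <- lapply(ubar$snaps, function(u) {
    uh <- fft_fwd(u, grid)
    lapply(seq_len(grid$d), function(j) {
      fft_inv(1i * grid$karr[[j]] * tables$V_eta_symbol * uh, grid)
    })
  })
  thr <- config$N^(-theta)
  cfg <- config
  max_dev <- numeric(replicas)
  dev_final <- numeric(replicas)
  for (r in seq_len(replicas)) {
    cfg$seed <- replica_seed(config$seed, 5000 + r)
    paths <- simulate_intermediate(cfg, ubar, tables)
    devs <- vapply(seq_along(paths$times), function(i) {
      X <- paths$snaps[[i]]
      emp <- pair_force_sum(X, grid$L, tables$dV_eta, tables$dr)
      ti <- which.min(abs(ubar$times - paths$times[i]))
      D2 <- 0
      for (j in seq_len(grid$d)) {
        fj <- cic_gather_cpp(as.vector(gfields[[ti]][[j]]), X, grid$n, grid$L)
        D2 <- D2 + (emp[, j] - fj)^2
      }
      sqrt(max(D2))
    }, numeric(1))
    max_dev[r] <- max(devs)
    dev_final[r] <- devs[length(devs)]
  }
  list(prob = mean(max_dev > thr), prob_final = mean(dev_final > thr),
       threshold = thr, max_dev = max_dev)
}

#' Empirical coupling probability
#'
#' Fraction of synchronously coupled replicas for which
#' `sup_t max_i |X_i - Xbar_i| > N^-alpha`.
#'
#' @param config a [sim_config()].
#' @param alpha threshold exponent; must lie in the admissible window
#'   `(beta (lambda + 3), 1/2 - beta (lambda + 1))`.
#' @param replicas Monte-Carlo replicas.
#' @return a list with `prob`, `threshold`, `sup_coupling` (per replica).
#' @export
coupling_probability <- function(config, alpha, replicas = 12) {
  lo <- config$beta * (config$lambda + 3)
  hi <- 0.5 - config$beta * (config$lambda + 1)
  if (!(alpha > lo && alpha < hi)) {
    stop(sprintf("alpha = %g outside the admissible window (%g, %g)",
                 alpha, lo, hi))
  }
  grid <- torus_grid(config$n, config$d, config$L)
  spec <- riesz_spec(config$d, config$lambda)
  tables <- build_kernel_tables(spec, mollifier_spec(config$eta, config$beta),
                                grid)
  u0 <- gaussian_field(grid, config$s0, config$center)
  ubar <- solve_forward(u0, tables$V_eta_symbol, config$sigma, config$kappa,
                        config$dt, config$T, save_stride = config$snapshot_stride)
  cfg <- config
  sup_c <- vapply(seq_len(replicas), function(r) {
    cfg$seed <- replica_seed(config$seed, 9000 + r)
    set.seed(cfg$seed)
    cpl <- simulate_coupled(cfg, ubar, tables)
    max(coupling_statistic(cpl))
  }, numeric(1))
  thr <- config$N^(-alpha)
  list(prob = mean(sup_c > thr), threshold = thr, sup_coupling = sup_c)
}
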