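test_that("smoothed error matches the i.i.d. sampling identity and is mean-free", {
  g <- fx_grid()
  tab <- fx_tables()
  u0 <- fx_u0()
  closed <- iid_smoothing_identity(u0, tab, 1000)
  uh <- modfluct:::fft_fwd(u0$values, g)
  set.seed(101)
  vals <- replicate(100, {
    X <- matrix(rnorm(3000), 1000, 3)
    X <- X - 10 * floor((X + 5) / 10)
    mu <- deposit_particles(X, g, "cic", deconvolve = TRUE)
    dh <- modfluct:::fft_fwd(mu$values - u0$values, g) * tab$Z_eta_symbol
    sum(Mod(dh)^2) / g$L^3
  })
  z <- (mean(vals) - closed) / (sd(vals) / sqrt(100))
  expect_lt(abs(z), 3)
  # the record is mean-free and nonnegative; the degenerate deposit (g vs g)
  # gives exactly zero
  cfg <- sim_config(N = 200, seed = 61, T = 0.05, dt = 0.005,
                    snapshot_stride = 10, eta = 0.73)
  ubar <- fx_ubar(T = 0.05)
  p <- simulate_interacting(cfg, tab)
  rec <- smoothed_error(p, ubar, tab)
  expect_lt(rec$mean_abs, 1e-12)
  expect_true(all(rec$l2_sq >= 0) && all(rec$h1_sq >= 0))
  expect_gte(rec$sup_l2_sq, max(rec$l2_sq))
  zero <- modfluct:::fft_fwd(ubar$snaps[[1]] - ubar$snaps[[1]], g)
  expect_identical(max(Mod(zero)), 0)
})

test_that("fixed-eta free particles decay at the Monte-Carlo rate N^-1", {
  # beta = 0 keeps eta fixed; the i.i.d. identity then forces slope 1
  cfg <- sim_config(N = 64, kappa = 0, sigma = 1, beta = 0, dt = 0.01,
                    T = 0.05, seed = 41, snapshot_stride = 5, test_mode = TRUE)
  fit <- estimate_rate(cfg, c(64, 128, 256, 512), replicas = 6)
  expect_lt(abs(fit$slope - 1), 3 * fit$slope_se)
  expect_equal(unname(coef(fit)["slope"]), fit$slope)
})

test_that("fluctuation pairing: mass cancellation and the t = 0 CLT", {
  g <- fx_grid()
  u0 <- fx_u0()
  cfg <- sim_config(N = 400, seed = 71)
  X <- sample_initial(cfg)
  one <- test_function("constant")
  expect_lt(abs(pair_fluctuation(X, u0, one, g)), sqrt(400) * 1e-12)
  # replicate variance at t = 0 equals <u0, phi^2> - <u0, phi>^2
  tf <- test_function("gaussian_bump", width = 1.5)
  phig <- tf_grid(tf, g)
  m1 <- sum(u0$values * phig$values) * g$h^3
  m2 <- sum(u0$values * phig$values^2) * g$h^3
  target <- m2 - m1^2
  cfg2 <- cfg
  vals <- vapply(1:150, function(r) {
    cfg2$seed <- modfluct:::replica_seed(71, r)
    pair_fluctuation(sample_initial(cfg2), u0, tf, g)
  }, numeric(1))
  sv <- var(vals)
  se <- sv * sqrt(2 / (length(vals) - 1))
  expect_lt(abs(sv - target), 3 * se)
  expect_gt(ks.test(vals, "pnorm", 0, sqrt(target))$p.value, 0.01)
})

test_that("predicted variance: short-time limit and kappa = 0 Gaussian oracle", {
  g <- fx_grid()
  u0 <- fx_u0()
  tab <- fx_tables()
  tf <- test_function("gaussian_bump", width = 1.2)
  phig <- tf_grid(tf, g)
  m1 <- sum(u0$values * phig$values) * g$h^3
  m2 <- sum(u0$values * phig$values^2) * g$h^3
  # t -> 0: the variance reduces to the initial i.i.d. part (the dynamic
  # term is O(t) and still visible at t = 0.01)
  usol <- solve_forward(u0, tab$Phi_symbol, 1, 1, 0.005, 0.01, save_stride = 1)
  dual <- solve_dual_backward(usol, tf, 0.01, tab$Phi_symbol, save_stride = 1)
  pv <- predicted_variance(usol, dual, u0, 1, 0.01)
  expect_equal(pv$total, m2 - m1^2, tolerance = 0.05)
  expect_lt(pv$dynamic, 0.1 * pv$total)
  # kappa = 0: all ingredients are explicit Gaussians; quadrature oracle
  sigma <- 1; t <- 0.2; w <- tf$width; s0 <- 1
  uheat <- solve_forward(u0, tab$Phi_symbol, sigma, 0, 0.005, t, save_stride = 2)
  dual0 <- solve_dual_backward(uheat, tf, t, tab$Phi_symbol, save_stride = 2)
  pv0 <- predicted_variance(uheat, dual0, u0, sigma, t)
  ss <- seq(0, t, length.out = 81)
  grad2 <- vapply(ss, function(s) {
    wt <- sqrt(w^2 + 2 * sigma * (t - s))
    amp <- (w^2 / wt^2)^1.5
    Tf <- tf_grid(test_function("gaussian_bump", width = wt, amplitude = amp), g)
    vh <- modfluct:::fft_fwd(Tf$values, g)
    acc <- 0
    for (j in 1:3) acc <- acc + modfluct:::fft_inv(1i * g$karr[[j]] * vh, g)^2
    us <- gaussian_field(g, sqrt(s0^2 + 2 * sigma * s))
    sum(us$values * acc) * g$h^3
  }, numeric(1))
  T0w <- sqrt(w^2 + 2 * sigma * t)
  T0 <- tf_grid(test_function("gaussian_bump", width = T0w,
                              amplitude = (w^2 / T0w^2)^1.5), g)
  oracle <- sum(u0$values * T0$values^2) * g$h^3 -
    (sum(u0$values * T0$values) * g$h^3)^2 +
    2 * sigma * modfluct:::trapz(ss, grad2)
  expect_equal(pv0$total, oracle, tolerance = 1e-3)
})

test_that("CLT test is calibrated on its own null and handles degeneracy", {
  set.seed(313)
  v <- 0.07
  samples <- rnorm(200, 0, sqrt(v))
  ct <- clt_test(samples, v)
  expect_gt(ct$ks_pvalue, 0.001)
  expect_lt(abs(ct$variance_ratio - 1), 3 * ct$var_boot_se / v)
  # constant test function: predicted variance 0, all pairings vanish
  ct0 <- clt_test(rep(0, 50), 0)
  expect_true(ct0$degenerate)
  expect_true(ct0$all_zero)
  expect_error(clt_test(rnorm(10), 1), "at least 30")
})

test_that("law-of-large-numbers deviations are far below the theta = 0 threshold", {
  cfg <- sim_config(N = 256, seed = 23, T = 0.1, dt = 0.005,
                    snapshot_stride = 10)
  out <- lln_probability(cfg, theta = 0, replicas = 5)
  expect_equal(out$prob, 0)
  expect_true(all(out$max_dev < 1))
})
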