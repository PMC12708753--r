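test_that("initial sampling has the right moments and is reproducible", {
  cfg <- sim_config(N = 4000, seed = 77, s0 = 0.8)
  X <- sample_initial(cfg)
  expect_true(all(X >= -5 & X < 5))
  expect_lt(max(abs(colMeans(X))), 3 * 0.8 / sqrt(4000))
  v <- apply(X, 2, var)
  se <- 0.8^2 * sqrt(2 / (4000 - 1))
  expect_true(all(abs(v - 0.8^2) < 3 * se))
  expect_identical(sample_initial(cfg), X)   # bit-exact replay
  expect_error(sample_initial(sim_config(N = 10, seed = 1, s0 = 3)),
               "overflow")
})

test_that("interaction drift balances forces and attracts in the far field", {
  tab <- fx_tables()
  expect_equal(drift_interacting(matrix(0, 1, 3), tab, 1), matrix(0, 1, 3))
  set.seed(5)
  X <- matrix(runif(90, -5, 5), 30, 3)
  dr <- drift_interacting(X, tab, 1)
  expect_lt(max(abs(colSums(dr))), 1e-12 * max(abs(dr)) * nrow(X))
  # two particles with eta << r << L: radial drift ~ (1/N) lambda r^(-lambda-1),
  # directed so that kappa = +1 makes them approach
  tab64 <- fx_tables(eta = 0.35, n = 64)
  X2 <- rbind(c(-1, 0, 0), c(1, 0, 0))      # separation r = 2
  d2 <- drift_interacting(X2, tab64, 1)
  mag <- 0.5 * 0.5 * 2^(-1.5)               # (1/N) lambda r^(-lambda-1), N = 2
  expect_equal(abs(d2[1, 1]), mag, tolerance = 0.1)
  expect_gt(d2[1, 1], 0)                    # particle 1 moves toward particle 2
  expect_equal(d2[2, ], -d2[1, ])
  d2r <- drift_interacting(X2, tab64, -1)   # repulsion reverses the force
  expect_equal(d2r, -d2)
})

test_that("Euler-Maruyama steps: degenerate cases, Brownian scaling, replay", {
  X <- matrix(c(0.3, -2, 1), 1, 3)
  expect_equal(step_euler_maruyama(X, matrix(0, 1, 3), 0, 0.01, 10,
                                   matrix(rnorm(3), 1, 3)), X)
  # free particles: displacement variance 2 sigma t per coordinate
  cfg <- sim_config(N = 2000, kappa = 0, sigma = 0.5, dt = 0.01, T = 0.2,
                    seed = 21, test_mode = TRUE)
  tab <- fx_tables()
  p <- simulate_interacting(cfg, tab)
  disp <- p$X - p$snaps[[1]]               # no wrapping occurs at these scales
  v <- var(as.vector(disp))
  target <- 2 * 0.5 * 0.2
  expect_lt(abs(v - target), 3 * target * sqrt(2 / (3 * 2000)))
  # fixed seed gives bit-exact trajectories
  p2 <- simulate_interacting(cfg, tab)
  expect_identical(p2$X, p$X)
})

test_that("intermediate system degenerates to free motion and is exchangeable", {
  tab <- fx_tables()
  ubar <- fx_ubar(T = 0.1)
  cfg <- sim_config(N = 16, kappa = 0, sigma = 1, dt = 0.005, T = 0.1,
                    seed = 9, test_mode = TRUE)
  X0 <- sample_initial(cfg)
  steps <- round(cfg$T / cfg$dt)
  set.seed(303)
  noise <- array(rnorm(steps * 16 * 3), c(steps, 16, 3))
  # kappa = 0 with shared noise and identical initial data: Xbar == X bit-exact
  a <- simulate_interacting(cfg, tab, X0 = X0, noise = noise)
  b <- simulate_intermediate(cfg, ubar, tab, X0 = X0, noise = noise)
  expect_identical(a$X, b$X)
  # permuting initial indices (and their noise streams) permutes trajectories
  cfg1 <- sim_config(N = 16, kappa = 1, sigma = 1, dt = 0.005, T = 0.1, seed = 9)
  perm <- sample(16)
  a1 <- simulate_interacting(cfg1, tab, X0 = X0, noise = noise)
  a2 <- simulate_interacting(cfg1, tab, X0 = X0[perm, ],
                             noise = noise[, perm, , drop = FALSE])
  expect_equal(a2$X, a1$X[perm, ], tolerance = 1e-12)
})

test_that("intermediate particles sample the intermediate density", {
  # CIC histogram of Xbar(T) approaches ubar(T) in L1 as N grows
  tab <- fx_tables()
  ubar <- fx_ubar(T = 0.2)
  g <- fx_grid()
  uT <- modfluct:::pde_at_time(ubar, 0.2)
  l1err <- vapply(c(1000, 10000), function(N) {
    cfg <- sim_config(N = N, kappa = 1, sigma = 1, dt = 0.005, T = 0.2,
                      seed = 31, eta = 0.73)
    p <- simulate_intermediate(cfg, ubar, tab)
    emp <- deposit_particles(p$X, g, "cic")
    sum(abs(emp$values - uT)) * g$h^3
  }, numeric(1))
  expect_lt(l1err[2], l1err[1])
})

test_that("coupling statistic vanishes for identical dynamics and freezes without motion", {
  tab <- fx_tables()
  ubar <- fx_ubar(T = 0.1)
  cfg <- sim_config(N = 32, kappa = 0, sigma = 1, dt = 0.005, T = 0.1,
                    seed = 13, test_mode = TRUE)
  cpl <- simulate_coupled(cfg, ubar, tab)
  expect_true(all(coupling_statistic(cpl) == 0))
  expect_error(coupling_statistic(list()), "coupled")
  # sigma = 0, kappa = 0: nothing moves, the statistic stays at its initial value
  cfg0 <- sim_config(N = 8, kappa = 0, sigma = 0, dt = 0.01, T = 0.05,
                     seed = 14, test_mode = TRUE)
  X0 <- sample_initial(cfg0)
  steps <- round(cfg0$T / cfg0$dt)
  noise <- array(rnorm(steps * 8 * 3), c(steps, 8, 3))
  a <- simulate_interacting(cfg0, tab, X0 = X0, noise = noise)
  b <- simulate_intermediate(cfg0, ubar, tab, X0 = X0 + 0.1, noise = noise)
  expect_equal(a$X - b$X, X0 - (X0 + 0.1), tolerance = 1e-12)
})

test_that("repulsive noiseless dynamics dissipates the interaction energy", {
  tab <- fx_tables()
  cfg <- sim_config(N = 64, kappa = -1, sigma = 0, dt = 0.002, T = 0.1,
                    seed = 17, s0 = 0.6, test_mode = TRUE,
                    snapshot_stride = 5)
  X <- sample_initial(cfg)
  energies <- interaction_energy(X, tab)
  for (s in 1:50) {
    dr <- drift_interacting(X, tab, -1)
    X <- step_euler_maruyama(X, dr, 0, cfg$dt, cfg$L, matrix(0, 64, 3))
    energies <- c(energies, interaction_energy(X, tab))
  }
  expect_true(all(diff(energies) <= 1e-10))
})

test_that("center of mass diffuses like a Brownian motion slowed by N", {
  tab <- fx_tables()
  N <- 32
  reps <- 64
  set.seed(55)
  seeds <- sample.int(1e6, reps)
  disp2 <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(N = N, kappa = 1, sigma = 1, dt = 0.01, T = 0.1,
                      seed = seeds[r])
    p <- simulate_interacting(cfg, tab)
    mean((colMeans(p$X) - colMeans(p$snaps[[1]]))^2)
  }, numeric(1))
  target <- 2 * 1 * 0.1 / N
  se <- target * sqrt(2 / (3 * reps))
  expect_lt(abs(mean(disp2) - target), 3 * se)
})
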