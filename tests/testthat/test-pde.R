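test_that("forward solver reproduces heat flow and conserves mass exactly", {
  g <- fx_grid()
  u0 <- fx_u0()
  heat <- solve_forward(u0, fx_tables()$Phi_symbol, sigma = 1, kappa = 0,
                        dt = 0.005, T = 0.5, equation_tag = "limit")
  exact <- gaussian_field(g, sqrt(1 + 2 * 1 * 0.5))
  uT <- heat$snaps[[length(heat$snaps)]]
  relerr <- sqrt(sum((uT - exact$values)^2) / sum(exact$values^2))
  expect_lt(relerr, 1e-6)    # diffusion is treated exactly in frequency space
  expect_lt(diff(range(heat$mass_series)), 1e-12)
  # the nonlinear run conserves mass to rounding as well
  full <- fx_ubar(T = 0.5)
  expect_lt(diff(range(full$mass_series)), 1e-12)
  expect_false(full$blowup)
})

test_that("repulsive flow spreads mass: sup norm nonincreasing", {
  rep <- solve_forward(fx_u0(), fx_tables()$V_eta_symbol, sigma = 1,
                       kappa = -1, dt = 0.005, T = 0.25)
  sups <- vapply(rep$snaps, max, numeric(1))
  expect_true(all(diff(sups) < 0))
})

test_that("dual backward flow honors terminal data, constants, heat oracle", {
  g <- fx_grid()
  ulim <- solve_forward(fx_u0(), fx_tables()$Phi_symbol, sigma = 1, kappa = 1,
                        dt = 0.005, T = 0.3, save_stride = 5,
                        equation_tag = "limit")
  tf <- test_function("gaussian_bump", width = 1.5)
  dual <- solve_dual_backward(ulim, tf, 0.3, fx_tables()$Phi_symbol,
                              save_stride = 5)
  # s = t returns phi exactly
  last <- dual$snaps[[length(dual$snaps)]]
  expect_equal(last, tf_grid(tf, g)$values, tolerance = 1e-12)
  expect_equal(dual$times[length(dual$times)], 0.3)
  expect_equal(dual$times[1], 0)
  # phi == 1: both linearized transport terms vanish, T stays 1
  dual1 <- solve_dual_backward(ulim, test_function("constant"), 0.3,
                               fx_tables()$Phi_symbol, save_stride = 5)
  for (v in dual1$snaps) expect_equal(max(abs(v - 1)), 0, tolerance = 1e-12)
  # kappa = 0: the dual flow is the heat semigroup applied to phi
  uheat <- solve_forward(fx_u0(), fx_tables()$Phi_symbol, sigma = 1, kappa = 0,
                         dt = 0.005, T = 0.3, save_stride = 5)
  dual0 <- solve_dual_backward(uheat, tf, 0.3, fx_tables()$Phi_symbol,
                               save_stride = 5)
  w <- tf$width
  tau <- 0.3                              # evolve over t - s = 0.3 at s = 0
  wt <- sqrt(w^2 + 2 * 1 * tau)
  exact <- tf_grid(test_function("gaussian_bump", width = wt,
                                 amplitude = (w^2 / wt^2)^1.5), g)
  relerr <- sqrt(sum((dual0$snaps[[1]] - exact$values)^2) /
                 sum(exact$values^2))
  expect_lt(relerr, 1e-3)
  expect_error(solve_dual_backward(ulim, tf, 0.5, fx_tables()$Phi_symbol),
               "span")
})

test_that("the dual flow is adjoint to the linearized forward flow", {
  g <- fx_grid()
  tab <- fx_tables()
  ulim <- solve_forward(fx_u0(), tab$Phi_symbol, sigma = 1, kappa = 1,
                        dt = 0.005, T = 0.3, save_stride = 5,
                        equation_tag = "limit")
  tf <- test_function("gaussian_bump", width = 1.5, center = c(1, 0, 0))
  dual <- solve_dual_backward(ulim, tf, 0.3, tab$Phi_symbol, save_stride = 5)
  # a smooth mean-zero perturbation transported by the linearized equation
  w0v <- gaussian_field(g, 0.9, center = c(0.5, -0.5, 0))$values -
    gaussian_field(g, 1.1, center = c(-1, 0.5, 0))$values
  w0 <- grid_field(w0v, g)
  lin <- solve_forward_linearized(w0, ulim, tab$Phi_symbol, T = 0.3,
                                  save_stride = 5)
  pair <- vapply(seq_along(lin$times), function(i) {
    j <- which.min(abs(dual$times - lin$times[i]))
    sum(lin$snaps[[i]] * dual$snaps[[j]]) * g$h^3
  }, numeric(1))
  expect_lt(diff(range(pair)) / max(abs(pair)), 1e-4)
})

test_that("time refinement of the transport scheme is second order", {
  u0 <- fx_u0()
  sym <- fx_tables()$V_eta_symbol
  ref <- solve_forward(u0, sym, 1, 1, 0.00125, 0.2, save_stride = 1e6)
  e <- vapply(c(0.01, 0.005), function(dt) {
    s <- solve_forward(u0, sym, 1, 1, dt, 0.2, save_stride = 1e6)
    sqrt(sum((s$snaps[[2]] - ref$snaps[[2]])^2))
  }, numeric(1))
  order <- log2(e[1] / e[2])
  expect_gt(order, 1.8)
})

test_that("lattice translations commute with the solver", {
  g <- fx_grid()
  shift <- 4   # cells along x
  u0 <- gaussian_field(g, 1)
  u0s <- gaussian_field(g, 1, center = c(shift * g$h, 0, 0))
  a <- solve_forward(u0, fx_tables()$V_eta_symbol, 1, 1, 0.005, 0.1)
  b <- solve_forward(u0s, fx_tables()$V_eta_symbol, 1, 1, 0.005, 0.1)
  aT <- a$snaps[[length(a$snaps)]]
  bT <- b$snaps[[length(b$snaps)]]
  idx <- c((g$n - shift + 1):g$n, 1:(g$n - shift))   # roll by +shift cells
  expect_equal(bT, aT[idx, , ], tolerance = 1e-10)
})

test_that("blow-up is flagged and reported, never silent", {
  expect_warning(
    sol <- solve_forward(fx_u0(), fx_tables()$V_eta_symbol, sigma = 1,
                         kappa = 1, dt = 0.005, T = 0.3,
                         blowup_ceiling = 0.05),
    "ceiling")
  expect_true(sol$blowup)
})
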