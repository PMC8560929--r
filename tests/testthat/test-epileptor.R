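test_that("5D vector field matches hand-evaluated piecewise terms", {
  p <- epileptor5d_params(x0 = -3, K = 0, C = matrix(0, 1, 1))
  st <- function(x1 = -1.98, y1 = 1, z = 4, x2 = -0.3, y2 = 0, u = 0)
    list(x1 = x1, y1 = y1, z = z, x2 = x2, y2 = y2, u = u)

  # f1 lower branch at x1 = -1: f1 = (-1)^3 - 3*(-1)^2 = -4
  d <- derivatives_5d(st(x1 = -1, y1 = 1, z = 4), p)
  expect_equal(d$x1, 1 - (-4) - 4 + 3.1)
  # y1 equation at x1 = -1, y1 = 1: 1 - 5 - 1 = -5
  expect_equal(d$y1, -5)

  # f2 zero branch below -0.25, linear branch at 0: 6*(0+0.25) = 1.5
  d_lo <- derivatives_5d(st(x2 = -0.3, y2 = 0), p)
  expect_equal(d_lo$y2, 0 / p$tau2)
  d_hi <- derivatives_5d(st(x2 = 0, y2 = 0), p)
  expect_equal(d_hi$y2, 1.5 / p$tau2)

  # convolution realized as u: du = x1 - gamma*u
  d_u <- derivatives_5d(st(x1 = -2, u = 10), p)
  expect_equal(d_u$u, -2 - 0.01 * 10)

  expect_error(derivatives_5d(st(x1 = Inf), p), "diverged")
})

test_that("2D vector field matches the printed equations", {
  # single node, K = 0: dx = 1+8-8-4+3.1 = 0.1; dz = (4*1 - 4)/20 = 0
  p <- epileptor2d_params(x0 = -3, K = 0, C = matrix(0, 1, 1), tau0 = 20)
  d <- derivatives_2d(-2, 4, p)
  expect_equal(d$x, 0.1)
  expect_equal(d$z, 0)

  # uniform x across regions: coupling term vanishes
  pc <- epileptor2d_params(x0 = rep(-2.5, 3), K = 2,
                           C = tiny_connectome(3)$weights, tau0 = 20)
  d_u <- derivatives_2d(rep(-1.5, 3), c(3, 3.2, 2.9), pc)
  p0 <- epileptor2d_params(x0 = rep(-2.5, 3), K = 0,
                           C = tiny_connectome(3)$weights, tau0 = 20)
  d_0 <- derivatives_2d(rep(-1.5, 3), c(3, 3.2, 2.9), p0)
  expect_equal(d_u$z, d_0$z)

  # at the isolated fixed point both derivatives vanish
  fp <- vepmap:::fixed_point_2d(-3)
  d_fp <- derivatives_2d(fp["x"], fp["z"], p)
  expect_equal(d_fp$x, 0, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(d_fp$z, 0, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(derivatives_2d(NaN, 1, p), "diverged")
})

test_that("two-node coupling contributions are equal and opposite", {
  C <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  p1 <- epileptor2d_params(x0 = c(-2, -2), K = 1.5, C = C, tau0 = 20)
  p0 <- epileptor2d_params(x0 = c(-2, -2), K = 0, C = C, tau0 = 20)
  x <- c(-1.2, -1.9); z <- c(3, 3)
  coup <- derivatives_2d(x, z, p1)$z - derivatives_2d(x, z, p0)$z
  expect_equal(coup[1], -coup[2])
  expect_gt(abs(coup[1]), 0)
})

test_that("Heun integration reproduces the hand-computed step and order", {
  # one step of dy = -y from 1 with dt = 0.1: 1 + 0.05*(-1 - 0.9) = 0.905
  tr <- integrate_heun(function(y) -y, 1, dt = 0.1, duration = 0.1)
  expect_equal(tr$states[2, 1], 0.905)

  # zero vector field: constant trajectory
  tr0 <- integrate_heun(function(y) 0 * y, c(2, -3), dt = 0.5, duration = 5)
  expect_true(all(tr0$states[, 1] == 2), all(tr0$states[, 2] == -3))

  # halving dt reduces the global error ~4x (order 2)
  err <- sapply(c(0.1, 0.05), function(h) {
    tr <- integrate_heun(function(y) -y, 1, dt = h, duration = 1)
    abs(tr$states[nrow(tr$states), 1] - exp(-1))
  })
  expect_equal(err[1] / err[2], 4, tolerance = 0.1)
})

test_that("RK4 integration matches the exponential to its order", {
  tr <- integrate_rk4(function(y) -y, 1, dt = 0.1, n_steps = 1)
  expect_equal(tr$states[2, 1], exp(-0.1), tolerance = 1e-7)

  tr0 <- integrate_rk4(function(y) 0 * y, c(1, 1), dt = 0.5, n_steps = 4)
  expect_true(all(tr0$states == 1))

  # halving dt reduces the global error ~16x (order 4)
  err <- sapply(c(0.2, 0.1), function(h) {
    tr <- integrate_rk4(function(y) -y, 1, dt = h, n_steps = round(1 / h))
    abs(tr$states[nrow(tr$states), 1] - exp(-1))
  })
  expect_equal(err[1] / err[2], 16, tolerance = 1)
})

test_that("integrators are deterministic and flag divergence with the step", {
  dfn <- function(y) c(y[2], -y[1])
  a <- integrate_heun(dfn, c(1, 0), 0.01, 2)
  b <- integrate_heun(dfn, c(1, 0), 0.01, 2)
  expect_identical(a, b)

  err <- tryCatch(integrate_heun(function(y) y^2, 2, 0.5, 10),
                  error = function(e) e)
  expect_match(conditionMessage(err), "diverged at step")
  expect_true(is.numeric(err$step))
})

test_that("compiled RK4 latent kernel agrees with the R-level integrators", {
  n <- 2
  conn <- tiny_connectome(n, seed = 3)
  p <- epileptor2d_params(x0 = c(-2.2, -2.6), K = 1, C = conn$weights,
                          tau0 = 20)
  dfn <- function(y) {
    d <- derivatives_2d(y[1:n], y[(n + 1):(2 * n)], p)
    c(d$x, d$z)
  }
  y0 <- c(-1.8, -2.0, 3.2, 3.4)
  nst <- 200
  tr_r <- integrate_rk4(dfn, y0, dt = 0.1, n_steps = nst)
  theta <- vep_theta(p$x0, y0[1:2], y0[3:4], K = 1, tau0 = 20, alpha = 1,
                     beta = 0, eps1 = 1, eps2 = 1)
  Y <- predict_latent_states(theta, conn, T = nst, dt = 0.1)
  expect_equal(Y$X[, nst], tr_r$states[nst + 1, 1:2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Y$Z[, nst], tr_r$states[nst + 1, 3:4], tolerance = 1e-12,
               ignore_attr = TRUE)

  # Heun at a finer step stays within discretization error of RK4
  tr_h <- integrate_heun(dfn, y0, dt = 1e-3, duration = nst * 0.1)
  expect_equal(tr_h$states[nrow(tr_h$states), ], tr_r$states[nst + 1, ],
               tolerance = 1e-3)
})

test_that("auxiliary state u tracks the exponential convolution of x1", {
  p <- epileptor5d_params(x0 = -3, K = 0, C = matrix(0, 1, 1))
  init <- vepmap:::init_state_5d(1, z_init = 3.5)
  sim <- vepmap:::.heun_5d_cpp(p$C, p$x0, 0, p$tau0, p$tau2, p$I1, p$I2,
                               p$gamma, init, 0.04, 10000L, 5L, 1e3, 0)
  tt <- sim$times
  x1 <- sim$x1[1, ]
  # direct quadrature of int exp(-gamma (t - s)) x1(s) ds with u(0) = 0
  dtr <- diff(tt)[1]
  conv <- stats::filter(c(0, (x1[-1] + x1[-length(x1)]) / 2 * dtr),
                        exp(-p$gamma * dtr), method = "recursive")
  i <- length(tt)
  expect_equal(sim$u[1, i], as.numeric(conv[i]), tolerance = 0.01)
})

test_that("isolated-node seizure threshold brackets the bifurcation", {
  expect_true(vepmap:::isolated_node_seizes(-1.8))
  expect_false(vepmap:::isolated_node_seizes(-3.0))
  xc <- seizure_threshold_2d(c(-3, -1), tol = 1e-3)
  expect_gte(xc, -2.1)
  expect_lte(xc, -2.0)
  # linear-stability oracle: trace of the Jacobian changes sign at x* = -4/3,
  # giving x0c = x* - z*/4 with z* from the x-nullcline
  xs <- -4 / 3
  zs <- 1 - xs^3 - 2 * xs^2 + 3.1
  expect_equal(xc, xs - zs / 4, tolerance = 5e-3)
  # monotone classification on the searched interval
  seiz <- sapply(c(-2.5, -2.2, -2.0, -1.6), vepmap:::isolated_node_seizes)
  expect_identical(seiz, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(seizure_threshold_2d(c(-4, -3)), "bracket")
})
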