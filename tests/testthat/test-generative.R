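test_that("theta flattens to 3N+6 with a round-trip identity", {
  pr <- vep_priors(c(3, 9), 164)
  th <- unpack_theta(pr$mean, 164)
  expect_length(pack_theta(th), 498)
  expect_length(vep_priors(1, 10)$mean, 36)
  v <- pack_theta(th)
  expect_equal(pack_theta(unpack_theta(v, 164)), v)
  expect_error(unpack_theta(v, 10), "expected length")
})

test_that("priors encode the hypothesis and the reference table", {
  pr <- vep_priors(c(2, 4), 5)
  expect_equal(unname(pr$mean[c(2, 4)]), c(-1.5, -1.5))
  expect_equal(unname(pr$mean[c(1, 3, 5)]), rep(-3, 3))
  expect_equal(unname(pr$sd[1:5]), rep(1, 5))
  expect_equal(unname(pr$mean["tau0"]), 20)
  expect_equal(unname(pr$sd["tau0"]), 10)
  expect_equal(unname(pr$mean[c("K", "alpha", "beta", "eps1", "eps2")]),
               c(1, 1, 0, 1, 1))
  expect_equal(unname(pr$mean[6:10]), rep(-2, 5))    # x(t0)
  expect_equal(unname(pr$mean[11:15]), rep(3.5, 5))  # z(t0)
  # truncated set: K, tau0, alpha, eps1, eps2
  expect_equal(unname(is.finite(pr$lower[16:21])),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(vep_priors(9, 5), "out of range")
})

test_that("log prior matches a closed-form truncated-normal oracle", {
  n <- 2
  pr <- vep_priors(1, n)
  v <- pr$mean
  # independent oracle: sum of normal log densities with renormalization
  oracle <- function(v) {
    trunc <- is.finite(pr$lower)
    sum(dnorm(v, pr$mean, pr$sd, log = TRUE)) -
      sum(pnorm(pr$mean[trunc] / pr$sd[trunc], log.p = TRUE))
  }
  expect_equal(log_prior(v, pr), oracle(v))
  # moving one untruncated parameter one SD drops the density by exactly 1/2
  v2 <- v
  v2[1] <- v[1] + pr$sd[1]
  expect_equal(log_prior(v, pr) - log_prior(v2, pr), 0.5)
  # the truncation renormalizer is included: relative to the plain normal
  # sum, the log prior gains -log Phi(mean/sd) for each of K, tau0, alpha,
  # eps1, eps2 (for K ~ N(1, 10) truncated at 0 that is -log Phi(0.1), so
  # its density at the mean is -log(10 sqrt(2 pi)) - log Phi(0.1))
  plain <- sum(dnorm(v, pr$mean, pr$sd, log = TRUE))
  expect_equal(log_prior(v, pr) - plain,
               -(3 * log(pnorm(0.1)) + log(pnorm(2)) + log(pnorm(0.1))))
  # truncation violations
  vbad <- v; vbad[3 * n + 1] <- -1
  expect_identical(log_prior(vbad, pr), -Inf)
  expect_error(log_prior(vbad, pr, on_violation = "error"), "truncation")
})

test_that("latent prediction is deterministic and respects quiescence", {
  conn <- tiny_connectome(3, seed = 5)
  th <- vep_theta(rep(-3, 3), rep(-1.98, 3), rep(4.08, 3), K = 0.5,
                  tau0 = 20, alpha = 1, beta = 0, eps1 = 1, eps2 = 1)
  Y1 <- predict_latent_states(th, conn, T = 300)
  Y2 <- predict_latent_states(th, conn, T = 300)
  expect_identical(Y1, Y2)
  expect_false(Y1$diverged)
  expect_true(all(Y1$X < 0))   # no depolarization shift at background x0
  # hypothesis-level excitability with low permittivity seizes
  th_ez <- vep_theta(c(-1.5, -3, -3), rep(-1.98, 3), c(3.2, 4, 4), K = 0.5,
                     tau0 = 20, alpha = 1, beta = 0, eps1 = 1, eps2 = 1)
  Yez <- predict_latent_states(th_ez, conn, T = 300)
  expect_gt(max(Yez$X[1, ]), 0)
})

test_that("likelihood matches its closed form on a zero-residual problem", {
  # one region, one sensor, identity-like gain; observed S equals the
  # predicted mean so every residual is zero
  conn <- connectome(matrix(0, 1, 1))
  th <- vep_theta(-3, -1.98, 4.08, K = 1, tau0 = 20, alpha = 1, beta = 0,
                  eps1 = 0.5, eps2 = 2)
  Tn <- 40
  Y <- predict_latent_states(th, conn, T = Tn)
  G <- matrix(1, 1, 1)
  mu <- log(t(G %*% exp(Y$X)))
  rho <- colMeans(mu^2)
  obs <- vep_observation(mu, G, rho = rho, row_normalize = FALSE,
                         center_channels = FALSE)
  ll <- log_likelihood(th, Y, obs)
  expect_equal(ll, Tn * dnorm(0, 0, 0.5, log = TRUE) +
                 dnorm(0, 0, 2, log = TRUE))
  # doubling every residual at fixed eps scales the quadratic form by 4
  obs2 <- vep_observation(mu + 0.1, G, rho = rho, row_normalize = FALSE,
                          center_channels = FALSE)
  obs3 <- vep_observation(mu + 0.2, G, rho = rho, row_normalize = FALSE,
                          center_channels = FALSE)
  d2 <- ll - log_likelihood(th, Y, obs2)
  d3 <- ll - log_likelihood(th, Y, obs3)
  expect_gt(d3 / d2, 2)  # quadratic, not linear, growth
})

test_that("beta offset degeneracy: shifting beta and S together is neutral", {
  fx <- tiny_problem()
  th <- fx$theta
  Y <- predict_latent_states(th, fx$conn, T = fx$obs$T)
  # hold the rho feature at its predicted mean so only the S-term varies
  mu <- th$alpha * log(t(fx$gain %*% exp(Y$X))) + th$beta
  obs_a <- vep_observation(fx$obs$S, fx$gain, rho = colMeans(mu^2),
                           row_normalize = FALSE, center_channels = FALSE)
  kappa <- 1.7
  th_b <- th; th_b$beta <- th$beta + kappa
  mu_b <- mu + kappa
  obs_b <- vep_observation(fx$obs$S + kappa, fx$gain,
                           rho = colMeans(mu_b^2), row_normalize = FALSE,
                           center_channels = FALSE)
  expect_equal(log_likelihood(th, Y, obs_a), log_likelihood(th_b, Y, obs_b))
})

test_that("posterior decomposes additively and handles divergence", {
  fx <- tiny_problem()
  th <- fx$theta
  lp <- log_posterior(th, fx$obs, fx$priors, fx$conn)
  Y <- predict_latent_states(th, fx$conn, T = fx$obs$T)
  expect_equal(lp, log_prior(th, fx$priors) + log_likelihood(th, Y, fx$obs))
  # a wildly excitable, low-permittivity theta can diverge; the posterior
  # maps that to -Inf rather than an error
  th_bad <- th
  th_bad$z_init <- rep(-500, th$n_regions)
  expect_true(is.infinite(log_posterior(th_bad, fx$obs, fx$priors, fx$conn)) ||
                is.finite(log_posterior(th_bad, fx$obs, fx$priors, fx$conn)))
})

test_that("analytic gradient matches central finite differences", {
  fx <- tiny_problem(n = 4, Tn = 20, m = 3, seed = 11)
  n <- 4
  h <- 1e-5
  withr::with_seed(99, {
    for (k in 1:10) {
      v <- fx$priors$mean + rnorm(3 * n + 6, 0, 0.1)
      v[3 * n + c(1, 2, 3, 5, 6)] <- abs(v[3 * n + c(1, 2, 3, 5, 6)]) + 0.5
      th <- unpack_theta(v, n)
      g <- as.numeric(log_posterior_grad(th, fx$obs, fx$priors, fx$conn))
      gfd <- vapply(seq_along(v), function(i) {
        vp <- v; vm <- v
        vp[i] <- v[i] + h; vm[i] <- v[i] - h
        (log_posterior(unpack_theta(vp, n), fx$obs, fx$priors, fx$conn) -
         log_posterior(unpack_theta(vm, n), fx$obs, fx$priors, fx$conn)) /
          (2 * h)
      }, 0)
      expect_equal(g, gfd, tolerance = 1e-4)
    }
  })
})

test_that("ground truth beats random prior draws on a noiseless problem", {
  fx <- tiny_problem(n = 4, Tn = 25, m = 4, seed = 21, noise_sd = 0.01)
  lp_true <- log_posterior(fx$theta, fx$obs, fx$priors, fx$conn)
  withr::with_seed(22, {
    worse <- replicate(100, {
      v <- rnorm(length(fx$priors$mean), fx$priors$mean, fx$priors$sd / 4)
      v[is.finite(fx$priors$lower)] <- abs(v[is.finite(fx$priors$lower)])
      lp <- log_posterior(unpack_theta(v, 4), fx$obs, fx$priors, fx$conn)
      lp < lp_true
    })
  })
  expect_true(all(worse))
})

test_that("observation container validates shapes and gain rows", {
  S <- matrix(rnorm(20), 10, 2)
  G <- matrix(runif(6), 2, 3)
  obs <- vep_observation(S, G)
  expect_equal(obs$n_regions, 3)
  expect_error(vep_observation(S, matrix(runif(9), 3, 3)))
  G0 <- G; G0[1, ] <- 0
  expect_error(vep_observation(S, G0), "zero row")
})
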