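#' Model parameter vector
#'
#' Collects all free parameters of the generative model: per-region
#' excitability `x0`, initial latent source states `x_init`/`z_init`, global
#' coupling `K`, latent timescale `tau0`, observation scaling `alpha` and
#' offset `beta`, and the observation noise SDs `eps1` (log power) and
#' `eps2` (total power). For N regions the flattened vector has length
#' 3N + 6 (498 for the 164-region Destrieux parcellation).
#'
#' @param x0,x_init,z_init length-N numeric vectors.
#' @param K,tau0 positive scalars.
#' @param alpha,beta scalars.
#' @param eps1,eps2 positive scalars.
#' @return an object of class `"vep_theta"`.
#' @export
vep_theta <- function(x0, x_init, z_init, K, tau0, alpha, beta, eps1, eps2) {
  n <- length(x0)
  stopifnot(length(x_init) == n, length(z_init) == n,
            K > 0, tau0 > 0, eps1 > 0, eps2 > 0)
  structure(list(x0 = as.numeric(x0), x_init = as.numeric(x_init),
                 z_init = as.numeric(z_init), K = K, tau0 = tau0,
                 alpha = alpha, beta = beta, eps1 = eps1, eps2 = eps2,
                 n_regions = n),
            class = "vep_theta")
}

#' @export
print.vep_theta <- function(x, ...) {
  cat(sprintf(paste0("vep_theta: %d regions (length %d); K=%.3g tau0=%.3g ",
                     "alpha=%.3g beta=%.3g eps1=%.3g eps2=%.3g\n"),
              x$n_regions, 3 * x$n_regions + 6, x$K, x$tau0, x$alpha,
              x$beta, x$eps1, x$eps2))
  cat(sprintf("  x0 in [%.2f, %.2f]; top regions by x0: %s\n",
              min(x$x0), max(x$x0),
              paste(order(x$x0, decreasing = TRUE)[1:min(4, x$n_regions)],
                    collapse = ", ")))
  invisible(x)
}

#' Flatten / restore the parameter vector
#'
#' Fixed ordering: `x0` block, `x_init` block, `z_init` block, then the
#' scalars `K, tau0, alpha, beta, eps1, eps2`.
#'
#' @param theta a [vep_theta()].
#' @return numeric vector of length `3 * n_regions + 6`.
#' @export
pack_theta <- function(theta) {
  c(theta$x0, theta$x_init, theta$z_init, theta$K, theta$tau0,
    theta$alpha, theta$beta, theta$eps1, theta$eps2)
}

#' @rdname pack_theta
#' @param v flat numeric vector of length `3 * n_regions + 6`.
#' @param n_regions number of regions N.
#' @export
unpack_theta <- function(v, n_regions) {
  if (length(v) != 3 * n_regions + 6)
    stop(sprintf("expected length %d, got %d", 3 * n_regions + 6, length(v)))
  n <- n_regions
  vep_theta(x0 = v[1:n], x_init = v[(n + 1):(2 * n)],
            z_init = v[(2 * n + 1):(3 * n)],
            K = v[3 * n + 1], tau0 = v[3 * n + 2], alpha = v[3 * n + 3],
            beta = v[3 * n + 4], eps1 = v[3 * n + 5], eps2 = v[3 * n + 6])
}

#' Hypothesis-conditioned priors
#'
#' All priors are normal, truncated below at zero for the structurally
#' positive parameters (`K`, `tau0`, `alpha`, `eps1`, `eps2`; the amplitude
#' scaling `alpha` maps source log power to observed log power and a negative
#' value would be an unphysical polarity inversion). The clinical EZ
#' hypothesis enters as a weakly informative prior on excitability:
#' `N(-1.5, 1)` for hypothesis regions (above the isolated-node seizure
#' threshold), `N(-3.0, 1)` otherwise. Remaining means/SDs: `K ~ N(1, 10)`,
#' `tau0 ~ N(20, 10)`, `x(t0) ~ N(-2, 10)`, `z(t0) ~ N(3.5, 10)`,
#' `alpha ~ N(1, 10)`, `beta ~ N(0, 10)`, `eps1 ~ N(1, 10)`,
#' `eps2 ~ N(1, 10)`.
#'
#' @param hypothesis integer indices of the clinically hypothesized EZ.
#' @param n_regions number of regions N.
#' @return an object of class `"vep_priors"`: list with packed `mean`, `sd`,
#'   `lower` (0 for truncated parameters, -Inf otherwise), `hypothesis`,
#'   `n_regions`.
#' @export
vep_priors <- function(hypothesis, n_regions) {
  hypothesis <- as.integer(hypothesis)
  if (length(hypothesis) &&
      (min(hypothesis) < 1 || max(hypothesis) > n_regions))
    stop("hypothesis region index out of range")
  n <- n_regions
  x0_mean <- rep(-3.0, n)
  x0_mean[hypothesis] <- -1.5
  mean <- c(x0_mean, rep(-2.0, n), rep(3.5, n), 1, 20, 1, 0, 1, 1)
  sd <- c(rep(1, n), rep(10, n), rep(10, n), 10, 10, 10, 10, 10, 10)
  lower <- c(rep(-Inf, 3 * n), 0, 0, 0, -Inf, 0, 0)
  names(mean) <- names(sd) <- names(lower) <- packed_names(n)
  structure(list(mean = mean, sd = sd, lower = lower,
                 hypothesis = hypothesis, n_regions = n),
            class = "vep_priors")
}

packed_names <- function(n) {
  c(sprintf("x0[%d]", 1:n), sprintf("x_init[%d]", 1:n),
    sprintf("z_init[%d]", 1:n), "K", "tau0", "alpha", "beta", "eps1", "eps2")
}

#' @export
print.vep_priors <- function(x, ...) {
  cat(sprintf("vep_priors: %d regions, hypothesis = {%s}\n", x$n_regions,
              paste(x$hypothesis, collapse = ", ")))
  invisible(x)
}

#' Log prior density
#'
#' Sum of per-parameter (truncated) normal log densities; truncated terms
#' include the renormalization constant `-log P(X > 0)`.
#'
#' @param theta a [vep_theta()] or packed numeric vector.
#' @param priors a [vep_priors()].
#' @param on_violation `"neg_inf"` (default) returns `-Inf` when a truncated
#'   parameter is non-positive; `"error"` raises an error.
#' @return scalar log density.
#' @export
log_prior <- function(theta, priors, on_violation = c("neg_inf", "error")) {
  on_violation <- match.arg(on_violation)
  v <- if (inherits(theta, "vep_theta")) pack_theta(theta) else theta
  stopifnot(length(v) == length(priors$mean))
  if (any(v <= priors$lower)) {
    if (on_violation == "error") stop("parameter violates truncation bound")
    return(-Inf)
  }
  trunc <- is.finite(priors$lower)
  ll <- sum(stats::dnorm(v, priors$mean, priors$sd, log = TRUE))
  # renormalization: P(X > 0) = pnorm(mean / sd) for lower truncation at 0
  ll - sum(stats::pnorm(priors$mean[trunc] / priors$sd[trunc],
                        log.p = TRUE))
}

grad_log_prior <- function(v, priors) {
  -(v - priors$mean) / priors$sd^2
}

#' Predict latent source states
#'
#' Deterministic latent trajectory of the coupled 2D Epileptor under the
#' parameters `theta`: starting from `(x_init, z_init)` at `t0`, each of the
#' `T` observation instants advances the state by `nsub` classical RK4 steps
#' of size `dt`. The latent matrix holds the states at `t_1 .. t_T`; the
#' initial state is a model parameter, not part of the trajectory.
#'
#' @param theta a [vep_theta()].
#' @param conn a [connectome()] (or plain N x N matrix).
#' @param T number of observation instants (default 300).
#' @param dt RK4 step size (default 0.1).
#' @param nsub RK4 substeps per observation interval (default 1).
#' @param bound divergence guard on state magnitude (default 1e3).
#' @param I1 drive constant (default 3.1).
#' @return an object of class `"latent_trajectory"`: list with `X`, `Z`
#'   (N x T matrices), `diverged` flag and failing `step`.
#' @export
predict_latent_states <- function(theta, conn, T = 300, dt = 0.1, nsub = 1,
                                  bound = 1e3, I1 = 3.1) {
  W <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  stopifnot(T >= 1, nrow(W) == theta$n_regions)
  out <- .latent_rk4_cpp(W, theta$x0, theta$K, theta$tau0, I1,
                         theta$x_init, theta$z_init, dt, as.integer(nsub),
                         as.integer(T), bound)
  structure(list(X = out$X, Z = out$Z, diverged = out$diverged,
                 step = out$step, dt = dt, nsub = nsub),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("latent_trajectory: %d regions x %d instants%s\n",
              nrow(x$X), ncol(x$X),
              if (x$diverged) sprintf(" (diverged at step %d)", x$step) else ""))
  invisible(x)
}

#' Observation container
#'
#' Pairs the extracted data features with the gain matrix they were (or are
#' modelled to be) generated through.
#'
#' @param features a [data_features()][extract_log_power()] object, or a
#'   plain T x M log-power matrix.
#' @param gain M x N gain matrix.
#' @param rho optional length-M total-power vector (recomputed when missing).
#' @param row_normalize divide each gain row by its sum (default `TRUE`).
#'   The observation mean carries a single global offset `beta`, so
#'   per-channel gain scale differences are not representable; row
#'   normalization removes them (within-row relative weights, which carry the
#'   source-attribution information, are unchanged).
#' @param center_channels subtract each channel's median log power (default
#'   `TRUE`), i.e. fit baseline-corrected log power. Channel baselines are
#'   set by background activity mixing incoherently at the sensor, which the
#'   coherent source-projection mean cannot represent; leaving them in biases
#'   the fit toward tonically active spurious sources. `rho` is recomputed
#'   from the centered matrix.
#' @return an object of class `"vep_observation"`.
#' @export
vep_observation <- function(features, gain, rho = NULL, row_normalize = TRUE,
                            center_channels = TRUE) {
  S <- if (inherits(features, "data_features")) features$S else as.matrix(features)
  times <- if (inherits(features, "data_features")) features$times
           else seq_len(nrow(S))
  if (center_channels) {
    S <- sweep(S, 2, apply(S, 2, stats::median))
    rho <- total_sensor_power(S)
  }
  if (is.null(rho))
    rho <- if (inherits(features, "data_features")) features$rho
           else total_sensor_power(S)
  stopifnot(ncol(S) == nrow(gain), length(rho) == ncol(S))
  if (any(rowSums(gain) <= 0))
    stop("gain matrix has a zero row: sensor sees no source")
  if (row_normalize) gain <- gain / rowSums(gain)
  structure(list(S = S, rho = rho, gain = gain, times = times,
                 n_sensors = ncol(S), n_regions = ncol(gain),
                 T = nrow(S)),
            class = "vep_observation")
}

#' Log likelihood of the observed features
#'
#' Gaussian observation model: each log-power sample has mean
#' `alpha * log(<G_i, exp(x(t_j))>) + beta` and SD `eps1`; each channel's
#' observed total power has mean equal to the second sample moment of that
#' channel's *model-predicted* log power and SD `eps2`. (Conditioning the
#' total-power mean on the observed log power instead would make the residual
#' identically zero and the posterior unbounded in `eps2`; the model-predicted
#' moment is also what the reference workflow displays as the fitted augmented
#' feature.)
#'
#' @param theta a [vep_theta()].
#' @param Y a [predict_latent_states()] trajectory.
#' @param obs a [vep_observation()].
#' @return scalar log likelihood (`-Inf` if the trajectory diverged).
#' @export
log_likelihood <- function(theta, Y, obs) {
  if (Y$diverged) return(-Inf)
  stopifnot(ncol(Y$X) == obs$T)
  P <- exp_projection(Y$X, obs$gain)           # T x M, <G_i, e^x(tj)>
  mu <- theta$alpha * log(P) + theta$beta
  ll_s <- sum(stats::dnorm(obs$S, mu, theta$eps1, log = TRUE))
  mu_rho <- colMeans(mu^2)
  ll_rho <- sum(stats::dnorm(obs$rho, mu_rho, theta$eps2, log = TRUE))
  ll_s + ll_rho
}

# t(G %*% exp(X)): T x M matrix of projected exponentiated sources
exp_projection <- function(X, gain) {
  E <- exp(X)
  t(gain %*% E)
}

#' Unnormalized log posterior
#'
#' `log_prior(theta) + log_likelihood(theta, predict_latent_states(theta))`.
#' Latent-state integration divergence maps to `-Inf`.
#'
#' @inheritParams log_likelihood
#' @param priors a [vep_priors()].
#' @param conn a [connectome()] or N x N matrix.
#' @param dt,nsub,bound latent integration settings
#'   (see [predict_latent_states()]).
#' @return scalar unnormalized log posterior.
#' @export
log_posterior <- function(theta, obs, priors, conn, dt = 0.1, nsub = 1,
                          bound = 1e3) {
  lp <- log_prior(theta, priors)
  if (!is.finite(lp)) return(-Inf)
  Y <- predict_latent_states(theta, conn, T = obs$T, dt = dt, nsub = nsub,
                             bound = bound)
  lp + log_likelihood(theta, Y, obs)
}

#' Gradient of the unnormalized log posterior
#'
#' Exact gradient in the natural parameter space, combining the closed-form
#' likelihood derivatives with a discrete adjoint of the RK4 latent
#' integration (so the gradient is that of the actually computed objective,
#' not of the continuous-time ideal).
#'
#' @inheritParams log_posterior
#' @return numeric gradient of length `3 * n_regions + 6`, in
#'   [pack_theta()] order. Attribute `"log_posterior"` carries the value.
#' @export
log_posterior_grad <- function(theta, obs, priors, conn, dt = 0.1, nsub = 1,
                               bound = 1e3) {
  W <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  n <- theta$n_regions
  Y <- predict_latent_states(theta, W, T = obs$T, dt = dt, nsub = nsub,
                             bound = bound)
  if (Y$diverged) {
    g <- rep(NA_real_, 3 * n + 6)
    attr(g, "log_posterior") <- -Inf
    return(g)
  }
  G <- obs$gain
  E <- exp(Y$X)                              # N x T
  P <- t(G %*% E)                            # T x M
  mu <- theta$alpha * log(P) + theta$beta
  R <- (obs$S - mu) / theta$eps1^2           # T x M residual / eps1^2
  ll_s <- sum(stats::dnorm(obs$S, mu, theta$eps1, log = TRUE))
  mu_rho <- colMeans(mu^2)                   # predicted second moment
  r_rho <- (obs$rho - mu_rho) / theta$eps2^2 # length M
  ll_rho <- sum(stats::dnorm(obs$rho, mu_rho, theta$eps2, log = TRUE))
  # total sensitivity to the predicted mean mu: S-term plus rho-term
  Tn <- nrow(obs$S)
  dLdmu <- R + (2 / Tn) * sweep(mu, 2, r_rho, "*")
  # direct parameter derivatives of the likelihood
  g_alpha <- sum(dLdmu * log(P))
  g_beta <- sum(dLdmu)
  g_eps1 <- sum((obs$S - mu)^2) / theta$eps1^3 - length(obs$S) / theta$eps1
  g_eps2 <- sum((obs$rho - mu_rho)^2) / theta$eps2^3 -
    length(obs$rho) / theta$eps2
  # gradient w.r.t. latent x: dL/dX = (G^T (alpha * dLdmu / P)^T) * E
  dLdP <- theta$alpha * dLdmu / P            # T x M
  dLdX <- (t(G) %*% t(dLdP)) * E             # N x T
  adj <- .latent_adjoint_cpp(W, theta$x0, theta$K, theta$tau0, 3.1,
                             theta$x_init, theta$z_init, dt,
                             as.integer(nsub), Y$X, Y$Z, dLdX)
  v <- pack_theta(theta)
  g <- grad_log_prior(v, priors)
  g[1:n] <- g[1:n] + adj$x0
  g[(n + 1):(2 * n)] <- g[(n + 1):(2 * n)] + adj$x_init
  g[(2 * n + 1):(3 * n)] <- g[(2 * n + 1):(3 * n)] + adj$z_init
  g[3 * n + 1] <- g[3 * n + 1] + adj$K
  g[3 * n + 2] <- g[3 * n + 2] + adj$tau0
  g[3 * n + 3] <- g[3 * n + 3] + g_alpha
  g[3 * n + 4] <- g[3 * n + 4] + g_beta
  g[3 * n + 5] <- g[3 * n + 5] + g_eps1
  g[3 * n + 6] <- g[3 * n + 6] + g_eps2
  attr(g, "log_posterior") <- log_prior(theta, priors) + ll_s + ll_rho
  g
}
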