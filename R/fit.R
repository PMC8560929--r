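#' Fit the seizure-propagation model by MAP optimization
#'
#' Maximizes the unnormalized log posterior of the generative model with
#' L-BFGS (via [stats::optim()]'s `"L-BFGS-B"` with analytic gradients).
#' The structurally positive parameters (`K`, `tau0`, `alpha`, `eps1`,
#' `eps2`) are
#' optimized through a log transform so the optimizer works on an
#' unconstrained space; no Jacobian adjustment is applied, so the optimum is
#' the mode of the natural-space posterior density (the usual MAP semantics
#' of probabilistic-programming optimizers). Latent-state integration
#' divergence during the line search is absorbed as a large finite barrier so
#' the search backtracks.
#'
#' Convergence is monitored on three criteria: change in unnormalized log
#' posterior below `tol_density` (1e-12), Euclidean gradient norm below
#' `tol_grad` (1e-8), or maximum absolute parameter change below `tol_param`
#' (1e-8).
#'
#' @param obs a [vep_observation()].
#' @param conn a [connectome()] or N x N coupling matrix.
#' @param hypothesis integer indices of the clinical EZ hypothesis (used to
#'   build default priors).
#' @param priors a [vep_priors()]; defaults to
#'   `vep_priors(hypothesis, n_regions)`.
#' @param init `"prior-means"` (default), a [vep_theta()], or a packed
#'   numeric vector.
#' @param dt,nsub latent RK4 step size and substeps per observation interval.
#' @param maxit iteration cap (default 20000).
#' @param lmm L-BFGS memory (default 10).
#' @param fixed optional named numeric vector holding scalar parameters
#'   (`K`, `tau0`, `alpha`, `beta`, `eps1`, `eps2`) at fixed values,
#'   excluding them from optimization (e.g. huge `eps1`/`eps2` flatten the
#'   likelihood, reducing the MAP problem to the prior mode).
#' @param tol_density,tol_grad,tol_param convergence thresholds.
#' @param bound divergence guard on latent state magnitude.
#' @return an object of class `"vep_fit"` with components `theta` (the MAP
#'   estimate, a [vep_theta()]), `log_posterior`, `log_prior`,
#'   `log_likelihood`, `latent` (trajectory at the mode), `converged`,
#'   `convergence_flags` (density/gradient/parameter), `iterations`, `trace`
#'   (best objective values), plus the inputs needed by the methods.
#' @seealso [vep_multistart()], [propagation_report()], [predict.vep_fit()]
#' @export
vep_fit <- function(obs, conn, hypothesis = integer(0),
                    priors = vep_priors(hypothesis, n_regions),
                    init = "prior-means", dt = 0.1, nsub = 1,
                    maxit = 20000, lmm = 10, fixed = NULL,
                    tol_density = 1e-12, tol_grad = 1e-8, tol_param = 1e-8,
                    bound = 1e3) {
  W <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  n_regions <- ncol(W)
  stopifnot(obs$n_regions == n_regions)
  n <- n_regions
  idx_pos <- 3 * n + c(1, 2, 3, 5, 6)

  to_phi <- function(v) { v[idx_pos] <- log(v[idx_pos]); v }
  to_theta_vec <- function(phi) { phi[idx_pos] <- exp(phi[idx_pos]); phi }

  scalar_slots <- c(K = 1, tau0 = 2, alpha = 3, beta = 4, eps1 = 5, eps2 = 6)
  idx_fixed <- integer(0)
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% names(scalar_slots)))
    idx_fixed <- 3 * n + scalar_slots[names(fixed)]
  }
  apply_fixed <- function(v) { v[idx_fixed] <- fixed; v }

  v0 <- if (identical(init, "prior-means")) priors$mean
        else if (inherits(init, "vep_theta")) pack_theta(init)
        else as.numeric(init)
  stopifnot(length(v0) == 3 * n + 6)
  v0 <- apply_fixed(v0)
  if (any(v0[idx_pos] <= 0))
    stop("initial value violates a positivity constraint")
  phi0 <- to_phi(v0)

  barrier <- 1e10
  cache <- new.env(parent = emptyenv())
  evaluate <- function(phi) {
    key <- paste(phi, collapse = ",")
    if (identical(cache$key, key)) return(cache$res)
    v <- apply_fixed(to_theta_vec(phi))
    if (any(!is.finite(v)) || any(v[idx_pos] <= 0)) {
      res <- list(value = barrier, grad = rep(0, length(phi)), lp = -Inf)
      cache$key <- key
      cache$res <- res
      return(res)
    }
    theta <- unpack_theta(v, n)
    g <- log_posterior_grad(theta, obs, priors, W, dt = dt, nsub = nsub,
                            bound = bound)
    lp <- attr(g, "log_posterior")
    if (!is.finite(lp)) {
      res <- list(value = barrier, grad = rep(0, length(phi)), lp = -Inf)
    } else {
      # negative log posterior; chain rule through the log reparameterization
      gphi <- as.numeric(g)
      gphi[idx_pos] <- gphi[idx_pos] * v[idx_pos]
      gphi[idx_fixed] <- 0
      res <- list(value = -lp, grad = -gphi, lp = lp)
    }
    cache$key <- key
    cache$res <- res
    res
  }

  trace_env <- new.env(parent = emptyenv())
  trace_env$values <- numeric(0)
  trace_env$pars <- list()
  fn <- function(phi) {
    r <- evaluate(phi)
    if (r$value < suppressWarnings(min(trace_env$values, Inf))) {
      trace_env$values <- c(trace_env$values, r$value)
      trace_env$pars <- c(trace_env$pars, list(phi))
    }
    r$value
  }
  gr <- function(phi) evaluate(phi)$grad

  r0 <- evaluate(phi0)
  if (!is.finite(r0$lp))
    stop("latent integration diverges at the initial point; choose a different init")

  opt <- stats::optim(phi0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, lmm = lmm,
                                     factr = 10, pgtol = tol_grad))
  phi_hat <- opt$par
  rhat <- evaluate(phi_hat)
  theta_hat <- unpack_theta(apply_fixed(to_theta_vec(phi_hat)), n)
  Y <- predict_latent_states(theta_hat, W, T = obs$T, dt = dt, nsub = nsub,
                             bound = bound)
  llik <- log_likelihood(theta_hat, Y, obs)
  lpri <- log_prior(theta_hat, priors)

  vals <- trace_env$values
  nv <- length(vals)
  flag_density <- nv >= 2 && abs(vals[nv] - vals[nv - 1]) < tol_density
  flag_grad <- sqrt(sum(rhat$grad^2)) < tol_grad
  flag_param <- nv >= 2 &&
    max(abs(trace_env$pars[[nv]] - trace_env$pars[[nv - 1]])) < tol_param
  converged <- opt$convergence == 0 || flag_density || flag_grad || flag_param

  structure(list(
    theta = theta_hat,
    log_posterior = rhat$lp,
    log_prior = lpri,
    log_likelihood = llik,
    latent = Y,
    converged = converged,
    convergence_flags = c(density = flag_density, gradient = flag_grad,
                          parameter = flag_param),
    iterations = opt$counts[["function"]],
    trace = -vals,
    optim = list(convergence = opt$convergence, message = opt$message),
    obs = obs, conn = W, priors = priors, dt = dt, nsub = nsub,
    init = v0, call = match.call()),
    class = "vep_fit")
}

#' Multi-start MAP estimation
#'
#' Draws `n_starts` initial parameter vectors from normal proposals centered
#' at the prior means with a common SD (truncated parameters redrawn until
#' positive), runs [vep_fit()] from each, and returns the run with the
#' highest final log posterior. Runs whose initial point diverges are
#' recorded and skipped.
#'
#' @inheritParams vep_fit
#' @param proposal_sd SD of the normal proposal around the prior means
#'   (> 0); as it tends to zero the procedure reduces to a prior-mean start.
#' @param n_starts number of starts (default 10).
#' @param seed integer seed for the proposal draws.
#' @return the best `"vep_fit"`, with extra fields `starts` (per-start log
#'   posterior, `NA` for diverged runs) and `n_diverged`.
#' @export
vep_multistart <- function(obs, conn, hypothesis = integer(0),
                           priors = vep_priors(hypothesis, obs$n_regions),
                           proposal_sd = 0.1, n_starts = 10, seed = 1, ...) {
  stopifnot(proposal_sd > 0, n_starts >= 1)
  local_rng(seed)
  trunc <- is.finite(priors$lower)
  draws <- lapply(seq_len(n_starts), function(s) {
    v <- stats::rnorm(length(priors$mean), priors$mean, proposal_sd)
    for (i in which(trunc)) {
      tries <- 0
      while (v[i] <= 0 && tries < 1000) {
        v[i] <- stats::rnorm(1, priors$mean[i], proposal_sd)
        tries <- tries + 1
      }
      if (v[i] <= 0) v[i] <- priors$mean[i]
    }
    v
  })
  fits <- vector("list", n_starts)
  lps <- rep(NA_real_, n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      vep_fit(obs, conn, priors = priors, init = draws[[s]], ...),
      error = function(e) NULL)
    if (!is.null(fits[[s]])) lps[s] <- fits[[s]]$log_posterior
  }
  if (all(is.na(lps))) stop("all starts diverged")
  best <- which.max(lps)
  fit <- fits[[best]]
  fit$starts <- lps
  fit$n_diverged <- sum(is.na(lps))
  fit$best_start <- best
  fit
}
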