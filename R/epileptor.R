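#' Parameters of the coupled 5D Epileptor network
#'
#' The Epileptor is a phenomenological neural-mass model of seizure dynamics
#' with five state variables per brain region: a fast oscillatory pair
#' (`x1`, `y1`) producing ictal fast discharges, an intermediate pair
#' (`x2`, `y2`) producing spike-and-wave activity, and a slow "permittivity"
#' variable `z` that gates the interictal/ictal transition. Regions are
#' coupled on a structural connectome through the permittivity equation.
#' The low-pass convolution term acting on the intermediate subsystem is
#' realized as a sixth auxiliary state `u` with `du/dt = x1 - gamma * u`,
#' entering the `x2` equation as `0.002 * u`.
#'
#' @param x0 numeric vector of per-region excitability values. An isolated
#'   node seizes autonomously when `x0` exceeds roughly -2.06.
#' @param K global coupling scalar (>= 0).
#' @param C connectome coupling matrix (N x N, nonnegative, zero diagonal).
#' @param tau0 slow timescale of the permittivity variable (default 2857).
#' @param tau2 timescale of the intermediate subsystem (default 10).
#' @param I1,I2 constant drives of the fast and intermediate subsystems
#'   (defaults 3.1 and 0.45).
#' @param gamma decay rate of the convolution kernel (default 0.01).
#' @return an object of class `"epileptor5d_params"`.
#' @seealso [derivatives_5d()], [epileptor2d_params()]
#' @export
epileptor5d_params <- function(x0, K, C, tau0 = 2857, tau2 = 10,
                               I1 = 3.1, I2 = 0.45, gamma = 0.01) {
  C <- as.matrix(C)
  n <- length(x0)
  stopifnot(n >= 1, all(is.finite(x0)), tau0 > 0, tau2 > 0, gamma > 0,
            K >= 0, nrow(C) == n, ncol(C) == n)
  if (any(C < 0)) stop("connectome weights must be nonnegative")
  if (any(diag(C) != 0)) stop("connectome must have a zero diagonal")
  structure(list(x0 = as.numeric(x0), K = K, C = C, tau0 = tau0,
                 tau2 = tau2, I1 = I1, I2 = I2, gamma = gamma,
                 n_regions = n),
            class = "epileptor5d_params")
}

#' Parameters of the coupled 2D Epileptor reduction
#'
#' Two-variable reduction of the Epileptor retaining the fast variable `x`
#' (a proxy for source log power) and the slow permittivity `z`; this is the
#' latent dynamical prior used for inference.
#'
#' @param x0 per-region excitability vector.
#' @param K global coupling scalar.
#' @param C connectome matrix (N x N, nonnegative, zero diagonal).
#' @param tau0 slow timescale (default 20, the prior mean used in fitting).
#' @param I1 constant drive (default 3.1).
#' @return an object of class `"epileptor2d_params"`.
#' @export
epileptor2d_params <- function(x0, K, C, tau0 = 20, I1 = 3.1) {
  C <- as.matrix(C)
  n <- length(x0)
  stopifnot(n >= 1, all(is.finite(x0)), tau0 > 0, K >= 0,
            nrow(C) == n, ncol(C) == n)
  if (any(C < 0)) stop("connectome weights must be nonnegative")
  if (any(diag(C) != 0)) stop("connectome must have a zero diagonal")
  structure(list(x0 = as.numeric(x0), K = K, C = C, tau0 = tau0, I1 = I1,
                 n_regions = n),
            class = "epileptor2d_params")
}

#' Time derivatives of the 5D Epileptor network
#'
#' Evaluates the coupled 5D vector field (plus the auxiliary convolution
#' state) at one network state. The state is a named list of length-N blocks
#' `x1, y1, z, x2, y2, u`.
#'
#' @param state named list with numeric blocks `x1, y1, z, x2, y2, u`.
#' @param params an [epileptor5d_params()] object.
#' @return a list of the same shape holding time derivatives.
#' @export
derivatives_5d <- function(state, params) {
  x1 <- state$x1; y1 <- state$y1; z <- state$z
  x2 <- state$x2; y2 <- state$y2; u <- state$u
  if (!all(is.finite(c(x1, y1, z, x2, y2, u))))
    stop("non-finite state: integration diverged")
  stopifnot(length(x1) == params$n_regions)
  f1 <- ifelse(x1 < 0,
               x1^3 - 3 * x1^2,
               (x2 - 0.6 * (z - 4)^2) * x1)
  f2 <- ifelse(x2 < -0.25, 0, 6 * (x2 + 0.25))
  coup <- drop(params$C %*% x1) - rowSums(params$C) * x1
  list(
    x1 = y1 - f1 - z + params$I1,
    y1 = 1 - 5 * x1^2 - y1,
    z  = (4 * (x1 - params$x0) - z - params$K * coup) / params$tau0,
    x2 = -y2 + x2 - x2^3 + params$I2 + 0.002 * u - 0.3 * (z - 3.5),
    y2 = (-y2 + f2) / params$tau2,
    u  = x1 - params$gamma * u
  )
}

#' Time derivatives of the 2D Epileptor network
#'
#' @param x per-region fast variable (length N).
#' @param z per-region permittivity variable (length N).
#' @param params an [epileptor2d_params()] object.
#' @return list with components `x` and `z` holding the derivatives.
#' @export
derivatives_2d <- function(x, z, params) {
  if (!all(is.finite(c(x, z))))
    stop("non-finite state: integration diverged")
  stopifnot(length(x) == params$n_regions, length(z) == length(x))
  coup <- drop(params$C %*% x) - rowSums(params$C) * x
  list(
    x = 1 - x^3 - 2 * x^2 - z + params$I1,
    z = (4 * (x - params$x0) - z - params$K * coup) / params$tau0
  )
}

check_divergence <- function(y, bound, step) {
  if (!all(is.finite(y)) || max(abs(y)) > bound) {
    e <- simpleError(sprintf("integration diverged at step %d", step))
    e$step <- step
    stop(e)
  }
}

#' Heun (explicit trapezoidal) integration
#'
#' Deterministic predictor-corrector scheme of global order 2; the scheme
#' used to generate the synthetic ground-truth seizures.
#'
#' @param deriv_fn function of a numeric state vector returning its
#'   derivative (same length).
#' @param init_state numeric initial state.
#' @param dt step size (> 0).
#' @param duration total integration time (>= dt).
#' @param bound divergence guard: any state magnitude above it aborts with an
#'   error carrying the failing step index (default 1e3).
#' @return a `"trajectory"` object: list with `times` (length S+1) and
#'   `states` ((S+1) x d matrix, rows are states, first row the initial one).
#' @export
integrate_heun <- function(deriv_fn, init_state, dt, duration, bound = 1e3) {
  stopifnot(dt > 0, duration >= dt)
  nsteps <- floor(duration / dt + 1e-9)
  y <- as.numeric(init_state)
  out <- matrix(NA_real_, nsteps + 1, length(y))
  out[1, ] <- y
  for (s in seq_len(nsteps)) {
    k1 <- deriv_fn(y)
    k2 <- deriv_fn(y + dt * k1)
    y <- y + dt / 2 * (k1 + k2)
    check_divergence(y, bound, s)
    out[s + 1, ] <- y
  }
  structure(list(times = dt * (0:nsteps), states = out), class = "trajectory")
}

#' Classical fourth-order Runge-Kutta integration
#'
#' @inheritParams integrate_heun
#' @param n_steps number of RK4 steps (>= 1).
#' @return a `"trajectory"` object as in [integrate_heun()].
#' @export
integrate_rk4 <- function(deriv_fn, init_state, dt, n_steps, bound = 1e3) {
  stopifnot(dt > 0, n_steps >= 1)
  y <- as.numeric(init_state)
  out <- matrix(NA_real_, n_steps + 1, length(y))
  out[1, ] <- y
  for (s in seq_len(n_steps)) {
    k1 <- deriv_fn(y)
    k2 <- deriv_fn(y + dt / 2 * k1)
    k3 <- deriv_fn(y + dt / 2 * k2)
    k4 <- deriv_fn(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    check_divergence(y, bound, s)
    out[s + 1, ] <- y
  }
  structure(list(times = dt * (0:n_steps), states = out), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples, %d state variables, t in [%g, %g]\n",
              length(x$times), ncol(x$states), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

# Stable (quiescent-branch) fixed point of an isolated 2D Epileptor node:
# x solves 1 - x^3 - 2x^2 + I1 = 4(x - x0) on the left branch, z = 4(x - x0).
fixed_point_2d <- function(x0, I1 = 3.1) {
  f <- function(x) 1 - x^3 - 2 * x^2 + I1 - 4 * (x - x0)
  root <- stats::uniroot(f, lower = -4, upper = -4 / 3, tol = 1e-12)$root
  c(x = root, z = 4 * (root - x0))
}

# Does an isolated (K = 0) 2D node with excitability x0 seize? Integrates
# from the x0 = -3 rest state (so the node's own dynamics decide) and tests
# whether x ever crosses `threshold`. The fast variable is stiff during the
# escape, so a small RK4 step is used via the compiled kernel.
isolated_node_seizes <- function(x0, tau0 = 1000, I1 = 3.1, threshold = 0,
                                 dt = 0.01, duration = NULL) {
  if (is.null(duration)) duration <- 6 * tau0
  init <- fixed_point_2d(-3, I1)
  nsamp <- ceiling(duration / (100 * dt))
  out <- .latent_rk4_cpp(matrix(0, 1, 1), x0, 0, tau0, I1,
                         init["x"], init["z"], dt, 100L, as.integer(nsamp),
                         1e3)
  if (out$diverged)
    stop(sprintf("isolated-node probe diverged at x0 = %g", x0))
  any(out$X[1, ] >= threshold)
}

#' Critical excitability of an isolated 2D Epileptor node
#'
#' Locates, by bisection on `x0`, the boundary between quiescence and
#' autonomous seizing for a single uncoupled 2D Epileptor node. Each
#' candidate `x0` is simulated from near the quiescent state and classified
#' as seizing if the fast variable crosses the onset threshold.
#'
#' @param search_interval length-2 numeric: must bracket the transition
#'   (quiescent at the lower end, seizing at the upper end).
#' @param tol bisection tolerance on `x0` (default 1e-3).
#' @param tau0 slow timescale used in the probe simulations; large values
#'   approach the static bifurcation value (default 1000).
#' @param I1 constant drive (default 3.1).
#' @param threshold onset threshold on the fast variable (default 0).
#' @return midpoint of the final bracket: the estimated critical `x0`.
#' @export
seizure_threshold_2d <- function(search_interval = c(-3, -1), tol = 1e-3,
                                 tau0 = 1000, I1 = 3.1, threshold = 0) {
  lo <- min(search_interval); hi <- max(search_interval)
  if (isolated_node_seizes(lo, tau0, I1, threshold))
    stop("lower end of search interval already seizes: no bracket")
  if (!isolated_node_seizes(hi, tau0, I1, threshold))
    stop("upper end of search interval does not seize: no bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isolated_node_seizes(mid, tau0, I1, threshold)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
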