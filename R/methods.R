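#' @export
print.vep_fit <- function(x, ...) {
  cat("MAP fit of the network seizure-propagation model\n")
  cat(sprintf("  regions: %d, sensors: %d, time points: %d\n",
              x$theta$n_regions, x$obs$n_sensors, x$obs$T))
  cat(sprintf("  log posterior: %.3f (prior %.3f, likelihood %.3f)\n",
              x$log_posterior, x$log_prior, x$log_likelihood))
  cat(sprintf("  converged: %s (density=%s gradient=%s parameter=%s), %d evaluations\n",
              x$converged, x$convergence_flags[["density"]],
              x$convergence_flags[["gradient"]],
              x$convergence_flags[["parameter"]], x$iterations))
  rep <- propagation_report(x)
  cat(sprintf("  inferred EZ (t_epsilon = %g): %s\n", rep$t_epsilon,
              paste(rep$ez, collapse = ", ")))
  invisible(x)
}

#' @export
coef.vep_fit <- function(object, type = c("packed", "theta"), ...) {
  type <- match.arg(type)
  if (type == "theta") return(object$theta)
  v <- pack_theta(object$theta)
  names(v) <- packed_names(object$theta$n_regions)
  v
}

#' @export
logLik.vep_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = 3 * object$theta$n_regions + 6,
            nobs = length(object$obs$S) + length(object$obs$rho),
            class = "logLik")
}

#' Summarize a MAP fit
#'
#' @param object a `"vep_fit"`.
#' @param t_epsilon onset tolerance used for the EZ/PZ classification shown
#'   in the summary (default 10).
#' @param ... unused.
#' @return an object of class `"summary.vep_fit"`: the scalar parameters, a
#'   per-region table (inferred excitability, prior mean, onset, label) and
#'   fit diagnostics.
#' @export
summary.vep_fit <- function(object, t_epsilon = 10, ...) {
  rep <- propagation_report(object, t_epsilon = t_epsilon)
  n <- object$theta$n_regions
  tab <- data.frame(
    region = seq_len(n),
    x0_hat = object$theta$x0,
    x0_prior_mean = object$priors$mean[1:n],
    onset = rep$regions$onset,
    label = rep$regions$label)
  out <- list(scalars = c(K = object$theta$K, tau0 = object$theta$tau0,
                          alpha = object$theta$alpha, beta = object$theta$beta,
                          eps1 = object$theta$eps1, eps2 = object$theta$eps2),
              regions = tab, report = rep,
              log_posterior = object$log_posterior,
              converged = object$converged,
              flags = object$convergence_flags,
              iterations = object$iterations)
  class(out) <- "summary.vep_fit"
  out
}

#' @export
print.summary.vep_fit <- function(x, ...) {
  cat("Scalar parameters at the MAP estimate:\n")
  print(round(x$scalars, 4))
  cat(sprintf("\nlog posterior: %.3f | converged: %s | evaluations: %d\n",
              x$log_posterior, x$converged, x$iterations))
  cat(sprintf("\nRegions (t_lambda = %s, t_epsilon = %g):\n",
              format(x$report$t_lambda), x$report$t_epsilon))
  print(x$regions, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predictions from a MAP fit
#'
#' @param object a `"vep_fit"`.
#' @param type `"latent"` returns the inferred latent trajectory;
#'   `"features"` (default) the model-predicted SEEG log power
#'   (T x M matrix `alpha * log(G exp(x)) + beta`).
#' @param ... unused.
#' @export
predict.vep_fit <- function(object, type = c("features", "latent"), ...) {
  type <- match.arg(type)
  if (type == "latent") return(object$latent)
  P <- exp_projection(object$latent$X, object$obs$gain)
  object$theta$alpha * log(P) + object$theta$beta
}

#' @export
fitted.vep_fit <- function(object, ...) predict(object, type = "features")

#' @export
residuals.vep_fit <- function(object, ...) {
  object$obs$S - fitted(object)
}

#' Simulate observations from the fitted observation model
#'
#' Draws replicated log-power feature matrices from the Gaussian observation
#' model at the MAP estimate (mean `alpha * log(G exp(x)) + beta`, SD
#' `eps1`).
#'
#' @param object a `"vep_fit"`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` T x M matrices.
#' @export
simulate.vep_fit <- function(object, nsim = 1, seed = NULL, ...) {
  local_rng(seed)
  mu <- fitted(object)
  lapply(seq_len(nsim), function(i)
    mu + matrix(stats::rnorm(length(mu), 0, object$theta$eps1),
                nrow(mu), ncol(mu)))
}

#' Plot a MAP fit
#'
#' Two panels: inferred latent fast-variable trajectories colored by the
#' EZ/PZ/not-recruited classification, and observed vs model-predicted SEEG
#' log power for the highest-power channels.
#'
#' @param x a `"vep_fit"`.
#' @param t_epsilon onset tolerance for the classification (default 10).
#' @param n_channels number of channels in the fit panel (default 6).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.vep_fit <- function(x, t_epsilon = 10, n_channels = 6, ...) {
  rep <- propagation_report(x, t_epsilon = t_epsilon)
  cols <- c(EZ = "red", PZ = "orange", NotRecruited = "grey40")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$obs$times, t(x$latent$X), type = "l", lty = 1,
                    col = cols[rep$regions$label],
                    xlab = "time", ylab = "latent x",
                    main = "Inferred source activity", ...)
  sel <- order(x$obs$rho, decreasing = TRUE)[seq_len(min(n_channels,
                                                         x$obs$n_sensors))]
  mu <- fitted(x)
  graphics::matplot(x$obs$times, x$obs$S[, sel], type = "l", lty = 1,
                    col = "grey60", xlab = "time", ylab = "SEEG log power",
                    main = "Observed (grey) vs predicted (red)")
  graphics::matlines(x$obs$times, mu[, sel], lty = 1, col = "red")
  invisible(x)
}
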