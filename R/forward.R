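#' Structural connectome
#'
#' Wraps a nonnegative coupling matrix, zeroes its diagonal and normalizes it
#' so the maximum entry equals one.
#'
#' @param weights N x N nonnegative numeric matrix.
#' @param region_labels optional character vector of N region names.
#' @return an object of class `"connectome"` (list with `weights`,
#'   `region_labels`, `n_regions`).
#' @export
connectome <- function(weights, region_labels = NULL) {
  w <- as.matrix(weights)
  stopifnot(nrow(w) == ncol(w), all(is.finite(w)))
  if (any(w < 0)) stop("connectome weights must be nonnegative")
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  n <- nrow(w)
  if (is.null(region_labels)) region_labels <- sprintf("region_%03d", seq_len(n))
  stopifnot(length(region_labels) == n)
  dimnames(w) <- list(region_labels, region_labels)
  structure(list(weights = w, region_labels = region_labels, n_regions = n),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, max weight %g, density %.2f\n",
              x$n_regions, max(x$weights),
              mean(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Source-to-sensor gain matrix
#'
#' Computes the linear source-to-sensor transformation under an
#' inverse-square distance decay: entry (i, j) sums, over the vertices of
#' region j's surface, the vertex area divided by the squared distance to
#' sensor i, scaled by `c`. Orientation of the neuronal tissue is not
#' modelled.
#'
#' @param surfaces data frame of region surface vertices with columns
#'   `region` (integer index), `x`, `y`, `z` (positions), `area` (> 0).
#' @param sensors data frame of sensors with columns `label`, `x`, `y`, `z`.
#' @param c scaling coefficient (default 1).
#' @param dist_floor distances are clamped below at this value to avoid a
#'   singular decay at implanted-contact range (default 1; set to 0 to
#'   disable, in which case a coincident sensor/vertex pair is an error).
#' @param n_regions number of regions (defaults to `max(surfaces$region)`).
#' @return M x N nonnegative gain matrix with attribute `"c"`.
#' @export
compute_gain <- function(surfaces, sensors, c = 1, dist_floor = 1,
                         n_regions = max(surfaces$region)) {
  stopifnot(all(surfaces$area > 0), nrow(sensors) >= 1)
  m <- nrow(sensors)
  G <- matrix(0, m, n_regions)
  sp <- as.matrix(sensors[, c("x", "y", "z")])
  vp <- as.matrix(surfaces[, c("x", "y", "z")])
  for (i in seq_len(m)) {
    d2 <- (vp[, 1] - sp[i, 1])^2 + (vp[, 2] - sp[i, 2])^2 +
      (vp[, 3] - sp[i, 3])^2
    if (dist_floor > 0) {
      d2 <- pmax(d2, dist_floor^2)
    } else if (any(d2 == 0)) {
      stop("sensor coincides with a surface vertex and distance clamp is disabled")
    }
    contrib <- c * surfaces$area / d2
    G[i, ] <- vapply(seq_len(n_regions),
                     function(j) sum(contrib[surfaces$region == j]), 0)
  }
  rownames(G) <- sensors$label
  attr(G, "c") <- c
  G
}

#' Project source activity to sensors
#'
#' @param source_activity N x T matrix of per-region source signals.
#' @param gain M x N gain matrix.
#' @return M x T matrix of sensor signals.
#' @export
project_to_sensors <- function(source_activity, gain) {
  if (ncol(gain) != nrow(source_activity))
    stop("gain columns must match source rows")
  gain %*% source_activity
}

#' Synthetic network geometry and connectome
#'
#' Generates a reproducible random stand-in for a patient-derived network:
#' region centroids with small vertex clouds, SEEG sensors implanted in the
#' vicinity of the EZ/PZ centroids, and a connectome in which the
#' propagation-zone regions are strongly connected to the epileptogenic-zone
#' regions (then max-normalized).
#'
#' @param n_regions number of regions (>= 8 recommended).
#' @param ez,pz disjoint integer index sets of EZ and PZ regions.
#' @param n_sensors number of SEEG contacts (default: two per EZ/PZ region
#'   plus four distant contacts).
#' @param seed integer seed for reproducibility.
#' @param n_vertices vertices per region surface (default 12).
#' @return list with elements `connectome`, `surfaces`, `sensors`.
#' @export
synthetic_network <- function(n_regions, ez, pz,
                              n_sensors = 2 * (length(ez) + length(pz)) + 4,
                              seed = 1, n_vertices = 12) {
  stopifnot(length(intersect(ez, pz)) == 0, n_sensors >= 1,
            all(c(ez, pz) >= 1), all(c(ez, pz) <= n_regions))
  rng <- local_rng(seed)
  centroids <- matrix(stats::runif(3 * n_regions, 0, 100), n_regions, 3)
  surfaces <- do.call(rbind, lapply(seq_len(n_regions), function(j) {
    offs <- matrix(stats::rnorm(3 * n_vertices, 0, 2), n_vertices, 3)
    data.frame(region = j,
               x = centroids[j, 1] + offs[, 1],
               y = centroids[j, 2] + offs[, 2],
               z = centroids[j, 3] + offs[, 3],
               area = stats::runif(n_vertices, 0.8, 1.2))
  }))
  # contacts near the seizing regions (mimicking clinical implantation), plus
  # a few distant ones
  focus <- c(ez, pz)
  spos <- NULL
  contact_near <- function(j) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    centroids[j, ] + dir * stats::runif(1, 3.5, 4.5)
  }
  for (j in focus) {
    for (k in 1:2) {
      spos <- rbind(spos, contact_near(j))
      if (nrow(spos) == n_sensors) break
    }
    if (nrow(spos) == n_sensors) break
  }
  while (is.null(spos) || nrow(spos) < n_sensors) {
    spos <- rbind(spos, contact_near(sample.int(n_regions, 1)))
  }
  sensors <- data.frame(label = sprintf("ch_%02d", seq_len(n_sensors)),
                        x = spos[, 1], y = spos[, 2], z = spos[, 3])
  # background connectivity weak and symmetric, an order below the EZ->PZ
  # pathway (max-normalized connectomes are strongly heterogeneous); the
  # permittivity coupling is diffusive, so dense strong backgrounds would
  # anchor every node at the network mean and suppress both autonomous
  # seizing and recruitment
  w <- matrix(stats::runif(n_regions^2, 0, 0.02), n_regions, n_regions)
  w <- (w + t(w)) / 2
  for (i in ez) for (j in pz) w[i, j] <- w[j, i] <- stats::runif(1, 0.95, 1.0)
  if (length(ez) > 1)
    for (i in ez) for (j in setdiff(ez, i)) w[i, j] <- w[j, i] <- 0.5
  diag(w) <- 0
  conn <- connectome(w)
  list(connectome = conn, surfaces = surfaces, sensors = sensors)
}

#' Seizure scenario specification
#'
#' Ground-truth configuration of a synthetic seizure: which regions form the
#' epileptogenic zone (excitability above the isolated-node threshold) and
#' the propagation zone (below threshold but recruited through coupling),
#' excitability values, global coupling, and integration settings. Defaults
#' are the reference scenario: EZ at `x0 = -1.8`, PZ at `-2.3`, background
#' `-3.0`, Heun integration with `dt = 0.04` for 2500 time units. Model time
#' is dimensionless; `seconds_per_unit` maps it to recording seconds for
#' feature extraction and onset tolerances.
#'
#' @param ez,pz disjoint integer index sets.
#' @param x0_ez,x0_pz,x0_background excitability values
#'   (defaults -1.8, -2.3, -3.0; must be decreasing in that order).
#' @param K global coupling (default 0.7; set by analyzing simulations so
#'   that the EZ seizes autonomously and recruits exactly the PZ within the
#'   simulated window).
#' @param z_init initial permittivity of every node (default 3.3: the
#'   recording starts during the pre-ictal approach to seizure rather than at
#'   the deep interictal equilibrium, whose slow relaxation would consume
#'   most of the simulated window).
#' @param dynamic_noise SD of additive Gaussian dynamic noise on the
#'   intermediate subsystem (`x2`, `y2`) per unit time (default 0.025, the
#'   scale conventionally used in stochastic whole-brain Epileptor
#'   simulations); gives every region ongoing background activity and
#'   sustains ictal discharges. Set 0 for a fully deterministic simulation.
#' @param dt Heun step size in model time units (default 0.04).
#' @param duration total simulated time (default 2500).
#' @param burn_in initial stretch of simulated time discarded from all
#'   outputs (default 300), long enough for the intermediate subsystem and
#'   the convolution state to settle from their nominal initial values.
#' @param seconds_per_unit nominal mapping from model time to recording
#'   seconds (default 0.1, giving a 250 s recording at 250 Hz).
#' @param onset_threshold ground-truth recruitment threshold on the fast
#'   variable `x1` (default 0: upward zero crossing).
#' @return an object of class `"seizure_scenario"`.
#' @export
seizure_scenario <- function(ez, pz, x0_ez = -1.8, x0_pz = -2.3,
                             x0_background = -3.0, K = 0.7, z_init = 3.3,
                             dynamic_noise = 0.025,
                             dt = 0.04, duration = 2500, burn_in = 300,
                             seconds_per_unit = 0.1, onset_threshold = 0) {
  stopifnot(length(intersect(ez, pz)) == 0,
            x0_ez > x0_pz, x0_pz > x0_background,
            dt > 0, duration >= dt, seconds_per_unit > 0, dynamic_noise >= 0,
            burn_in >= 0)
  structure(list(ez = sort(ez), pz = sort(pz), x0_ez = x0_ez, x0_pz = x0_pz,
                 x0_background = x0_background, K = K, z_init = z_init,
                 dynamic_noise = dynamic_noise,
                 dt = dt, duration = duration, burn_in = burn_in,
                 seconds_per_unit = seconds_per_unit,
                 onset_threshold = onset_threshold),
            class = "seizure_scenario")
}

# Initial state for the 5D network: every node near the isolated quiescent
# fixed point of the x0 = -3 dynamics, with the permittivity perturbed to
# `z_init` (pre-ictal approach), u = 0.
init_state_5d <- function(n, z_init = 3.3, I1 = 3.1) {
  fp <- fixed_point_2d(-3, I1)
  cbind(x1 = rep(fp["x"], n),
        y1 = rep(1 - 5 * fp["x"]^2, n),
        z  = rep(z_init, n),
        x2 = rep(-0.25, n),
        y2 = rep(0, n),
        u  = rep(0, n))
}

#' Simulate a synthetic SEEG seizure dataset
#'
#' Integrates the coupled 5D Epileptor network under a [seizure_scenario()],
#' projects the local field potential `x1(t) + x2(t)` to SEEG sensors through
#' the gain matrix, optionally adds Gaussian observation noise at a target
#' SNR, and records ground-truth recruitment (upward threshold crossings of
#' the source fast variable) for later evaluation.
#'
#' @param scenario a [seizure_scenario()].
#' @param network output of [synthetic_network()] (or a compatible list with
#'   `connectome`, `surfaces`, `sensors`).
#' @param gain optional precomputed gain matrix; computed from the network
#'   geometry when missing.
#' @param seed integer seed controlling the noise realization.
#' @param target_snr channel-averaged signal-to-noise variance ratio;
#'   `Inf` (default) disables noise.
#' @param hw_hp_hz acquisition high-pass cutoff in Hz applied to the
#'   projected SEEG before noise is added (default 0.16, the lower edge of
#'   the hardware band-pass of clinical SEEG amplifiers). Removes the slow
#'   baseline shift of the local field potential so that, as in recorded
#'   SEEG, channel variance reflects oscillatory activity. Set 0 to disable.
#' @return an object of class `"seizure_dataset"`: SEEG matrices (clean and
#'   noisy, channels x time), sampling rate, source trajectories (`x1`, `z`,
#'   `lfp`), ground-truth onsets (seconds) and recruited set, scenario, seed.
#' @export
simulate_seizure_dataset <- function(scenario, network, gain = NULL,
                                     seed = 1, target_snr = Inf,
                                     hw_hp_hz = 0.16) {
  conn <- network$connectome
  n <- conn$n_regions
  stopifnot(all(c(scenario$ez, scenario$pz) <= n))
  if (is.null(gain))
    gain <- compute_gain(network$surfaces, network$sensors, n_regions = n)
  x0 <- rep(scenario$x0_background, n)
  x0[scenario$ez] <- scenario$x0_ez
  x0[scenario$pz] <- scenario$x0_pz
  nburn <- floor(scenario$burn_in / scenario$dt + 1e-9)
  nsteps <- floor(scenario$duration / scenario$dt + 1e-9) + nburn
  local_rng(seed)
  sim <- .heun_5d_cpp(conn$weights, x0, scenario$K, 2857, 10, 3.1, 0.45, 0.01,
                      init_state_5d(n, scenario$z_init), scenario$dt, nsteps,
                      1L, 1e3, scenario$dynamic_noise)
  if (nburn > 0) {
    keep <- (nburn + 1):length(sim$times)
    sim$times <- sim$times[keep] - sim$times[nburn + 1]
    for (nm in c("x1", "y1", "z", "x2", "y2", "u")) sim[[nm]] <- sim[[nm]][, keep]
  }
  lfp <- sim$x1 + sim$x2
  clean <- project_to_sensors(lfp, gain)
  fs <- 1 / (scenario$dt * scenario$seconds_per_unit)
  if (hw_hp_hz > 0) {
    bhw <- signal::butter(1, hw_hp_hz / (fs / 2), type = "high")
    npad <- min(ncol(clean) - 1L, ceiling(2 * fs / hw_hp_hz))
    for (i in seq_len(nrow(clean)))
      clean[i, ] <- filtfilt_padded(bhw, clean[i, ], npad)
  }
  # continue on the seeded stream (no reseed) for the observation noise
  noisy <- add_observation_noise(clean, target_snr, seed = NULL)
  onsets_units <- detect_onsets(sim$x1, sim$times,
                                threshold = scenario$onset_threshold)
  onsets_sec <- onsets_units * scenario$seconds_per_unit
  structure(list(
    seeg = noisy, seeg_clean = clean, fs = fs,
    channel_labels = rownames(gain), gain = gain,
    times = sim$times * scenario$seconds_per_unit,
    source = list(times = sim$times, x1 = sim$x1, z = sim$z, lfp = lfp),
    truth = list(onsets = onsets_sec,
                 recruited = which(!is.na(onsets_sec)),
                 ez = scenario$ez, pz = scenario$pz),
    scenario = scenario, seed = seed, target_snr = target_snr),
    class = "seizure_dataset")
}

#' @export
print.seizure_dataset <- function(x, ...) {
  cat(sprintf(paste0("seizure_dataset: %d channels x %d samples (%.0f Hz), ",
                     "%d regions, %d recruited (EZ: %s; PZ: %s), SNR %s\n"),
              nrow(x$seeg), ncol(x$seeg), x$fs, nrow(x$source$x1),
              length(x$truth$recruited),
              paste(x$truth$ez, collapse = ","),
              paste(x$truth$pz, collapse = ","),
              format(x$target_snr)))
  invisible(x)
}

#' Add Gaussian observation noise at a target SNR
#'
#' A single noise SD is chosen so the channel-averaged ratio of clean signal
#' variance to noise variance equals `target_snr`; independent zero-mean
#' Gaussian noise with that SD is then added to every channel.
#'
#' @param clean_seeg M x T numeric matrix.
#' @param target_snr positive scalar; `Inf` returns the input unchanged.
#' @param seed integer seed.
#' @return noisy M x T matrix.
#' @export
add_observation_noise <- function(clean_seeg, target_snr, seed = 1) {
  stopifnot(target_snr > 0)
  if (!is.finite(target_snr)) return(clean_seeg)
  v <- apply(clean_seeg, 1, stats::var)
  if (mean(v) == 0) stop("clean signal has zero variance")
  sd_noise <- sqrt(mean(v) / target_snr)
  local_rng(seed)
  clean_seeg + matrix(stats::rnorm(length(clean_seeg), 0, sd_noise),
                      nrow(clean_seeg), ncol(clean_seeg))
}

# Seeded RNG scoped to the calling function: restores the global seed state
# when the caller exits, so library code does not disturb the user's stream.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}
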