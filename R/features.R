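#' SEEG recording container
#'
#' @param samples channels x time numeric matrix.
#' @param fs sampling rate in Hz (> 0).
#' @param labels optional channel labels.
#' @return an object of class `"seeg_recording"`.
#' @export
seeg_recording <- function(samples, fs, labels = NULL) {
  samples <- as.matrix(samples)
  stopifnot(fs > 0, all(is.finite(samples)))
  if (is.null(labels)) labels <- rownames(samples)
  if (is.null(labels)) labels <- sprintf("ch_%02d", seq_len(nrow(samples)))
  stopifnot(length(labels) == nrow(samples))
  rownames(samples) <- labels
  structure(list(samples = samples, fs = fs, labels = labels),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("seeg_recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Feature-extraction settings
#'
#' @param hp_hz high-pass cutoff in Hz removing the slow baseline so that the
#'   envelope tracks ictal fast activity (default 10).
#' @param window_sec sliding window length in seconds for the power estimate
#'   (default 1).
#' @param overlap fractional window overlap (default 0.5).
#' @param lp_frac low-pass smoothing cutoff for the log-power envelope, as a
#'   fraction of the envelope Nyquist frequency (default 0.1); analogous to
#'   the per-patient smoothing tuning of clinical pipelines.
#' @param n_points number of output time points after resampling
#'   (default 300).
#' @param filter_order Butterworth order for the high-pass, applied
#'   forward-backward (zero phase, so onset times are not lagged and the
#'   effective magnitude order doubles); the envelope smoother uses half
#'   this order. Default 2: higher orders at the low normalized cutoffs of
#'   long recordings are numerically marginal in transfer-function form.
#' @param rel_floor per-channel floor on the windowed power relative to that
#'   channel's peak, guarding the log transform (default `1e-6`, a 60 dB
#'   dynamic-range cap; recordings without a physiological noise floor, e.g.
#'   noiseless simulations, would otherwise produce arbitrarily deep
#'   log-power cliffs).
#' @return list of settings.
#' @export
feature_config <- function(hp_hz = 10, window_sec = 1, overlap = 0.5,
                           lp_frac = 0.1, n_points = 300, filter_order = 2,
                           rel_floor = 1e-6) {
  stopifnot(hp_hz > 0, window_sec > 0, overlap >= 0, overlap < 1,
            lp_frac > 0, lp_frac < 1, n_points >= 2, filter_order >= 1,
            rel_floor > 0, rel_floor < 1)
  list(hp_hz = hp_hz, window_sec = window_sec, overlap = overlap,
       lp_frac = lp_frac, n_points = n_points, filter_order = filter_order,
       rel_floor = rel_floor)
}

#' Extract SEEG log-power data features
#'
#' The fitted data feature is the slow envelope of SEEG power: the raw signal
#' is high-pass filtered (zero-phase Butterworth), squared and averaged over
#' a sliding window, log-transformed (natural log, with a floor at a machine
#' epsilon multiple of the peak power to guard the log), smoothed with a
#' zero-phase low-pass filter, and resampled to exactly `n_points` samples.
#' The per-channel total power (second sample moment of each channel's
#' log-power series) is returned as the augmented feature.
#'
#' @param rec a [seeg_recording()].
#' @param config a [feature_config()].
#' @return an object of class `"data_features"`: list with `S`
#'   (`n_points` x M log-power matrix), `rho` (length-M total power),
#'   `times` (seconds), `labels`, `fs_envelope`.
#' @export
extract_log_power <- function(rec, config = feature_config()) {
  x <- rec$samples
  fs <- rec$fs
  w <- max(2L, round(config$window_sec * fs))
  if (ncol(x) <= w)
    stop("recording shorter than one analysis window")
  wn <- config$hp_hz / (fs / 2)
  if (wn >= 1) stop("high-pass cutoff at or above Nyquist")
  bf <- signal::butter(config$filter_order, wn, type = "high")
  stride <- max(1L, round(w * (1 - config$overlap)))
  # keep window centers a full window clear of the recording edges, where the
  # zero-phase filters leave startup transients
  centers <- seq(from = w + 1L, to = ncol(x) - w, by = stride)
  if (length(centers) < 4)
    stop("recording too short for the configured window/overlap")
  kern <- rep(1 / w, w)
  npad_hp <- min(ncol(x) - 1L, ceiling(2 * fs / config$hp_hz))
  S <- matrix(NA_real_, length(centers), nrow(x))
  for (i in seq_len(nrow(x))) {
    hp <- filtfilt_padded(bf, x[i, ], npad_hp)
    p <- stats::filter(hp^2, kern, sides = 2)
    p <- as.numeric(p)[centers]
    S[, i] <- p
  }
  peak <- apply(S, 2, max, na.rm = TRUE)
  floorp <- pmax(config$rel_floor * peak, .Machine$double.xmin)
  S <- log(pmax(S, rep(floorp, each = nrow(S))))
  # smooth the envelope; skip when too short for a stable zero-phase pass
  if (nrow(S) > 6 * config$filter_order) {
    bl <- signal::butter(max(1, config$filter_order %/% 2), config$lp_frac,
                         type = "low")
    npad_lp <- min(nrow(S) - 1L, ceiling(6 / config$lp_frac))
    S <- apply(S, 2, function(col) filtfilt_padded(bl, col, npad_lp))
  }
  t_env <- (centers - 1) / fs
  t_out <- seq(t_env[1], t_env[length(t_env)], length.out = config$n_points)
  S_out <- apply(S, 2, function(col) stats::approx(t_env, col, t_out)$y)
  colnames(S_out) <- rec$labels
  structure(list(S = S_out, rho = total_sensor_power(S_out), times = t_out,
                 labels = rec$labels,
                 fs_envelope = 1 / (t_out[2] - t_out[1])),
            class = "data_features")
}

#' @export
print.data_features <- function(x, ...) {
  cat(sprintf("data_features: %d time points x %d channels, t in [%.1f, %.1f] s\n",
              nrow(x$S), ncol(x$S), min(x$times), max(x$times)))
  invisible(x)
}

# Zero-phase filtering with odd-reflection padding at both ends, suppressing
# the startup transients that plain forward-backward filtering leaves at the
# recording edges.
filtfilt_padded <- function(filt, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad < 1) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(npad + 1):(npad + n)]
}

#' Observation features from a synthetic dataset
#'
#' Reference pipeline from a simulated recording to the fitted observation:
#' optionally clip the recording to a seizure-centered window (as clinical
#' workflows fit the ictal clip rather than the whole recording), extract
#' log-power features, and pair them with the dataset's gain matrix.
#'
#' @param dataset a [simulate_seizure_dataset()] output.
#' @param config a [feature_config()]; the default uses a 1 Hz high-pass and
#'   strong envelope smoothing (`lp_frac = 0.065`), appropriate for the
#'   time-mapped frequencies of the bundled scenario.
#' @param window optional length-2 numeric, seconds: the clip to fit
#'   (default `c(20, 160)`, bracketing the bundled scenario's seizure;
#'   `NULL` fits the whole recording).
#' @return a [vep_observation()].
#' @export
dataset_features <- function(dataset,
                             config = feature_config(hp_hz = 1,
                                                     lp_frac = 0.065),
                             window = c(20, 160)) {
  seeg <- dataset$seeg
  if (!is.null(window)) {
    keep <- which(dataset$times >= window[1] & dataset$times <= window[2])
    if (length(keep) < 2) stop("clip window outside the recording")
    seeg <- seeg[, keep, drop = FALSE]
  }
  feats <- extract_log_power(
    seeg_recording(seeg, dataset$fs, dataset$channel_labels), config)
  if (!is.null(window)) feats$times <- feats$times + window[1]
  vep_observation(feats, dataset$gain)
}

#' Per-channel total power of the log-power matrix
#'
#' Second sample moment of each channel's log-power series,
#' `rho_i = mean_j s_i(t_j)^2`; used as an augmented data feature.
#'
#' @param S T x M log-power matrix.
#' @return length-M numeric vector.
#' @export
total_sensor_power <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) < 1 || ncol(S) < 1) stop("empty log-power matrix")
  colMeans(S^2)
}
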