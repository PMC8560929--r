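#' Run configuration
#'
#' Loads a JSON run configuration (or passes a list through), filling
#' defaults. All tunable constants of the pipeline live here: scenario
#' excitability values, integration steps, feature settings, onset tolerance,
#' optimizer settings, and the seed. Every artifact written by the `run_*`
#' commands embeds the configuration hash and seed.
#'
#' @param config path to a JSON file or a named list.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(
    n_regions = 24, ez = c(1, 2), pz = c(3, 4, 5, 6),
    x0_ez = -1.8, x0_pz = -2.3, x0_background = -3.0, K = 0.7, z_init = 3.3,
    dt = 0.04, duration = 2500, seconds_per_unit = 0.1,
    n_sensors = NULL, target_snr = Inf,
    hp_hz = 1, window_sec = 1, overlap = 0.5, lp_frac = 0.065, n_points = 300,
    latent_dt = 0.1, nsub = 1, maxit = 20000,
    fit_window = c(20, 160),
    t_epsilon = 10, onset_threshold = 0,
    seed = 1, out_dir = "vepmap_out",
    dataset_dir = NULL, hypothesis = NULL)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  structure(cfg, class = "run_config")
}

cfg_network <- function(cfg) {
  ns <- cfg$n_sensors
  if (is.null(ns)) ns <- 2 * (length(cfg$ez) + length(cfg$pz)) + 4
  synthetic_network(cfg$n_regions, ez = cfg$ez, pz = cfg$pz,
                    n_sensors = ns, seed = cfg$seed)
}

cfg_scenario <- function(cfg) {
  seizure_scenario(ez = cfg$ez, pz = cfg$pz, x0_ez = cfg$x0_ez,
                   x0_pz = cfg$x0_pz, x0_background = cfg$x0_background,
                   K = cfg$K, z_init = cfg$z_init,
                   dt = cfg$dt, duration = cfg$duration,
                   seconds_per_unit = cfg$seconds_per_unit,
                   onset_threshold = cfg$onset_threshold)
}

write_provenance <- function(cfg, dir, extra = list()) {
  prov <- c(list(config = unclass(cfg), config_hash = config_hash(cfg),
                 seed = cfg$seed, package_version =
                   as.character(utils::packageVersion("vepmap"))),
            extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
}

#' Simulate a synthetic dataset from a configuration
#'
#' Generates the synthetic network and scenario described by the
#' configuration, simulates the seizure, and writes the dataset plus
#' provenance to `out_dir`.
#'
#' @param config a [run_config()] input (JSON path or list).
#' @return invisibly, a list with the dataset, network and output directory.
#' @export
run_simulate <- function(config = list()) {
  cfg <- run_config(config)
  net <- cfg_network(cfg)
  scen <- cfg_scenario(cfg)
  ds <- simulate_seizure_dataset(scen, net, seed = cfg$seed,
                                 target_snr = cfg$target_snr)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(ds, net$connectome, cfg$out_dir)
  write_provenance(cfg, cfg$out_dir)
  message(sprintf("dataset written to %s (%d regions, %d recruited)",
                  cfg$out_dir, cfg$n_regions, length(ds$truth$recruited)))
  invisible(list(dataset = ds, network = net, dir = cfg$out_dir))
}

#' Fit the model on a configured dataset
#'
#' Runs the full inversion pipeline (features, MAP fit, onset classification)
#' on a dataset: either the directory written by [run_simulate()]
#' (`dataset_dir`) or a freshly simulated one. Writes the estimated
#' parameters, the propagation report and a provenance log.
#'
#' @param config a [run_config()] input. `hypothesis` defaults to the
#'   dataset's ground-truth EZ when available.
#' @return invisibly, a list with the fit, report and output directory.
#' @export
run_fit <- function(config = list()) {
  cfg <- run_config(config)
  if (!is.null(cfg$dataset_dir)) {
    meta <- jsonlite::read_json(file.path(cfg$dataset_dir, "metadata.json"),
                                simplifyVector = TRUE)
    seeg <- as.matrix(utils::read.table(file.path(cfg$dataset_dir, "seeg.tsv")))
    gain <- as.matrix(utils::read.table(file.path(cfg$dataset_dir, "gain.tsv")))
    conn <- read_connectome(file.path(cfg$dataset_dir, "connectome.tsv"))
    fs <- meta$fs
    truth_ez <- meta$truth$ez
  } else {
    sim <- run_simulate(cfg)
    seeg <- sim$dataset$seeg
    gain <- sim$dataset$gain
    conn <- sim$network$connectome
    fs <- sim$dataset$fs
    truth_ez <- sim$dataset$truth$ez
  }
  hypothesis <- cfg$hypothesis
  if (is.null(hypothesis)) hypothesis <- truth_ez
  if (is.character(hypothesis) && length(hypothesis) == 1 &&
      file.exists(hypothesis))
    hypothesis <- read_hypothesis(hypothesis, conn$region_labels)
  if (is.null(hypothesis))
    stop("no hypothesis available: set `hypothesis` in the config")
  fcfg <- feature_config(hp_hz = cfg$hp_hz, window_sec = cfg$window_sec,
                         overlap = cfg$overlap, lp_frac = cfg$lp_frac,
                         n_points = cfg$n_points)
  if (!is.null(cfg$fit_window)) {
    times <- (seq_len(ncol(seeg)) - 1) / fs
    keep <- which(times >= cfg$fit_window[1] & times <= cfg$fit_window[2])
    if (length(keep) > 1) seeg <- seeg[, keep, drop = FALSE]
  }
  feats <- extract_log_power(seeg_recording(seeg, fs), fcfg)
  obs <- vep_observation(feats, gain)
  fit <- vep_fit(obs, conn, hypothesis = hypothesis, dt = cfg$latent_dt,
                 nsub = cfg$nsub, maxit = cfg$maxit)
  rep <- propagation_report(fit, t_epsilon = cfg$t_epsilon,
                            threshold = cfg$onset_threshold)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- coef(fit)
  utils::write.table(data.frame(parameter = names(v), value = v),
                     file.path(cfg$out_dir, "theta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_report(rep, file.path(cfg$out_dir, "report"))
  write_provenance(cfg, cfg$out_dir, extra = list(
    log_posterior = fit$log_posterior, converged = fit$converged,
    convergence_flags = as.list(fit$convergence_flags),
    iterations = fit$iterations, hypothesis = hypothesis))
  message(sprintf("fit written to %s (log posterior %.2f, EZ: %s)",
                  cfg$out_dir, fit$log_posterior,
                  paste(rep$ez, collapse = ", ")))
  invisible(list(fit = fit, report = rep, dir = cfg$out_dir))
}

#' Evaluate reports against hypotheses
#'
#' Computes precision/recall (pooled and per patient), the 3-class confusion
#' matrix, and an optional onset-tolerance sweep, writing TSV tables to
#' `out_dir`.
#'
#' @param reports a `"propagation_report"` or list of them; alternatively a
#'   fitted `"vep_fit"` list via `fits`.
#' @param hypotheses matched region-index sets.
#' @param config a [run_config()] input.
#' @param t_epsilon_grid optional vector of tolerances for a sweep; the sweep
#'   re-classifies from the fits when `fits` is given.
#' @param fits optional list of `"vep_fit"` objects (enables the sweep).
#' @return invisibly, a list with the metrics.
#' @export
run_evaluate <- function(reports = NULL, hypotheses, config = list(),
                         t_epsilon_grid = NULL, fits = NULL) {
  cfg <- run_config(config)
  if (is.null(reports)) {
    if (is.null(fits)) stop("provide `reports` or `fits`")
    reports <- lapply(fits, propagation_report, t_epsilon = cfg$t_epsilon)
  }
  if (inherits(reports, "propagation_report")) reports <- list(reports)
  if (!is.list(hypotheses)) hypotheses <- list(hypotheses)
  if (length(reports) != length(hypotheses))
    stop("mismatched report and hypothesis lists")
  pooled <- precision_recall(reports, hypotheses, mode = "pooled")
  per_pat <- precision_recall(reports, hypotheses, mode = "per_patient")
  conf <- confusion_3class(reports, hypotheses)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(per_pat, file.path(cfg$out_dir, "precision_recall.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(class = rownames(conf$counts),
                           as.data.frame(conf$counts)),
                     file.path(cfg$out_dir, "confusion.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sweep_tab <- NULL
  if (!is.null(t_epsilon_grid) && !is.null(fits)) {
    sweep_tab <- do.call(rbind, lapply(t_epsilon_grid, function(te) {
      reps <- lapply(fits, propagation_report, t_epsilon = te)
      pr <- precision_recall(reps, hypotheses, mode = "pooled")
      data.frame(t_epsilon = te, precision = pr[["precision"]],
                 recall = pr[["recall"]])
    }))
    utils::write.table(sweep_tab,
                       file.path(cfg$out_dir, "t_epsilon_sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_provenance(cfg, cfg$out_dir,
                   extra = list(pooled = as.list(pooled)))
  invisible(list(pooled = pooled, per_patient = per_pat, confusion = conf,
                 t_epsilon_sweep = sweep_tab, dir = cfg$out_dir))
}
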