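#' Read / write a connectome as a delimited matrix
#'
#' The matrix file is whitespace- or comma-delimited with no header; an
#' optional sidecar `<path>.labels` holds one region label per line.
#'
#' @param path file path.
#' @return a [connectome()].
#' @export
read_connectome <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  w <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  labels_path <- paste0(path, ".labels")
  labels <- if (file.exists(labels_path)) readLines(labels_path) else NULL
  connectome(w, labels)
}

#' @rdname read_connectome
#' @param conn a [connectome()].
#' @export
write_connectome <- function(conn, path) {
  utils::write.table(conn$weights, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  writeLines(conn$region_labels, paste0(path, ".labels"))
  invisible(path)
}

#' Read sensors / surfaces tables
#'
#' Sensors: TSV with header `label, x, y, z`. Surfaces: TSV with header
#' `region, x, y, z, area`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_sensors <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname read_sensors
#' @export
read_surfaces <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Read a delimited SEEG matrix with a JSON sidecar
#'
#' The matrix is channels x time, whitespace- or tab-delimited, no header;
#' the sidecar `<path>.json` must carry at least `fs` (Hz) and may carry
#' `labels`.
#'
#' @param path file path.
#' @return a [seeg_recording()].
#' @export
read_seeg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, header = FALSE))
  seeg_recording(x, fs = meta$fs, labels = meta$labels)
}

#' Write a synthetic dataset to a directory
#'
#' Writes delimited matrices (`seeg.tsv`, `seeg_clean.tsv`, `source_x1.tsv`,
#' `gain.tsv`, `connectome.tsv`) plus `metadata.json` (scenario, seed, ground
#' truth, sampling rate, config hash).
#'
#' @param dataset a [simulate_seizure_dataset()] output.
#' @param conn the generating [connectome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, conn, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(m, f) utils::write.table(m, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, col.names = FALSE)
  wt(dataset$seeg, "seeg.tsv")
  wt(dataset$seeg_clean, "seeg_clean.tsv")
  wt(dataset$source$x1, "source_x1.tsv")
  wt(dataset$gain, "gain.tsv")
  write_connectome(conn, file.path(dir, "connectome.tsv"))
  meta <- list(
    fs = dataset$fs, seed = dataset$seed, target_snr = dataset$target_snr,
    channel_labels = dataset$channel_labels,
    scenario = unclass(dataset$scenario),
    truth = list(onsets = dataset$truth$onsets,
                 recruited = dataset$truth$recruited,
                 ez = dataset$truth$ez, pz = dataset$truth$pz))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' Write a propagation report
#'
#' TSV (region, onset, label) plus a JSON summary.
#'
#' @param report a `"propagation_report"`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$regions, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(t_lambda = report$t_lambda, t_epsilon = report$t_epsilon,
         ez = report$ez, pz = report$pz,
         not_recruited = report$not_recruited),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a hypothesis file
#'
#' Newline-separated region indices (integers) or region labels (resolved
#' against `region_labels` when given).
#'
#' @param path file path.
#' @param region_labels optional label vector for name resolution.
#' @return integer region indices.
#' @export
read_hypothesis <- function(path, region_labels = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  idx <- suppressWarnings(as.integer(lines))
  if (!anyNA(idx)) return(idx)
  if (is.null(region_labels)) stop("non-numeric hypothesis needs region labels")
  m <- match(lines, region_labels)
  if (anyNA(m)) stop("unknown region label(s): ",
                     paste(lines[is.na(m)], collapse = ", "))
  m
}

# stable hash of a configuration list (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
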