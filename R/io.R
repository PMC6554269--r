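#' Read a tuning curve from CSV
#'
#' Format: columns `wavelength_nm,response,point_class` (header required;
#' `point_class` optional, one of peak/trough/zero/plain).
#'
#' @param path CSV file path.
#' @return Validated tuning-curve data frame.
#' @export
read_curve <- function(path) {
  validate_curve(utils::read.csv(path))
}

#' Write a tuning curve to CSV
#' @param curve Tuning-curve data frame.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(validate_curve(curve), path, row.names = FALSE)
}

#' Read a batch of curves via a manifest
#'
#' The manifest CSV has columns `neuron_id,file`; file paths are resolved
#' relative to the manifest's directory.
#'
#' @param manifest Manifest CSV path.
#' @return Named list of tuning-curve data frames.
#' @export
read_curve_batch <- function(manifest) {
  mf <- utils::read.csv(manifest)
  stopifnot(all(c("neuron_id", "file") %in% names(mf)))
  base <- dirname(manifest)
  curves <- lapply(file.path(base, mf$file), read_curve)
  stats::setNames(curves, mf$neuron_id)
}

#' Write a synthetic batch as curve CSVs plus manifest and truth table
#'
#' Emits the same per-curve CSV and manifest format [read_curve_batch()]
#' reads, with the ground truth alongside as TSV.
#'
#' @param batch A `synthetic_batch`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_batch <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(batch$curves)
  files <- paste0(ids, ".csv")
  for (i in seq_along(ids))
    write_curve(batch$curves[[i]], file.path(dir, files[i]))
  mf <- data.frame(neuron_id = ids, file = files)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(mf, manifest, row.names = FALSE)
  utils::write.table(batch$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Write a neuron library as JSON-lines plus a curve matrix TSV
#'
#' @param lib A `neuron_library`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "neurons.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_along(lib$neurons)) {
    n <- lib$neurons[[i]]
    writeLines(jsonlite::toJSON(list(
      id = i, w_S = n$w[["S"]], w_M = n$w[["M"]], w_L = n$w[["L"]],
      activation = list(kind = "piecewise", t_min = n$t_min,
                        t_max = n$t_max, alpha = n$alpha)),
      auto_unbox = TRUE, digits = NA), con)
  }
  m <- cbind(neuron = seq_len(nrow(lib$curves)), lib$curves)
  utils::write.table(m, file.path(dir, "curves.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a persisted neuron library
#'
#' Restores the curve matrix and neuron parameters written by
#' [write_library()], so downstream stages (clustering, perception) can be
#' re-run in isolation from persisted intermediates.
#'
#' @param dir Directory written by [write_library()].
#' @return A `neuron_library` (without the generating config).
#' @export
read_library <- function(dir) {
  m <- utils::read.table(file.path(dir, "curves.tsv"), sep = "\t",
                         header = TRUE, check.names = FALSE)
  curves <- as.matrix(m[, -1, drop = FALSE])
  lambda <- as.numeric(colnames(curves))
  neurons <- lapply(readLines(file.path(dir, "neurons.jsonl")), function(l) {
    j <- jsonlite::fromJSON(l)
    structure(list(w = c(S = j$w_S, M = j$w_M, L = j$w_L),
                   activation = "piecewise", alpha = j$activation$alpha,
                   t_min = j$activation$t_min, t_max = j$activation$t_max,
                   A0 = 1, baseline = NULL, v = c(-1, -1, -1)),
              class = "third_order_neuron")
  })
  structure(list(neurons = neurons, curves = unname(curves),
                 lambda = lambda, config = NULL, receptors = NULL),
            class = "neuron_library")
}

#' Write a distance matrix as TSV with wavelength labels
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- dm$d
  dimnames(m) <- list(dm$lambda, dm$lambda)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
}
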