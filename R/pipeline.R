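#' Pipeline configuration
#'
#' End-to-end settings for [run_colour_pipeline()]. Unknown keys passed via
#' `...` are rejected. Stage seeds are derived from the global seed plus a
#' fixed per-stage offset.
#'
#' @param seed Global integer seed.
#' @param curves Optional named list of tuning-curve data frames (or a
#'   manifest CSV path); when `NULL` a synthetic batch is generated.
#' @param n_synth Number of synthetic curves when generating.
#' @param noise_sd Synthetic measurement-noise sd.
#' @param fit A [fit_config()] (its seed is overridden by the stage seed).
#' @param n_neurons Library size.
#' @param sweep_lambda Library sweep wavelengths.
#' @param dpgmm_runs Repeated Dirichlet-process runs for cluster counting.
#' @param k_range Silhouette-scan cluster counts.
#' @param sensitivity_csv Optional receptor-sensitivity CSV path.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, curves = NULL, n_synth = 22,
                            noise_sd = 0.05, fit = fit_config(),
                            n_neurons = 5500,
                            sweep_lambda = seq(300, 700, by = 10),
                            dpgmm_runs = 100, k_range = 2:20,
                            sensitivity_csv = NULL) {
  structure(list(seed = as.integer(seed), curves = curves,
                 n_synth = n_synth, noise_sd = noise_sd, fit = fit,
                 n_neurons = n_neurons, sweep_lambda = sweep_lambda,
                 dpgmm_runs = dpgmm_runs, k_range = k_range,
                 sensitivity_csv = sensitivity_csv),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(synth = 11L, fit = 23L, weights = 37L, library = 53L,
               curves = 71L, perception = 89L)
  config$seed * 100L + offsets[[stage]]
}

# Polynomial rolling hash (mod 2^31 - 1) of the serialised config, reported
# as 8 hex digits; identifies the config that produced a set of outputs.
config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(config, function(x)
    if (is.function(x)) "<function>" else x), auto_unbox = TRUE, force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on synthetic or supplied curves:
#' (1) obtain tuning curves, (2) fit every curve, (3) PCA and repeated
#' Dirichlet-process clustering of the fitted weights, (4) generate the
#' randomly wired neuron library, (5) cluster the library curves
#' (Dirichlet process and k-means silhouette scan) and tabulate the
#' peak/trough histogram, (6) perceptual-distance analyses. Writes
#' plain-text outputs and a run manifest to `out_dir`; identical configs
#' give identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips writing.
#' @param quiet Suppress stage messages.
#' @return A `pipeline_result` list with each stage's outputs and the run
#'   `manifest`.
#' @export
run_colour_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                                quiet = FALSE) {
  say <- function(...) if (!quiet) message("[beevision] ", ...)
  t0 <- Sys.time()
  receptors <- if (is.null(config$sensitivity_csv)) honeybee_sensitivities()
               else read_sensitivities(config$sensitivity_csv)

  say("stage 1/6: tuning curves")
  batch <- NULL
  if (is.null(config$curves)) {
    batch <- make_batch(config$n_synth, seed = stage_seed(config, "synth"),
                        noise_sd = config$noise_sd, receptors = receptors)
    curves <- batch$curves
  } else if (is.character(config$curves)) {
    curves <- read_curve_batch(config$curves)
  } else curves <- config$curves
  if (length(curves) == 0) stop("no input curves")

  say("stage 2/6: fitting ", length(curves), " curves")
  fitcfg <- config$fit
  fitcfg$seed <- stage_seed(config, "fit")
  fits <- fit_tuning_batch(curves, receptors, fitcfg)

  say("stage 3/6: weight-cloud structure")
  W <- as.matrix(fits$summary[, c("w_S", "w_M", "w_L")])
  pca <- pca_weights(W)
  wcount <- dpgmm_cluster_count(W, n_runs = config$dpgmm_runs,
                                seed = stage_seed(config, "weights"))

  say("stage 4/6: library of ", config$n_neurons, " random neurons")
  lib <- generate_library(
    library_config(config$n_neurons, seed = stage_seed(config, "library")),
    receptors, config$sweep_lambda)
  hist <- extrema_histogram(lib)

  say("stage 5/6: library clustering")
  ccount <- dpgmm_cluster_count(lib$curves, n_runs = config$dpgmm_runs,
                                seed = stage_seed(config, "curves"))
  scan <- kmeans_silhouette_scan(lib$curves, config$k_range,
                                 seed = stage_seed(config, "curves"))

  say("stage 6/6: perceptual distances")
  sw <- monochromatic_sweep(receptors, config$sweep_lambda)
  d_ens <- ensemble_distance(lib)
  d_rec <- receptor_distance(sw)
  d_opp <- opponent_distance(sw)
  perception <- list(
    ensemble = d_ens, receptor = d_rec, opponent = d_opp,
    monotonicity = c(ensemble = monotonicity_statistic(d_ens),
                     receptor = monotonicity_statistic(d_rec),
                     opponent = monotonicity_statistic(d_opp)),
    region_means = c(blue = region_mean_distance(d_ens, 400, 480),
                     yellow = region_mean_distance(d_ens, 520, 600)))

  manifest <- list(
    config_hash = config_hash(config), seed = config$seed,
    stage_seeds = sapply(c("synth", "fit", "weights", "library", "curves",
                           "perception"), stage_seed, config = config),
    n_curves = length(curves), n_neurons = config$n_neurons,
    r_squared_range = range(fits$summary$r_squared),
    pca_two_component_variance = sum(pca$variance_explained[1:2]),
    weight_clusters_mean = wcount$mean,
    curve_clusters_mean = ccount$mean, curve_clusters_sd = ccount$sd,
    best_k = scan$k[which.max(scan$silhouette)],
    monotonicity = perception$monotonicity,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(batch)) write_batch(batch, file.path(out_dir, "synth"))
    utils::write.table(fits$summary, file.path(out_dir, "fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_library(lib, file.path(out_dir, "library"))
    utils::write.table(
      data.frame(k = scan$k, silhouette = scan$silhouette),
      file.path(out_dir, "silhouette.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
    utils::write.table(hist, file.path(out_dir, "extrema.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_distance_matrix(d_ens, file.path(out_dir, "distance_ensemble.tsv"))
    write_distance_matrix(d_rec, file.path(out_dir, "distance_receptor.tsv"))
    write_distance_matrix(d_opp, file.path(out_dir, "distance_opponent.tsv"))
    jsonlite::write_json(
      list(weight_clusters = wcount[c("mean", "sd", "counts")],
           curve_clusters = ccount[c("mean", "sd", "counts")]),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(curves = curves, batch = batch, fits = fits, pca = pca,
                 weight_clusters = wcount, library = lib,
                 extrema = hist, curve_clusters = ccount,
                 silhouette = scan, perception = perception,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("beevision pipeline run (config ", m$config_hash, ")\n", sep = "")
  cat("  curves fitted: ", m$n_curves, "; R-squared ",
      round(m$r_squared_range[1], 3), "-", round(m$r_squared_range[2], 3),
      "\n", sep = "")
  cat("  weight PCA top-2 variance: ",
      round(100 * m$pca_two_component_variance, 1), "%; weight clusters ",
      round(m$weight_clusters_mean, 2), "\n", sep = "")
  cat("  library: ", m$n_neurons, " neurons; curve clusters ",
      round(m$curve_clusters_mean, 2), " +/- ",
      round(m$curve_clusters_sd, 2), "; best k ", m$best_k, "\n", sep = "")
  cat("  monotonicity (ensemble/receptor/opponent): ",
      paste(round(m$monotonicity, 3), collapse = " / "), "\n", sep = "")
  invisible(x)
}
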