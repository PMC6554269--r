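#' Truncated Dirichlet-process Gaussian mixture
#'
#' Fits a truncated stick-breaking Dirichlet-process mixture of full-
#' covariance Gaussians by mean-field variational inference. Priors follow
#' common practice: stick concentration `1/max_components`, mean prior at
#' the data mean with precision 1, Wishart degrees of freedom equal to the
#' dimension, covariance prior equal to the empirical covariance.
#' Responsibilities are initialised from a seeded k-means partition.
#'
#' @param X Numeric matrix (rows = observations).
#' @param max_components Truncation level K (default 30).
#' @param weight_concentration Stick-breaking concentration prior.
#' @param occupancy_threshold Mixing-weight threshold above which a
#'   component counts as occupied (default `1/(2 * max_components)`).
#' @param max_iter,tol Variational iteration cap and convergence tolerance
#'   (change in the mean log-normaliser). The defaults are deliberately
#'   strict: component merging is slow, and stopping early inflates the
#'   occupied-component count.
#' @param seed Integer seed (k-means initialisation).
#' @return List with `weights`, `labels`, `n_occupied`, `n_iter`,
#'   `converged`.
#' @export
dpgmm <- function(X, max_components = 30,
                  weight_concentration = 1 / max_components,
                  occupancy_threshold = 1 / (2 * max_components),
                  max_iter = 1000, tol = 1e-7, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in data")
  n <- nrow(X); d <- ncol(X)
  if (n < 3) stop("need at least 3 observations")
  K <- as.integer(min(max_components, n - 1))
  resp <- with_seed(seed, {
    km <- suppressWarnings(stats::kmeans(X, centers = K, iter.max = 10,
                                         nstart = 1))
    r <- matrix(0, n, K)
    r[cbind(seq_len(n), km$cluster)] <- 1
    r
  })
  m0 <- colMeans(X)
  Psi0 <- stats::cov(X)
  # guard a singular empirical covariance (e.g. constant columns)
  Psi0 <- Psi0 + diag(1e-10 + 1e-8 * mean(diag(as.matrix(Psi0))), d)
  fit <- .cpp_dpgmm(X, resp, weight_concentration, 1.0, m0, d,
                    as.matrix(Psi0), as.integer(max_iter), tol)
  fit$n_occupied <- sum(fit$weights > occupancy_threshold)
  fit
}

#' Repeated Dirichlet-process cluster counting
#'
#' Runs [dpgmm()] `n_runs` times from different seeds and summarises the
#' distribution of occupied-component counts.
#'
#' @inheritParams dpgmm
#' @param n_runs Number of repeated runs (default 100).
#' @param seed Base seed; run r uses `seed + r`.
#' @param ... Passed to [dpgmm()].
#' @return A `cluster_count_result`: list with `counts`, `mean`, `sd`,
#'   `n_runs`.
#' @export
dpgmm_cluster_count <- function(X, n_runs = 100, seed = 1L, ...) {
  counts <- vapply(seq_len(n_runs), function(r)
    dpgmm(X, seed = seed + r, ...)$n_occupied, integer(1))
  structure(list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
                 n_runs = n_runs),
            class = "cluster_count_result")
}

#' @export
print.cluster_count_result <- function(x, ...) {
  cat("Occupied Dirichlet-process components over", x$n_runs, "runs:\n")
  cat("  mean", round(x$mean, 2), "+/-", round(x$sd, 2), "s.d.; range",
      min(x$counts), "-", max(x$counts), "\n")
  invisible(x)
}

#' PCA of a presynaptic weight cloud
#'
#' Principal component analysis of fitted (w_S, w_M, w_L) triplets, centred
#' before decomposition, with the loadings of the three receptor axes.
#'
#' @param W Matrix or data frame with columns w_S, w_M, w_L (>= 2 rows).
#' @param normalise If `TRUE`, rows are scaled to unit L1 norm first
#'   (relative-weight framing).
#' @return List with `scores` (first two components), `loadings`,
#'   `variance_explained` (fractions over all three components, summing to
#'   1), and the full `prcomp` object.
#' @export
pca_weights <- function(W, normalise = FALSE) {
  W <- as.matrix(W)
  if (nrow(W) < 2) stop("PCA needs at least 2 rows")
  if (!all(is.finite(W))) stop("non-finite weights")
  if (normalise) W <- W / rowSums(abs(W))
  if (all(apply(W, 2, stats::sd) < 1e-12))
    stop("degenerate weight cloud: all rows identical")
  p <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, 1:2, drop = FALSE], loadings = p$rotation,
       variance_explained = ve, prcomp = p)
}

# Mean silhouette width for an integer clustering, from a precomputed
# distance matrix (cluster::silhouette does the work).
mean_silhouette <- function(d, labels) {
  sil <- cluster::silhouette(labels, dmatrix = as.matrix(d))
  mean(sil[, "sil_width"])
}

#' K-means silhouette scan over curve shapes
#'
#' Clusters (normalised) tuning curves with k-means under the Euclidean
#' metric on the common wavelength grid for each k in `k_range` and reports
#' the mean silhouette coefficient (k = 1 is excluded: silhouettes are
#' undefined there).
#'
#' @param curves Matrix of curves (rows = neurons).
#' @param k_range Integer vector of cluster counts (default 2:20).
#' @param seed Integer seed for the k-means starts.
#' @param normalise Scale each curve to max absolute response 1 first.
#' @param nstart k-means restarts per k.
#' @return A `silhouette_scan`: list with `k`, `silhouette`, `assignments`
#'   (matrix, one column per k).
#' @export
kmeans_silhouette_scan <- function(curves, k_range = 2:20, seed = 1L,
                                   normalise = TRUE, nstart = 3) {
  if (any(k_range < 2)) stop("silhouette is undefined for k < 2")
  X <- normalise_curves(as.matrix(curves), normalise)
  D <- as.matrix(stats::dist(X))
  res <- with_seed(seed, {
    sil <- numeric(length(k_range))
    asg <- matrix(NA_integer_, nrow(X), length(k_range))
    for (i in seq_along(k_range)) {
      km <- suppressWarnings(stats::kmeans(X, centers = k_range[i],
                                           nstart = nstart, iter.max = 50))
      sil[i] <- mean_silhouette(D, km$cluster)
      asg[, i] <- km$cluster
    }
    list(sil = sil, asg = asg)
  })
  structure(list(k = k_range, silhouette = res$sil, assignments = res$asg),
            class = "silhouette_scan")
}

normalise_curves <- function(X, normalise = TRUE) {
  if (!normalise) return(X)
  m <- apply(abs(X), 1, max)
  m[m == 0] <- 1
  X / m
}

#' @export
print.silhouette_scan <- function(x, ...) {
  best <- x$k[which.max(x$silhouette)]
  cat("Silhouette scan over k =", min(x$k), "-", max(x$k),
      "; best k =", best,
      "(mean silhouette", round(max(x$silhouette), 3), ")\n")
  invisible(x)
}

#' Cluster exemplar curves
#'
#' Mean curve and within-cluster dispersion for each assignment label.
#'
#' @param curves Matrix of curves (rows = members).
#' @param assignments Integer cluster labels, one per row.
#' @return List with `exemplars` (one row per cluster), `spread` (root mean
#'   squared deviation from the exemplar, per cluster) and `sizes`.
#' @export
cluster_exemplars <- function(curves, assignments) {
  curves <- as.matrix(curves)
  stopifnot(nrow(curves) == length(assignments))
  labs <- sort(unique(assignments))
  ex <- t(vapply(labs, function(l)
    colMeans(curves[assignments == l, , drop = FALSE]),
    numeric(ncol(curves))))
  spread <- vapply(labs, function(l) {
    M <- curves[assignments == l, , drop = FALSE]
    sqrt(mean(sweep(M, 2, colMeans(M))^2))
  }, numeric(1))
  rownames(ex) <- labs
  list(exemplars = ex, spread = spread,
       sizes = as.integer(table(factor(assignments, levels = labs))))
}
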