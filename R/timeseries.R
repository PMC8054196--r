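#' Z-score MS1 areas per run
#'
#' Column-wise standard scores `z = (x - mu) / sigma`, one column per MS
#' run (time point), with the population standard deviation (divide by n).
#' A zero-variance column is an error naming the run.
#'
#' @param mat numeric matrix, peptides x runs; dimnames preserved.
#' @return matrix of z-scores with attribute `state = "zscored"`.
#' @export
zscore_per_run <- function(mat) {
  mat <- as.matrix(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma == 0) {
      run <- if (!is.null(colnames(mat))) colnames(mat)[j] else j
      stop(sprintf("zscore_per_run: zero variance in run '%s'", run))
    }
    out[, j] <- (x - mu) / sigma
  }
  attr(out, "state") <- "zscored"
  out
}

#' Reference trajectories to the first time point
#'
#' Subtracts the median z-score of the first time-point column — a single
#' scalar — from every cell, so all trajectories are expressed relative to
#' the baseline acquisition. Between-trajectory differences at each time
#' point are preserved (global shift).
#'
#' @param mat z-scored matrix (first column = first time point).
#' @return baselined matrix with attribute `state = "baselined"`.
#' @export
baseline_reference <- function(mat) {
  if (ncol(mat) < 1L) stop("baseline_reference: no first time point")
  out <- mat - stats::median(mat[, 1])
  attr(out, "state") <- "baselined"
  out
}

#' K-means clustering of MS1 trajectories
#'
#' Euclidean k-means on the trajectory row-vectors, best of `n_init`
#' random initializations by total within-cluster sum of squares
#' (inertia); deterministic for a fixed seed.
#'
#' @param mat baselined trajectory matrix (rows = peptides).
#' @param k number of clusters (the published analysis uses six).
#' @param n_init random restarts.
#' @param seed RNG seed.
#' @return list (`TrajectoryClustering`): k, assignments, centroids,
#'   inertia, seed.
#' @export
cluster_trajectories <- function(mat, k = 6L, n_init = 10L, seed = 1L) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("cluster_trajectories: k exceeds row count")
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = n_init, iter.max = 100L)
  list(k = k, assignments = km$cluster, centroids = km$centers,
       inertia = km$tot.withinss, seed = seed)
}
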