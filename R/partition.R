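#' Number of clusters from the sample size
#'
#' The cluster count targets a fixed average cluster size:
#' \eqn{M = \lceil n / 50 \rceil} for \eqn{n \le 200} and
#' \eqn{M = \lceil n / 80 \rceil} for larger samples, so each cluster holds
#' roughly 50 (small samples) or 80 (large samples) points — enough for a
#' stable local HSIC estimate while keeping the z-values within a cluster
#' close.
#'
#' @param n Sample size, n >= 2.
#' @param avg_cluster_size_small Target average size for n <= threshold.
#' @param avg_cluster_size_large Target average size for n > threshold.
#' @param threshold Sample-size cutoff between the two regimes.
#' @return A positive integer cluster count in [1, n].
#' @examples
#' choose_cluster_count(100)  # 2
#' choose_cluster_count(400)  # 5
#' @export
choose_cluster_count <- function(n, avg_cluster_size_small = 50L,
                                 avg_cluster_size_large = 80L,
                                 threshold = 200L) {
  n <- .stop_if_not_count(n, "n", min = 2L)
  .stop_if_not_count(avg_cluster_size_small, "avg_cluster_size_small")
  .stop_if_not_count(avg_cluster_size_large, "avg_cluster_size_large")
  avg <- if (n <= threshold) avg_cluster_size_small else avg_cluster_size_large
  m <- as.integer(ceiling(n / avg))
  max(1L, min(m, n))
}

#' Partition samples by k-means on the conditioning block
#'
#' Clusters the n rows of \code{z} into \code{m} groups with seeded,
#' multi-restart k-means (Hartigan-Wong, \code{\link[stats]{kmeans}}).
#' Only the z-block enters the clustering; x and y play no role. If the
#' data contain fewer distinct rows than \code{m}, the cluster count is
#' reduced to the number of distinct rows with a warning. A cluster left
#' empty by a degenerate fit is repaired by moving the point farthest from
#' its assigned centroid into the empty cluster.
#'
#' @param z Numeric vector or n x d matrix of conditioning values.
#' @param m Number of clusters, 1 <= m <= n.
#' @param seed Optional integer; fixes the k-means restarts so repeated
#'   calls return identical labels.
#' @param nstart Number of random restarts (default 10).
#' @param scale_z Standardise columns of z to unit variance before
#'   clustering (default off; the raw coordinates are used).
#' @return An object of class \code{"ci_partition"}: a list with integer
#'   \code{labels} in 1..m, the cluster count \code{m} and the
#'   \code{sizes} vector (sums to n, no empty cluster).
#' @export
cluster_z <- function(z, m, seed = NULL, nstart = 10L, scale_z = FALSE) {
  z <- .as_block(z, "z")
  n <- nrow(z)
  m <- .stop_if_not_count(m, "m", min = 1L)
  if (m > n) stop("'m' must not exceed the number of samples", call. = FALSE)
  if (isTRUE(scale_z)) {
    sds <- apply(z, 2L, stats::sd)
    sds[!is.finite(sds) | sds == 0] <- 1
    z <- sweep(z, 2L, sds, "/")
  }
  if (m == 1L) {
    labels <- rep.int(1L, n)
  } else if (m == n) {
    labels <- seq_len(n)       # forced: every cluster a singleton
  } else {
    n_distinct <- nrow(unique(z))
    if (n_distinct < m) {
      warning(sprintf("only %d distinct z rows; reducing m from %d", n_distinct, m),
              call. = FALSE)
      m <- n_distinct
    }
    if (m == 1L) {
      labels <- rep.int(1L, n)
    } else {
      km <- with_seed(seed,
                      stats::kmeans(z, centers = m, nstart = nstart, iter.max = 100L))
      labels <- as.integer(km$cluster)
      labels <- .repair_empty_clusters(z, labels, m, km$centers)
    }
  }
  sizes <- tabulate(labels, nbins = m)
  structure(list(labels = labels, m = m, sizes = sizes), class = "ci_partition")
}

# Move the globally farthest-from-centroid point into each empty cluster.
# stats::kmeans essentially never returns empty clusters, but degenerate
# inputs are repaired rather than rejected.
.repair_empty_clusters <- function(z, labels, m, centers) {
  sizes <- tabulate(labels, nbins = m)
  while (any(sizes == 0L)) {
    empty <- which(sizes == 0L)[1L]
    d <- rowSums((z - centers[labels, , drop = FALSE])^2)
    d[sizes[labels] <= 1L] <- -Inf   # never empty another cluster
    mover <- which.max(d)
    labels[mover] <- empty
    sizes <- tabulate(labels, nbins = m)
  }
  labels
}

#' @export
print.ci_partition <- function(x, ...) {
  cat(sprintf("k-means partition of %d samples into %d cluster(s)\n",
              sum(x$sizes), x$m))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}
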