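#' Construct a conditional-independence sample
#'
#' Bundles the observed x, y and z blocks into a validated sample object.
#' Each block may be a numeric vector (one column), matrix or data frame;
#' all three must share the same number of rows n >= 2 and contain only
#' finite values.
#'
#' @param x,y The two blocks whose conditional dependence is under test.
#' @param z The conditioning block (may be multivariate).
#' @return An object of class \code{"ci_sample"}: a list with matrix
#'   components \code{x}, \code{y}, \code{z} and the sample size \code{n}.
#' @export
ci_sample <- function(x, y, z) {
  x <- .as_block(x, "x")
  y <- .as_block(y, "y")
  z <- .as_block(z, "z")
  n <- nrow(x)
  if (nrow(y) != n || nrow(z) != n)
    stop("'x', 'y' and 'z' must have the same number of rows", call. = FALSE)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  structure(list(x = x, y = y, z = z, n = n), class = "ci_sample")
}

#' @export
print.ci_sample <- function(x, ...) {
  cat(sprintf("ci_sample: n = %d, d_x = %d, d_y = %d, d_z = %d\n",
              x$n, ncol(x$x), ncol(x$y), ncol(x$z)))
  invisible(x)
}

#' Local HSIC of one cluster
#'
#' Restricts x and y to the member rows, picks bandwidths under the given
#' kernel configuration (per-cluster median heuristic by default), builds
#' the two Gaussian Gram matrices and evaluates the biased HSIC estimator
#' with n replaced by the cluster size. A cluster of size 1 carries no
#' dependence information and returns 0.
#'
#' @param sample A \code{\link{ci_sample}}.
#' @param member_indices Integer indices of the cluster's rows.
#' @param kconf A \code{\link{kernel_config}}.
#' @return A list with \code{value} (non-negative HSIC), \code{sigma_x}
#'   and \code{sigma_y} (NA for a size-1 cluster).
#' @export
local_hsic <- function(sample, member_indices, kconf = kernel_config()) {
  stopifnot(inherits(sample, "ci_sample"))
  if (length(member_indices) < 1L)
    stop("'member_indices' must be non-empty", call. = FALSE)
  member_indices <- as.integer(member_indices)
  if (any(member_indices < 1L | member_indices > sample$n))
    stop("'member_indices' out of range", call. = FALSE)
  if (length(member_indices) == 1L)
    return(list(value = 0, sigma_x = NA_real_, sigma_y = NA_real_))
  xm <- sample$x[member_indices, , drop = FALSE]
  ym <- sample$y[member_indices, , drop = FALSE]
  s <- .cluster_bandwidths(xm, ym, kconf)
  v <- .hsic_from_grams(exp(-.sqdist(xm) / s[1L]), exp(-.sqdist(ym) / s[2L]))
  list(value = v, sigma_x = s[1L], sigma_y = s[2L])
}

#' Bundled HSIC test statistic
#'
#' Computes the statistic \eqn{T = \sum_{m=1}^{M} \widehat{HSIC}_{C_m}(X, Y)}:
#' the sum over clusters of the biased HSIC estimate of (x, y) restricted
#' to each cluster. The conditioning values z enter only through the
#' partition; the statistic itself never touches them. Clusters are
#' visited in label order and the sum is accumulated in that fixed order.
#'
#' @param sample A \code{\link{ci_sample}}.
#' @param partition A \code{\link{cluster_z}} partition of the same n rows.
#' @param kconf A \code{\link{kernel_config}}.
#' @return An object of class \code{"bhsic_breakdown"}: list with
#'   \code{total}, per-cluster values \code{per_cluster}, the M x 2
#'   \code{bandwidths} matrix (sigma_x, sigma_y) and cluster \code{sizes}.
#' @export
bhsic_statistic <- function(sample, partition, kconf = kernel_config()) {
  stopifnot(inherits(sample, "ci_sample"), inherits(partition, "ci_partition"))
  if (length(partition$labels) != sample$n)
    stop("partition and sample sizes differ", call. = FALSE)
  members <- split(seq_len(sample$n), factor(partition$labels, levels = seq_len(partition$m)))
  if (any(partition$sizes == 1L))
    warning("cluster(s) of size 1 contribute 0 to the statistic", call. = FALSE)
  per <- numeric(partition$m)
  bw <- matrix(NA_real_, partition$m, 2L,
               dimnames = list(NULL, c("sigma_x", "sigma_y")))
  for (m in seq_len(partition$m)) {
    h <- local_hsic(sample, members[[m]], kconf)
    per[m] <- h$value
    bw[m, ] <- c(h$sigma_x, h$sigma_y)
  }
  structure(list(total = sum(per), per_cluster = per, bandwidths = bw,
                 sizes = partition$sizes),
            class = "bhsic_breakdown")
}

# Hot path for the bootstrap loop under fixed observed bandwidths. Because
# the local bootstrap resamples whole rows of the observed x and y, every
# Gram entry of a replicate is an entry of the full-sample kernel matrix;
# these are precomputed once per cluster bandwidth and gathered here.
# Ex/Ey are per-cluster n x n kernel matrices (NULL for size-1 clusters);
# ix/iy are the resampled row indices.
.bhsic_total_pre <- function(Ex, Ey, members, ix, iy) {
  total <- 0
  for (m in seq_along(members)) {
    if (is.null(Ex[[m]])) next
    idx <- members[[m]]
    sx <- ix[idx]
    sy <- iy[idx]
    total <- total + .hsic_from_grams(Ex[[m]][sx, sx], Ey[[m]][sy, sy])
  }
  total
}

# Full-sample kernel matrices at each cluster's bandwidth (NULL where the
# cluster is degenerate, i.e. size 1).
.precompute_cluster_kernels <- function(block, sigmas) {
  d2 <- .sqdist(block)
  lapply(sigmas, function(s) if (is.na(s)) NULL else exp(-d2 / s))
}

# As above but bandwidths recomputed from the (resampled) cluster points.
.bhsic_total_recompute <- function(x, y, members, kconf) {
  total <- 0
  for (idx in members) {
    if (length(idx) < 2L) next
    xm <- x[idx, , drop = FALSE]
    ym <- y[idx, , drop = FALSE]
    s <- .cluster_bandwidths(xm, ym, kconf)
    total <- total + .hsic_from_grams(exp(-.sqdist(xm) / s[1L]),
                                      exp(-.sqdist(ym) / s[2L]))
  }
  total
}
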