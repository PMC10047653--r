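#' Monte-Carlo p-value from bootstrap statistics
#'
#' The p-value is the fraction of null statistics at least as large as the
#' observed one, ties counted in favour of the null:
#' \eqn{p = (1/K)\sum_k 1\{T_k \ge T\}}. No add-one correction is applied
#' by default; set \code{correction = TRUE} for the
#' \eqn{(1 + \#\{T_k \ge T\})/(K + 1)} variant, which is guaranteed valid
#' at any finite K.
#'
#' @param observed Observed statistic T.
#' @param null_stats Non-empty numeric vector of bootstrap statistics.
#' @param correction Apply the add-one correction (default FALSE).
#' @return p-value in [0, 1].
#' @export
compute_p_value <- function(observed, null_stats, correction = FALSE) {
  if (length(null_stats) < 1L)
    stop("'null_stats' must be non-empty", call. = FALSE)
  if (!is.numeric(observed) || length(observed) != 1L || !is.finite(observed))
    stop("'observed' must be a single finite number", call. = FALSE)
  cnt <- sum(null_stats >= observed)
  if (correction) (1 + cnt) / (length(null_stats) + 1) else cnt / length(null_stats)
}

#' Bundled-HSIC conditional independence test
#'
#' Tests H0: X independent of Y given Z. The conditioning values are
#' partitioned once by k-means into M clusters (M from
#' \code{\link{choose_cluster_count}} unless \code{m} is given); the test
#' statistic is the sum over clusters of the biased HSIC of (x, y)
#' restricted to each cluster, with per-cluster median-heuristic
#' bandwidths. The null distribution is generated by the local bootstrap
#' (\code{\link{build_plan}}, \code{\link{draw_null_sample}}): z stays
#' fixed, x and y are resampled independently from kernel-weighted
#' nearest-neighbour conditionals, and the statistic is recomputed on each
#' of \code{n_bootstrap} replicates. Since the bootstrap leaves z
#' unchanged, the partition and the sampling plan are built once and
#' reused for every replicate.
#'
#' Under the default \code{bandwidth_refresh = "reuse_observed"} the
#' per-cluster bandwidths found on the observed data are reused on every
#' replicate, so the identical statistic functional is applied throughout;
#' \code{"recompute_per_replicate"} re-runs the median heuristic on each
#' resampled cluster instead.
#'
#' @param x,y Observed blocks under test (vector, matrix or data frame),
#'   or a \code{\link{ci_sample}} as \code{x} with \code{y}, \code{z}
#'   missing.
#' @param z Conditioning block.
#' @param alpha Significance level in (0, 1); H0 is rejected when
#'   p < alpha (strict).
#' @param n_bootstrap Number K of bootstrap replicates (default 1000).
#' @param k_nn Neighbourhood size of the local bootstrap (default 10).
#' @param m Optional cluster count override.
#' @param avg_cluster_size_small,avg_cluster_size_large,size_threshold
#'   Parameters of the cluster-count rule (defaults 50 / 80 / 200).
#' @param kernel A \code{\link{kernel_config}}.
#' @param seed Optional integer seed; fixes clustering restarts and all
#'   bootstrap draws, making the result fully reproducible.
#' @param bandwidth_refresh \code{"reuse_observed"} (default) or
#'   \code{"recompute_per_replicate"}.
#' @param p_value_correction Use the add-one Monte-Carlo correction
#'   (default FALSE).
#' @param nstart,scale_z Passed to \code{\link{cluster_z}}.
#' @return An object of classes \code{"bhsic"} and \code{"htest"}: the
#'   observed \code{statistic}, \code{p.value}, logical \code{reject},
#'   the vector of \code{null_statistics}, the \code{partition}, the
#'   per-cluster \code{breakdown}, the bootstrap \code{plan} and a
#'   \code{config} echo including the seed.
#' @examples
#' s <- simulate_ci_data("linear", n = 120, d_z = 1, c = 0, seed = 7)
#' bhsic_test(s, n_bootstrap = 100, seed = 1)
#' @export
bhsic_test <- function(x, y, z, alpha = 0.05, n_bootstrap = 1000L, k_nn = 10L,
                       m = NULL, avg_cluster_size_small = 50L,
                       avg_cluster_size_large = 80L, size_threshold = 200L,
                       kernel = kernel_config(), seed = NULL,
                       bandwidth_refresh = c("reuse_observed",
                                             "recompute_per_replicate"),
                       p_value_correction = FALSE,
                       nstart = 10L, scale_z = FALSE) {
  if (inherits(x, "ci_sample") && missing(y) && missing(z)) {
    dname <- deparse1(substitute(x))
    sample <- x
  } else {
    dname <- paste(deparse1(substitute(x)), "and", deparse1(substitute(y)),
                   "given", deparse1(substitute(z)))
    sample <- ci_sample(x, y, z)
  }
  bandwidth_refresh <- match.arg(bandwidth_refresh)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  n_bootstrap <- .stop_if_not_count(n_bootstrap, "n_bootstrap", min = 1L)
  if (sample$n < 4L)
    warning("n < 4: the test is unreliable at this sample size", call. = FALSE)
  if (is.null(m))
    m <- choose_cluster_count(sample$n, avg_cluster_size_small,
                              avg_cluster_size_large, size_threshold)

  res <- with_seed(seed, {
    part <- cluster_z(sample$z, m, seed = NULL, nstart = nstart,
                      scale_z = scale_z)
    bd <- bhsic_statistic(sample, part, kernel)
    plan <- build_plan(sample$z, k_nn = k_nn)
    members <- split(seq_len(sample$n),
                     factor(part$labels, levels = seq_len(part$m)))
    reuse <- bandwidth_refresh == "reuse_observed"
    if (reuse) {
      Ex <- .precompute_cluster_kernels(sample$x, bd$bandwidths[, 1L])
      Ey <- .precompute_cluster_kernels(sample$y, bd$bandwidths[, 2L])
    }
    nulls <- numeric(n_bootstrap)
    for (k in seq_len(n_bootstrap)) {
      ix <- .draw_indices(plan)
      iy <- .draw_indices(plan)
      nulls[k] <- if (reuse)
        .bhsic_total_pre(Ex, Ey, members, ix, iy)
      else
        .bhsic_total_recompute(sample$x[ix, , drop = FALSE],
                               sample$y[iy, , drop = FALSE], members, kernel)
    }
    list(part = part, bd = bd, plan = plan, nulls = nulls)
  })

  if (!is.finite(res$bd$total) || !all(is.finite(res$nulls)))
    stop("non-finite statistic encountered; check the input data", call. = FALSE)
  p <- compute_p_value(res$bd$total, res$nulls, correction = p_value_correction)

  structure(list(
    statistic = c(T = res$bd$total),
    p.value = p,
    reject = p < alpha,
    alpha = alpha,
    null_statistics = res$nulls,
    partition = res$part,
    breakdown = res$bd,
    plan = res$plan,
    method = "Bundled HSIC conditional independence test (local bootstrap)",
    data.name = dname,
    alternative = "X and Y are conditionally dependent given Z",
    config = list(alpha = alpha, n_bootstrap = n_bootstrap, k_nn = k_nn,
                  m = res$part$m,
                  avg_cluster_size_small = avg_cluster_size_small,
                  avg_cluster_size_large = avg_cluster_size_large,
                  size_threshold = size_threshold, kernel = kernel,
                  bandwidth_refresh = bandwidth_refresh,
                  p_value_correction = p_value_correction,
                  nstart = nstart, scale_z = scale_z, seed = seed)
  ), class = c("bhsic", "htest"))
}

#' @export
print.bhsic <- function(x, digits = 4L, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("data:  ", x$data.name, "\n", sep = "")
  cat(sprintf("T = %s, clusters M = %d, bootstrap K = %d, p-value %s %s\n",
              format(unname(x$statistic), digits = digits), x$config$m,
              x$config$n_bootstrap,
              if (x$p.value < .Machine$double.eps) "<" else "=",
              format(max(x$p.value, .Machine$double.eps), digits = digits)))
  cat("alternative hypothesis: ", x$alternative, "\n", sep = "")
  cat(sprintf("decision at alpha = %s: %s H0 (X indep. Y | Z)\n",
              format(x$alpha), if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' @export
summary.bhsic <- function(object, ...) {
  print(object)
  bd <- object$breakdown
  tab <- data.frame(cluster = seq_along(bd$per_cluster),
                    size = bd$sizes,
                    hsic = bd$per_cluster,
                    sigma_x = bd$bandwidths[, 1L],
                    sigma_y = bd$bandwidths[, 2L])
  cat("\nPer-cluster breakdown:\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' Histogram of the bootstrap null distribution
#'
#' Plots the bootstrap statistics with the observed statistic marked; the
#' p-value is the mass to the right of the line.
#'
#' @param x A \code{\link{bhsic_test}} result.
#' @param ... Passed to \code{\link[graphics]{hist}}.
#' @export
plot.bhsic <- function(x, ...) {
  graphics::hist(x$null_statistics, breaks = 30,
                 main = "Local-bootstrap null distribution",
                 xlab = "bootstrap statistic T*",
                 xlim = range(c(x$null_statistics, x$statistic)), ...)
  graphics::abline(v = x$statistic, col = 2, lwd = 2)
  graphics::legend("topright", legend = sprintf("observed T (p = %.3g)", x$p.value),
                   col = 2, lwd = 2, bty = "n")
  invisible(x)
}
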