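#' Build the local-bootstrap sampling plan
#'
#' For every sample i the candidate set is the \code{k_nn} nearest points
#' to z_i in Euclidean distance, the point itself included (its
#' self-distance 0 ranks first; ties are broken by original index). The
#' local bandwidth \eqn{\gamma_i} is the squared Euclidean distance from
#' z_i to its k_nn-th nearest candidate. Sampling weights over the
#' candidate set follow the Nadaraya-Watson form
#' \eqn{w_j \propto \exp(-\|z_j - z_i\|^2 / \gamma_i)}, renormalised to
#' sum to 1.
#'
#' Degenerate geometry: if the k_nn-th candidate distance is 0 (duplicated
#' z values), \eqn{\gamma_i} falls back to the smallest strictly positive
#' candidate distance; if all candidate distances are 0 the weights are
#' uniform and \eqn{\gamma_i = 1}.
#'
#' @param z Numeric vector or n x d matrix of conditioning values, n >= 2.
#' @param k_nn Neighbourhood size (default 10); values above n are clamped
#'   to n with a warning.
#' @param exclude_self Logical; drop i from its own candidate set (default
#'   \code{FALSE}: the observed point is its own nearest neighbour and
#'   keeps the largest weight).
#' @return An object of class \code{"bootstrap_plan"}: candidate index
#'   matrix (n x k_nn), \code{gamma} vector, weight matrix and cached
#'   cumulative weights.
#' @export
build_plan <- function(z, k_nn = 10L, exclude_self = FALSE) {
  z <- .as_block(z, "z")
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  k_nn <- .stop_if_not_count(k_nn, "k_nn", min = 1L)
  n_avail <- if (exclude_self) n - 1L else n
  if (k_nn > n_avail) {
    warning(sprintf("k_nn = %d exceeds the %d available neighbours; clamping",
                    k_nn, n_avail), call. = FALSE)
    k_nn <- n_avail
  }
  d2 <- .sqdist(z)
  idx <- seq_len(n)
  cand <- matrix(0L, n, k_nn)
  gamma <- numeric(n)
  w <- matrix(0, n, k_nn)
  for (i in idx) {
    di <- d2[i, ]
    if (exclude_self) di[i] <- Inf
    ord <- order(di, idx)[seq_len(k_nn)]   # distance, then original index
    cd <- di[ord]
    g <- cd[k_nn]
    if (g <= 0) {
      pos <- cd[cd > 0]
      g <- if (length(pos)) min(pos) else NA_real_
    }
    if (is.na(g)) {              # all candidates coincide with z_i
      g <- 1
      wi <- rep.int(1 / k_nn, k_nn)
    } else {
      wi <- exp(-cd / g)
      wi <- wi / sum(wi)
    }
    cand[i, ] <- ord
    gamma[i] <- g
    w[i, ] <- wi
  }
  cw <- if (k_nn == 1L) matrix(1, n, 1L) else t(apply(w, 1L, cumsum))
  cw[, k_nn] <- 1                # guard against round-off at the top bin
  structure(list(candidates = cand, gamma = gamma, weights = w,
                 cum_weights = cw, k_nn = k_nn, n = n),
            class = "bootstrap_plan")
}

#' Bootstrap weight kernel
#'
#' The unnormalised sampling weight of a neighbour at displacement
#' \code{delta} under local bandwidth \code{gamma}:
#' \eqn{\exp(-\|\delta\|^2 / \gamma)} — the same Gaussian convention as
#' the Gram-matrix kernel.
#'
#' @param delta Numeric displacement vector z_j - z*.
#' @param gamma Strictly positive local bandwidth (squared-distance scale).
#' @return A value in (0, 1].
#' @export
weight_kernel <- function(delta, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single, strictly positive, finite number", call. = FALSE)
  if (!all(is.finite(delta))) stop("'delta' must be finite", call. = FALSE)
  exp(-sum(delta^2) / gamma)
}

# One set of n candidate-index draws from the plan (inverse-CDF on the
# cached cumulative weights; vectorised over i).
.draw_indices <- function(plan) {
  u <- stats::runif(plan$n)
  pos <- rowSums(u > plan$cum_weights) + 1L
  plan$candidates[cbind(seq_len(plan$n), pos)]
}

#' Draw one sample from the conditional-independence null
#'
#' Implements the local bootstrap: z is kept fixed (the returned z-block
#' is the input z-block, bitwise), and for each i the rows x*_i and y*_i
#' are drawn as two independent picks from i's candidate weight vector.
#' Using the same conditional weights but independent randomness preserves
#' the (X, Z) and (Y, Z) dependence while breaking any direct X-Y
#' dependence, so repeated draws emulate H0: X independent of Y given Z.
#'
#' @param sample A \code{\link{ci_sample}}.
#' @param plan A \code{\link{build_plan}} built from \code{sample$z}.
#' @param seed Optional integer seed for the draws.
#' @return A new \code{\link{ci_sample}} of the same size.
#' @export
draw_null_sample <- function(sample, plan, seed = NULL) {
  stopifnot(inherits(sample, "ci_sample"), inherits(plan, "bootstrap_plan"))
  if (plan$n != sample$n)
    stop("plan and sample sizes differ", call. = FALSE)
  ids <- with_seed(seed, list(ix = .draw_indices(plan), iy = .draw_indices(plan)))
  structure(list(x = sample$x[ids$ix, , drop = FALSE],
                 y = sample$y[ids$iy, , drop = FALSE],
                 z = sample$z,
                 n = sample$n),
            class = "ci_sample")
}
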