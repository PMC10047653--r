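# Independent oracles and shared helpers for the test suite.

# Brute-force Gaussian Gram matrix: elementwise double loop.
naive_gram <- function(p, sigma) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 1) else as.matrix(p)
  n <- nrow(p)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- exp(-sum((p[i, ] - p[j, ])^2) / sigma)
  K
}

# Naive O(n^3) biased HSIC: build H explicitly and take the trace of the
# dense product. Deliberately independent of the package's centering path.
naive_hsic <- function(Kx, Ky) {
  n <- nrow(Kx)
  H <- diag(n) - matrix(1 / n, n, n)
  sum(diag(Kx %*% H %*% Ky %*% H)) / n^2
}

# Within-cluster sum of squared distances to centroids (k-means objective).
wcss <- function(z, labels) {
  z <- if (is.null(dim(z))) matrix(z, ncol = 1) else as.matrix(z)
  total <- 0
  for (g in unique(labels)) {
    rows <- z[labels == g, , drop = FALSE]
    ctr <- colMeans(rows)
    total <- total + sum(sweep(rows, 2, ctr)^2)
  }
  total
}

# Three binomial standard errors around rate p0 at r replicates: the
# Monte-Carlo slack used for every rate assertion in this suite.
binom_tol <- function(p0, r) 3 * sqrt(p0 * (1 - p0) / r)
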