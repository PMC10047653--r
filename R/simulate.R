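# Post-nonlinear link functions for the second simulation model.
.g_set <- list(
  identity = function(u) u,
  square   = function(u) u^2,
  cube     = function(u) u^3,
  tanh     = function(u) tanh(u),
  gauss    = function(u) exp(-u^2)
)

#' Simulate data for the conditional-independence benchmarks
#'
#' Generates one dataset from either of two structural models. In both,
#' the d_z conditioning columns are i.i.d. standard Gaussian and the
#' noises e1, e2, eb are independent standard Gaussian per sample. The
#' confounder strength \code{c} controls the truth: \code{c = 0} gives
#' H0 (X independent of Y given Z), \code{c = 1} a shared hidden
#' confounder eb, i.e. conditional dependence.
#'
#' \describe{
#'   \item{linear}{x = sum_i alpha_i z_i + c eb + e1,
#'     y = sum_i beta_i z_i + c eb + e2, with alpha_i, beta_i drawn once
#'     per dataset from Uniform(-0.5/d_z, 0.5/d_z).}
#'   \item{postnonlinear}{x = g1(sum_i z_i + c eb + e1),
#'     y = g2(sum_i z_i + c eb + e2), with g1, g2 drawn independently and
#'     uniformly from \{identity, square, cube, tanh, exp(-u^2)\}.}
#' }
#'
#' @param model \code{"linear"} or \code{"postnonlinear"}.
#' @param n Sample size, n >= 2.
#' @param d_z Conditioning dimension, >= 1.
#' @param c Confounding strength (0 under H0, 1 under H1; any real
#'   accepted).
#' @param coefs Optional list with numeric vectors \code{alpha},
#'   \code{beta} of length d_z, fixing the linear coefficients instead of
#'   drawing them.
#' @param g_funs Optional character pair naming the links for the
#'   post-nonlinear model (subset of
#'   \code{c("identity", "square", "cube", "tanh", "gauss")}).
#' @param seed Optional integer seed; the same seed reproduces the
#'   dataset exactly.
#' @return A \code{\link{ci_sample}} with attributes \code{model},
#'   \code{c}, \code{coefs} (linear) or \code{g_names} (post-nonlinear).
#' @examples
#' s <- simulate_ci_data("postnonlinear", n = 200, d_z = 1, c = 1, seed = 3)
#' attr(s, "g_names")
#' @export
simulate_ci_data <- function(model = c("linear", "postnonlinear"), n,
                             d_z = 1L, c = 0, coefs = NULL, g_funs = NULL,
                             seed = NULL) {
  model <- match.arg(model)
  n <- .stop_if_not_count(n, "n", min = 2L)
  d_z <- .stop_if_not_count(d_z, "d_z", min = 1L)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c))
    stop("'c' must be a single finite number", call. = FALSE)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * d_z), n, d_z)
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    eb <- stats::rnorm(n)
    if (model == "linear") {
      if (is.null(coefs)) {
        alpha <- stats::runif(d_z, -0.5 / d_z, 0.5 / d_z)
        beta <- stats::runif(d_z, -0.5 / d_z, 0.5 / d_z)
      } else {
        alpha <- rep_len(as.numeric(coefs$alpha), d_z)
        beta <- rep_len(as.numeric(coefs$beta), d_z)
      }
      x <- drop(z %*% alpha) + c * eb + e1
      y <- drop(z %*% beta) + c * eb + e2
      out <- ci_sample(x, y, z)
      attr(out, "coefs") <- list(alpha = alpha, beta = beta)
    } else {
      gn <- if (is.null(g_funs)) sample(names(.g_set), 2L, replace = TRUE)
            else rep_len(match.arg(g_funs, names(.g_set), several.ok = TRUE), 2L)
      s <- rowSums(z)
      x <- .g_set[[gn[1L]]](s + c * eb + e1)
      y <- .g_set[[gn[2L]]](s + c * eb + e2)
      out <- ci_sample(x, y, z)
      attr(out, "g_names") <- gn
    }
    attr(out, "model") <- model
    attr(out, "c") <- c
    out
  })
}

#' Type-I / Type-II error experiment
#'
#' Runs \code{replications} independent rounds of
#' \code{\link{simulate_ci_data}} followed by \code{\link{bhsic_test}} and
#' returns the empirical rejection rate. With \code{c = 0} the rejection
#' rate estimates the Type-I error; with \code{c = 1} the Type-II error is
#' one minus the rejection rate. Per-replicate seeds are derived
#' deterministically from \code{seed}, so coefficients and link functions
#' are redrawn for every replicate and the whole experiment reruns
#' identically under the same seed.
#'
#' @param model,n,d_z,c As in \code{\link{simulate_ci_data}}.
#' @param replications Number of independent replicates (>= 1).
#' @param alpha Significance level (default 0.05).
#' @param n_bootstrap Bootstrap repeats per test (default 1000).
#' @param k_nn Neighbourhood size for the local bootstrap.
#' @param m Optional cluster-count override passed to
#'   \code{\link{bhsic_test}}.
#' @param seed Root seed for the whole experiment.
#' @param ... Further arguments to \code{\link{bhsic_test}} (e.g.
#'   \code{bandwidth_refresh}).
#' @return An object of class \code{"ci_experiment"}: rejection rate,
#'   per-replicate p-values, the cluster count used and a config echo.
#' @export
error_rate_experiment <- function(model, n, d_z = 1L, c = 0, replications,
                                  alpha = 0.05, n_bootstrap = 1000L,
                                  k_nn = 10L, m = NULL, seed = NULL, ...) {
  replications <- .stop_if_not_count(replications, "replications", min = 1L)
  seeds <- with_seed(seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       2L * replications), ncol = 2L))
  p_values <- numeric(replications)
  m_used <- NA_integer_
  for (r in seq_len(replications)) {
    dat <- simulate_ci_data(model, n = n, d_z = d_z, c = c,
                            seed = seeds[r, 1L])
    fit <- bhsic_test(dat, alpha = alpha, n_bootstrap = n_bootstrap,
                      k_nn = k_nn, m = m, seed = seeds[r, 2L], ...)
    p_values[r] <- fit$p.value
    if (r == 1L) m_used <- fit$config$m
  }
  structure(list(model = model, n = n, d_z = d_z, c = c,
                 m = m_used, replications = replications,
                 rejection_rate = mean(p_values < alpha),
                 mean_p = mean(p_values), p_values = p_values,
                 alpha = alpha, n_bootstrap = n_bootstrap, k_nn = k_nn,
                 seed = seed),
            class = "ci_experiment")
}

#' @export
print.ci_experiment <- function(x, ...) {
  cat(sprintf("CI test experiment: model = %s, n = %d, d_z = %d, c = %g, M = %s\n",
              x$model, x$n, x$d_z, x$c, format(x$m)))
  cat(sprintf("replications = %d, alpha = %g, K = %d\n",
              x$replications, x$alpha, x$n_bootstrap))
  cat(sprintf("rejection rate = %.3f (mean p = %.3f)\n",
              x$rejection_rate, x$mean_p))
  if (x$c == 0)
    cat(sprintf("=> empirical Type-I error %.3f at nominal %g\n",
                x$rejection_rate, x$alpha))
  else
    cat(sprintf("=> empirical Type-II error %.3f\n", 1 - x$rejection_rate))
  invisible(x)
}

#' Write experiment results as a tidy TSV
#'
#' One row per experiment with columns model, n, d_z, c, M, replications,
#' rejection_rate, mean_p, seed.
#'
#' @param experiments A single \code{\link{error_rate_experiment}} result
#'   or a list of them.
#' @param path Output file path ("" writes to stdout).
#' @return The data frame written, invisibly.
#' @export
write_experiment_tsv <- function(experiments, path) {
  if (inherits(experiments, "ci_experiment")) experiments <- list(experiments)
  rows <- lapply(experiments, function(e)
    data.frame(model = e$model, n = e$n, d_z = e$d_z, c = e$c, M = e$m,
               replications = e$replications,
               rejection_rate = e$rejection_rate, mean_p = e$mean_p,
               seed = if (is.null(e$seed)) NA_integer_ else e$seed))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
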