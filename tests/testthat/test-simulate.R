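test_that("the generators honour their structural contracts", {
  s <- simulate_ci_data("linear", n = 50, d_z = 3, c = 0, seed = 12)
  expect_s3_class(s, "ci_sample")
  expect_identical(dim(s$z), c(50L, 3L))
  expect_identical(attr(s, "model"), "linear")
  expect_length(attr(s, "coefs")$alpha, 3L)
  # same seed, same dataset
  expect_identical(s, simulate_ci_data("linear", n = 50, d_z = 3, c = 0,
                                       seed = 12))

  s2 <- simulate_ci_data("postnonlinear", n = 50, d_z = 2, c = 1, seed = 12)
  expect_length(attr(s2, "g_names"), 2L)
  expect_true(all(attr(s2, "g_names") %in%
                    c("identity", "square", "cube", "tanh", "gauss")))
  expect_error(simulate_ci_data("linear", n = 1), "integer >= 2")
})

test_that("a seed sweep exercises all five post-nonlinear links", {
  seen <- character(0)
  for (seed in 1:40) {
    s <- simulate_ci_data("postnonlinear", n = 2, d_z = 1, c = 0, seed = seed)
    seen <- union(seen, attr(s, "g_names"))
  }
  expect_setequal(seen, c("identity", "square", "cube", "tanh", "gauss"))
})

test_that("the confounder induces the closed-form correlation", {
  # linear model with alpha = beta = 0 and c = 1:
  # var(x) = var(y) = c^2 + 1 = 2, cov(x, y) = c^2 = 1 -> corr 0.5
  s <- simulate_ci_data("linear", n = 10000, d_z = 1, c = 1,
                        coefs = list(alpha = 0, beta = 0), seed = 77)
  expect_equal(cor(s$x, s$y)[1, 1], 0.5, tolerance = 0.03)
  # under c = 0 with zero coefficients x and y are independent draws
  s0 <- simulate_ci_data("linear", n = 10000, d_z = 1, c = 0,
                         coefs = list(alpha = 0, beta = 0), seed = 78)
  expect_lt(abs(cor(s0$x, s0$y)[1, 1]), 0.03)
})

test_that("error_rate_experiment aggregates p-values reproducibly", {
  e <- error_rate_experiment("linear", n = 60, d_z = 1, c = 0,
                             replications = 6, n_bootstrap = 40, seed = 5)
  expect_s3_class(e, "ci_experiment")
  expect_length(e$p_values, 6L)
  expect_identical(e$rejection_rate, mean(e$p_values < e$alpha))
  expect_identical(e,
                   error_rate_experiment("linear", n = 60, d_z = 1, c = 0,
                                         replications = 6, n_bootstrap = 40,
                                         seed = 5))
  e1 <- error_rate_experiment("postnonlinear", n = 60, d_z = 1, c = 1,
                              replications = 1, n_bootstrap = 40, seed = 5)
  expect_true(e1$rejection_rate %in% c(0, 1))
})

test_that("experiment TSVs are tidy and stable across reruns", {
  e <- error_rate_experiment("linear", n = 60, d_z = 1, c = 0,
                             replications = 4, n_bootstrap = 30, seed = 8)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_experiment_tsv(e, f1)
  df <- read.delim(f1)
  expect_identical(names(df),
                   c("model", "n", "d_z", "c", "M", "replications",
                     "rejection_rate", "mean_p", "seed"))
  expect_identical(nrow(df), 1L)
  e2 <- error_rate_experiment("linear", n = 60, d_z = 1, c = 0,
                              replications = 4, n_bootstrap = 30, seed = 8)
  write_experiment_tsv(e2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a list of experiments yields one row per cell
  write_experiment_tsv(list(e, e2), f1)
  expect_identical(nrow(read.delim(f1)), 2L)
})

test_that("growing the cluster count does not inflate size but costs power", {
  # reduced-scale sweep of the cluster-count sensitivity at n = 400
  r <- 25
  null5 <- error_rate_experiment("postnonlinear", n = 400, d_z = 1, c = 0,
                                 replications = r, n_bootstrap = 200,
                                 m = 5L, seed = 31)
  # size-1 clusters are expected at M = 20 and warn by design
  null20 <- suppressWarnings(
    error_rate_experiment("postnonlinear", n = 400, d_z = 1, c = 0,
                          replications = r, n_bootstrap = 200,
                          m = 20L, seed = 31))
  expect_lte(null20$rejection_rate, 0.05 + binom_tol(0.05, r))
  expect_lte(null5$rejection_rate, 0.05 + binom_tol(0.05, r))
  alt5 <- error_rate_experiment("postnonlinear", n = 400, d_z = 1, c = 1,
                                replications = r, n_bootstrap = 200,
                                m = 5L, seed = 32)
  alt20 <- suppressWarnings(
    error_rate_experiment("postnonlinear", n = 400, d_z = 1, c = 1,
                          replications = r, n_bootstrap = 200,
                          m = 20L, seed = 32))
  # Type-II error may only grow (weakly) with M, up to Monte-Carlo slack
  expect_lte(alt20$rejection_rate,
             alt5$rejection_rate + binom_tol(alt5$rejection_rate + 0.01, r))
})

test_that("power grows weakly with the sample size", {
  r <- 25
  rates <- vapply(c(100, 200, 400), function(n)
    error_rate_experiment("postnonlinear", n = n, d_z = 1, c = 1,
                          replications = r, n_bootstrap = 200,
                          seed = 1000 + n)$rejection_rate,
    numeric(1))
  expect_gte(rates[2], rates[1] - binom_tol(max(rates[1], 0.05), r))
  expect_gte(rates[3], rates[2] - binom_tol(max(rates[2], 0.05), r))
  expect_gt(rates[3], 0.5)
})
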