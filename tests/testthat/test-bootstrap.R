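test_that("build_plan applies the neighbour, bandwidth and weight rules", {
  # two points: candidates are both, gamma = squared distance to 2nd NN = 1
  pl <- build_plan(c(0, 1), k_nn = 2)
  expect_identical(pl$candidates[1, ], c(1L, 2L))
  expect_identical(pl$candidates[2, ], c(2L, 1L))
  expect_equal(pl$gamma, c(1, 1))
  expect_equal(pl$weights[1, ], c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)

  # weights always normalise; gamma always positive
  set.seed(8)
  pl <- build_plan(matrix(rnorm(60), 30, 2), k_nn = 10)
  expect_equal(rowSums(pl$weights), rep(1, 30), tolerance = 1e-12)
  expect_true(all(pl$gamma > 0))
  expect_identical(dim(pl$candidates), c(30L, 10L))
  # self is always the first candidate (distance 0, stable tie-break)
  expect_identical(pl$candidates[, 1], 1:30)

  # identical z values: uniform weights
  plu <- build_plan(rep(3, 6), k_nn = 4)
  expect_true(all(abs(plu$weights - 0.25) < 1e-12))
  expect_true(all(plu$gamma > 0))

  expect_warning(plc <- build_plan(c(0, 1, 2), k_nn = 10), "clamp")
  expect_identical(plc$k_nn, 3L)
})

test_that("weight_kernel matches the Gaussian convention", {
  expect_equal(weight_kernel(0, 2), 1)
  expect_equal(weight_kernel(c(1, 1), 2), exp(-1), tolerance = 1e-12)
  expect_error(weight_kernel(1, 0), "positive")
  # equidistant candidates get equal weights after normalisation
  pl <- build_plan(c(-1, 0, 1), k_nn = 3)
  expect_equal(pl$weights[2, 2], pl$weights[2, 3], tolerance = 1e-12)
})

test_that("draw_null_sample keeps z fixed and resamples observed rows", {
  set.seed(17)
  s <- ci_sample(rnorm(25), rnorm(25), matrix(rnorm(50), 25, 2))
  pl <- build_plan(s$z, k_nn = 5)
  ns <- draw_null_sample(s, pl, seed = 2)
  expect_identical(ns$z, s$z)                      # bitwise: same object
  expect_true(all(ns$x %in% s$x))
  expect_true(all(ns$y %in% s$y))
  expect_identical(ns$n, s$n)
  # reproducible draws
  expect_identical(ns, draw_null_sample(s, pl, seed = 2))
})

test_that("k_nn = 1 reproduces the original sample exactly", {
  set.seed(19)
  s <- ci_sample(rnorm(15), rnorm(15), rnorm(15))
  pl <- build_plan(s$z, k_nn = 1)
  expect_identical(pl$candidates[, 1], 1:15)       # self is nearest
  ns <- draw_null_sample(s, pl, seed = 1)
  expect_identical(ns$x, s$x)
  expect_identical(ns$y, s$y)
})

test_that("per-unit draws follow the weights and factorise", {
  set.seed(23)
  n <- 40
  # x and y carry the row index so draws can be identified
  s <- ci_sample(seq_len(n), seq_len(n), rnorm(n))
  pl <- build_plan(s$z, k_nn = 10)
  i <- 7L
  draws <- 10000L
  ix <- integer(draws); iy <- integer(draws)
  set.seed(101)
  for (d in seq_len(draws)) {
    ns <- draw_null_sample(s, pl)
    ix[d] <- as.integer(ns$x[i, 1])
    iy[d] <- as.integer(ns$y[i, 1])
  }
  cand <- pl$candidates[i, ]
  expect_true(all(ix %in% cand) && all(iy %in% cand))
  # marginal matches the weight vector (chi-square goodness of fit)
  counts <- tabulate(match(ix, cand), nbins = length(cand))
  expect_gt(chisq.test(counts, p = pl$weights[i, ])$p.value, 0.001)
  # joint factorises: x-draw and y-draw of the same unit are independent
  tab <- table(factor(ix, levels = cand), factor(iy, levels = cand))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("weighted conditional means converge to the true conditional mean", {
  # smooth 1-D model x = sin(2 z) + noise; the Nadaraya-Watson weights of
  # the plan should estimate E[x | z] better as n grows
  mae <- vapply(c(100, 400, 1600), function(n) {
    set.seed(n + 5)
    z <- rnorm(n)
    x <- sin(2 * z) + rnorm(n, sd = 0.1)
    pl <- build_plan(z, k_nn = 10)
    est <- rowSums(pl$weights * matrix(x[t(pl$candidates)], n, pl$k_nn,
                                       byrow = TRUE))
    mean(abs(est - sin(2 * z)))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("bootstrap statistics fall below the observed statistic under H1", {
  # post-nonlinear data with an active confounder: resampling x and y
  # independently should destroy the dependence, placing the observed
  # statistic in the upper tail of the bootstrap distribution
  wins <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    s <- simulate_ci_data("postnonlinear", n = 400, d_z = 1, c = 1,
                          seed = 700 + r)
    fit <- bhsic_test(s, n_bootstrap = 200, seed = 800 + r)
    wins <- wins + (fit$statistic > quantile(fit$null_statistics, 0.95))
  }
  expect_gte(wins, 8)
})
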