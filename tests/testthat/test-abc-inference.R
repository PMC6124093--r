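test_that("replicate averaging is an elementwise mean with NA propagation", {
  a <- list(N = 20, Cy = c(1, 2))
  b <- list(N = 30, Cy = c(3, NA))
  expect_equal(average_over_replicates(list(a)), a)
  avg <- average_over_replicates(list(a, b))
  expect_equal(avg$N, 25)
  expect_equal(avg$Cy, c(2, NA))

  set.seed(1)
  tables <- lapply(1:7, function(i)
    list(s1 = rnorm(1), s2 = rnorm(5)))
  avg <- average_over_replicates(tables)
  expect_equal(avg$s2,
               rowMeans(sapply(tables, `[[`, "s2")))
})

test_that("the MAD follows the unscaled median-deviation definition", {
  expect_equal(median_absolute_deviation(c(1, 2, 3)), 1)
  expect_equal(median_absolute_deviation(c(1, 2, 4, 7)), 1.5)
  expect_equal(median_absolute_deviation(rep(5, 9)), 0)
})

test_that("MAD weights floor zero spreads and drop dead elements", {
  mats <- list(s = cbind(c(1, 2, 3, 4), rep(7, 4), c(10, 20, 30, 40)))
  w <- mad_weights(mats)$s
  expect_equal(w[1], 1)
  expect_equal(w[3], 10)
  expect_equal(w[2], 1)  # floored at the smallest positive MAD
  all_dead <- list(s = cbind(rep(1, 4), rep(2, 4)))
  expect_true(all(is.na(mad_weights(all_dead)$s)))
})

test_that("distances follow the length-averaged squared standardized form", {
  expect_equal(statistic_distance(3, 1, 2), 1)
  expect_equal(statistic_distance(c(2, 7), c(1, 4), c(1, 1)), 5)
  expect_equal(statistic_distance(c(5, 5), c(5, 5), c(1, 2)), 0)
  # NA-weighted elements are excluded and reduce the divisor
  expect_equal(statistic_distance(c(3, 99), c(1, 0), c(2, NA)), 1)
  expect_equal(combined_distance(0.7), 0.49)
  expect_equal(combined_distance(c(1, 2)), 5)
  expect_equal(combined_distance(c(0, 0, 0)), 0)
})

test_that("rejection keeps exactly the top percentile, ranked by distance", {
  set.seed(2)
  d <- scratch_design(n_replicates = 2)
  obs <- generate_observed_dataset(d, true_params(), seed = 10)
  cache <- prior_predictive_sample(200, d, stat_ids = "N")
  fit <- abc_rejection(obs, "N", cache = cache, adjust = FALSE)
  expect_equal(nrow(fit$theta), 2L)  # ceiling(0.01 * 200)
  expect_lte(max(fit$distances[fit$accepted]),
             min(fit$distances[-fit$accepted]))
  expect_equal(fit$threshold, max(fit$distances[fit$accepted]))

  # acceptance is rank-based: the distance convention cannot change the
  # accepted set for a single statistic
  fit2 <- abc_rejection(obs, "N", cache = cache, adjust = FALSE,
                        distance_convention = "linear")
  expect_identical(fit$accepted, fit2$accepted)
})

test_that("regression adjustment reproduces hand OLS and its invariances", {
  theta <- cbind(pm = c(1, 2, 3), pp = c(1, 2, 3))
  s <- matrix(c(1, 2, 3), ncol = 1)
  adj <- regression_adjustment(theta, s, 2)
  expect_equal(unname(adj), cbind(c(2, 2, 2), c(2, 2, 2)))
  # shifting every summary by a constant leaves the adjustment unchanged
  adj2 <- regression_adjustment(theta, s + 10, 12)
  expect_equal(adj, adj2)
  # constant summaries carry no information: adjustment is a no-op
  expect_equal(regression_adjustment(theta, matrix(1, 3, 1), 1), theta)
  # too few samples for the element count: skipped with a warning
  expect_warning(
    out <- regression_adjustment(theta, matrix(rnorm(9), 3, 3), rep(0, 3)),
    "too few")
  expect_equal(out, theta)

  # adjustment shrinks the spread when parameters track the summaries
  set.seed(3)
  th <- rnorm(200)
  sm <- th + rnorm(200, sd = 0.1)
  adj3 <- regression_adjustment(cbind(th, th), cbind(sm), 0)
  expect_lt(stats::sd(adj3[, 1]), stats::sd(th))
})

test_that("the KDE posterior integrates to one and locates its mass", {
  set.seed(4)
  prior <- prior_spec()
  theta <- cbind(runif(300, 0.2, 0.3), runif(300, 2e-3, 3e-3))
  grid <- kde_posterior(theta, prior, n_grid = 256)
  expect_lt(abs(sum(grid$values) * grid$cell_area - 1), 1e-6)
  # a tight cluster puts the argmax at the cluster
  tight <- cbind(rnorm(100, 0.5, 1e-4), rnorm(100, 5e-3, 1e-6))
  gt <- kde_posterior(tight, prior, n_grid = 256)
  mode <- posterior_mode(gt)
  expect_lt(abs(mode["pm"] - 0.5), 2 * diff(prior$pm_range) / 256)
  expect_lt(abs(mode["pp"] - 5e-3), 2 * diff(prior$pp_range) / 256)
  # identical points still give a unit-mass bump at the point
  same <- cbind(rep(0.4, 30), rep(4e-3, 30))
  gs <- kde_posterior(same, prior, n_grid = 256)
  expect_lt(abs(sum(gs$values) * gs$cell_area - 1), 1e-6)
  expect_lt(abs(posterior_mode(gs)["pm"] - 0.4), 2 * diff(prior$pm_range) / 256)
})

test_that("the KDE recovers a known truncated Gaussian in total variation", {
  set.seed(5)
  prior <- prior_spec()
  n <- 1e5
  pm <- rnorm(3 * n, 0.4, 0.12); pp <- rnorm(3 * n, 4e-3, 1.2e-3)
  keep <- pm > 0 & pm < 0.99 & pp > 0 & pp < 0.01
  pm <- pm[keep][1:n]; pp <- pp[keep][1:n]
  grid <- kde_posterior(cbind(pm, pp), prior)
  fx <- stats::dnorm(grid$pm, 0.4, 0.12)
  fy <- stats::dnorm(grid$pp, 4e-3, 1.2e-3)
  truth <- outer(fx, fy)
  truth <- truth / (sum(truth) * grid$cell_area)
  tv <- 0.5 * sum(abs(grid$values - truth)) * grid$cell_area
  expect_lt(tv, 0.05)
})

test_that("point estimates and intervals follow the stated conventions", {
  const <- rep(3, 25)
  est <- point_estimate_and_ci(const)
  expect_equal(est$estimate, 3)
  expect_equal(est$ci, c(3, 3))
  est2 <- point_estimate_and_ci(1:100)
  expect_equal(est2$ci, c(5.95, 95.05))
  set.seed(6)
  x <- rnorm(5000)
  est3 <- point_estimate_and_ci(x)
  expect_lt(abs(est3$estimate - mean(x)), 0.3)  # mode estimate is noisier
  expect_equal(point_estimate_and_ci(x, method = "mean")$estimate, mean(x))
})

test_that("N identifies proliferation but leaves motility at its prior", {
  set.seed(7)
  obs <- generate_observed_dataset(growth_design(), true_params(), seed = 20)
  fit <- abc_rejection(obs, "N", K = 2000, adjust = FALSE)
  # accepted p_move values stay indistinguishable from the uniform prior
  ks <- stats::ks.test(fit$theta[, "pm"], "punif", 0, 0.99)
  expect_gt(ks$p.value, 0.01)
})

test_that("scratch-design correlation statistics recover the truth", {
  set.seed(8)
  hits <- 0
  for (run in 1:5) {
    obs <- generate_observed_dataset(scratch_design(), true_params(),
                                     seed = 30 + run)
    fit <- abc_rejection(obs, "Cy", K = 2000, adjust = FALSE)
    if (inside_convex_hull(c(0.25, 0.0025), fit$theta)) hits <- hits + 1
    expect_true(all(fit$theta[, "pm"] > 0 & fit$theta[, "pm"] < 0.99))
    expect_true(all(fit$theta[, "pp"] > 0 & fit$theta[, "pp"] < 0.01))
  }
  expect_gte(hits, 4)
})

test_that("the accepted set concentrates as the prior sample grows", {
  set.seed(9)
  d <- scratch_design(n_replicates = 3)
  sds <- sapply(1:6, function(i) {
    obs <- generate_observed_dataset(d, true_params(), seed = 40 + i)
    small <- abc_rejection(obs, "N", K = 500, adjust = FALSE)
    large <- abc_rejection(obs, "N", K = 2500, adjust = FALSE)
    c(small = stats::sd(small$theta[, "pp"]),
      large = stats::sd(large$theta[, "pp"]))
  })
  expect_lt(mean(sds["large", ]), mean(sds["small", ]))
})
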