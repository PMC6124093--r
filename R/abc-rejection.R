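#' Uniform prior over the parameter box
#'
#' The prior for `(p_move, p_prolif)` is uniform on a rectangle, by default
#' `(0, 0.99) x (0, 0.01)` so that `p_move + p_prolif <= 1` everywhere on its
#' support.
#'
#' @param pm_range,pp_range Numeric length-2 intervals.
#' @return An object of class `prior_spec` with fields `pm_range`,
#'   `pp_range` and `density` (the constant density on the box).
#' @export
prior_spec <- function(pm_range = c(0, 0.99), pp_range = c(0, 0.01)) {
  stopifnot(length(pm_range) == 2L, length(pp_range) == 2L,
            pm_range[1] < pm_range[2], pp_range[1] < pp_range[2])
  if (pm_range[2] + pp_range[2] > 1)
    stop("prior box must respect p_move + p_prolif <= 1", call. = FALSE)
  area <- diff(pm_range) * diff(pp_range)
  structure(list(pm_range = pm_range, pp_range = pp_range,
                 density = 1 / area),
            class = "prior_spec")
}

in_prior_box <- function(theta, prior) {
  theta[1L] > prior$pm_range[1] & theta[1L] < prior$pm_range[2] &
    theta[2L] > prior$pp_range[1] & theta[2L] < prior$pp_range[2]
}

#' Average summary statistics over replicates
#'
#' Elementwise arithmetic mean over the `M` replicates of a dataset, for
#' every statistic and vector element. Missing (degenerate) elements
#' propagate as missing.
#'
#' @param per_replicate_stats List of statistic sets, one per replicate, as
#'   returned by [compute_statistic_set()].
#' @return Named list of replicate-averaged statistic vectors.
#' @export
average_over_replicates <- function(per_replicate_stats) {
  stopifnot(length(per_replicate_stats) >= 1L)
  ids <- names(per_replicate_stats[[1L]])
  out <- lapply(ids, function(id) {
    vals <- vapply(per_replicate_stats, function(s) as.numeric(s[[id]]),
                   numeric(length(per_replicate_stats[[1L]][[id]])))
    if (is.null(dim(vals))) mean(vals) else rowMeans(matrix(vals, ncol = length(per_replicate_stats)))
  })
  names(out) <- ids
  out
}

#' Replicate-averaged statistics of an observed dataset
#'
#' @param dataset An `observed_dataset`.
#' @param stat_ids Statistics to compute.
#' @return Named list of replicate-averaged statistic vectors.
#' @export
observed_summaries <- function(dataset, stat_ids = summary_statistic_ids()) {
  average_over_replicates(lapply(dataset$replicates, compute_statistic_set,
                                 stat_ids = stat_ids))
}

#' Median absolute deviation
#'
#' Raw (unscaled) MAD, `median(|x - median(x)|)`, the robust spread used to
#' standardize summary-statistic elements in the ABC distance. Medians of
#' even-length samples are the mean of the two central order statistics.
#'
#' @param values Numeric sample.
#' @return The MAD.
#' @examples
#' median_absolute_deviation(c(1, 2, 4, 7))  # 1.5
#' @export
median_absolute_deviation <- function(values) {
  stopifnot(length(values) >= 1L)
  stats::mad(values, constant = 1)
}

#' Replicate-to-replicate MAD of an observed dataset's statistics
#'
#' Per statistic and element, the raw median absolute deviation across the
#' `M` observed replicates. This is the natural noise scale of a summary
#' statistic under the experimental design, and the scale on which the
#' data-cloning kernel tolerances are defined.
#'
#' @param dataset An `observed_dataset`.
#' @param stat_ids Statistics to evaluate.
#' @return Named list of per-element MAD vectors.
#' @export
observed_replicate_mad <- function(dataset,
                                   stat_ids = summary_statistic_ids()) {
  per <- lapply(dataset$replicates, compute_statistic_set,
                stat_ids = stat_ids)
  out <- lapply(stat_ids, function(id) {
    m <- matrix(vapply(per, function(s) as.numeric(s[[id]]),
                       numeric(length(per[[1L]][[id]]))),
                ncol = length(per))
    apply(m, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else stats::mad(v, constant = 1)
    })
  })
  stats::setNames(out, stat_ids)
}

#' Simulate the prior-predictive sample used by ABC rejection
#'
#' Draws `K` parameter pairs from the prior and, for each, simulates a full
#' dataset (`M` replicates under `design`) and stores the replicate-averaged
#' summary statistics. The same cached sample can be reused across any
#' combination of summary statistics, since rejection-ABC distances depend on
#' the simulations only through these averaged summaries.
#'
#' @param K Number of prior draws.
#' @param design A [design_spec()].
#' @param config A [lattice_config()].
#' @param prior A [prior_spec()].
#' @param stat_ids Statistics to record.
#' @return An object of class `prior_predictive`: list with `theta`
#'   (`K x 2` matrix), `stats` (named list of `K x L_j` matrices), and the
#'   generating settings.
#' @export
prior_predictive_sample <- function(K, design, config = lattice_config(),
                                    prior = prior_spec(),
                                    stat_ids = summary_statistic_ids()) {
  stopifnot(K >= 1L)
  theta <- cbind(pm = runif(K, prior$pm_range[1], prior$pm_range[2]),
                 pp = runif(K, prior$pp_range[1], prior$pp_range[2]))
  n_steps <- n_steps_for(design, config)
  lens <- statistic_lengths(stat_ids)
  stats_mats <- lapply(lens, function(L) matrix(NA_real_, K, L))
  norm <- corr_norm_factors(config)
  for (k in seq_len(K)) {
    avg <- simulate_averaged_summaries(theta[k, 1L], theta[k, 2L], design,
                                       config, n_steps, stat_ids, norm)
    for (id in stat_ids) stats_mats[[id]][k, ] <- avg[[id]]
  }
  structure(list(theta = theta, stats = stats_mats, design = design,
                 config = config, prior = prior, stat_ids = stat_ids,
                 K = as.integer(K)),
            class = "prior_predictive")
}

statistic_lengths <- function(stat_ids) {
  lens <- ifelse(stat_ids %in% c("Cxy", "Cxy_hat", "Cy", "Cy_hat"),
                 CORR_MAX_L, 1L)
  stats::setNames(as.integer(lens), stat_ids)
}

# one dataset at (pm, pp): M replicates, statistics averaged over replicates
simulate_averaged_summaries <- function(pm, pp, design, config, n_steps,
                                        stat_ids, norm = NULL) {
  res <- cpp_run_dataset(design$n_replicates, config$n_rows, config$n_cols,
                         design$seeded_rows, design$n_initial,
                         design$n_tracked, pm, pp, n_steps,
                         design$record_interval)
  per_rep <- lapply(res, function(r)
    compute_stats_raw(r$cells, r$traj, config, stat_ids, norm))
  average_over_replicates(per_rep)
}

#' MAD weights for a set of prior-predictive summaries
#'
#' Per statistic and element, the median absolute deviation across the `K`
#' replicate-averaged prior-predictive summaries. Elements with zero MAD are
#' floored at the smallest positive MAD among that statistic's elements;
#' elements that are degenerate everywhere (all-zero spread, or expected
#' pair count zero) get weight `NA` and are excluded from distances.
#'
#' @param cache A `prior_predictive` object (or a named list of `K x L`
#'   matrices).
#' @return Named list of per-element weight vectors.
#' @export
mad_weights <- function(cache) {
  mats <- if (inherits(cache, "prior_predictive")) cache$stats else cache
  lapply(mats, function(m) {
    sig <- apply(m, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0L) NA_real_ else stats::mad(col, constant = 1)
    })
    pos <- sig[!is.na(sig) & sig > 0]
    floor_val <- if (length(pos)) min(pos) else NA_real_
    sig[!is.na(sig) & sig == 0] <- floor_val
    sig
  })
}

#' MAD-weighted distance for one summary statistic
#'
#' `d_j = (1/L_j) * sum_l ((s(l) - s_obs(l)) / sigma_j(l))^2`, the
#' length-averaged squared standardized deviation (no square root), so that
#' statistics of different lengths contribute on a common scale. Elements
#' with `NA` weight are excluded (and `L_j` reduced accordingly); an `NA`
#' simulated element makes the distance infinite.
#'
#' @param averaged Simulated replicate-averaged statistic vector.
#' @param observed_avg Observed replicate-averaged statistic vector.
#' @param weights Per-element MAD weights.
#' @return The per-statistic distance `d_j >= 0`.
#' @export
statistic_distance <- function(averaged, observed_avg, weights) {
  stopifnot(length(averaged) == length(observed_avg),
            length(weights) == length(observed_avg))
  use <- !is.na(weights) & !is.na(observed_avg)
  if (!any(use)) stop("no usable elements in statistic", call. = FALSE)
  if (any(weights[use] == 0))
    stop("zero weight on a used element", call. = FALSE)
  z <- (averaged[use] - observed_avg[use]) / weights[use]
  if (anyNA(z)) return(Inf)
  mean(z^2)
}

# vectorized over the K cached samples; returns a K-vector with Inf for
# samples carrying degenerate elements
statistic_distance_matrix <- function(sim_mat, observed_avg, weights) {
  use <- !is.na(weights) & !is.na(observed_avg)
  if (!any(use)) stop("no usable elements in statistic", call. = FALSE)
  z <- sweep(sim_mat[, use, drop = FALSE], 2L, observed_avg[use], "-")
  z <- sweep(z, 2L, weights[use], "/")
  d <- rowMeans(z^2)
  d[is.na(d)] <- Inf
  d
}

#' Combine per-statistic distances
#'
#' For a chosen set of `A` statistics, the combined distance is the sum of
#' squares of the per-statistic distances, `d = sum_a (d_a)^2`. A variant
#' summing the unsquared `d_a` is available for sensitivity analysis; for a
#' single statistic both induce the same acceptance ranking.
#'
#' @param d_values Numeric vector of per-statistic distances.
#' @param convention `"squared"` (default) or `"linear"`.
#' @return The combined distance.
#' @export
combined_distance <- function(d_values, convention = c("squared", "linear")) {
  convention <- match.arg(convention)
  if (convention == "squared") sum(d_values^2) else sum(d_values)
}

#' ABC rejection sampling
#'
#' Draws `K` parameter pairs from the prior, simulates a dataset (of `M`
#' replicates, matching the observed design) for each, and accepts the
#' 1st percentile of samples ranked by the MAD-weighted combined distance
#' between simulated and observed replicate-averaged summary statistics.
#' Accepted parameters are then regression-adjusted towards the observed
#' summaries.
#'
#' @param observed An `observed_dataset`.
#' @param stat_ids One to three statistic ids (see
#'   [summary_statistic_ids()]) entering the distance.
#' @param K Number of prior draws (ignored when `cache` is supplied).
#' @param prior A [prior_spec()].
#' @param accept_frac Acceptance fraction; the `ceiling(accept_frac * K)`
#'   samples with the smallest distances are retained.
#' @param adjust Apply local-linear regression adjustment (default `TRUE`).
#' @param cache Optional `prior_predictive` object to reuse across statistic
#'   choices; must cover `stat_ids`.
#' @param distance_convention Passed to [combined_distance()].
#' @return An object of class `abc_fit`: accepted `theta` and adjusted
#'   `theta_adj` matrices, the realized threshold `delta`, per-statistic
#'   distances, MAD weights, accepted summaries, and settings.
#' @examples
#' \donttest{
#' obs <- generate_observed_dataset(design_spec(seeded_rows = 6, n_initial = 24),
#'                                  model_params(0.25, 0.0025), seed = 5)
#' set.seed(9)
#' fit <- abc_rejection(obs, "N", K = 2000)
#' point_estimate_and_ci(fit$theta_adj[, "pp"])
#' }
#' @export
abc_rejection <- function(observed, stat_ids, K = 10000L,
                          prior = prior_spec(), accept_frac = 0.01,
                          adjust = TRUE, cache = NULL,
                          distance_convention = c("squared", "linear")) {
  distance_convention <- match.arg(distance_convention)
  stopifnot(length(stat_ids) >= 1L)
  if (is.null(cache)) {
    stopifnot(K >= 100L)
    cache <- prior_predictive_sample(K, observed$design, observed$config,
                                     prior, stat_ids)
  } else {
    stopifnot(inherits(cache, "prior_predictive"),
              all(stat_ids %in% cache$stat_ids))
    K <- cache$K
    prior <- cache$prior
  }
  obs_avg <- observed_summaries(observed, stat_ids)
  weights <- mad_weights(cache)[stat_ids]
  d_mat <- vapply(stat_ids, function(id)
    statistic_distance_matrix(cache$stats[[id]], obs_avg[[id]],
                              weights[[id]]),
    numeric(K))
  d <- apply(matrix(d_mat, nrow = K), 1L, combined_distance,
             convention = distance_convention)
  n_acc <- ceiling(accept_frac * K)
  ord <- order(d)
  acc <- ord[seq_len(n_acc)]
  delta <- d[ord[n_acc]]
  theta <- cache$theta[acc, , drop = FALSE]
  s_acc <- accepted_summary_matrix(cache, stat_ids, acc, weights, obs_avg)
  theta_adj <- theta
  if (adjust)
    theta_adj <- regression_adjustment(theta, s_acc$sim, s_acc$obs,
                                       lower = c(prior$pm_range[1], prior$pp_range[1]),
                                       upper = c(prior$pm_range[2], prior$pp_range[2]))
  # robust spread of the *accepted* summaries: this is the scale on which
  # the data-cloning kernel tolerances are defined
  mad_acc <- mad_weights(lapply(stats::setNames(stat_ids, stat_ids),
                                function(id)
                                  cache$stats[[id]][acc, , drop = FALSE]))
  structure(list(theta = theta, theta_adj = theta_adj, accepted = acc,
                 threshold = delta, distances = d,
                 mad_accepted = mad_acc,
                 per_statistic_distances = matrix(d_mat, nrow = K,
                                                  dimnames = list(NULL, stat_ids)),
                 mad = weights, stat_ids = stat_ids, prior = prior,
                 K = K, accept_frac = accept_frac, adjusted = adjust,
                 observed_avg = obs_avg, accepted_summaries = s_acc$sim),
            class = "abc_fit")
}

# concatenated usable summary elements for the accepted samples (used by the
# regression adjustment)
accepted_summary_matrix <- function(cache, stat_ids, acc, weights, obs_avg) {
  sims <- list(); obs <- numeric(0)
  for (id in stat_ids) {
    use <- !is.na(weights[[id]]) & !is.na(obs_avg[[id]])
    sims[[id]] <- cache$stats[[id]][acc, use, drop = FALSE]
    colnames(sims[[id]]) <- paste0(id, seq_len(sum(use)))
    obs <- c(obs, stats::setNames(obs_avg[[id]][use],
                                  paste0(id, seq_len(sum(use)))))
  }
  list(sim = do.call(cbind, sims), obs = obs)
}

#' Local-linear regression adjustment of accepted parameters
#'
#' Fits, per parameter component, an ordinary least-squares regression of the
#' accepted parameters on the (simulated minus observed) summary elements,
#' and shifts each accepted parameter by its fitted summary discrepancy:
#' `theta* = theta - (s - s_obs)' beta_hat`. Constant summary columns are
#' dropped; if fewer accepted samples than coefficients remain, or the design
#' matrix is rank deficient, the adjustment is skipped with a warning.
#' Adjusted values are clipped to the prior box when bounds are given.
#'
#' @param theta `n x 2` matrix of accepted parameters.
#' @param summaries `n x p` matrix of the corresponding simulated summary
#'   elements.
#' @param observed_avg Length-`p` vector of observed summary elements.
#' @param lower,upper Optional per-parameter clipping bounds.
#' @return The adjusted `n x 2` matrix.
#' @export
regression_adjustment <- function(theta, summaries, observed_avg,
                                  lower = NULL, upper = NULL) {
  theta <- as.matrix(theta)
  X <- sweep(as.matrix(summaries), 2L, observed_avg, "-")
  keep <- apply(X, 2L, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  n <- nrow(theta); p <- ncol(X)
  if (p == 0L) return(theta)
  if (n <= p + 1L) {
    warning("too few accepted samples for regression adjustment; skipped")
    return(theta)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1L) {
    warning("rank-deficient design matrix; regression adjustment skipped")
    return(theta)
  }
  beta <- qr.coef(qrX, theta)[-1L, , drop = FALSE]
  adj <- theta - X %*% beta
  if (!is.null(lower))
    adj <- pmax(adj, matrix(lower, n, ncol(theta), byrow = TRUE))
  if (!is.null(upper))
    adj <- pmin(adj, matrix(upper, n, ncol(theta), byrow = TRUE))
  dimnames(adj) <- dimnames(theta)
  adj
}

#' Gaussian kernel density estimate of the posterior on a fine mesh
#'
#' Evaluates a product-Gaussian KDE of the parameter sample on a regular
#' `n_grid x n_grid` mesh of cell centres over the prior box. Parameters are
#' affinely rescaled to the unit square first (the two prior ranges differ by
#' two orders of magnitude); bandwidths follow Silverman's rule per dimension
#' (`sd * n^(-1/6)`) with a floor of one grid cell. Mass leaking outside the
#' box is renormalized away, so the returned grid integrates to 1 under the
#' midpoint rule.
#'
#' @param theta `n x 2` matrix of parameter draws (`p_move`, `p_prolif`).
#' @param prior A [prior_spec()] defining the box.
#' @param n_grid Mesh size per dimension (default 512).
#' @param bandwidth Optional length-2 bandwidth override, on the unit-square
#'   scale.
#' @return An object of class `posterior_grid`: `values` (an
#'   `n_grid x n_grid` density matrix, rows indexing `p_move`), axis vectors
#'   `pm` and `pp` of cell centres, and `cell_area`.
#' @export
kde_posterior <- function(theta, prior = prior_spec(), n_grid = 512L,
                          bandwidth = NULL) {
  theta <- as.matrix(theta)
  stopifnot(nrow(theta) >= 1L, ncol(theta) == 2L)
  n <- nrow(theta)
  w1 <- diff(prior$pm_range); w2 <- diff(prior$pp_range)
  u1 <- (theta[, 1L] - prior$pm_range[1]) / w1
  u2 <- (theta[, 2L] - prior$pp_range[1]) / w2
  if (is.null(bandwidth)) {
    bw <- function(u) max(stats::sd(u) * n^(-1 / 6), 1 / n_grid, na.rm = TRUE)
    bandwidth <- c(bw(u1), bw(u2))
  }
  bandwidth <- pmax(bandwidth, 1 / n_grid)
  g <- (seq_len(n_grid) - 0.5) / n_grid
  vals <- matrix(0, n_grid, n_grid)
  # accumulate in chunks so large samples stay within memory
  chunk <- 4096L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    A <- stats::dnorm(outer(g, u1[idx], "-") / bandwidth[1]) / bandwidth[1]
    B <- stats::dnorm(outer(g, u2[idx], "-") / bandwidth[2]) / bandwidth[2]
    vals <- vals + tcrossprod(A, B)
  }
  cell_area <- (w1 / n_grid) * (w2 / n_grid)
  vals <- vals / (sum(vals) * cell_area)
  structure(list(values = vals,
                 pm = prior$pm_range[1] + g * w1,
                 pp = prior$pp_range[1] + g * w2,
                 cell_area = cell_area, prior = prior,
                 bandwidth = bandwidth),
            class = "posterior_grid")
}

#' Discretized uniform prior density
#'
#' @param prior A [prior_spec()].
#' @param n_grid Mesh size per dimension.
#' @return A `posterior_grid` holding the constant prior density.
#' @export
uniform_prior_grid <- function(prior = prior_spec(), n_grid = 512L) {
  w1 <- diff(prior$pm_range); w2 <- diff(prior$pp_range)
  g <- (seq_len(n_grid) - 0.5) / n_grid
  structure(list(values = matrix(1 / (w1 * w2), n_grid, n_grid),
                 pm = prior$pm_range[1] + g * w1,
                 pp = prior$pp_range[1] + g * w2,
                 cell_area = (w1 / n_grid) * (w2 / n_grid),
                 prior = prior, bandwidth = NULL),
            class = "posterior_grid")
}

#' Grid argmax of a posterior density
#'
#' @param grid A `posterior_grid`.
#' @return Named vector `(pm, pp)` at the cell of maximum density.
#' @export
posterior_mode <- function(grid) {
  idx <- which(grid$values == max(grid$values), arr.ind = TRUE)[1L, ]
  c(pm = grid$pm[idx[1L]], pp = grid$pp[idx[2L]])
}

#' Per-parameter marginal modes of a posterior grid
#'
#' Argmax of each parameter's marginal density (row and column sums of the
#' mesh). Unlike the joint argmax, the marginal mode remains stable when the
#' other parameter is unidentified and the posterior is a flat ridge.
#'
#' @param grid A `posterior_grid`.
#' @return Named vector `(pm, pp)` of marginal modes.
#' @export
posterior_marginal_modes <- function(grid) {
  c(pm = grid$pm[which.max(rowSums(grid$values))],
    pp = grid$pp[which.max(colSums(grid$values))])
}

#' Point estimates and intervals of an ABC rejection fit
#'
#' The reported point estimate per parameter is the marginal mode of the
#' mesh KDE posterior of the adjusted sample (the package's KDE bandwidth
#' conventions apply); the sample mean and the empirical 5-95% percentile
#' interval are reported alongside.
#'
#' @param fit An `abc_fit`.
#' @param n_grid Mesh size for the KDE (default 512).
#' @return Data frame with rows `pm`, `pp` and columns `estimate`, `mean`,
#'   `lo90`, `hi90`.
#' @export
abc_point_estimates <- function(fit, n_grid = 512L) {
  grid <- kde_posterior(fit$theta_adj, fit$prior, n_grid)
  modes <- posterior_marginal_modes(grid)
  ci <- apply(fit$theta_adj, 2L, stats::quantile, probs = c(0.05, 0.95),
              type = 7)
  data.frame(row.names = c("pm", "pp"),
             estimate = as.numeric(modes),
             mean = as.numeric(colMeans(fit$theta_adj)),
             lo90 = as.numeric(ci[1L, ]), hi90 = as.numeric(ci[2L, ]))
}

#' Point estimate and empirical 90% interval
#'
#' Per parameter, returns a point estimate - either the mode of a 1-d
#' Gaussian KDE of the sample (the natural point summary of a rejection
#' posterior) or the sample mean - together with the empirical 5th-95th
#' percentile interval (linear interpolation between order statistics).
#'
#' @param samples Numeric vector (or one column of an accepted-parameter
#'   matrix).
#' @param method `"mode"` (default) or `"mean"`.
#' @return List with `estimate`, `ci` (length-2), `mean` and `mode`.
#' @export
point_estimate_and_ci <- function(samples, method = c("mode", "mean")) {
  method <- match.arg(method)
  stopifnot(length(samples) >= 20L)
  mo <- if (stats::sd(samples) == 0) samples[1L] else {
    dd <- stats::density(samples)
    dd$x[which.max(dd$y)]
  }
  me <- mean(samples)
  list(estimate = if (method == "mode") mo else me,
       ci = unname(stats::quantile(samples, c(0.05, 0.95), type = 7)),
       mean = me, mode = mo)
}

#' @export
print.abc_fit <- function(x, ...) {
  cat("<abc_fit> statistics:", paste(x$stat_ids, collapse = "+"),
      "| K =", x$K, "| accepted", nrow(x$theta),
      "| threshold =", signif(x$threshold, 4), "\n")
  if (nrow(x$theta_adj) >= 20L) {
    est <- abc_point_estimates(x)
    for (p in c("pm", "pp"))
      cat(sprintf("  %s: mode %.4g, mean %.4g, 90%% CI (%.4g, %.4g)\n",
                  p, est[p, "estimate"], est[p, "mean"], est[p, "lo90"],
                  est[p, "hi90"]))
  }
  invisible(x)
}
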