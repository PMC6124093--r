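#' Kullback-Leibler information gain between two gridded densities
#'
#' Midpoint-rule integral of `F * log(F / G)` over the shared mesh, with the
#' convention `0 * log 0 = 0`. Used as the information gained in moving from
#' the (uniform) prior to an estimated posterior: the larger the divergence,
#' the more the data constrained the parameters.
#'
#' @param posterior,prior `posterior_grid` objects on identical axes; the
#'   prior must be strictly positive wherever the posterior has mass.
#' @return The divergence, in nats (non-negative up to quadrature error).
#' @export
kl_divergence <- function(posterior, prior) {
  stopifnot(inherits(posterior, "posterior_grid"),
            inherits(prior, "posterior_grid"))
  if (!identical(dim(posterior$values), dim(prior$values)) ||
      max(abs(posterior$pm - prior$pm)) > 1e-12 ||
      max(abs(posterior$pp - prior$pp)) > 1e-12)
    stop("posterior and prior grids must share axes", call. = FALSE)
  f <- posterior$values
  g <- prior$values
  pos <- f > 0
  if (any(g[pos] == 0))
    stop("prior density is zero where the posterior has mass", call. = FALSE)
  # log(f) - log(g) rather than log(f/g): the ratio itself can underflow to
  # zero for subnormal densities in the KDE tails
  sum(f[pos] * (log(f[pos]) - log(g[pos]))) * posterior$cell_area
}

#' Plan for a design x summary-statistic comparison study
#'
#' @param designs List of `design_spec` objects (or a data frame with
#'   columns `seeded_rows`, `n_initial`).
#' @param stat_sets List of character vectors, each a combination of 1-3
#'   statistic ids to score.
#' @param n_reps Independent repetitions of the whole pipeline per cell
#'   (fresh observed data and fresh ABC run each time).
#' @param K Prior draws per ABC run.
#' @param params_true Generating parameters for the in silico observed data.
#' @param config A [lattice_config()].
#' @param prior A [prior_spec()].
#' @param n_grid KDE mesh size used for the information gain.
#' @return An object of class `study_plan`.
#' @export
study_plan <- function(designs, stat_sets, n_reps = 5L, K = 5000L,
                       params_true = model_params(0.25, 0.0025),
                       config = lattice_config(), prior = prior_spec(),
                       n_grid = 512L) {
  if (is.data.frame(designs))
    designs <- lapply(seq_len(nrow(designs)), function(i)
      design_spec(seeded_rows = designs$seeded_rows[i],
                  n_initial = designs$n_initial[i]))
  stopifnot(length(designs) >= 1L, length(stat_sets) >= 1L,
            all(vapply(stat_sets, length, 1L) <= 3L))
  structure(list(designs = designs, stat_sets = stat_sets,
                 n_reps = as.integer(n_reps), K = as.integer(K),
                 params_true = params_true, config = config, prior = prior,
                 n_grid = as.integer(n_grid)),
            class = "study_plan")
}

#' Run a design x summary-statistic information-gain study
#'
#' For every repetition and every design, generates a fresh in silico
#' observed dataset at the true parameters and one prior-predictive sample
#' of `K` simulated datasets. The simulations are cached and shared across
#' all statistic combinations (rejection-ABC acceptance depends on them only
#' through the per-statistic distances, so results are identical to
#' recomputing them per combination). Each combination is scored by the
#' Kullback-Leibler divergence of its regression-adjusted KDE posterior from
#' the uniform prior.
#'
#' @param plan A [study_plan()].
#' @param seed Master seed; repetition seeds are spawned from it.
#' @return A data frame (class `information_result`) with one row per
#'   (design, combination): `seeded_rows`, `n_initial`, `combo`, `mean_kl`,
#'   `sd_kl`, `n_reps`, `K`. The per-repetition values are in
#'   `attr(, "per_rep")`.
#' @export
run_design_study <- function(plan, seed = 1L) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, plan$n_reps)
  all_ids <- unique(unlist(plan$stat_sets))
  prior_grid <- uniform_prior_grid(plan$prior, plan$n_grid)
  rows <- list()
  for (rep in seq_len(plan$n_reps)) {
    for (di in seq_along(plan$designs)) {
      design <- plan$designs[[di]]
      set.seed(rep_seeds[rep] %% 1000000L * 100L + di)
      obs <- generate_observed_dataset(design, plan$params_true, plan$config,
                                       seed = sample.int(.Machine$integer.max, 1L))
      cache <- prior_predictive_sample(plan$K, design, plan$config,
                                       plan$prior, all_ids)
      for (ci in seq_along(plan$stat_sets)) {
        ids <- plan$stat_sets[[ci]]
        fit <- abc_rejection(obs, ids, cache = cache)
        grid <- kde_posterior(fit$theta_adj, plan$prior, plan$n_grid)
        rows[[length(rows) + 1L]] <- data.frame(
          rep = rep, seeded_rows = design$seeded_rows,
          n_initial = design$n_initial,
          combo = paste(ids, collapse = "+"),
          kl = kl_divergence(grid, prior_grid))
      }
    }
  }
  per_rep <- do.call(rbind, rows)
  agg <- stats::aggregate(kl ~ seeded_rows + n_initial + combo, per_rep,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(seeded_rows = agg$seeded_rows,
                    n_initial = agg$n_initial, combo = agg$combo,
                    mean_kl = agg$kl[, "mean"], sd_kl = agg$kl[, "sd"],
                    n_reps = plan$n_reps, K = plan$K)
  attr(out, "per_rep") <- per_rep
  class(out) <- c("information_result", class(out))
  out
}

#' Rank statistic combinations by information gain
#'
#' Sorts the study results by mean KL divergence, descending, within each
#' design; ties are broken by the combination label.
#'
#' @param results An `information_result` data frame from
#'   [run_design_study()].
#' @return The reordered data frame.
#' @export
rank_combinations <- function(results) {
  stopifnot(nrow(results) >= 1L)
  ord <- order(results$seeded_rows, results$n_initial, -results$mean_kl,
               results$combo)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Posterior predictive check for a scalar summary statistic
#'
#' Draws parameters from a posterior sample, simulates one fresh replicate
#' per draw under the observed design, and computes the chosen scalar
#' statistic. Each observed replicate's statistic is then compared against
#' the predictive mean and the empirical 2.5-97.5 percentile interval.
#'
#' @param posterior_theta Matrix of posterior parameter draws (columns
#'   `pm`, `pp`), e.g. `fit$theta_adj`.
#' @param observed An `observed_dataset` providing the design and the
#'   per-replicate observed values.
#' @param statistic_id A scalar statistic id (`L_j = 1`).
#' @param n_draws Number of posterior draws to simulate (default 1000).
#' @return A data frame (class `predictive_check`) with one row per observed
#'   replicate: `replicate`, `observed_value`, `predictive_mean`, `lo95`,
#'   `hi95`, `inside`.
#' @export
posterior_predictive_check <- function(posterior_theta, observed,
                                       statistic_id, n_draws = 1000L) {
  stopifnot(n_draws >= 100L)
  if (statistic_lengths(statistic_id) != 1L)
    stop("posterior predictive checks are defined for scalar statistics",
         call. = FALSE)
  posterior_theta <- as.matrix(posterior_theta)
  design <- observed$design
  config <- observed$config
  n_steps <- n_steps_for(design, config)
  idx <- sample.int(nrow(posterior_theta), n_draws, replace = TRUE)
  pred <- vapply(idx, function(i) {
    r <- cpp_run_dataset(1L, config$n_rows, config$n_cols,
                         design$seeded_rows, design$n_initial,
                         design$n_tracked, posterior_theta[i, 1L],
                         posterior_theta[i, 2L], n_steps,
                         design$record_interval)[[1L]]
    as.numeric(compute_stats_raw(r$cells, r$traj, config,
                                 statistic_id)[[1L]])
  }, numeric(1))
  lo <- stats::quantile(pred, 0.025, type = 7, na.rm = TRUE)
  hi <- stats::quantile(pred, 0.975, type = 7, na.rm = TRUE)
  obs_vals <- vapply(observed$replicates, function(r)
    as.numeric(compute_statistic_set(r, statistic_id)[[1L]]), numeric(1))
  out <- data.frame(replicate = seq_along(obs_vals),
                    observed_value = obs_vals,
                    predictive_mean = mean(pred, na.rm = TRUE),
                    lo95 = unname(lo), hi95 = unname(hi),
                    inside = obs_vals >= lo & obs_vals <= hi)
  class(out) <- c("predictive_check", class(out))
  out
}
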