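#' Staging schedule for data-cloning ABC-MCMC
#'
#' The sampler runs through `P + Q` populations: first `P` stages over which
#' the acceptance tolerance `epsilon` is decreased (with one data clone),
#' then `Q` stages over which the number of clones `K` is increased at fixed
#' tolerance, concentrating the chain on the maximum-likelihood estimate.
#' The defaults are the staging used throughout this package's analyses:
#' sample counts `(1000 x 8, 2000)`, clones `K = (1,1,1,1,1,1,2,3,4)` and
#' tolerances `eps = (5, 2, 1, 0.5, 0.25, 0.25, 0.25, 0.25, 0.25)`, with
#' `P = 5` and `Q = 4`.
#'
#' @param n_samples Per-population chain lengths.
#' @param n_clones Per-population clone counts (non-decreasing).
#' @param tolerance Per-population tolerances (non-increasing).
#' @param n_tolerance_stages,n_clone_stages The counts `P` and `Q`,
#'   `P + Q = length(n_samples)`.
#' @return An object of class `dc_schedule`.
#' @export
dc_schedule <- function(n_samples = c(rep(1000L, 8L), 2000L),
                        n_clones = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L),
                        tolerance = c(5, 2, 1, 0.5, 0.25, 0.25, 0.25, 0.25,
                                      0.25),
                        n_tolerance_stages = 5L, n_clone_stages = 4L) {
  n_stages <- length(n_samples)
  stopifnot(length(n_clones) == n_stages, length(tolerance) == n_stages,
            n_tolerance_stages + n_clone_stages == n_stages,
            all(n_samples >= 1L), all(n_clones >= 1L), all(tolerance > 0))
  if (any(diff(tolerance) > 0))
    stop("tolerances must be non-increasing", call. = FALSE)
  if (any(diff(n_clones) < 0))
    stop("clone counts must be non-decreasing", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_clones = as.integer(n_clones), tolerance = tolerance,
                 n_tolerance_stages = as.integer(n_tolerance_stages),
                 n_clone_stages = as.integer(n_clone_stages)),
            class = "dc_schedule")
}

#' Gaussian ABC kernel
#'
#' `J_eps(d) = exp(-d^2 / (2 eps^2))`: a Gaussian acceptance kernel centred
#' on the observed summaries, evaluated at the MAD-weighted per-statistic
#' distance `d`. Strictly decreasing in `d` and increasing in `eps`, with
#' values in `(0, 1]`.
#'
#' @param distance Per-statistic distance `d >= 0`.
#' @param tolerance Kernel scale `eps > 0`.
#' @return Kernel value in `(0, 1]`.
#' @export
gaussian_abc_kernel <- function(distance, tolerance) {
  stopifnot(all(tolerance > 0), all(distance >= 0))
  exp(-distance^2 / (2 * tolerance^2))
}

# log-kernel from a combined distance (for one statistic the combined
# distance is d_j^2, so this matches gaussian_abc_kernel exactly)
log_kernel_combined <- function(combined_d, tolerance) {
  -combined_d / (2 * tolerance^2)
}

# distances for n_clones fresh cloned datasets at theta
simulate_clone_distances <- function(theta, n_clones, design, config,
                                     n_steps, stat_ids, weights, obs_avg,
                                     distance_convention, norm = NULL) {
  vapply(seq_len(n_clones), function(k) {
    avg <- simulate_averaged_summaries(theta[1L], theta[2L], design, config,
                                       n_steps, stat_ids, norm)
    d <- vapply(stat_ids, function(id)
      statistic_distance(avg[[id]], obs_avg[[id]], weights[[id]]),
      numeric(1))
    combined_distance(d, convention = distance_convention)
  }, numeric(1))
}

# same but also returning the concatenated summary vector of the last clone
# (used to adjust the final population)
simulate_clone_summaries <- function(theta, n_clones, design, config,
                                     n_steps, stat_ids, weights, obs_avg,
                                     distance_convention, norm = NULL) {
  dists <- numeric(n_clones)
  s_sum <- NULL
  for (k in seq_len(n_clones)) {
    avg <- simulate_averaged_summaries(theta[1L], theta[2L], design, config,
                                       n_steps, stat_ids, norm)
    d <- vapply(stat_ids, function(id)
      statistic_distance(avg[[id]], obs_avg[[id]], weights[[id]]),
      numeric(1))
    dists[k] <- combined_distance(d, convention = distance_convention)
    s_vec <- unlist(lapply(stat_ids, function(id) {
      use <- !is.na(weights[[id]]) & !is.na(obs_avg[[id]])
      avg[[id]][use]
    }))
    s_sum <- if (is.null(s_sum)) s_vec else s_sum + s_vec
  }
  list(distances = dists, summary = s_sum / n_clones)
}

#' Data-cloning ABC-MCMC maximum-likelihood estimation
#'
#' Runs an ABC Markov chain with a Gaussian acceptance kernel through the
#' staged schedule: tolerances are first decreased, then the likelihood is
#' raised to increasing clone powers by simulating `K` independent cloned
#' datasets per proposal. The acceptance probability compares the product of
#' the clone kernel values at the proposal against the (retained, not
#' re-simulated) values at the current state, times the prior ratio;
#' proposals outside the prior box are rejected outright. The MLE is the
#' mean of the final population (regression-adjusted by default), with the
#' empirical 5-95% percentiles as the credible interval.
#'
#' MAD weights and the chain's starting point are taken from a pilot ABC
#' rejection run (the accepted sample with the smallest distance) unless
#' supplied.
#'
#' @param observed An `observed_dataset`.
#' @param stat_ids Statistic ids entering the distance.
#' @param schedule A [dc_schedule()].
#' @param proposal_scale Standard deviations of the symmetric Gaussian
#'   random-walk proposal, per parameter.
#' @param prior A [prior_spec()].
#' @param pilot Either an `abc_fit` (reused for MAD weights and the initial
#'   state) or an integer `K` for a fresh pilot rejection run.
#' @param refresh Re-simulate the current state's kernel values at every
#'   iteration instead of retaining them (diagnostic option; default
#'   `FALSE`).
#' @param adjust Regression-adjust the final population (default `TRUE`).
#' @param distance_convention Passed to [combined_distance()].
#' @param kernel_mad Sample from which the kernel MAD weights are taken:
#'   `"observed"` (default) uses the replicate-to-replicate spread of the
#'   observed statistics, `"accepted"` the spread of the pilot run's
#'   accepted summaries (a sensitivity option; it freezes the chain into a
#'   sticky pseudo-marginal regime under the default tolerances).
#' @return An object of class `abc_dc_fit`: `mle` and `ci` per parameter,
#'   the per-population chains, acceptance rates, and settings.
#' @export
run_abc_dc <- function(observed, stat_ids, schedule = dc_schedule(),
                       proposal_scale = c(0.02, 2e-4),
                       prior = prior_spec(), pilot = 1000L,
                       refresh = FALSE, adjust = TRUE,
                       distance_convention = c("squared", "linear"),
                       kernel_mad = c("observed", "accepted")) {
  distance_convention <- match.arg(distance_convention)
  design <- observed$design
  config <- observed$config
  n_steps <- n_steps_for(design, config)
  obs_avg <- observed_summaries(observed, stat_ids)
  norm <- corr_norm_factors(config)

  if (!inherits(pilot, "abc_fit"))
    pilot <- abc_rejection(observed, stat_ids, K = as.integer(pilot),
                           prior = prior, adjust = FALSE)
  stopifnot(all(stat_ids %in% names(pilot$mad)))
  # The kernel tolerances are calibrated against the replicate-to-replicate
  # spread of the observed statistics: that is the scale on which the staged
  # tolerances (down to eps = 0.25) neither flatten the kernel (as the
  # prior-predictive spread does) nor freeze the chain (as the accepted-set
  # spread does). Elements with zero observed spread fall back to the
  # pilot's prior-predictive MAD.
  weights <- switch(match.arg(kernel_mad),
                    observed = observed_replicate_mad(observed, stat_ids),
                    accepted = pilot$mad_accepted[stat_ids])
  for (id in stat_ids) {
    dead <- (is.na(weights[[id]]) | weights[[id]] == 0) &
      !is.na(pilot$mad[[id]])
    weights[[id]][dead] <- pilot$mad[[id]][dead]
    weights[[id]][weights[[id]] == 0] <- NA_real_
  }
  theta <- as.numeric(pilot$theta[1L, ])  # smallest-distance accepted sample

  n_stages <- length(schedule$n_samples)
  chains <- vector("list", n_stages)
  acc_rates <- numeric(n_stages)
  cur <- NULL  # clone distances of the retained state
  s_cur <- NULL
  final_summaries <- NULL
  for (stage in seq_len(n_stages)) {
    eps <- schedule$tolerance[stage]
    Kc <- schedule$n_clones[stage]
    r <- schedule$n_samples[stage]
    last <- stage == n_stages
    # refresh the retained state's kernel values at each stage boundary: the
    # tolerance or clone count has changed, so stored values no longer match
    sc <- simulate_clone_summaries(theta, Kc, design, config, n_steps,
                                   stat_ids, weights, obs_avg,
                                   distance_convention, norm)
    cur <- sc$distances
    s_cur <- sc$summary
    chain <- matrix(NA_real_, r, 2L, dimnames = list(NULL, c("pm", "pp")))
    if (last)
      final_summaries <- matrix(NA_real_, r, length(s_cur))
    n_acc <- 0L
    for (it in seq_len(r)) {
      prop <- theta + stats::rnorm(2L) * proposal_scale
      if (in_prior_box(prop, prior)) {
        sp <- simulate_clone_summaries(prop, Kc, design, config, n_steps,
                                       stat_ids, weights, obs_avg,
                                       distance_convention, norm)
        if (refresh) {
          sc <- simulate_clone_summaries(theta, Kc, design, config, n_steps,
                                         stat_ids, weights, obs_avg,
                                         distance_convention, norm)
          cur <- sc$distances
          s_cur <- sc$summary
        }
        lk_prop <- sum(log_kernel_combined(sp$distances, eps))
        lk_cur <- sum(log_kernel_combined(cur, eps))
        # a degenerate current state (infinite distance) is always left
        accept <- if (lk_prop == -Inf) FALSE
          else if (lk_cur == -Inf) TRUE
          else log(stats::runif(1)) < lk_prop - lk_cur
        if (accept) {
          theta <- prop
          cur <- sp$distances
          s_cur <- sp$summary
          n_acc <- n_acc + 1L
        }
      }
      chain[it, ] <- theta
      if (last) final_summaries[it, ] <- s_cur
    }
    chains[[stage]] <- chain
    acc_rates[stage] <- n_acc / r
    if (n_acc == 0L && stage > 1L)
      stop("data-cloning chain stalled: zero acceptances over population ",
           stage, " (tolerance ", eps, ", ", Kc,
           " clones); consider a smaller proposal_scale", call. = FALSE)
  }

  final <- chains[[n_stages]]
  if (adjust)
    final <- regression_adjustment(final, final_summaries,
                                   unlist(lapply(stat_ids, function(id) {
                                     use <- !is.na(weights[[id]]) &
                                       !is.na(obs_avg[[id]])
                                     obs_avg[[id]][use]
                                   })),
                                   lower = c(prior$pm_range[1], prior$pp_range[1]),
                                   upper = c(prior$pm_range[2], prior$pp_range[2]))
  mle <- colMeans(final)
  ci <- apply(final, 2L, stats::quantile, probs = c(0.05, 0.95), type = 7)
  structure(list(mle = mle, ci = ci, final_population = final,
                 chains = chains, acceptance_rates = acc_rates,
                 schedule = schedule, stat_ids = stat_ids, prior = prior,
                 proposal_scale = proposal_scale, mad = weights,
                 adjusted = adjust),
            class = "abc_dc_fit")
}

#' @export
print.abc_dc_fit <- function(x, ...) {
  cat("<abc_dc_fit> statistics:", paste(x$stat_ids, collapse = "+"),
      "|", length(x$chains), "populations | acceptance",
      paste(sprintf("%.2f", x$acceptance_rates), collapse = " "), "\n")
  cat(sprintf("  MLE: pm = %.4g (%.4g, %.4g); pp = %.4g (%.4g, %.4g)\n",
              x$mle["pm"], x$ci[1, "pm"], x$ci[2, "pm"],
              x$mle["pp"], x$ci[1, "pp"], x$ci[2, "pp"]))
  invisible(x)
}

#' Chain trace of a data-cloning fit as a tidy table
#'
#' @param fit An `abc_dc_fit`.
#' @return Data frame with columns `population`, `iteration`, `pm`, `pp`,
#'   `n_clones`, `tolerance`.
#' @export
dc_chain_trace <- function(fit) {
  do.call(rbind, lapply(seq_along(fit$chains), function(s) {
    ch <- fit$chains[[s]]
    data.frame(population = s, iteration = seq_len(nrow(ch)),
               pm = ch[, 1L], pp = ch[, 2L],
               n_clones = fit$schedule$n_clones[s],
               tolerance = fit$schedule$tolerance[s])
  }))
}
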