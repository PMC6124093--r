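# Shared parameter-recovery state for the slower end-to-end tests: one
# scratch-assay observed dataset at the true parameters, one K = 10000
# prior-predictive sample covering the three benchmark statistics, and the
# rejection fits derived from it. Built lazily, once per test run.
.recovery <- new.env(parent = emptyenv())

recovery_state <- function() {
  if (!is.null(.recovery$fits)) return(.recovery)
  set.seed(20250927)
  obs <- generate_observed_dataset(scratch_design(), true_params(),
                                   seed = 1201)
  cache <- prior_predictive_sample(10000, obs$design,
                                   stat_ids = c("N", "disp", "Cxy"))
  fits <- list(disp = abc_rejection(obs, "disp", cache = cache),
               Cxy = abc_rejection(obs, "Cxy", cache = cache),
               N = abc_rejection(obs, "N", cache = cache))
  .recovery$obs <- obs
  .recovery$cache <- cache
  .recovery$fits <- fits
  .recovery
}

# reference 90% rejection intervals for the scratch-assay benchmark (per-step
# probabilities; pp on the 10^-2 scale)
REJ_CI <- list(disp_pm = c(0.231, 0.300),
               Cxy_pm = c(0.174, 0.310),
               Cxy_pp100 = c(0.215, 0.270),
               N_pp100 = c(0.220, 0.282))
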