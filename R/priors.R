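#' Prior specification for the hierarchical race model
#'
#' Group-level locations have truncated-normal priors on the natural scale
#' for the ex-Gaussian parameters and normal priors on the probit scale for
#' the two failure probabilities. Location prior means default to 1.5 s for
#' the two go runners' mu and 1.0 s for the stop runner's mu (appropriate
#' for slowed reaction times in older and clinical populations), 0.1 s for
#' sigma and 0.2 s for tau, and -1.5 on the probit scale (about 0.07) for
#' `p_tf` and `p_gf`. Group-level scales have half-normal priors truncated
#' below at 0.01 (10 ms, or 0.01 probit units): group SDs under that floor
#' are below any meaningful resolution of the task and degenerate the
#' hierarchy. All entries can be edited before fitting.
#'
#' @return A tibble with one row per parameter: `parameter`, `loc_mean`,
#'   `loc_sd`, `lower`, `upper` (support bounds, also the truncation of the
#'   location prior and of the participant-level group distribution),
#'   `scale_sd` (half-normal prior scale for the group SD), `scale_lower`
#'   and `scale_upper` (truncation of the group-SD prior).
#' @export
race_priors <- function() {
  tibble::tibble(
    parameter = race_param_names(),
    loc_mean = c(1.5, 0.1, 0.2, 1.5, 0.1, 0.2, 1.0, 0.1, 0.2, -1.5, -1.5),
    loc_sd   = c(1.0, 0.5, 0.5, 1.0, 0.5, 0.5, 1.0, 0.5, 0.5, 1.0, 1.0),
    lower    = c(0, 0, 0, 0, 0, 0, 0, 0, 0, -6, -6),
    upper    = c(10, 5, 5, 10, 5, 5, 10, 5, 5, 6, 6),
    scale_sd = rep(0.5, 11),
    scale_lower = rep(0.01, 11),
    scale_upper = rep(3, 11)
  )
}

#' Sampler configuration for the hierarchical fit
#'
#' Defaults mirror the study's estimation settings: the number of chains is
#' three times the number of free parameters (33 for the 11-parameter
#' model), retained samples are thinned to every 10th iteration, and
#' migration (a cyclic swap of states among a random subset of chains)
#' occurs with probability 0.05 per iteration. Burn-in proceeds in blocks
#' gated by the split-chain potential scale reduction statistic R-hat
#' replacing visual inspection of trace plots; once the gate passes (or
#' `max_burnin_blocks` is exhausted, with a warning), `final_iterations`
#' thinned draws per chain are retained as the posterior.
#'
#' @param n_chains Number of chains; default `3 * 11`. Must be at least 13
#'   (parameter-block dimension + 2) for differential-evolution proposals.
#' @param thin Retain every `thin`-th iteration.
#' @param migration_prob Per-iteration probability of a migration sweep.
#' @param burnin_block_iters Raw iterations per burn-in block.
#' @param max_burnin_blocks Maximum number of burn-in blocks.
#' @param final_iterations Retained (post-thinning) draws per chain.
#' @param rhat_threshold Convergence gate on the maximum R-hat.
#' @param seed Integer seed (required at fit time).
#' @return A list with class `sampler_config`.
#' @export
sampler_config <- function(n_chains = NULL, thin = 10L,
                           migration_prob = 0.05,
                           burnin_block_iters = 200L,
                           max_burnin_blocks = 25L,
                           final_iterations = 500L,
                           rhat_threshold = 1.1,
                           seed = NULL) {
  n_par <- length(race_param_names())
  if (is.null(n_chains)) n_chains <- 3L * n_par
  n_chains <- as.integer(n_chains)
  if (n_chains < n_par + 2L) {
    rlang::abort(sprintf("n_chains must be at least %d (parameters + 2)",
                         n_par + 2L))
  }
  if (migration_prob < 0 || migration_prob > 1) {
    rlang::abort("migration_prob must lie in [0, 1]")
  }
  structure(list(n_chains = n_chains, thin = as.integer(thin),
                 migration_prob = migration_prob,
                 burnin_block_iters = as.integer(burnin_block_iters),
                 max_burnin_blocks = as.integer(max_burnin_blocks),
                 final_iterations = as.integer(final_iterations),
                 rhat_threshold = rhat_threshold, seed = seed),
            class = "sampler_config")
}

# log density of a normal truncated to [lower, upper]
dtnorm_log <- function(x, mean, sd, lower, upper) {
  z <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  out <- dnorm(x, mean, sd, log = TRUE) - base::log(z)
  out[x < lower | x > upper] <- -Inf
  out
}
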