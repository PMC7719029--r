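# Shared fixtures: representative race-model parameter sets and small
# configurations used across the suite.

typical_params <- function() {
  race_params(go_match = c(0.55, 0.08, 0.15),
              go_mismatch = c(0.70, 0.10, 0.20),
              stop = c(0.20, 0.03, 0.05),
              p_tf = 0.05, p_gf = 0.02)
}

# parameter sets spanning slow/fast go and stop processes and failure mixes
param_grid <- function() {
  list(
    typical_params(),
    race_params(c(0.45, 0.05, 0.10), c(0.55, 0.06, 0.12),
                c(0.15, 0.02, 0.04), p_tf = 0, p_gf = 0),
    race_params(c(0.70, 0.12, 0.30), c(0.85, 0.15, 0.35),
                c(0.30, 0.06, 0.15), p_tf = 0.15, p_gf = 0.08),
    race_params(c(0.50, 0.05, 0.10), c(0.60, 0.05, 0.10),
                c(0.25, 0.08, 0.20), p_tf = 0.3, p_gf = 0.01),
    race_params(c(0.60, 0.10, 0.20), c(0.75, 0.10, 0.25),
                c(0.18, 0.04, 0.08), p_tf = 0.02, p_gf = 0.15))
}

small_task <- function() {
  task_config(blocks = 2L, trials_per_block = 150L, n_go = 225L,
              n_nogo = 25L, n_stop = 50L, practice_trials = 0L)
}

tiny_sampler <- function(seed = 1) {
  sampler_config(n_chains = 13L, thin = 1L, burnin_block_iters = 40L,
                 max_burnin_blocks = 2L, final_iterations = 12L, seed = seed)
}

# one-row trial record helper
trial_row <- function(trial_type, stimulus = "left", ssd = NA_real_,
                      response = "none", rt = NA_real_) {
  tibble::tibble(trial_type = trial_type, stimulus = stimulus, ssd = ssd,
                 response = response, rt = rt)
}
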