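test_that("DE-MC moves behave at the degenerate corners", {
  states <- matrix(rnorm(12), 4, 3)
  # a target that is -Inf everywhere off the current states: nothing moves
  lt_neginf <- function(x) -Inf
  st <- withr::with_seed(1, demc_step(states, lt_neginf,
                                      lp = rep(0, 4)))
  expect_identical(st$states, states)
  expect_false(any(st$accepted))
  # gamma = 0, eps = 0: proposal equals the state, always accepted
  lt <- function(x) -sum(x^2) / 2
  st2 <- withr::with_seed(2, demc_step(states, lt, gamma = 0, eps = 0))
  expect_equal(st2$states, states)
  expect_true(all(st2$accepted))
  expect_error(demc_step(states[1:2, ], lt), "3 chains")
})

test_that("DE-MC recovers the moments of a known Gaussian target", {
  s <- matrix(c(1, 0.6, 0.6, 1), 2)
  si <- solve(s)
  lt <- function(x) -0.5 * drop(t(x) %*% si %*% x)
  init <- matrix(rnorm(20 * 2, 0, 2), 20, 2)
  draws <- demc_sample(lt, init, n_iter = 3000, burnin = 1000,
                       migration_prob = 0.05, seed = 3)
  flat <- apply(draws, 3, as.vector)
  expect_equal(colMeans(flat), c(0, 0), tolerance = 0.1)
  expect_equal(cov(flat), s, tolerance = 0.25)
})

test_that("split-chain R-hat separates mixing from non-mixing chains", {
  expect_equal(rhat(matrix(5, 100, 4)), 1)
  set.seed(4)
  good <- matrix(rnorm(4e4), 1e4, 4)
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(100, 0), rnorm(100, 50))
  expect_gt(rhat(bad), 10)
  # within-chain trend is caught by splitting
  trend <- matrix(rep(seq(0, 10, length.out = 100), 3), 100, 3)
  expect_gt(rhat(trend + rnorm(300, 0, 0.1)), 1.5)
  expect_error(rhat(matrix(1, 100, 1)), "2 chains")
  expect_error(rhat(matrix(1, 3, 4)), "4 iterations")
})

test_that("log posterior decomposes into hyperprior, group and likelihood", {
  priors <- race_priors()
  loc <- priors$loc_mean
  scale <- rep(0.3, 11)
  # zero participants: hyperprior only, against a hand-written oracle
  dtn <- function(x, m, s, a, b) {
    dnorm(x, m, s, log = TRUE) - log(pnorm(b, m, s) - pnorm(a, m, s))
  }
  oracle_hyper <- sum(dtn(loc, priors$loc_mean, priors$loc_sd,
                          priors$lower, priors$upper)) +
    sum(dtn(scale, 0, priors$scale_sd, priors$scale_lower,
            priors$scale_upper))
  expect_equal(log_posterior(NULL, NULL, loc, scale, priors), oracle_hyper)
  # two participants: brute-force composition from exported pieces
  cfg <- small_task()
  ses <- dplyr::bind_rows(
    dplyr::mutate(run_session(typical_params(),
                              build_trial_sequence(cfg, seed = 51), cfg,
                              seed = 52), participant_id = "a"),
    dplyr::mutate(run_session(typical_params(),
                              build_trial_sequence(cfg, seed = 53), cfg,
                              seed = 54), participant_id = "b"))
  phi <- rbind(a = c(0.56, 0.09, 0.14, 0.72, 0.11, 0.19,
                     0.21, 0.04, 0.06, -1.6, -2.0),
               b = c(0.52, 0.07, 0.16, 0.68, 0.10, 0.21,
                     0.19, 0.03, 0.05, -1.7, -2.1))
  colnames(phi) <- race_param_names()
  got <- log_posterior(ses, phi, loc, scale, priors)
  oracle <- oracle_hyper
  for (id in c("a", "b")) {
    nat <- phi[id, ]
    nat[10:11] <- pnorm(nat[10:11])
    trials <- analysable_trials(ses[ses$participant_id == id, ])
    oracle <- oracle + as.numeric(loglik_session(trials, nat)) +
      sum(dtn(phi[id, ], loc, scale, priors$lower, priors$upper))
  }
  expect_equal(got, oracle, tolerance = 1e-8)
  # out-of-support participant parameters give -Inf
  phi_bad <- phi
  phi_bad[1, "sigma_stop"] <- -0.1
  expect_equal(log_posterior(ses, phi_bad, loc, scale, priors), -Inf)
})

make_tiny_fit <- function(seed = 61, n_part = 2) {
  cfg <- small_task()
  spec <- cohort_spec(n_controls = 0, n_patients = n_part, seed = seed)
  parts <- generate_participants(spec)
  ses <- generate_sessions(parts, cfg, seed = seed + 1)
  fit <- suppressWarnings(
    fit_race_model(ses, config = tiny_sampler(seed + 2), group = "patient"))
  list(fit = fit, parts = parts, ses = ses, cfg = cfg)
}

test_that("the hierarchical fit is reproducible and respects supports", {
  a <- make_tiny_fit()
  b <- make_tiny_fit()
  expect_identical(a$fit$draws, b$fit$draws)
  td <- tidy(a$fit)
  expect_true(all(td$value[td$parameter %in% c("p_tf", "p_gf") &
                             td$level == "participant"] >= 0))
  expect_true(all(td$value[td$parameter %in% c("p_tf", "p_gf") &
                             td$level == "participant"] <= 1))
  pos <- td$parameter %in% race_param_names()[1:9] &
    td$level == "participant"
  expect_true(all(td$value[pos] > 0))
  expect_equal(dim(a$fit$draws$phi)[1], 13)
  g <- glance(a$fit)
  expect_equal(g$n_participants, 2)
  expect_s3_class(autoplot(a$fit), "ggplot")
  expect_s3_class(autoplot(a$fit, type = "trace"), "ggplot")
})

test_that("default chain count is three chains per model parameter", {
  expect_equal(sampler_config()$n_chains, 33)
  expect_equal(sampler_config()$thin, 10L)
  expect_equal(sampler_config()$migration_prob, 0.05)
  expect_equal(sampler_config()$final_iterations, 500L)
  expect_error(sampler_config(n_chains = 5), "at least 13")
  expect_error(sampler_config(migration_prob = 2), "migration_prob")
})

test_that("SSRT posteriors are aligned draws of mu_stop + tau_stop", {
  a <- make_tiny_fit()
  sp <- ssrt_posterior(a$fit)
  expect_setequal(unique(sp$participant_id), a$fit$participants)
  j_mu <- match("mu_stop", race_param_names())
  j_tau <- match("tau_stop", race_param_names())
  manual <- a$fit$draws$phi[2, 5, 1, j_mu] + a$fit$draws$phi[2, 5, 1, j_tau]
  got <- sp$ssrt[sp$chain == 2 & sp$iteration == 5 &
                   sp$participant_id == a$fit$participants[1]]
  expect_equal(got, manual)
  # tau > 0 implies the SSRT posterior mean exceeds the mu_stop mean
  mu_draws <- tidy(a$fit) |>
    dplyr::filter(.data$parameter == "mu_stop",
                  .data$participant_id == a$fit$participants[1])
  expect_gt(mean(sp$ssrt[sp$participant_id == a$fit$participants[1]]),
            mean(mu_draws$value))
  expect_error(ssrt_posterior(a$fit, "nobody"), "unknown")
})

test_that("posterior predictive checks cover data simulated from the model", {
  a <- make_tiny_fit(seed = 71)
  ppc <- posterior_predictive(a$fit, a$cfg, n_draws = 20, seed = 72)
  td <- tidy(ppc)
  expect_true(all(c("observed", "pred_lo", "pred_hi", "inside") %in%
                    names(td)))
  # data were generated by the model itself: most summaries must fall
  # inside their predictive intervals
  expect_gt(mean(td$inside), 0.8)
  ppc2 <- posterior_predictive(a$fit, a$cfg, n_draws = 20, seed = 72)
  expect_equal(ppc$simulated, ppc2$simulated)
  expect_error(posterior_predictive(a$fit, a$cfg, n_draws = 0), "n_draws")
})
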