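test_that("SSRT is the sum of the stop runner's mu and tau", {
  p <- race_params(c(0.5, 0.05, 0.1), c(0.6, 0.05, 0.1), c(1.0, 0.1, 0.2))
  expect_equal(ssrt_from_params(p), 1.2)
  # invariant to go runners and failure parameters
  q <- race_params(c(0.9, 0.2, 0.4), c(0.3, 0.01, 0.02), c(1.0, 0.1, 0.2),
                   p_tf = 0.4, p_gf = 0.4)
  expect_equal(ssrt_from_params(q), 1.2)
  # tau -> 0 limit: SSRT -> mu
  r <- race_params(c(0.5, 0.05, 0.1), c(0.6, 0.05, 0.1), c(1.0, 0.1, 1e-9))
  expect_equal(ssrt_from_params(r), 1.0, tolerance = 1e-8)
  df <- tibble::as_tibble(as.list(unclass(p)))
  expect_equal(ssrt_from_params(df), 1.2)
})

test_that("trial log-likelihoods match the mixture arithmetic", {
  p <- race_params(c(0.5, 0.05, 0.1), c(0.6, 0.05, 0.1), c(0.2, 0.03, 0.05),
                   p_tf = 0.1, p_gf = 0.3)
  # go omission has probability p_gf
  expect_equal(as.numeric(loglik_trials(trial_row("go_left"), p)), log(0.3))
  # stopping impossible without a trigger and without go failure -> floored
  q <- race_params(c(0.5, 0.05, 0.1), c(0.6, 0.05, 0.1), c(0.2, 0.03, 0.05),
                   p_tf = 1, p_gf = 0)
  ll <- loglik_trials(trial_row("stop", ssd = 0.2), q)
  expect_equal(as.numeric(ll), -745)
  expect_equal(attr(ll, "n_floor"), 1L)
  # go response density: (1 - p_gf) f_match(t) S_mismatch(t)
  t0 <- 0.55
  expected <- log(0.7) + dexgauss(t0, 0.5, 0.05, 0.1, log = TRUE) +
    log(sexgauss(t0, 0.6, 0.05, 0.1))
  got <- loglik_trials(trial_row("go_left", response = "left", rt = t0), p)
  expect_equal(as.numeric(got), expected, tolerance = 1e-10)
  # mismatching response swaps the runner roles
  expected_mm <- log(0.7) + dexgauss(t0, 0.6, 0.05, 0.1, log = TRUE) +
    log(sexgauss(t0, 0.5, 0.05, 0.1))
  got_mm <- loglik_trials(trial_row("go_left", response = "right", rt = t0), p)
  expect_equal(as.numeric(got_mm), expected_mm, tolerance = 1e-10)
  # signal-respond trial: stop survival factor with negative argument is 1,
  # so an RT at or below the SSD reduces to the go-trial density times the
  # trigger mixture at survival one
  d <- 0.6
  got_fast <- loglik_trials(
    trial_row("stop", ssd = d, response = "left", rt = 0.55), p)
  exp_fast <- log(0.7) + dexgauss(0.55, 0.5, 0.05, 0.1, log = TRUE) +
    log(sexgauss(0.55, 0.6, 0.05, 0.1)) +
    log(0.1 + 0.9 * sexgauss(0.55 - d, 0.2, 0.03, 0.05))
  expect_equal(as.numeric(got_fast), exp_fast, tolerance = 1e-10)
})

test_that("analytic outcome probabilities sum to one across the grid", {
  for (p in param_grid()) {
    for (tt in c("go", "stop")) {
      for (d in c(0.05, 0.25, 0.5)) {
        op <- outcome_probs(p, tt, d)
        expect_true(all(op >= 0 & op <= 1))
        expect_equal(sum(op), 1, tolerance = 1e-6)
        if (tt == "go") break # SSD is irrelevant on go trials
      }
    }
  }
})

test_that("no-go trials use delay zero", {
  p <- typical_params()
  ll_nogo <- loglik_trials(trial_row("no_go", ssd = NA_real_), p)
  ll_stop0 <- loglik_trials(trial_row("stop", ssd = 0), p)
  expect_equal(as.numeric(ll_nogo), as.numeric(ll_stop0))
  expect_equal(exp(as.numeric(ll_nogo)), stop_success_prob(p, 0),
               tolerance = 1e-7)
})

test_that("simulator and likelihood agree on outcome frequencies", {
  # the module's central correctness property, scaled to suite runtime;
  # the full-size version runs in the acceptance suite
  set.seed(21)
  n <- 4e4
  for (p in param_grid()[1:3]) {
    for (d in c(0.1, 0.3)) {
      sim <- simulate_trials(rep("stop", n), ssd = d, params = p)
      op <- outcome_probs(p, "stop", d)
      for (k in 1:3) {
        emp <- switch(k, mean(sim$response == sim$stimulus & sim$response != "none"),
                      mean(sim$response != sim$stimulus & sim$response != "none"),
                      mean(sim$response == "none"))
        err <- sqrt(max(op[k] * (1 - op[k]), 1e-8) / n)
        expect_lt(abs(emp - op[k]), 4 * err + 1e-4)
      }
    }
  }
  # and the analytic signal-respond RT density matches simulated RTs
  p <- typical_params()
  sim <- simulate_trials(rep("stop", n), ssd = 0.2, params = p)
  rts <- sim$rt[!is.na(sim$rt)]
  f <- function(t) {
    (dexgauss(t, p["mu_go_match"], p["sigma_go_match"], p["tau_go_match"]) *
       sexgauss(t, p["mu_go_mismatch"], p["sigma_go_mismatch"], p["tau_go_mismatch"]) +
     dexgauss(t, p["mu_go_mismatch"], p["sigma_go_mismatch"], p["tau_go_mismatch"]) *
       sexgauss(t, p["mu_go_match"], p["sigma_go_match"], p["tau_go_match"])) *
      (p["p_tf"] + (1 - p["p_tf"]) * sexgauss(t - 0.2, p["mu_stop"],
                                              p["sigma_stop"], p["tau_stop"]))
  }
  norm <- integrate(f, 0, 5)$value
  med_analytic <- uniroot(function(q) integrate(f, 0, q)$value / norm - 0.5,
                          c(0.2, 2))$root
  expect_equal(median(rts), med_analytic, tolerance = 0.01)
})

test_that("session likelihood is additive and order-invariant", {
  p <- typical_params()
  cfg <- small_task()
  sq <- build_trial_sequence(cfg, seed = 31)
  ses <- analysable_trials(run_session(p, sq, cfg, seed = 32))
  one <- ses[5, ]
  expect_equal(as.numeric(loglik_session(one, p)),
               as.numeric(loglik_trials(one, p)))
  full <- as.numeric(loglik_session(ses, p))
  perm <- as.numeric(loglik_session(ses[sample.int(nrow(ses)), ], p))
  expect_equal(full, perm)
  expect_equal(full, sum(loglik_trials(ses, p)))
  expect_error(loglik_session(ses[0, ], p), "empty")
})

test_that("true parameters beat perturbed ones in expected log-likelihood", {
  p <- typical_params()
  cfg <- small_task()
  set.seed(33)
  lls <- replicate(6, {
    sq <- build_trial_sequence(cfg, seed = sample.int(1e6, 1))
    ses <- analysable_trials(run_session(p, sq, cfg,
                                         seed = sample.int(1e6, 1)))
    worse <- unclass(p)
    worse[c("mu_go_match", "mu_stop")] <- worse[c("mu_go_match", "mu_stop")] * 1.3
    names(worse) <- race_param_names()
    c(true = as.numeric(loglik_session(ses, p)),
      pert = as.numeric(loglik_session(ses, worse)))
  })
  expect_gt(mean(lls["true", ] - lls["pert", ]), 0)
})

test_that("malformed trial records are rejected", {
  p <- typical_params()
  expect_error(loglik_trials(trial_row("go_left", response = "left"), p),
               "rt")
  expect_error(loglik_trials(trial_row("go_left", rt = 0.5), p), "rt")
  expect_error(loglik_trials(trial_row("stop", ssd = -0.1), p), "ssd")
  expect_error(loglik_trials(trial_row("banana"), p), "trial_type")
})
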