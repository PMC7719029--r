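# Hierarchical Bayesian estimation of the race model by differential-
# evolution MCMC (DE-MC). Each chain carries the full model state:
# participant-level parameter vectors (11 per participant, failure
# probabilities on the probit scale) plus group-level location and scale
# for every parameter. Participant blocks and per-parameter group blocks
# are updated by crossover proposals built from differences of other
# chains' states; occasional migration sweeps cyclically swap whole states
# among a random subset of chains.

PROBIT_IDX <- c(10L, 11L)

# sampling-scale matrix -> natural-scale matrix for the likelihood
to_natural <- function(theta) {
  theta[, PROBIT_IDX] <- pnorm(theta[, PROBIT_IDX])
  theta
}

encode_participant_sessions <- function(sessions) {
  need <- "participant_id"
  if (!need %in% names(sessions)) {
    rlang::abort("sessions need a participant_id column")
  }
  sessions <- analysable_trials(sessions)
  split(sessions, sessions$participant_id)
}

# ---------------------------------------------------------------------------
# generic DE-MC move (also the reference implementation validated on
# closed-form targets in the test suite)

de_propose <- function(states, gamma, eps) {
  n <- nrow(states)
  d <- ncol(states)
  # distinct a, b != c, drawn without per-chain loops: offsets 1..n-1 from c
  # give a != c; a second distinct offset gives b != c, b != a
  o1 <- sample.int(n - 1L, n, replace = TRUE)
  o2 <- sample.int(n - 2L, n, replace = TRUE)
  o2 <- o2 + (o2 >= o1)
  a <- (seq_len(n) - 1L + o1) %% n + 1L
  b <- (seq_len(n) - 1L + o2) %% n + 1L
  states + gamma * (states[a, , drop = FALSE] - states[b, , drop = FALSE]) +
    matrix(runif(n * d, -eps, eps), n, d)
}

#' One differential-evolution MCMC step
#'
#' For every chain `c` a crossover proposal
#' `x* = x_c + gamma (x_a - x_b) + epsilon` is formed from two distinct
#' other chains `a, b`, with `gamma = 2.38 / sqrt(2 d)` by default and
#' `epsilon` uniform on `(-eps, eps)` per coordinate, then accepted or
#' rejected by a Metropolis test. With probability `migration_prob` the
#' step is instead a migration sweep: a random subset of chains cyclically
#' proposes to take over the state of its neighbour in the subset, each
#' swap accepted by a Metropolis test.
#'
#' @param states Numeric matrix, chains x parameters (at least 3 chains).
#' @param log_target Function mapping a parameter vector to its log
#'   density; `-Inf` encodes out-of-support proposals.
#' @param lp Optional vector of current log densities (recomputed if
#'   missing).
#' @param gamma Crossover weight; `NULL` for the default.
#' @param eps Half-width of the uniform jitter.
#' @param migration_prob Probability that this step is a migration sweep.
#' @return List with updated `states`, `lp` and the logical `accepted`
#'   vector.
#' @export
demc_step <- function(states, log_target, lp = NULL, gamma = NULL,
                      eps = 0.001, migration_prob = 0) {
  if (nrow(states) < 3) rlang::abort("DE-MC needs at least 3 chains")
  d <- ncol(states)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  if (is.null(lp)) lp <- apply(states, 1, log_target)
  n <- nrow(states)
  if (runif(1) < migration_prob) {
    k <- if (n >= 4) sample(2:max(2L, n %/% 2L), 1L) else 2L
    idx <- sample.int(n, k)
    donors <- idx[c(k, seq_len(k - 1L))]
    old_states <- states
    old_lp <- lp
    acc <- log(runif(k)) < (old_lp[donors] - old_lp[idx])
    states[idx[acc], ] <- old_states[donors[acc], , drop = FALSE]
    lp[idx[acc]] <- old_lp[donors[acc]]
    accepted <- rep(FALSE, n)
    accepted[idx[acc]] <- TRUE
    return(list(states = states, lp = lp, accepted = accepted))
  }
  prop <- de_propose(states, gamma, eps)
  lp_prop <- apply(prop, 1, log_target)
  accepted <- log(runif(n)) < (lp_prop - lp)
  states[accepted, ] <- prop[accepted, , drop = FALSE]
  lp[accepted] <- lp_prop[accepted]
  list(states = states, lp = lp, accepted = accepted)
}

#' Sample an arbitrary target with DE-MC
#'
#' Thin convenience wrapper around [demc_step()] used for validating the
#' sampler on closed-form targets.
#'
#' @param log_target Log-density function of a parameter vector.
#' @param init Matrix of starting states, chains x parameters.
#' @param n_iter Iterations to run.
#' @param burnin Iterations to discard.
#' @param seed Integer seed.
#' @inheritParams demc_step
#' @return Array `chains x retained iterations x parameters`.
#' @export
demc_sample <- function(log_target, init, n_iter, burnin = 0, gamma = NULL,
                        eps = 0.001, migration_prob = 0, seed = 1) {
  withr::with_seed(seed, {
    states <- init
    lp <- apply(states, 1, log_target)
    keep <- array(NA_real_, c(nrow(init), n_iter - burnin, ncol(init)))
    for (it in seq_len(n_iter)) {
      st <- demc_step(states, log_target, lp, gamma, eps, migration_prob)
      states <- st$states
      lp <- st$lp
      if (it > burnin) keep[, it - burnin, ] <- states
    }
    keep
  })
}

# ---------------------------------------------------------------------------
# hierarchical model internals

# log group density of participant values for parameter j (truncated normal
# on the sampling scale)
group_logdens <- function(x, loc, scale, lower, upper) {
  dtnorm_log(x, loc, scale, lower, upper)
}

hyper_logprior_j <- function(loc, scale, pr_j) {
  s_lo <- if ("scale_lower" %in% names(pr_j)) pr_j$scale_lower else 0
  dtnorm_log(loc, pr_j$loc_mean, pr_j$loc_sd, pr_j$lower, pr_j$upper) +
    dtnorm_log(scale, 0, pr_j$scale_sd, s_lo, pr_j$scale_upper)
}

#' Hierarchical log posterior
#'
#' Unnormalised log posterior of the hierarchical race model: the sum of
#' every participant's session log-likelihood, the truncated-normal group
#' density of each participant-level parameter given the group location and
#' scale, and the hyperpriors on the group parameters. Participant
#' parameters are given on the sampling scale: natural seconds for the
#' ex-Gaussian parameters and probit values for `p_tf` and `p_gf` (the
#' likelihood sees `pnorm` of those columns).
#'
#' @param sessions Trial records with a `participant_id` column; practice
#'   and initialisation trials are dropped. May be `NULL` (or empty) with
#'   zero participants, in which case only the hyperprior is returned.
#' @param phi Matrix or data frame of participant parameters, one row per
#'   participant in the order of `sort(unique(sessions$participant_id))`,
#'   columns ordered as [race_param_names()].
#' @param loc,scale Numeric vectors of length 11: group-level location and
#'   scale on the sampling scale.
#' @param priors A [race_priors()] table.
#' @return Scalar log density (`-Inf` outside the support).
#' @export
log_posterior <- function(sessions, phi, loc, scale, priors = race_priors()) {
  lp <- sum(vapply(seq_len(nrow(priors)), function(j) {
    hyper_logprior_j(loc[j], scale[j], priors[j, ])
  }, numeric(1)))
  if (!is.finite(lp)) return(-Inf)
  if (is.null(sessions) || is.null(phi) ||
      (is.data.frame(phi) && nrow(phi) == 0)) {
    return(lp)
  }
  phi <- as.matrix(phi[, race_param_names()])
  data_i <- encode_participant_sessions(sessions)
  if (length(data_i) != nrow(phi)) {
    rlang::abort("phi must have one row per participant")
  }
  for (i in seq_len(nrow(phi))) {
    gd <- sum(group_logdens(phi[i, ], loc, scale, priors$lower, priors$upper))
    if (!is.finite(gd)) return(-Inf)
    nat <- to_natural(phi[i, , drop = FALSE])
    ll <- loglik_session(data_i[[i]], setNames(drop(nat), race_param_names()))
    lp <- lp + gd + as.numeric(ll)
  }
  lp
}

# penalised per-participant MAP used to position the chain ensemble: the
# session likelihood plus a very weak pull towards the prior locations
participant_map <- function(enc_trials, start, priors, g) {
  lower <- priors$lower
  upper <- priors$upper
  negpost <- function(th) {
    if (any(th < lower) || any(th > upper)) return(1e10)
    nat <- matrix(th, 1, 11)
    nat[, PROBIT_IDX] <- pnorm(nat[, PROBIT_IDX])
    res <- session_loglik_multi_cpp(enc_trials$type, enc_trials$responded,
                                    enc_trials$match, enc_trials$rt,
                                    enc_trials$ssd, nat, g$x, g$w)
    -(res$loglik + sum(dnorm(th, priors$loc_mean, 4 * priors$loc_sd,
                             log = TRUE)))
  }
  opt <- stats::optim(start, negpost, method = "Nelder-Mead",
                      control = list(maxit = 1500))
  pmin(pmax(opt$par, lower + 1e-6), upper - 1e-6)
}

# crude per-participant starting values from observed summaries
init_from_data <- function(trials) {
  go <- trials[trials$trial_type %in% c("go_left", "go_right"), ]
  rts <- go$rt[!is.na(go$rt)]
  m <- if (length(rts) > 3) mean(rts) else 0.8
  s <- if (length(rts) > 3) max(sd(rts), 0.03) else 0.2
  tau0 <- min(max(0.8 * s, 0.03), 1.5)
  mu0 <- max(m - tau0, 0.08)
  sigma0 <- min(max(0.6 * s, 0.02), 1.5)
  omit <- if (nrow(go) > 0) mean(is.na(go$rt)) else 0.02
  pgf0 <- qnorm(min(max(omit, 0.005), 0.4))
  c(mu0, sigma0, tau0, mu0 * 1.2, sigma0, tau0,
    max(0.5 * mu0, 0.12), 0.05, 0.08, qnorm(0.05), pgf0)
}

new_ssm_fit <- function(x) structure(x, class = "ssm_fit")

#' Fit the hierarchical race model to a set of sessions
#'
#' Estimates the 11 race-model parameters of every participant and the
#' group-level locations and scales by differential-evolution MCMC (see
#' [sampler_config()] for the schedule). The model should be fitted
#' separately per diagnostic group. Initialisation and practice trials are
#' excluded automatically; participants are expected to have been screened
#' for a sufficient number of stop trials beforehand (see
#' [apply_exclusions()]).
#'
#' @param sessions Trial records for all participants of one group, with a
#'   `participant_id` column and the columns required by
#'   [loglik_trials()].
#' @param priors A [race_priors()] table.
#' @param config A [sampler_config()]; `config$seed` must be set.
#' @param group Optional group label stored with the fit.
#' @return An `ssm_fit` object: retained draws (`chain x iteration` arrays)
#'   for participant-level parameters and group-level location/scale, the
#'   R-hat table, a convergence flag, and the data the model was fitted to.
#'   Use [tidy()], [glance()], [ssrt_posterior()] and
#'   [posterior_predictive()] to work with it.
#' @export
fit_race_model <- function(sessions, priors = race_priors(),
                           config = sampler_config(), group = NULL) {
  if (is.null(config$seed)) rlang::abort("config$seed must be set")
  data_i <- encode_participant_sessions(sessions)
  ids <- names(data_i)
  n_part <- length(ids)
  if (n_part == 0) rlang::abort("no participants in sessions")
  enc <- lapply(data_i, encode_trials)
  n_stop <- vapply(data_i, function(d)
    sum(d$trial_type %in% c("stop", "no_go")), numeric(1))
  if (any(vapply(data_i, nrow, numeric(1)) == 0)) {
    rlang::abort("a participant has no analysable trials")
  }

  nc <- config$n_chains
  np <- 11L
  g <- gl_nodes(32L)
  lower <- priors$lower
  upper <- priors$upper
  gamma_p <- 2.38 / sqrt(2 * np)
  gamma_g <- 2.38 / sqrt(2 * 2)
  gamma_g4 <- 2.38 / sqrt(2 * 4)
  eps <- 0.001
  rw_prob <- 0.15
  # random-walk step sizes, roughly the participant-level posterior scale of
  # each parameter for sessions of a few hundred trials, shrunk by the usual
  # multivariate random-walk factor; the failure probabilities are sampled
  # non-centred (standardised z), hence order-one steps
  rw_step <- c(0.01, 0.005, 0.01, 0.015, 0.01, 0.015,
               0.01, 0.005, 0.01, 0.5, 0.5) * (2.38 / sqrt(np))
  # each runner's (mu, tau) pair is weakly identified along mu + tau = const
  # with limited trials; dedicated moves travel that ridge jointly for all
  # participants and the group location of one runner at a time
  ridge_prob <- 0.1
  ridge_pairs <- list(c(1L, 3L), c(4L, 6L), c(7L, 9L))
  ridge_sd <- 0.03

  # raw likelihood over rows of a natural-scale parameter matrix
  lik_rows <- function(i, nat) {
    res <- session_loglik_multi_cpp(enc[[i]]$type, enc[[i]]$responded,
                                    enc[[i]]$match, enc[[i]]$rt,
                                    enc[[i]]$ssd, nat, g$x, g$w)
    the$n_floor_total <- the$n_floor_total + sum(res$n_floor)
    res$loglik
  }

  withr::with_seed(config$seed, {
    the$n_floor_total <- 0

    # --- initialisation: per-participant penalised MAP, jittered per chain --
    centre <- t(vapply(seq_len(n_part), function(i) {
      participant_map(enc[[i]], init_from_data(data_i[[i]]), priors, g)
    }, numeric(np)))

    # group-level state; the failure probabilities are non-centred, so their
    # participant coordinates are standardised deviations z with phi_probit
    # = loc + scale * z, which removes the hierarchical funnel for the two
    # weakly informed probability parameters
    loc <- matrix(NA_real_, nc, np)
    scl <- matrix(NA_real_, nc, np)
    for (j in seq_len(np)) {
      cm <- mean(centre[, j])
      cs <- max(sd(centre[, j]), 0.05)
      if (n_part == 1) cs <- 0.1
      cs <- max(cs, 0.1 * abs(cm), 0.05)
      loc[, j] <- pmin(pmax(cm + rnorm(nc, 0, 0.5 * cs),
                            lower[j] + 1e-6), upper[j] - 1e-6)
      scl[, j] <- pmin(pmax(cs * exp(rnorm(nc, 0, 0.3)),
                            priors$scale_lower[j] + 1e-6),
                       priors$scale_upper[j] - 1e-6)
    }
    phi <- array(NA_real_, c(nc, n_part, np))
    for (i in seq_len(n_part)) {
      for (j in 1:9) {
        v <- centre[i, j] + rnorm(nc, 0, 3 * rw_step[j])
        phi[, i, j] <- pmin(pmax(v, lower[j] + 1e-6), upper[j] - 1e-6)
      }
      for (j in PROBIT_IDX) {
        p0 <- centre[i, j] + rnorm(nc, 0, 0.3)
        phi[, i, j] <- pmin(pmax((p0 - loc[, j]) / scl[, j], -6 + 1e-6),
                            6 - 1e-6)
      }
      # spread the ensemble along each runner's mu/tau ridge so that
      # crossover proposals include that direction from the start
      for (pr in ridge_pairs) {
        eta <- rnorm(nc, 0, ridge_sd)
        phi[, i, pr[1]] <- pmin(pmax(phi[, i, pr[1]] - eta,
                                     lower[pr[1]] + 1e-6), upper[pr[1]] - 1e-6)
        phi[, i, pr[2]] <- pmin(pmax(phi[, i, pr[2]] + eta,
                                     lower[pr[2]] + 1e-6), upper[pr[2]] - 1e-6)
      }
    }
    # bounds on the sampling scale: z is standardised
    s_lower <- lower
    s_upper <- upper
    s_lower[PROBIT_IDX] <- -6
    s_upper[PROBIT_IDX] <- 6

    # natural-scale matrix for participant i given sampling-scale rows and
    # group state rows (defaults: current state)
    nat_of <- function(theta, l10, s10, l11, s11) {
      nat <- theta
      nat[, 10] <- pnorm(l10 + s10 * theta[, 10])
      nat[, 11] <- pnorm(l11 + s11 * theta[, 11])
      nat
    }

    # --- caches ------------------------------------------------------------
    ll <- matrix(NA_real_, nc, n_part)
    for (i in seq_len(n_part)) {
      ll[, i] <- lik_rows(i, nat_of(matrix(phi[, i, ], nc, np),
                                    loc[, 10], scl[, 10],
                                    loc[, 11], scl[, 11]))
    }
    gld <- array(NA_real_, c(nc, n_part, np))
    refresh_gld <- function(j) {
      if (j %in% PROBIT_IDX) {
        dtnorm_log(matrix(phi[, , j], nc, n_part), 0, 1, -6, 6)
      } else {
        group_logdens(matrix(phi[, , j], nc, n_part), loc[, j], scl[, j],
                      lower[j], upper[j])
      }
    }
    for (j in seq_len(np)) gld[, , j] <- refresh_gld(j)
    hyp <- matrix(NA_real_, nc, np)
    for (j in seq_len(np)) hyp[, j] <- hyper_logprior_j(loc[, j], scl[, j],
                                                        priors[j, ])

    full_lp <- function() {
      rowSums(ll) + apply(gld, 1, sum) + rowSums(hyp)
    }

    one_iteration <- function(update_group = TRUE) {
      # migration sweep: cyclic full-state swaps among a random chain subset
      if (runif(1) < config$migration_prob && nc >= 4) {
        k <- sample(2:(nc %/% 2L), 1L)
        idx <- sample.int(nc, k)
        donors <- idx[c(k, seq_len(k - 1L))]
        lp <- full_lp()
        acc <- log(runif(k)) < (lp[donors] - lp[idx])
        take <- idx[acc]
        give <- donors[acc]
        if (length(take)) {
          phi[take, , ] <<- phi[give, , , drop = FALSE]
          loc[take, ] <<- loc[give, , drop = FALSE]
          scl[take, ] <<- scl[give, , drop = FALSE]
          ll[take, ] <<- ll[give, , drop = FALSE]
          gld[take, , ] <<- gld[give, , , drop = FALSE]
          hyp[take, ] <<- hyp[give, , drop = FALSE]
        }
      }
      # participant-level updates: crossover proposals, mixed with occasional
      # random-walk moves whose scale does not depend on the population
      # spread (guards against degeneracy of the chain ensemble)
      for (i in seq_len(n_part)) {
        cur <- matrix(phi[, i, ], nc, np)
        u_move <- runif(1)
        if (u_move < rw_prob) {
          prop <- cur + matrix(rnorm(nc * np), nc, np) *
            matrix(rw_step, nc, np, byrow = TRUE)
          for (pr in ridge_pairs) {
            eta <- rnorm(nc, 0, ridge_sd)
            prop[, pr[1]] <- prop[, pr[1]] - eta
            prop[, pr[2]] <- prop[, pr[2]] + eta
          }
        } else if (u_move < rw_prob + 0.2) {
          # ridge-only proposal: travel each runner's mu/tau degeneracy at
          # no extra likelihood cost (high acceptance, large steps)
          prop <- cur
          for (pr in ridge_pairs) {
            eta <- rnorm(nc, 0, 2 * ridge_sd)
            prop[, pr[1]] <- prop[, pr[1]] - eta
            prop[, pr[2]] <- prop[, pr[2]] + eta
          }
        } else {
          prop <- de_propose(cur, gamma_p * runif(1, 0.5, 1), eps)
        }
        ok <- rowSums(sweep(prop, 2, s_lower, "<")) == 0 &
          rowSums(sweep(prop, 2, s_upper, ">")) == 0
        if (!any(ok)) next
        llp <- rep(-Inf, nc)
        llp[ok] <- lik_rows(i, nat_of(prop, loc[, 10], scl[, 10],
                                      loc[, 11], scl[, 11])[ok, , drop = FALSE])
        gldp <- matrix(-Inf, nc, np)
        for (j in 1:9) {
          gldp[, j] <- group_logdens(prop[, j], loc[, j], scl[, j],
                                     lower[j], upper[j])
        }
        for (j in PROBIT_IDX) {
          gldp[, j] <- dtnorm_log(prop[, j], 0, 1, -6, 6)
        }
        num <- llp + rowSums(gldp)
        den <- ll[, i] + rowSums(matrix(gld[, i, ], nc, np))
        acc <- ok & (log(runif(nc)) < (num - den))
        if (any(acc)) {
          phi[acc, i, ] <<- prop[acc, , drop = FALSE]
          ll[acc, i] <<- llp[acc]
          gld[acc, i, ] <<- gldp[acc, , drop = FALSE]
        }
      }
      if (!update_group) return(invisible(NULL))
      # group-level (location, scale) updates for the centred parameters:
      # crossover mixed with random-walk moves (multiplicative for the
      # scale, with the log-normal proposal correction)
      for (j in 1:9) {
        cur <- cbind(loc[, j], scl[, j])
        lqr <- 0
        if (runif(1) < rw_prob) {
          prop <- cbind(cur[, 1] + rnorm(nc, 0, pmax(0.2 * cur[, 2], 0.01)),
                        cur[, 2] * exp(rnorm(nc, 0, 0.3)))
          lqr <- base::log(prop[, 2]) - base::log(cur[, 2])
        } else {
          prop <- de_propose(cur, gamma_g * runif(1, 0.5, 1), eps)
        }
        ok <- prop[, 1] >= lower[j] & prop[, 1] <= upper[j] &
          prop[, 2] >= priors$scale_lower[j] &
          prop[, 2] <= priors$scale_upper[j]
        prop[!ok, 1] <- loc[!ok, j]
        prop[!ok, 2] <- scl[!ok, j]
        phij <- matrix(phi[, , j], nc, n_part)
        gldj <- group_logdens(phij, prop[, 1], prop[, 2], lower[j], upper[j])
        hypj <- hyper_logprior_j(prop[, 1], prop[, 2], priors[j, ])
        num <- rowSums(gldj) + hypj
        num[!ok] <- -Inf
        den <- rowSums(matrix(gld[, , j], nc, n_part)) + hyp[, j]
        acc <- log(runif(nc)) < (num - den + lqr)
        if (any(acc)) {
          loc[acc, j] <<- prop[acc, 1]
          scl[acc, j] <<- prop[acc, 2]
          gld[acc, , j] <<- gldj[acc, , drop = FALSE]
          hyp[acc, j] <<- hypj[acc]
        }
      }
      # group-location ridge blocks: joint (loc_mu down, loc_tau up) moves
      # cost no likelihood evaluations, only group densities
      for (pr in ridge_pairs) {
        jm <- pr[1]
        jt <- pr[2]
        delta <- rnorm(nc, 0, 0.02)
        nlm <- loc[, jm] - delta
        nlt <- loc[, jt] + delta
        ok <- nlm > lower[jm] & nlm < upper[jm] &
          nlt > lower[jt] & nlt < upper[jt]
        nlm[!ok] <- loc[!ok, jm]
        nlt[!ok] <- loc[!ok, jt]
        gm <- group_logdens(matrix(phi[, , jm], nc, n_part), nlm, scl[, jm],
                            lower[jm], upper[jm])
        gt <- group_logdens(matrix(phi[, , jt], nc, n_part), nlt, scl[, jt],
                            lower[jt], upper[jt])
        hm <- hyper_logprior_j(nlm, scl[, jm], priors[jm, ])
        ht <- hyper_logprior_j(nlt, scl[, jt], priors[jt, ])
        dlt <- rowSums(gm - matrix(gld[, , jm], nc, n_part)) +
          rowSums(gt - matrix(gld[, , jt], nc, n_part)) +
          (hm - hyp[, jm]) + (ht - hyp[, jt])
        acc <- ok & (log(runif(nc)) < dlt)
        if (any(acc)) {
          loc[acc, jm] <<- nlm[acc]
          loc[acc, jt] <<- nlt[acc]
          gld[acc, , jm] <<- gm[acc, , drop = FALSE]
          gld[acc, , jt] <<- gt[acc, , drop = FALSE]
          hyp[acc, jm] <<- hm[acc]
          hyp[acc, jt] <<- ht[acc]
        }
      }
      # non-centred group block for the failure probabilities: (loc, scale)
      # of p_tf and p_gf move jointly; participants' standardised deviations
      # stay fixed so the likelihood must be re-evaluated
      probit_group_move()
      # full ridge moves: shift one runner's mu down and tau up by the same
      # amount for every participant and the group location jointly
      for (pr in ridge_pairs) {
        if (runif(1) < ridge_prob) ridge_move(pr)
      }
      invisible(NULL)
    }

    probit_group_move <- function() {
      cur <- cbind(loc[, 10], scl[, 10], loc[, 11], scl[, 11])
      if (runif(1) < rw_prob) {
        prop <- cur + matrix(rnorm(nc * 4), nc, 4) *
          matrix(c(0.12, 0.06, 0.12, 0.06), nc, 4, byrow = TRUE)
      } else {
        prop <- de_propose(cur, gamma_g4 * runif(1, 0.5, 1), eps)
      }
      ok <- prop[, 1] >= lower[10] & prop[, 1] <= upper[10] &
        prop[, 3] >= lower[11] & prop[, 3] <= upper[11] &
        prop[, 2] >= priors$scale_lower[10] &
        prop[, 2] <= priors$scale_upper[10] &
        prop[, 4] >= priors$scale_lower[11] &
        prop[, 4] <= priors$scale_upper[11]
      if (!any(ok)) return(invisible(NULL))
      ll_new <- matrix(-Inf, nc, n_part)
      for (i in seq_len(n_part)) {
        theta <- matrix(phi[, i, ], nc, np)
        nat <- theta
        nat[, 10] <- pnorm(prop[, 1] + prop[, 2] * theta[, 10])
        nat[, 11] <- pnorm(prop[, 3] + prop[, 4] * theta[, 11])
        ll_new[ok, i] <- lik_rows(i, nat[ok, , drop = FALSE])
      }
      hyp10 <- hyper_logprior_j(prop[, 1], prop[, 2], priors[10, ])
      hyp11 <- hyper_logprior_j(prop[, 3], prop[, 4], priors[11, ])
      dlt <- rowSums(ll_new - ll) + (hyp10 - hyp[, 10]) +
        (hyp11 - hyp[, 11])
      acc <- ok & (log(runif(nc)) < dlt)
      if (any(acc)) {
        loc[acc, 10] <<- prop[acc, 1]
        scl[acc, 10] <<- prop[acc, 2]
        loc[acc, 11] <<- prop[acc, 3]
        scl[acc, 11] <<- prop[acc, 4]
        ll[acc, ] <<- ll_new[acc, , drop = FALSE]
        hyp[acc, 10] <<- hyp10[acc]
        hyp[acc, 11] <<- hyp11[acc]
      }
      invisible(NULL)
    }

    ridge_move <- function(pr) {
      jm <- pr[1]
      jt <- pr[2]
      delta <- rnorm(nc, 0, ridge_sd)
      new_mu <- matrix(phi[, , jm], nc, n_part) - delta
      new_tau <- matrix(phi[, , jt], nc, n_part) + delta
      new_locm <- loc[, jm] - delta
      new_loct <- loc[, jt] + delta
      ok <- rowSums(new_mu <= lower[jm] | new_mu >= upper[jm] |
                      new_tau <= lower[jt] | new_tau >= upper[jt]) == 0 &
        new_locm > lower[jm] & new_locm < upper[jm] &
        new_loct > lower[jt] & new_loct < upper[jt]
      if (!any(ok)) return(invisible(NULL))
      ll_new <- matrix(-Inf, nc, n_part)
      for (i in seq_len(n_part)) {
        theta <- matrix(phi[, i, ], nc, np)
        theta[, jm] <- new_mu[, i]
        theta[, jt] <- new_tau[, i]
        nat <- nat_of(theta, loc[, 10], scl[, 10], loc[, 11], scl[, 11])
        ll_new[ok, i] <- lik_rows(i, nat[ok, , drop = FALSE])
      }
      gld_m <- group_logdens(new_mu, new_locm, scl[, jm], lower[jm], upper[jm])
      gld_t <- group_logdens(new_tau, new_loct, scl[, jt], lower[jt], upper[jt])
      hyp_m <- hyper_logprior_j(new_locm, scl[, jm], priors[jm, ])
      hyp_t <- hyper_logprior_j(new_loct, scl[, jt], priors[jt, ])
      dlt <- rowSums(ll_new - ll) +
        rowSums(gld_m - matrix(gld[, , jm], nc, n_part)) +
        rowSums(gld_t - matrix(gld[, , jt], nc, n_part)) +
        (hyp_m - hyp[, jm]) + (hyp_t - hyp[, jt])
      acc <- ok & (log(runif(nc)) < dlt)
      if (any(acc)) {
        phi[acc, , jm] <<- new_mu[acc, , drop = FALSE]
        phi[acc, , jt] <<- new_tau[acc, , drop = FALSE]
        loc[acc, jm] <<- new_locm[acc]
        loc[acc, jt] <<- new_loct[acc]
        ll[acc, ] <<- ll_new[acc, , drop = FALSE]
        gld[acc, , jm] <<- gld_m[acc, , drop = FALSE]
        gld[acc, , jt] <<- gld_t[acc, , drop = FALSE]
        hyp[acc, jm] <<- hyp_m[acc]
        hyp[acc, jt] <<- hyp_t[acc]
      }
      invisible(NULL)
    }

    verbose <- isTRUE(getOption("stopsig.verbose"))
    # recorded participant draws carry the implied probit values, not the
    # standardised deviations, so downstream summaries see the natural
    # parameterisation
    record_phi <- function() {
      out <- phi
      for (j in PROBIT_IDX) {
        out[, , j] <- loc[, j] + scl[, j] * matrix(phi[, , j], nc, n_part)
      }
      out
    }
    run_block <- function(n_keep, label = "") {
      kp <- array(NA_real_, c(nc, n_keep, n_part, np))
      kl <- array(NA_real_, c(nc, n_keep, np))
      ks <- array(NA_real_, c(nc, n_keep, np))
      t0 <- Sys.time()
      for (t in seq_len(n_keep)) {
        for (s in seq_len(config$thin)) one_iteration()
        kp[, t, , ] <- record_phi()
        kl[, t, ] <- loc
        ks[, t, ] <- scl
        if (verbose && t %% 50 == 0) {
          rlang::inform(sprintf("  %s %d/%d draws (%.1fs)", label, t, n_keep,
                                as.numeric(Sys.time() - t0, units = "secs")))
        }
      }
      list(phi = kp, loc = kl, scale = ks)
    }

    max_rhat_of <- function(bl) {
      rs <- c(
        vapply(seq_len(np), function(j)
          rhat(t(bl$loc[, , j])), numeric(1)),
        vapply(seq_len(np), function(j)
          rhat(t(bl$scale[, , j])), numeric(1)))
      for (i in seq_len(n_part)) {
        rs <- c(rs, vapply(seq_len(np), function(j)
          rhat(t(bl$phi[, , i, j])), numeric(1)))
      }
      max(rs, na.rm = TRUE)
    }

    # --- adaptation: let participants differentiate under a broad, fixed
    # group level, then re-seed the group parameters from the realised
    # participant spread (avoids the hierarchical funnel trapping the
    # ensemble at a collapsed group scale)
    for (s in seq_len(config$burnin_block_iters)) one_iteration(FALSE)
    implied <- record_phi()
    for (j in seq_len(np)) {
      pm <- matrix(implied[, , j], nc, n_part)
      m <- rowMeans(pm)
      s <- if (n_part > 1) apply(pm, 1, sd) else rep(0.1, nc)
      loc[, j] <- pmin(pmax(m, lower[j] + 1e-6), upper[j] - 1e-6)
      scl[, j] <- pmin(pmax(s * exp(rnorm(nc, 0, 0.2)),
                            priors$scale_lower[j] + 1e-6),
                       priors$scale_upper[j] - 1e-6)
      if (j %in% PROBIT_IDX) {
        phi[, , j] <- pmin(pmax((pm - loc[, j]) / scl[, j], -6 + 1e-6),
                           6 - 1e-6)
      }
      gld[, , j] <- refresh_gld(j)
      hyp[, j] <- hyper_logprior_j(loc[, j], scl[, j], priors[j, ])
    }
    # implied probit values moved slightly where z was clamped: refresh ll
    for (i in seq_len(n_part)) {
      ll[, i] <- lik_rows(i, nat_of(matrix(phi[, i, ], nc, np),
                                    loc[, 10], scl[, 10],
                                    loc[, 11], scl[, 11]))
    }

    # --- burn-in with R-hat gate -------------------------------------------
    converged <- FALSE
    blocks_used <- 0L
    keep_per_block <- max(4L, config$burnin_block_iters %/% config$thin)
    for (b in seq_len(config$max_burnin_blocks)) {
      bl <- run_block(keep_per_block, sprintf("burn-in block %d", b))
      blocks_used <- b
      mr <- max_rhat_of(bl)
      if (verbose) {
        rlang::inform(sprintf("burn-in block %d: gate R-hat %.3f", b, mr))
      }
      if (mr < config$rhat_threshold) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      rlang::warn(sprintf(
        "R-hat gate not passed after %d burn-in blocks; samples may not have converged",
        blocks_used))
    }

    # --- sampling phase ----------------------------------------------------
    draws <- run_block(config$final_iterations, "sampling")

    rhat_tbl <- dplyr::bind_rows(
      tibble::tibble(level = "group", participant_id = NA_character_,
                     parameter = paste0(race_param_names(), "_loc"),
                     rhat = vapply(seq_len(np), function(j)
                       rhat(t(draws$loc[, , j])), numeric(1))),
      tibble::tibble(level = "group", participant_id = NA_character_,
                     parameter = paste0(race_param_names(), "_scale"),
                     rhat = vapply(seq_len(np), function(j)
                       rhat(t(draws$scale[, , j])), numeric(1))),
      dplyr::bind_rows(lapply(seq_len(n_part), function(i) {
        tibble::tibble(level = "participant", participant_id = ids[i],
                       parameter = race_param_names(),
                       rhat = vapply(seq_len(np), function(j)
                         rhat(t(draws$phi[, , i, j])), numeric(1)))
      })))

    new_ssm_fit(list(
      draws = draws, participants = ids, group = group,
      priors = priors, config = config,
      n_stop_trials = setNames(as.numeric(n_stop), ids),
      rhat = rhat_tbl,
      converged = converged && all(rhat_tbl$rhat < config$rhat_threshold),
      burnin_blocks_used = blocks_used,
      n_floor = the$n_floor_total,
      sessions = tibble::as_tibble(sessions)))
  })
}

#' Split-chain potential scale reduction statistic (R-hat)
#'
#' Gelman-Rubin convergence diagnostic with each chain split in half, so
#' within-chain trends inflate the statistic. Values near 1 indicate
#' mixing; values above about 1.1 indicate non-convergence. When all
#' sequences are constant and equal the statistic is reported as 1.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains and 4
#'   iterations).
#' @return Scalar R-hat (>= 1 up to floating error).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) rlang::abort("R-hat needs at least 2 chains")
  if (nrow(x) < 4) rlang::abort("R-hat needs at least 4 iterations per chain")
  n2 <- nrow(x) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(c) {
    cbind(x[seq_len(n2), c], x[n2 + seq_len(n2), c])
  }))
  w <- mean(apply(halves, 2, var))
  b <- n2 * var(colMeans(halves))
  if (!is.finite(w) || w <= 0) {
    return(if (!is.finite(b) || b <= 1e-300) 1 else Inf)
  }
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

#' Posterior distribution of SSRT per participant
#'
#' For every retained draw, SSRT is the participant's `mu_stop + tau_stop`.
#' Draw indexing (chain, iteration) is preserved so that draws are aligned
#' across participants for the correlation analysis.
#'
#' @param fit An `ssm_fit`.
#' @param participants Participant ids to extract (default all).
#' @return Tibble with columns `chain`, `iteration`, `participant_id`,
#'   `ssrt`.
#' @export
ssrt_posterior <- function(fit, participants = NULL) {
  stopifnot(inherits(fit, "ssm_fit"))
  if (is.null(participants)) participants <- fit$participants
  unknown <- setdiff(participants, fit$participants)
  if (length(unknown)) {
    rlang::abort(paste0("unknown participants: ", toString(unknown)))
  }
  nc <- dim(fit$draws$phi)[1]
  nk <- dim(fit$draws$phi)[2]
  j_mu <- match("mu_stop", race_param_names())
  j_tau <- match("tau_stop", race_param_names())
  purrr::map_dfr(participants, function(id) {
    i <- match(id, fit$participants)
    tibble::tibble(
      chain = rep(seq_len(nc), nk),
      iteration = rep(seq_len(nk), each = nc),
      participant_id = id,
      ssrt = as.vector(fit$draws$phi[, , i, j_mu] +
                       fit$draws$phi[, , i, j_tau]))
  })
}
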