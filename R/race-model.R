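# Gauss-Legendre nodes for the successful-stop integral, cached per session.
the <- new.env(parent = emptyenv())

gl_nodes <- function(n = 64L) {
  key <- paste0("gl", n)
  if (is.null(the[[key]])) {
    g <- pracma::gaussLegendre(n, 0, 1)
    the[[key]] <- list(x = g$x, w = g$w)
  }
  the[[key]]
}

# Validate a trial table and encode it for the compiled likelihood.
# Required columns: trial_type, stimulus, ssd, response, rt.
encode_trials <- function(trials) {
  need <- c("trial_type", "stimulus", "ssd", "response", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    rlang::abort(paste0("trial table is missing columns: ",
                        paste(miss, collapse = ", ")))
  }
  tt <- as.character(trials$trial_type)
  bad <- !tt %in% c("go_left", "go_right", "stop", "no_go")
  if (any(bad)) rlang::abort("unknown trial_type values")
  is_stop <- tt %in% c("stop", "no_go")
  resp <- as.character(trials$response)
  resp[is.na(resp)] <- "none"
  responded <- resp != "none"
  rt <- trials$rt
  if (any(responded & (is.na(rt) | rt <= 0))) {
    rlang::abort("rt must be present and positive exactly when a response was made")
  }
  if (any(!responded & !is.na(rt))) {
    rlang::abort("rt must be absent when response is 'none'")
  }
  ssd <- trials$ssd
  ssd[tt == "no_go"] <- 0
  if (any(is_stop & (is.na(ssd) | ssd < 0))) {
    rlang::abort("stop trials need a nonnegative ssd")
  }
  list(
    type = as.integer(is_stop),
    responded = as.integer(responded),
    match = as.integer(responded & resp == as.character(trials$stimulus)),
    rt = ifelse(is.na(rt), 0, as.numeric(rt)),
    ssd = ifelse(is.na(ssd), 0, as.numeric(ssd))
  )
}

#' Trial-level log-likelihood under the race model
#'
#' Computes the log-likelihood of each trial record under the three-runner
#' ex-Gaussian race model with go-failure (`p_gf`) and trigger-failure
#' (`p_tf`) mixtures. Outcome densities are:
#' * go trial, response at time t: `(1 - p_gf) f_resp(t) S_other(t)`, where
#'   the responding runner is the matching or mismatching go runner;
#' * go omission: `p_gf`;
#' * stop / no-go trial, response at t with delay d:
#'   `(1 - p_gf) f_resp(t) S_other(t) [p_tf + (1 - p_tf) S_stop(t - d)]`;
#' * stop / no-go trial, no response:
#'   `p_gf + (1 - p_gf)(1 - p_tf) P(stop wins | all started)`, with the
#'   stop-wins probability computed by Gauss-Legendre quadrature.
#'
#' No-go trials are stop trials with delay zero. Trials whose probability
#' underflows are floored at log = -745 and counted in the `n_floor`
#' attribute rather than returning `-Inf`.
#'
#' @param trials Data frame of trial records with columns `trial_type`
#'   (`go_left`, `go_right`, `stop`, `no_go`), `stimulus` (`left`/`right`),
#'   `ssd` (seconds; ignored for go trials), `response` (`left`, `right`,
#'   `none` or `NA`) and `rt` (seconds, `NA` for no response).
#' @param params Race parameters (see [race_params()]).
#' @return Numeric vector of per-trial log-likelihoods with attribute
#'   `n_floor` (number of floored trials).
#' @export
loglik_trials <- function(trials, params) {
  p <- as_race_params(params)
  enc <- encode_trials(trials)
  g <- gl_nodes()
  res <- trial_loglik_cpp(enc$type, enc$responded, enc$match, enc$rt,
                          enc$ssd, unname(p), g$x, g$w)
  out <- res$loglik
  attr(out, "n_floor") <- res$n_floor
  out
}

#' Session log-likelihood
#'
#' Sum of [loglik_trials()] over all rows. Initialisation go trials and
#' practice trials must be excluded upstream (see [analysable_trials()]).
#'
#' @inheritParams loglik_trials
#' @return Scalar log-likelihood with attribute `n_floor`.
#' @export
loglik_session <- function(trials, params) {
  if (nrow(trials) == 0) rlang::abort("empty trial table")
  ll <- loglik_trials(trials, params)
  out <- sum(ll)
  attr(out, "n_floor") <- attr(ll, "n_floor")
  out
}

#' Drop trials that do not enter the likelihood
#'
#' Removes practice trials and the leading go trials of each block that are
#' used only to initialise the staircase.
#'
#' @param trials Trial table with logical columns `is_init_go` and
#'   (optionally) `is_practice`.
#' @return Filtered tibble.
#' @export
analysable_trials <- function(trials) {
  out <- dplyr::filter(trials, !.data$is_init_go)
  if ("is_practice" %in% names(out)) {
    out <- dplyr::filter(out, !.data$is_practice)
  }
  tibble::as_tibble(out)
}

#' Simulate race-model trials
#'
#' Draws the go-failure and trigger-failure indicators, samples the active
#' runners' ex-Gaussian finishing times, and applies the race rules: a
#' response is emitted by whichever go runner finishes first, unless the
#' stop runner (starting at the stop-signal delay) beats both. Go failures
#' produce omissions on every trial type.
#'
#' `simulate_trials()` is vectorised over trials and uses the current RNG
#' state; `simulate_trial()` simulates a single trial, optionally seeded.
#'
#' @param trial_type Character vector: `go_left`, `go_right`, `stop`,
#'   `no_go`.
#' @param ssd Stop-signal delay in seconds (recycled); ignored on go
#'   trials, forced to 0 on no-go trials.
#' @param params Race parameters.
#' @param stimulus Stimulus side `left`/`right` (recycled); defaults to the
#'   side named by go trial types and `left` otherwise.
#' @param seed Optional integer seed (`simulate_trial` only).
#' @return A tibble with columns `trial_type`, `stimulus`, `ssd`,
#'   `response`, `rt`.
#' @export
simulate_trials <- function(trial_type, ssd = 0, params, stimulus = NULL) {
  p <- as_race_params(params)
  n <- length(trial_type)
  ssd <- rep_len(ssd, n)
  if (is.null(stimulus)) {
    stimulus <- ifelse(trial_type == "go_right", "right", "left")
  } else {
    stimulus <- rep_len(stimulus, n)
  }
  is_stop <- trial_type %in% c("stop", "no_go")
  ssd[trial_type == "no_go"] <- 0
  ssd[!is_stop] <- NA_real_

  gf <- runif(n) < p["p_gf"]
  tf <- runif(n) < p["p_tf"]
  t_match <- rexgauss(n, p["mu_go_match"], p["sigma_go_match"], p["tau_go_match"])
  t_mis <- rexgauss(n, p["mu_go_mismatch"], p["sigma_go_mismatch"],
                    p["tau_go_mismatch"])
  t_stop <- rexgauss(n, p["mu_stop"], p["sigma_stop"], p["tau_stop"])

  go_rt <- pmin(t_match, t_mis)
  go_side <- ifelse(t_match <= t_mis, stimulus,
                    ifelse(stimulus == "left", "right", "left"))
  stop_active <- is_stop & !tf & !gf
  stop_abs <- ssd + t_stop
  inhibited <- stop_active & stop_abs < go_rt

  responded <- !gf & !inhibited
  response <- ifelse(responded, go_side, "none")
  rt <- ifelse(responded, go_rt, NA_real_)

  tibble::tibble(trial_type = trial_type, stimulus = stimulus, ssd = ssd,
                 response = response, rt = rt)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(trial_type, ssd = 0, params, stimulus = NULL,
                           seed = NULL) {
  sim <- function() simulate_trials(trial_type[1], ssd[1], params, stimulus)
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Analytic outcome probabilities for one trial type
#'
#' Integrates the race-model outcome densities to give the probability of a
#' matching response, a mismatching response, and no response, for a go
#' trial or a stop/no-go trial at a given delay. Used for posterior
#' predictive summaries and for validating the likelihood against
#' simulation; the three probabilities sum to one.
#'
#' @param params Race parameters.
#' @param trial_type One of `go`, `stop`, `no_go`.
#' @param ssd Stop-signal delay in seconds (0 for no-go).
#' @return Named numeric vector `c(match, mismatch, none)`.
#' @export
outcome_probs <- function(params, trial_type = c("go", "stop", "no_go"),
                          ssd = 0) {
  trial_type <- match.arg(trial_type)
  p <- as_race_params(params)
  if (trial_type == "no_go") ssd <- 0
  d <- if (trial_type == "go") NA_real_ else ssd
  f_m <- function(t) dexgauss(t, p["mu_go_match"], p["sigma_go_match"],
                              p["tau_go_match"])
  s_m <- function(t) sexgauss(t, p["mu_go_match"], p["sigma_go_match"],
                              p["tau_go_match"])
  f_x <- function(t) dexgauss(t, p["mu_go_mismatch"], p["sigma_go_mismatch"],
                              p["tau_go_mismatch"])
  s_x <- function(t) sexgauss(t, p["mu_go_mismatch"], p["sigma_go_mismatch"],
                              p["tau_go_mismatch"])
  s_s <- function(t) sexgauss(t, p["mu_stop"], p["sigma_stop"], p["tau_stop"])
  stop_mix <- if (trial_type == "go") {
    function(t) rep(1, length(t))
  } else {
    function(t) p["p_tf"] + (1 - p["p_tf"]) * s_s(t - d)
  }
  quad <- function(f) {
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12,
                     stop.on.error = FALSE)$value
  }
  p_match <- (1 - p["p_gf"]) * quad(function(t) f_m(t) * s_x(t) * stop_mix(t))
  p_mis <- (1 - p["p_gf"]) * quad(function(t) f_x(t) * s_m(t) * stop_mix(t))
  p_none <- if (trial_type == "go") {
    p["p_gf"]
  } else {
    stop_success_prob(p, d)
  }
  out <- c(match = unname(p_match), mismatch = unname(p_mis),
           none = unname(p_none))
  out
}

#' Probability of a successful stop
#'
#' Analytic probability that a stop (or no-go) trial at delay `ssd` ends
#' with no response: the go process fails to start, or the stop process
#' starts and finishes before both go runners:
#' `p_gf + (1 - p_gf)(1 - p_tf) \int f_stop(u - d) S_match(u) S_mismatch(u) du`.
#'
#' @param params Race parameters.
#' @param ssd Stop-signal delay in seconds.
#' @return Probability in `[0, 1]`.
#' @export
stop_success_prob <- function(params, ssd) {
  p <- as_race_params(params)
  lo <- p["mu_stop"] - 12 * p["sigma_stop"]
  hi <- p["mu_stop"] + 20 * (p["sigma_stop"] + p["tau_stop"])
  win <- stats::integrate(
    function(v) {
      dexgauss(v, p["mu_stop"], p["sigma_stop"], p["tau_stop"]) *
        sexgauss(ssd + v, p["mu_go_match"], p["sigma_go_match"],
                 p["tau_go_match"]) *
        sexgauss(ssd + v, p["mu_go_mismatch"], p["sigma_go_mismatch"],
                 p["tau_go_mismatch"])
    }, lo, hi, rel.tol = 1e-10, abs.tol = 1e-12,
    subdivisions = 500L, stop.on.error = FALSE)$value
  unname(p["p_gf"] + (1 - p["p_gf"]) * (1 - p["p_tf"]) * min(win, 1))
}
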